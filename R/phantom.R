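#' Specification of a synthetic phantom cohort
#'
#' Defines a cohort of phantom eyes with known analytic ground truth,
#' emulating the structure of a paired two-device GA imaging study:
#' fovea-centered volumes, elliptical atrophy lesions with nested
#' per-band extents (EZ-loss extent contains ELM-loss extent contains
#' RPE-loss extent), drusen elevations, extrafoveally placed paraboloid
#' SDD mounds with superior weighting, device-specific band-thickness
#' offsets and SDD visibility, per-acquisition offsets, and independent
#' per-column surface jitter.
#'
#' Defaults describe the emulated cohort: 32 patients contributing 40
#' eyes, 1024 x 49 lattices over a 20 degree field, baseline thicknesses
#' ELM+MZ 20 um / EZ 27 um / RPE 21 um on the standard device with
#' high-resolution offsets -1.5 / +1.1 / -5.1 um, an RPE-loss ellipse of
#' semi-axes 1.0 x 0.5 mm (area pi/2 mm^2) dilated by 0.15 mm for ELM
#' loss and 0.3 mm for EZ loss, and SDD mounds whose visible height is
#' scaled per device.  These are emulation anchors for a published
#' cohort, not ground truth about any patient.
#'
#' @param seed RNG seed for [generate_cohort()].
#' @param n_patients number of patients.
#' @param prob_both_eyes fraction of patients contributing both eyes
#'   (`round(prob_both_eyes * n_patients)` patients contribute two eyes).
#' @param n_ascans,n_bscans,fov_deg,mm_per_deg lattice, see
#'   [make_geometry()].
#' @param devices character vector of device labels (>= 1); all eyes are
#'   acquired on every device on identical lattices with identical fovea
#'   centers (registered follow-up protocol).
#' @param thickness_mean_um,thickness_sd_um named (`ELM_MZ`, `EZ`, `RPE`)
#'   baseline band thickness means and between-eye SDs (um), standard
#'   device scale.
#' @param thickness_patient_sd_um named SDs (um) of a shared per-patient
#'   thickness effect, making fellow eyes of one patient correlated (the
#'   structure the patient-level random intercept accounts for).
#' @param ez_radial_slope_um_per_mm linear increase of EZ band thickness
#'   with eccentricity (um per mm), anchored at `ez_slope_ref_mm` so the
#'   field mean stays near the baseline.
#' @param ez_slope_ref_mm anchor radius of the EZ eccentricity trend.
#' @param device_thickness_offset_um named list (per device) of named
#'   additive band-thickness offsets (um).
#' @param device_sdd_visibility named vector (per device) scaling the
#'   visible SDD mound height.
#' @param lesion_center_mm `c(x, y)` lesion center offset from the fovea
#'   (mm; x image-right, y superior).
#' @param rpe_semi_axes_mm `c(a, b)` semi-axes of the RPE-loss ellipse
#'   (mm); `c(0, 0)` disables the lesion.
#' @param semi_axis_sd_log between-eye lognormal SD of a shared
#'   semi-axis scaling factor (skews loss areas right, as observed
#'   clinically); the factor is truncated so the dilated EZ-loss ellipse
#'   always fits the field of view (lesions larger than the field are
#'   rejected).
#' @param margin_elm_mm,margin_ez_mm dilation of the ELM- and EZ-loss
#'   ellipses beyond the RPE-loss semi-axes (mm); requires
#'   `margin_ez_mm >= margin_elm_mm >= 0`.
#' @param drusen_count,drusen_height_um,drusen_sigma_mm Gaussian drusen
#'   elevations of the RPE reference surface (affect all surfaces
#'   equally, hence no band thickness).
#' @param sdd_count number of SDD mounds attempted per eye.
#' @param sdd_height_um,sdd_height_sd_um,sdd_radius_mm,sdd_radius_sd_mm
#'   paraboloid mound peak height (um) and footprint radius (mm)
#'   distributions.
#' @param sdd_min_radial_mm,sdd_max_radial_mm radial annulus of mound
#'   centers; the minimum excludes the central 1-mm circle.
#' @param sdd_superior_weight sampling weight of the superior quadrant
#'   relative to each other quadrant.
#' @param sdd_disruption_height_um visible mound height above which the
#'   column is flagged as SDD-disrupted EZ (counts as EZ loss).
#' @param acquisition_offset_sd_um SD of a per-eye x device x band
#'   session-level thickness offset (um), the between-acquisition
#'   variability of a follow-up scan.
#' @param jitter_sd_um SD of independent per-surface per-column Gaussian
#'   jitter (um), residual reader-correction error; crossings introduced
#'   by jitter are projected back onto the anterior-to-posterior
#'   ordering.
#' @param sdd_threshold_um threshold used in the closed-form truth for
#'   visible SDD volume (matches the quantification default).
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(
    seed = 1L, n_patients = 32L, prob_both_eyes = 0.25,
    n_ascans = 1024L, n_bscans = 49L, fov_deg = 20, mm_per_deg = 0.293,
    devices = c("standard", "high_res"),
    thickness_mean_um = c(ELM_MZ = 20, EZ = 27, RPE = 21),
    thickness_sd_um = c(ELM_MZ = 2, EZ = 2.5, RPE = 2),
    thickness_patient_sd_um = c(ELM_MZ = 1.5, EZ = 1.5, RPE = 1.5),
    ez_radial_slope_um_per_mm = 1.8, ez_slope_ref_mm = 2.2,
    device_thickness_offset_um = list(
      standard = c(ELM_MZ = 0, EZ = 0, RPE = 0),
      high_res = c(ELM_MZ = -1.5, EZ = 1.1, RPE = -5.1)),
    device_sdd_visibility = c(standard = 1, high_res = 1.5),
    lesion_center_mm = c(0, 0), rpe_semi_axes_mm = c(1.0, 0.5),
    semi_axis_sd_log = 0.25,
    margin_elm_mm = 0.15, margin_ez_mm = 0.3,
    drusen_count = 3L, drusen_height_um = 30, drusen_sigma_mm = 0.2,
    sdd_count = 40L, sdd_height_um = 13, sdd_height_sd_um = 2,
    sdd_radius_mm = 0.24, sdd_radius_sd_mm = 0.03,
    sdd_min_radial_mm = 0.8, sdd_max_radial_mm = 2.6,
    sdd_superior_weight = 1.3,
    sdd_disruption_height_um = 35,
    acquisition_offset_sd_um = 0.5, jitter_sd_um = 1.0,
    sdd_threshold_um = 4) {
  if (!length(devices)) stop("at least one device is required")
  stopifnot(prob_both_eyes >= 0, prob_both_eyes <= 1, n_patients >= 1)
  stopifnot(all(thickness_sd_um >= 0), jitter_sd_um >= 0,
            acquisition_offset_sd_um >= 0, semi_axis_sd_log >= 0)
  stopifnot(all(rpe_semi_axes_mm >= 0), length(rpe_semi_axes_mm) == 2)
  if (margin_elm_mm < 0 || margin_ez_mm < margin_elm_mm)
    stop("need margin_ez_mm >= margin_elm_mm >= 0 (nested lesion extents)")
  stopifnot(all(thickness_patient_sd_um >= 0))
  for (nm in c("thickness_mean_um", "thickness_sd_um",
               "thickness_patient_sd_um"))
    if (!all(BAND_NAMES %in% names(get(nm))))
      stop(nm, " must be named with ", paste(BAND_NAMES, collapse = ", "))
  if (!setequal(names(device_thickness_offset_um), devices) ||
      !setequal(names(device_sdd_visibility), devices))
    stop("device_thickness_offset_um and device_sdd_visibility must be ",
         "keyed by exactly the simulated devices")
  spec <- as.list(environment())
  structure(spec, class = "phantom_spec")
}

#' Area of an ellipse
#' @param a,b semi-axes (mm).
#' @return `pi * a * b` (mm^2).
#' @export
ellipse_area_mm2 <- function(a, b) pi * a * b

#' Closed-form volume of a paraboloid SDD mound
#'
#' A mound of peak height `h` (um) and footprint radius `r` (um) has the
#' profile `h * (1 - (d/r)^2)`.  Its full volume is `pi/2 * r^2 * h`.
#' The volume registered by thresholded quantification — the full column
#' thickness integrated where the profile strictly exceeds `threshold`
#' — is `pi * h * r^2 * s * (1 - s/2)` with `s = 1 - threshold/h`
#' (0 when `h <= threshold`).
#'
#' @param height_um mound peak height (um).
#' @param radius_um mound footprint radius (um).
#' @param threshold_um registration threshold (um); 0 gives the full
#'   volume.
#' @return volume in um^3 (vectorized).
#' @export
mound_visible_volume_um3 <- function(height_um, radius_um, threshold_um = 0) {
  s <- pmax(0, 1 - threshold_um / height_um)
  ifelse(height_um <= 0, 0, pi * height_um * radius_um^2 * s * (1 - s / 2))
}

# quadrant label of anatomical offsets (x toward image-right, y superior)
.anatomical_quadrant <- function(x_mm, y_mm, laterality) {
  .quadrant_of(x_mm, y_mm, laterality)
}

# rejection-sample SDD mound centers: annulus around the fovea with
# superior weighting, outside the dilated EZ-loss ellipse, mutually
# non-overlapping, inside the field of view.  Returns a data.frame
# (possibly fewer rows than requested).
.place_mounds <- function(spec, lesion, half_x, half_y) {
  n <- spec$sdd_count
  if (n < 1) return(data.frame(x = numeric(0), y = numeric(0),
                               r0 = numeric(0), h0 = numeric(0)))
  w <- c(spec$sdd_superior_weight, 1, 1, 1)  # superior, left, inferior, right
  starts <- c(45, 135, 225, 315)
  xs <- ys <- r0s <- h0s <- numeric(0)
  for (i in seq_len(n)) {
    placed <- FALSE
    for (try in seq_len(500)) {
      r0 <- max(0.08, stats::rnorm(1, spec$sdd_radius_mm, spec$sdd_radius_sd_mm))
      h0 <- max(5, stats::rnorm(1, spec$sdd_height_um, spec$sdd_height_sd_um))
      rad <- stats::runif(1, spec$sdd_min_radial_mm, spec$sdd_max_radial_mm)
      q <- sample.int(4, 1, prob = w)
      ang <- stats::runif(1, starts[q], starts[q] + 90) * pi / 180
      x <- rad * cos(ang); y <- rad * sin(ang)
      if (abs(x) > half_x - r0 - 0.02 || abs(y) > half_y - r0 - 0.02) next
      if (!is.null(lesion)) {
        ael <- lesion$a_ez + r0 + 0.05; bel <- lesion$b_ez + r0 + 0.05
        if (((x - lesion$cx) / ael)^2 + ((y - lesion$cy) / bel)^2 <= 1) next
      }
      if (length(xs) &&
          any(sqrt((xs - x)^2 + (ys - y)^2) <= r0s + r0 + 0.01)) next
      xs <- c(xs, x); ys <- c(ys, y); r0s <- c(r0s, r0); h0s <- c(h0s, h0)
      placed <- TRUE
      break
    }
    if (!placed) next
  }
  data.frame(x = xs, y = ys, r0 = r0s, h0 = h0s)
}

#' Generate a phantom cohort with analytic ground truth
#'
#' Draws a cohort of paired multi-device phantom eyes from a
#' [phantom_spec()].  For each eye, one [surface_set()] per device is
#' produced on an identical lattice with an identical fovea center; only
#' band-thickness offsets, SDD visibility, per-acquisition offsets and
#' independent jitter differ between devices.  Columns inside a band's
#' lesion ellipse have that band's boundary surfaces set missing.  SDD
#' mounds are inserted as a gap between `EZ_outer` and `RPE_inner`,
#' lifting the EZ/ELM complex anteriorly above the deposit.
#'
#' Ground truth is computed from closed forms only (ellipse areas
#' `pi*a*b`, paraboloid mound volumes) and never calls the
#' quantification functions.
#'
#' @param spec a [phantom_spec()].
#' @return An object of class `phantom_cohort`: list with
#'   `surface_sets` (flat named list, `"<eye_id>.<device>"`), `truth`
#'   (list of data frames `loss`, `thickness`, `sdd`), and `spec`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed)
  nb <- spec$n_bscans; na_ <- spec$n_ascans
  fovea <- c(floor(nb / 2) + 1L, floor(na_ / 2) + 1L)

  # cohort roster: which patients contribute both eyes
  n_both <- round(spec$prob_both_eyes * spec$n_patients)
  pids <- sprintf("P%02d", seq_len(spec$n_patients))
  both <- if (n_both > 0) sample(pids, n_both) else character(0)
  eyes <- list()
  for (p in pids) {
    lats <- if (p %in% both) c("OD", "OS") else sample(c("OD", "OS"), 1)
    for (lat in lats)
      eyes[[length(eyes) + 1]] <- list(patient_id = p, laterality = lat,
                                       eye_id = paste0(p, "_", lat))
  }

  geom0 <- make_geometry(fov_deg = spec$fov_deg, n_ascans = na_,
                         n_bscans = nb, mm_per_deg = spec$mm_per_deg)
  half_x <- (na_ - 1) * lateral_spacing_um(geom0) / 2000
  half_y <- (nb - 1) * geom0$bscan_spacing_um / 2000

  # column offsets from the fovea (mm), shared by all eyes
  xs <- (seq_len(na_) - fovea[2]) * lateral_spacing_um(geom0) / 1000
  ys <- (seq_len(nb) - fovea[1]) * geom0$bscan_spacing_um / 1000
  X <- matrix(xs, nb, na_, byrow = TRUE)
  Y <- matrix(ys, nb, na_)
  R <- sqrt(X^2 + Y^2)

  surface_sets <- list()
  truth_loss <- truth_thick <- truth_sdd <- truth_mounds <- list()
  ring_rbar <- {  # mean eccentricity per ETDRS ring over the lattice
    rr <- c(0.5, 1.5, 3.0)
    ring <- cut(R, c(0, rr, Inf), right = FALSE,
                labels = c("center", "parafoveal_ring", "perifoveal_ring",
                           "outside"))
    tapply(R, ring, mean)
  }

  # shared per-patient thickness effects (fellow-eye correlation)
  pat_eff <- matrix(stats::rnorm(
    length(pids) * length(BAND_NAMES), 0,
    rep(spec$thickness_patient_sd_um[BAND_NAMES], each = length(pids))),
    nrow = length(pids), dimnames = list(pids, BAND_NAMES))

  for (eye in eyes) {
    base_t <- vapply(BAND_NAMES, function(b)
      max(5, stats::rnorm(1, spec$thickness_mean_um[[b]] +
                            pat_eff[eye$patient_id, b],
                          spec$thickness_sd_um[[b]])), numeric(1))

    # lesion: shared factor scales both semi-axes, truncated to the field
    lesion <- NULL
    ax <- spec$rpe_semi_axes_mm
    if (all(ax > 0)) {
      f <- exp(stats::rnorm(1, 0, spec$semi_axis_sd_log))
      cx <- spec$lesion_center_mm[1]; cy <- spec$lesion_center_mm[2]
      f_max <- min((half_x - 0.05 - spec$margin_ez_mm - abs(cx)) / ax[1],
                   (half_y - 0.05 - spec$margin_ez_mm - abs(cy)) / ax[2])
      if (f_max < 1)
        stop("lesion (plus EZ margin) cannot fit the field of view")
      f <- min(f, f_max)   # clip policy: only the random factor is truncated
      lesion <- list(
        cx = cx, cy = cy,
        a_rpe = ax[1] * f, b_rpe = ax[2] * f,
        a_elm = ax[1] * f + spec$margin_elm_mm,
        b_elm = ax[2] * f + spec$margin_elm_mm,
        a_ez = ax[1] * f + spec$margin_ez_mm,
        b_ez = ax[2] * f + spec$margin_ez_mm)
    }

    # drusen elevations of the RPE reference surface
    z_ref <- 250 + 10 * (R / 3)^2
    if (spec$drusen_count > 0) {
      for (i in seq_len(spec$drusen_count)) {
        dx <- stats::runif(1, -half_x * 0.8, half_x * 0.8)
        dy <- stats::runif(1, -half_y * 0.8, half_y * 0.8)
        d2 <- (X - dx)^2 + (Y - dy)^2
        z_ref <- z_ref - spec$drusen_height_um *
          exp(-d2 / (2 * spec$drusen_sigma_mm^2))
      }
    }

    mounds <- .place_mounds(spec, lesion, half_x, half_y)
    if (nrow(mounds))
      truth_mounds[[length(truth_mounds) + 1]] <- data.frame(
        eye_id = eye$eye_id, x_mm = mounds$x, y_mm = mounds$y,
        r0_mm = mounds$r0, h0_um = mounds$h0)
    h_base <- matrix(0, nb, na_)   # unit-visibility mound height field
    if (nrow(mounds)) {
      for (i in seq_len(nrow(mounds))) {
        m <- mounds[i, ]
        ai <- which(abs(xs - m$x) <= m$r0)
        bi <- which(abs(ys - m$y) <= m$r0)
        if (!length(ai) || !length(bi)) next
        d2 <- outer((ys[bi] - m$y)^2, (xs[ai] - m$x)^2, "+")
        prof <- m$h0 * pmax(0, 1 - d2 / m$r0^2)
        h_base[bi, ai] <- pmax(h_base[bi, ai], prof)
      }
    }

    in_ellipse <- function(a, b) {
      if (is.null(lesion)) return(matrix(FALSE, nb, na_))
      ((X - lesion$cx) / a)^2 + ((Y - lesion$cy) / b)^2 < 1
    }
    les_rpe <- if (is.null(lesion)) matrix(FALSE, nb, na_) else
      in_ellipse(lesion$a_rpe, lesion$b_rpe)
    les_elm <- if (is.null(lesion)) matrix(FALSE, nb, na_) else
      in_ellipse(lesion$a_elm, lesion$b_elm)
    les_ez <- if (is.null(lesion)) matrix(FALSE, nb, na_) else
      in_ellipse(lesion$a_ez, lesion$b_ez)

    for (dev in spec$devices) {
      off <- spec$device_thickness_offset_um[[dev]]
      vis <- spec$device_sdd_visibility[[dev]]
      acq <- stats::rnorm(length(BAND_NAMES), 0, spec$acquisition_offset_sd_um)
      names(acq) <- BAND_NAMES
      t_eff <- vapply(BAND_NAMES, function(b)
        max(3, base_t[[b]] + off[[b]] + acq[[b]]), numeric(1))

      t_ez_field <- t_eff[["EZ"]] +
        spec$ez_radial_slope_um_per_mm * (R - spec$ez_slope_ref_mm)
      t_ez_field[t_ez_field < 3] <- 3
      h_vis <- vis * h_base

      s <- list(
        RPE_inner = z_ref,
        RPE_outer = z_ref + t_eff[["RPE"]],
        EZ_outer = z_ref - h_vis)
      s$EZ_inner <- s$EZ_outer - t_ez_field
      s$ELM <- s$EZ_inner - t_eff[["ELM_MZ"]]
      s <- s[SURFACE_NAMES]

      if (spec$jitter_sd_um > 0) {
        for (nm in SURFACE_NAMES)
          s[[nm]] <- s[[nm]] + matrix(
            stats::rnorm(nb * na_, 0, spec$jitter_sd_um), nb, na_)
        # project back onto the ordering: raise posterior onto anterior
        run <- s[[1]]
        for (nm in SURFACE_NAMES[-1]) {
          s[[nm]] <- pmax(s[[nm]], run)
          run <- s[[nm]]
        }
      }

      disrupted <- h_vis > spec$sdd_disruption_height_um
      s$ELM[les_elm] <- NA_real_
      s$EZ_inner[les_ez] <- NA_real_
      s$EZ_outer[les_ez] <- NA_real_
      s$RPE_inner[les_rpe] <- NA_real_
      s$RPE_outer[les_rpe] <- NA_real_

      g <- make_geometry(fov_deg = spec$fov_deg, n_ascans = na_,
                         n_bscans = nb, mm_per_deg = spec$mm_per_deg,
                         laterality = eye$laterality, device_label = dev)
      ss <- surface_set(s, g, fovea, eye_id = eye$eye_id,
                        patient_id = eye$patient_id,
                        sdd_disrupted = disrupted, validate = FALSE)
      surface_sets[[paste(eye$eye_id, dev, sep = ".")]] <- ss

      # --- truth: thickness (closed form; EZ records the core value,
      #     excluding SDD elevation, with the eccentricity trend averaged
      #     over the lattice per ring) ---
      for (b in BAND_NAMES) {
        for (ring in c("whole_field", names(ring_rbar)[1:3])) {
          mu <- t_eff[[b]]
          if (b == "EZ") {
            rbar <- if (ring == "whole_field") mean(R) else ring_rbar[[ring]]
            mu <- mu + spec$ez_radial_slope_um_per_mm *
              (rbar - spec$ez_slope_ref_mm)
          }
          truth_thick[[length(truth_thick) + 1]] <- data.frame(
            eye_id = eye$eye_id, patient_id = eye$patient_id, device = dev,
            band = b, subfield = ring, true_mean_um = mu)
        }
      }

      # --- truth: visible SDD volume per anatomical quadrant ---
      if (nrow(mounds)) {
        vols <- mound_visible_volume_um3(vis * mounds$h0, mounds$r0 * 1000,
                                         spec$sdd_threshold_um) / 1e6
        quads <- .anatomical_quadrant(mounds$x, mounds$y, eye$laterality)
        for (q in c(quadrant_labels, "center")) {
          truth_sdd[[length(truth_sdd) + 1]] <- data.frame(
            eye_id = eye$eye_id, patient_id = eye$patient_id, device = dev,
            quadrant = q, true_sdd_nl = sum(vols[quads == q]),
            n_mounds = sum(quads == q))
        }
      } else {
        truth_sdd[[length(truth_sdd) + 1]] <- data.frame(
          eye_id = eye$eye_id, patient_id = eye$patient_id, device = dev,
          quadrant = "superior", true_sdd_nl = 0, n_mounds = 0L)
      }
    }

    # --- truth: loss areas (device-independent, exact ellipse areas) ---
    areas <- if (is.null(lesion)) c(ELM_MZ = 0, EZ = 0, RPE = 0) else
      c(ELM_MZ = ellipse_area_mm2(lesion$a_elm, lesion$b_elm),
        EZ = ellipse_area_mm2(lesion$a_ez, lesion$b_ez),
        RPE = ellipse_area_mm2(lesion$a_rpe, lesion$b_rpe))
    for (b in BAND_NAMES)
      truth_loss[[length(truth_loss) + 1]] <- data.frame(
        eye_id = eye$eye_id, patient_id = eye$patient_id, band = b,
        true_loss_mm2 = areas[[b]])
  }

  structure(
    list(surface_sets = surface_sets,
         truth = list(loss = do.call(rbind, truth_loss),
                      thickness = do.call(rbind, truth_thick),
                      sdd = do.call(rbind, truth_sdd),
                      mounds = if (length(truth_mounds))
                        do.call(rbind, truth_mounds) else NULL),
         spec = spec),
    class = "phantom_cohort")
}

#' @export
print.phantom_cohort <- function(x, ...) {
  n_eyes <- length(unique(x$truth$loss$eye_id))
  cat(sprintf("<phantom_cohort> %d eyes of %d patients on %d device(s), %s\n",
              n_eyes, x$spec$n_patients, length(x$spec$devices),
              paste0(x$spec$n_ascans, "x", x$spec$n_bscans, " lattice")))
  invisible(x)
}

#' A fixed miniature phantom eye for documentation and fast tests
#'
#' One deterministic eye (64 A-scans x 9 B-scans) with a fovea-centered
#' lesion and three SDD mounds, acquired on the two default devices.
#' Repeated calls are bit-identical.  The same eye (rounded to 0.01 um)
#' ships as plain-text fixtures under `inst/extdata/`.
#'
#' @return list with elements `standard` and `high_res`
#'   ([surface_set()]s) and `truth` (as in [generate_cohort()]).
#' @export
worked_example_eye <- function() {
  spec <- phantom_spec(
    seed = 101L, n_patients = 1L, prob_both_eyes = 0,
    n_ascans = 64L, n_bscans = 9L,
    semi_axis_sd_log = 0, drusen_count = 1L,
    sdd_count = 3L, sdd_min_radial_mm = 1.0, sdd_max_radial_mm = 2.3,
    jitter_sd_um = 0.5)
  coh <- generate_cohort(spec)
  eye <- unique(coh$truth$loss$eye_id)[1]
  list(standard = coh$surface_sets[[paste0(eye, ".standard")]],
       high_res = coh$surface_sets[[paste0(eye, ".high_res")]],
       truth = coh$truth)
}
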