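#' Fovea-centered ETDRS grid
#'
#' The Early Treatment Diabetic Retinopathy Study grid: concentric
#' circles of 1, 3 and 6 mm diameter centered on the fovea, with the
#' outer rings split into superior / nasal / inferior / temporal
#' quadrants at the +-45 degree diagonals.  Nasal/temporal assignment
#' depends on laterality.
#'
#' @param fovea_center 1-based `c(bscan, ascan)` fovea indices.
#' @param laterality `"OD"` or `"OS"`.
#' @param radii_mm strictly increasing ring radii; defaults
#'   `c(0.5, 1.5, 3.0)` mm.
#' @return An object of class `etdrs_grid`.
#' @export
etdrs_grid <- function(fovea_center, laterality = c("OD", "OS"),
                       radii_mm = c(0.5, 1.5, 3.0)) {
  laterality <- match.arg(laterality)
  stopifnot(length(radii_mm) == 3, all(diff(radii_mm) > 0), all(radii_mm > 0))
  structure(list(fovea_center = as.integer(fovea_center),
                 laterality = laterality, radii_mm = radii_mm),
            class = "etdrs_grid")
}

#' Nominal ETDRS ring areas in mm^2
#'
#' Full (unclipped) areas of the central circle and the parafoveal and
#' perifoveal rings: `pi*r1^2`, `pi*(r2^2 - r1^2)`, `pi*(r3^2 - r2^2)`.
#' With the standard 0.5/1.5/3.0 mm radii these report as 0.79, 6.28 and
#' 21.21 mm^2 — the denominators used to normalize absolute losses to
#' relative (percent) losses.  Unrounded values are used internally;
#' rounding to two decimals is applied only for reporting.
#'
#' @param radii_mm ring radii (default standard grid).
#' @param rounded round to 2 decimals for reporting (default `TRUE`).
#' @return named vector `c(center, parafoveal_ring, perifoveal_ring)`.
#' @export
subfield_areas_mm2 <- function(radii_mm = c(0.5, 1.5, 3.0), rounded = TRUE) {
  a <- c(center = pi * radii_mm[1]^2,
         parafoveal_ring = pi * (radii_mm[2]^2 - radii_mm[1]^2),
         perifoveal_ring = pi * (radii_mm[3]^2 - radii_mm[2]^2))
  if (rounded) round(a, 2) else a
}

ring_labels <- c("center", "parafoveal_ring", "perifoveal_ring")
quadrant_labels <- c("superior", "temporal", "inferior", "nasal")

# physical offsets (mm) of lattice columns from the fovea.
# dx: image left->right; dy: inferior->superior (B-scan 1 is inferior-most).
.column_offsets_mm <- function(bscan, ascan, grid, geometry) {
  dx <- (ascan - grid$fovea_center[2]) * lateral_spacing_um(geometry) / 1000
  dy <- (bscan - grid$fovea_center[1]) * geometry$bscan_spacing_um / 1000
  list(dx = dx, dy = dy, r = sqrt(dx^2 + dy^2))
}

# quadrant of (dx, dy): +x image-right maps to nasal for OD, temporal for OS.
# Boundaries at the +-45 degree diagonals, half-open so a column exactly on
# a diagonal joins the counter-clockwise quadrant.
.quadrant_of <- function(dx, dy, laterality) {
  x_nasal <- if (laterality == "OD") dx else -dx
  deg <- (atan2(dy, x_nasal) * 180 / pi) %% 360
  idx <- floor(((deg - 45) %% 360) / 90) + 1  # 1 sup, 2 temp, 3 inf, 4 nasal
  quadrant_labels[idx]
}

#' Assign lattice columns to ETDRS subfields
#'
#' Distance from the fovea is computed from column centers in physical mm
#' using the anisotropic A-scan and B-scan spacings.  Ring bins are
#' half-open: `[0, 0.5)` center, `[0.5, 1.5)` parafoveal, `[1.5, 3.0)`
#' perifoveal, `>= 3.0` outside.  Ring subfields outside the center are
#' labelled `<ring>_<quadrant>`, e.g. `"parafoveal_superior"`.
#'
#' @param bscan,ascan 1-based indices (vectorized, recycled together).
#' @param grid an [etdrs_grid()].
#' @param geometry a [make_geometry()] object.
#' @return character vector of subfield labels (`"center"`,
#'   `"parafoveal_<quadrant>"`, `"perifoveal_<quadrant>"`, `"outside"`).
#' @export
assign_subfield <- function(bscan, ascan, grid, geometry) {
  stopifnot(inherits(grid, "etdrs_grid"))
  o <- .column_offsets_mm(bscan, ascan, grid, geometry)
  r <- grid$radii_mm
  ring <- cut(o$r, breaks = c(0, r[1], r[2], r[3], Inf), right = FALSE,
              labels = c("center", "parafoveal", "perifoveal", "outside"))
  quad <- .quadrant_of(o$dx, o$dy, grid$laterality)
  out <- as.character(ring)
  sel <- out %in% c("parafoveal", "perifoveal")
  out[sel] <- paste(out[sel], quad[sel], sep = "_")
  out
}

# ring and quadrant label matrices for a whole lattice
.subfield_maps <- function(grid, geometry) {
  nb <- geometry$n_bscans; na <- geometry$n_ascans
  b <- matrix(seq_len(nb), nb, na)
  a <- matrix(seq_len(na), nb, na, byrow = TRUE)
  o <- .column_offsets_mm(b, a, grid, geometry)
  r <- grid$radii_mm
  ring <- matrix(as.character(
    cut(o$r, breaks = c(0, r[1], r[2], r[3], Inf), right = FALSE,
        labels = c("center", "parafoveal", "perifoveal", "outside"))), nb, na)
  quad <- matrix(.quadrant_of(o$dx, o$dy, grid$laterality), nb, na)
  list(ring = ring, quadrant = quad, r_mm = matrix(o$r, nb, na))
}

#' Fraction of the 6-mm ETDRS circle covered by the scan field
#'
#' A 20 degree field (about 5.86 mm at 0.293 mm/deg) slightly clips the
#' 6-mm circle; relative losses nevertheless divide by the full nominal
#' ring areas.  This diagnostic reports the covered fraction per ring so
#' the clipping is visible in logs.
#'
#' @param grid an [etdrs_grid()].
#' @param geometry a [make_geometry()] object.
#' @return named vector of covered-area fractions per ring.
#' @export
etdrs_covered_fraction <- function(grid, geometry) {
  maps <- .subfield_maps(grid, geometry)
  cell <- column_cell_area_mm2(geometry)
  nominal <- subfield_areas_mm2(grid$radii_mm, rounded = FALSE)
  covered <- c(center = sum(maps$ring == "center"),
               parafoveal_ring = sum(maps$ring == "parafoveal"),
               perifoveal_ring = sum(maps$ring == "perifoveal")) * cell
  covered / nominal
}

#' Per-subfield summaries of a quantified eye
#'
#' Summarizes a [quantify_eye()] result over the ETDRS grid:
#' * per ring (center / parafoveal / perifoveal): mean band thickness (um,
#'   over non-missing columns), absolute band loss (mm^2) and relative
#'   band loss (% of the nominal ring area), and SDD volume (nL);
#' * per quadrant, merging the parafoveal and perifoveal rings: SDD
#'   volume (nL) and area-normalized SDD volume (nL/mm^2), plus the
#'   central circle, matching quadrant-level SDD reporting.
#'
#' @param quant a [quantify_eye()] result.
#' @param grid an [etdrs_grid()] sharing the fovea center and geometry.
#' @return An object of class `subfield_report`: a tidy data frame with
#'   columns `eye_id, patient_id, device, subfield, outcome, value`.
#' @export
summarize_subfields <- function(quant, grid = etdrs_grid(
                                  quant$fovea_center,
                                  quant$geometry$laterality)) {
  stopifnot(inherits(quant, "quant_result"), inherits(grid, "etdrs_grid"))
  if (!identical(grid$fovea_center, quant$fovea_center))
    stop("grid and quantification disagree on the fovea center")
  g <- quant$geometry
  maps <- .subfield_maps(grid, g)
  cell_mm2 <- column_cell_area_mm2(g)
  nominal <- subfield_areas_mm2(grid$radii_mm, rounded = FALSE)
  rows <- list()
  add <- function(subfield, outcome, value) {
    rows[[length(rows) + 1]] <<- data.frame(
      eye_id = quant$eye_id, patient_id = quant$patient_id,
      device = quant$device, subfield = subfield, outcome = outcome,
      value = value, stringsAsFactors = FALSE)
  }
  ring_key <- c(center = "center", parafoveal = "parafoveal_ring",
                perifoveal = "perifoveal_ring")
  for (ring in names(ring_key)) {
    sel <- maps$ring == ring
    label <- ring_key[[ring]]
    for (b in BAND_NAMES) {
      th <- quant$bands[[b]]$thickness$values[sel]
      lo <- quant$bands[[b]]$loss$values[sel]
      abs_loss <- sum(lo > 0, na.rm = TRUE) * cell_mm2
      add(label, paste0(b, "_thickness_um"),
          if (any(!is.na(th))) mean(th, na.rm = TRUE) else NA_real_)
      add(label, paste0(b, "_loss_mm2"), abs_loss)
      add(label, paste0(b, "_loss_rel_pct"), abs_loss / nominal[[label]] * 100)
    }
    add(label, "SDD_volume_nl", sdd_volume_nl(quant$sdd_thickness, g, sel))
  }
  # quadrant-merged SDD volumes (parafoveal + perifoveal per quadrant)
  for (q in quadrant_labels) {
    sel <- maps$quadrant == q & maps$ring %in% c("parafoveal", "perifoveal")
    vol <- sdd_volume_nl(quant$sdd_thickness, g, sel)
    area <- sum(sel) * cell_mm2
    add(paste0("quadrant_", q), "SDD_volume_nl", vol)
    add(paste0("quadrant_", q), "SDD_volume_nl_per_mm2",
        if (area > 0) vol / area else NA_real_)
  }
  sel_c <- maps$ring == "center"
  add("quadrant_center", "SDD_volume_nl",
      sdd_volume_nl(quant$sdd_thickness, g, sel_c))
  add("quadrant_center", "SDD_volume_nl_per_mm2",
      sdd_volume_nl(quant$sdd_thickness, g, sel_c) / (sum(sel_c) * cell_mm2))
  out <- do.call(rbind, rows)
  class(out) <- c("subfield_report", class(out))
  out
}

#' Cohort-average en-face SDD volume map
#'
#' Fovea-registers the SDD thickness maps of a cohort (shifting lattices
#' so the fovea centers coincide, cropping to the common extent) and
#' returns the per-column mean over eyes of the projected SDD volume
#' (thickness times cell area) in um^3 — the summarized SDD distribution
#' map.
#'
#' @param quants list of [quantify_eye()] results on identically spaced
#'   lattices.
#' @return an [enface_map()] of mean per-column SDD volume (um^3).
#' @export
sdd_distribution_map <- function(quants) {
  if (!length(quants)) stop("empty cohort")
  stopifnot(all(vapply(quants, inherits, logical(1), "quant_result")))
  g0 <- quants[[1]]$geometry
  sp <- vapply(quants, function(q) c(lateral_spacing_um(q$geometry),
                                     q$geometry$bscan_spacing_um),
               numeric(2))
  if (any(abs(sp - sp[, 1]) > 1e-9))
    stop("cohort lattices have differing spacings; cannot fovea-register")
  fb <- vapply(quants, function(q) q$fovea_center[1], integer(1))
  fa <- vapply(quants, function(q) q$fovea_center[2], integer(1))
  nb <- vapply(quants, function(q) q$geometry$n_bscans, integer(1))
  na_ <- vapply(quants, function(q) q$geometry$n_ascans, integer(1))
  below <- min(fb - 1L); above <- min(nb - fb)
  left <- min(fa - 1L); right <- min(na_ - fa)
  acc <- matrix(0, below + above + 1L, left + right + 1L)
  cnt <- matrix(0, nrow(acc), ncol(acc))
  for (i in seq_along(quants)) {
    q <- quants[[i]]
    cell_um2 <- lateral_spacing_um(q$geometry) * q$geometry$bscan_spacing_um
    v <- q$sdd_thickness$values[(fb[i] - below):(fb[i] + above),
                                (fa[i] - left):(fa[i] + right)] * cell_um2
    ok <- !is.na(v)
    acc[ok] <- acc[ok] + v[ok]
    cnt <- cnt + ok
  }
  mean_map <- acc / pmax(cnt, 1)
  mean_map[cnt == 0] <- NA_real_
  g <- make_geometry(fov_deg = g0$fov_deg * (ncol(acc) - 1) / (g0$n_ascans - 1),
                     n_ascans = ncol(acc), n_bscans = nrow(acc),
                     mm_per_deg = g0$mm_per_deg,
                     bscan_spacing_um = g0$bscan_spacing_um,
                     axial_pitch_um = g0$axial_pitch_um,
                     laterality = g0$laterality,
                     device_label = "cohort")
  enface_map(mean_map, "mean_SDD_volume_um3_per_column", g,
             c(below + 1L, left + 1L))
}
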