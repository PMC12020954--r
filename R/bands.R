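#' Outer retinal band definitions
#'
#' The three quantified bands and their bounding surfaces:
#' * `ELM_MZ` — ELM to EZ_inner: the external limiting membrane plus the
#'   myoid zone.
#' * `EZ` — EZ_inner to RPE_inner: the ellipsoid zone band including the
#'   interdigitation zone, measured down to the inner RPE boundary.
#' * `RPE` — RPE_inner to RPE_outer: the RPE monolayer, excluding basal
#'   laminar deposits, drusen, and Bruch's membrane by construction of the
#'   outer boundary.
#'
#' @param band one of `"ELM_MZ"`, `"EZ"`, `"RPE"`.
#' @return list with `band`, `anterior`, `posterior` (surface names) and
#'   `loss_surface`, the surface whose absence defines loss of this band.
#' @export
band_definition <- function(band = c("ELM_MZ", "EZ", "RPE")) {
  band <- match.arg(band)
  switch(band,
    ELM_MZ = list(band = "ELM_MZ", anterior = "ELM", posterior = "EZ_inner",
                  loss_surface = "ELM"),
    EZ = list(band = "EZ", anterior = "EZ_inner", posterior = "RPE_inner",
              loss_surface = "EZ_inner"),
    RPE = list(band = "RPE", anterior = "RPE_inner", posterior = "RPE_outer",
               loss_surface = "RPE_inner"))
}

#' All three band labels
#' @export
BAND_NAMES <- c("ELM_MZ", "EZ", "RPE")

#' Band thickness en-face map
#'
#' Thickness = posterior minus anterior surface (um) per A-scan column;
#' `NA` where either bounding surface is missing.  For the EZ band,
#' columns flagged as SDD-disrupted are also set missing (they count as
#' EZ loss, so their thickness must not enter thickness means).
#' Thickness at loss columns is excluded (`NA`), never zero, so that
#' thickness means describe surviving tissue only.
#'
#' @param surfaces a validated [surface_set()].
#' @param band a band label or a [band_definition()].
#' @return an [enface_map()] in um.
#' @export
thickness_map <- function(surfaces, band) {
  stopifnot(inherits(surfaces, "surface_set"))
  bd <- if (is.character(band)) band_definition(band) else band
  v <- surfaces$surfaces[[bd$posterior]] - surfaces$surfaces[[bd$anterior]]
  if (any(v < -1e-6, na.rm = TRUE))
    stop("negative ", bd$band,
         " thickness: surface ordering violated (corrupt segmentation)")
  v[v < 0] <- 0
  if (bd$band == "EZ") v[surfaces$sdd_disrupted] <- NA_real_
  enface_map(v, paste0(bd$band, "_thickness_um"), surfaces$geometry,
             surfaces$fovea_center)
}

#' Band-loss indicator en-face map
#'
#' Loss of a band is encoded by missing segmentation at its defining
#' surface (the reader cuts the line where the band's reflectivity ends):
#' ELM_MZ loss where ELM is missing, EZ loss where EZ_inner is missing,
#' RPE loss where RPE_inner is missing.  EZ loss additionally includes
#' columns whose `sdd_disrupted` flag is set (SDDs visibly displacing the
#' EZ are marked as EZ loss).
#'
#' @param surfaces a validated [surface_set()].
#' @param band a band label or a [band_definition()].
#' @return an [enface_map()] with values 0/1.
#' @export
loss_mask <- function(surfaces, band) {
  stopifnot(inherits(surfaces, "surface_set"))
  bd <- if (is.character(band)) band_definition(band) else band
  lost <- is.na(surfaces$surfaces[[bd$loss_surface]])
  if (bd$band == "EZ") lost <- lost | surfaces$sdd_disrupted
  enface_map(lost + 0, paste0(bd$band, "_loss"), surfaces$geometry,
             surfaces$fovea_center)
}

#' Loss area from an indicator map
#'
#' Number of loss columns times the en-face cell area
#' ([column_cell_area_mm2()]): the rectangle-rule integral of the mask.
#'
#' @param mask an indicator [enface_map()] (values 0/1, `NA` treated as 0).
#' @param geometry a [make_geometry()] object.
#' @return loss area in mm^2.
#' @export
loss_area_mm2 <- function(mask, geometry = mask$geometry) {
  v <- if (inherits(mask, "enface_map")) mask$values else mask
  sum(v > 0, na.rm = TRUE) * column_cell_area_mm2(geometry)
}

#' SDD thickness en-face map
#'
#' The subretinal drusenoid deposit (SDD) thickness at a column is the
#' gap between the inner RPE boundary and the outer EZ boundary
#' (`RPE_inner - EZ_outer`), registered only where it exceeds
#' `threshold_um` (strictly); gaps at or below the threshold — including
#' diffuse stage-1-like material and residual segmentation error — count
#' as 0.  Columns where either surface is missing are `NA`.
#'
#' @param surfaces a validated [surface_set()].
#' @param threshold_um registration threshold in um (default 4, one
#'   axial pixel on a conventional device).
#' @return an [enface_map()] in um (values `>= 0` or `NA`).
#' @export
sdd_thickness_map <- function(surfaces, threshold_um = 4) {
  stopifnot(inherits(surfaces, "surface_set"), threshold_um >= 0)
  gap <- surfaces$surfaces[["RPE_inner"]] - surfaces$surfaces[["EZ_outer"]]
  gap[gap < 0] <- 0       # sub-um crossings outside SDDs are tolerated
  gap[!is.na(gap) & gap <= threshold_um] <- 0
  enface_map(gap, "SDD_thickness_um", surfaces$geometry,
             surfaces$fovea_center)
}

#' SDD volume from an SDD thickness map
#'
#' Rectangle-rule integral: sum of per-column thickness (um) times the
#' cell area (um^2), converted to nL via [um3_to_nl()].  An optional
#' logical region mask restricts the integral.
#'
#' @param sdd_map an [enface_map()] from [sdd_thickness_map()].
#' @param geometry a [make_geometry()] object.
#' @param region_mask optional logical matrix of the lattice shape.
#' @return volume in nL.
#' @export
sdd_volume_nl <- function(sdd_map, geometry = sdd_map$geometry,
                          region_mask = NULL) {
  v <- if (inherits(sdd_map, "enface_map")) sdd_map$values else sdd_map
  if (!is.null(region_mask)) {
    if (!identical(dim(region_mask), dim(v)))
      stop("region_mask shape does not match the SDD map")
    v <- v * (region_mask + 0)
  }
  cell_um2 <- lateral_spacing_um(geometry) * geometry$bscan_spacing_um
  um3_to_nl(sum(v * cell_um2, na.rm = TRUE))
}

#' Quantify one eye: thickness maps, loss areas, SDD volumetry
#'
#' Runs the full stage-1 quantification of a surface set: per-band
#' thickness maps and loss masks/areas, the SDD thickness map and
#' whole-field SDD volume.
#'
#' @param surfaces a [surface_set()] (validated here).
#' @param sdd_threshold_um SDD registration threshold in um.
#' @return An object of class `quant_result`: a list with `bands` (per
#'   band: `thickness`, `loss` maps and `loss_area_mm2`), `sdd_thickness`,
#'   `sdd_volume_nl`, `geometry`, `fovea_center` and the eye identifiers.
#' @export
quantify_eye <- function(surfaces, sdd_threshold_um = 4) {
  validate_surface_set(surfaces)
  g <- surfaces$geometry
  bands <- lapply(BAND_NAMES, function(b) {
    th <- thickness_map(surfaces, b)
    lm <- loss_mask(surfaces, b)
    list(thickness = th, loss = lm, loss_area_mm2 = loss_area_mm2(lm, g))
  })
  names(bands) <- BAND_NAMES
  sdd <- sdd_thickness_map(surfaces, sdd_threshold_um)
  structure(
    list(bands = bands, sdd_thickness = sdd,
         sdd_volume_nl = sdd_volume_nl(sdd, g),
         geometry = g, fovea_center = surfaces$fovea_center,
         eye_id = surfaces$eye_id, patient_id = surfaces$patient_id,
         device = surfaces$device,
         sdd_threshold_um = sdd_threshold_um),
    class = "quant_result")
}

#' @export
print.quant_result <- function(x, ...) {
  cat(sprintf("<quant_result> eye %s (%s, device %s)\n",
              x$eye_id, x$patient_id, x$device))
  for (b in BAND_NAMES) {
    th <- x$bands[[b]]$thickness$values
    cat(sprintf("  %-6s mean thickness %6.2f um, loss %6.3f mm^2\n", b,
                mean(th, na.rm = TRUE), x$bands[[b]]$loss_area_mm2))
  }
  cat(sprintf("  SDD volume %.2f nL (threshold %g um)\n",
              x$sdd_volume_nl, x$sdd_threshold_um))
  invisible(x)
}

#' Keep every second B-scan of a 97-B-scan volume
#'
#' Emulates quantification restricted to 49 manually corrected B-scans of
#' a 97-B-scan acquisition: B-scans 1, 3, ..., 97 are retained and the
#' slab width doubles.  Works for any odd step-compatible lattice.
#'
#' @param surfaces a [surface_set()].
#' @param step subsampling step (default 2).
#' @return a new [surface_set()] on the coarser lattice.
#' @export
subsample_bscans <- function(surfaces, step = 2L) {
  stopifnot(inherits(surfaces, "surface_set"), step >= 1)
  g <- surfaces$geometry
  keep <- seq(1L, g$n_bscans, by = step)
  g2 <- make_geometry(
    fov_deg = g$fov_deg, n_ascans = g$n_ascans, n_bscans = length(keep),
    mm_per_deg = g$mm_per_deg, bscan_spacing_um = g$bscan_spacing_um * step,
    axial_pitch_um = g$axial_pitch_um, laterality = g$laterality,
    device_label = g$device_label)
  fb <- which.min(abs(keep - surfaces$fovea_center[1]))
  surface_set(
    surfaces = lapply(surfaces$surfaces, function(m) m[keep, , drop = FALSE]),
    geometry = g2, fovea_center = c(fb, surfaces$fovea_center[2]),
    eye_id = surfaces$eye_id, patient_id = surfaces$patient_id,
    sdd_disrupted = surfaces$sdd_disrupted[keep, , drop = FALSE])
}
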