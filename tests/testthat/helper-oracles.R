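# Independent oracles and small builders used across the test files.

# Brute-force ellipse-area oracle: rasterize on a fine square grid
# (cell centers), independent of the lattice/masking code under test.
rasterize_ellipse_area_mm2 <- function(a, b, res_mm = 0.001) {
  xs <- seq(-a + res_mm / 2, a, by = res_mm)
  ys <- seq(-b + res_mm / 2, b, by = res_mm)
  inside <- outer(ys^2 / b^2, xs^2 / a^2, "+") < 1
  sum(inside) * res_mm^2
}

# Brute-force visible-volume oracle for a paraboloid mound: numeric
# radial integration of the profile where it strictly exceeds the
# threshold (independent of the closed form under test).
rasterize_mound_volume_um3 <- function(h_um, r_um, threshold_um,
                                       n = 20000) {
  d <- seq(r_um / n / 2, r_um, length.out = n)
  prof <- h_um * (1 - (d / r_um)^2)
  keep <- prof > threshold_um
  sum(2 * pi * d[keep] * prof[keep]) * (r_um / n)
}

# Flat-surface builder: five parallel surfaces with given band
# thicknesses (um) on a small lattice; optional SDD gap matrix lifts
# EZ_outer (and the EZ/ELM complex) anteriorly off RPE_inner.
flat_surface_set <- function(n_bscans = 9, n_ascans = 32,
                             t_elm_mz = 20, t_ez = 27, t_rpe = 21,
                             gap = NULL, z0 = 200,
                             laterality = "OD", device = "standard",
                             fov_deg = 20, eye_id = "eyeA",
                             patient_id = "patA") {
  g <- make_geometry(fov_deg = fov_deg, n_ascans = n_ascans,
                     n_bscans = n_bscans, laterality = laterality,
                     device_label = device)
  z <- matrix(z0, n_bscans, n_ascans)
  if (is.null(gap)) gap <- matrix(0, n_bscans, n_ascans)
  s <- list(RPE_inner = z, RPE_outer = z + t_rpe, EZ_outer = z - gap)
  s$EZ_inner <- s$EZ_outer - t_ez
  s$ELM <- s$EZ_inner - t_elm_mz
  surface_set(s[SURFACE_NAMES], g,
              c(floor(n_bscans / 2) + 1L, floor(n_ascans / 2) + 1L),
              eye_id = eye_id, patient_id = patient_id)
}

# Paraboloid gap matrix for one mound at (x_mm, y_mm) from the fovea.
mound_gap_matrix <- function(geom, fovea, x_mm, y_mm, h_um, r_mm) {
  xs <- (seq_len(geom$n_ascans) - fovea[2]) * lateral_spacing_um(geom) / 1000
  ys <- (seq_len(geom$n_bscans) - fovea[1]) * geom$bscan_spacing_um / 1000
  d2 <- outer((ys - y_mm)^2, (xs - x_mm)^2, "+")
  h_um * pmax(0, 1 - d2 / r_mm^2)
}

# A reduced phantom spec for fast cohort-level tests.
small_phantom_spec <- function(seed, n_patients = 8, ...) {
  args <- list(seed = seed, n_patients = n_patients,
               n_ascans = 64L, n_bscans = 9L,
               sdd_count = 4L, drusen_count = 1L)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(phantom_spec, args)
}

# Tidy per-eye whole-field measurements of a cohort.
cohort_whole_field <- function(cohort) {
  do.call(rbind, lapply(cohort$surface_sets, function(s)
    whole_field_measurements(quantify_eye(s))))
}
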