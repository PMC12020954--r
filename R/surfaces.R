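#' Names of the five segmented outer retinal surfaces
#'
#' Ordered anterior to posterior: external limiting membrane (ELM), inner
#' and outer boundaries of the ellipsoid zone band (EZ), inner and outer
#' boundaries of the retinal pigment epithelium band (RPE).  Axial
#' positions increase posteriorly.
#' @export
SURFACE_NAMES <- c("ELM", "EZ_inner", "EZ_outer", "RPE_inner", "RPE_outer")

#' A set of five segmented surfaces for one eye on one device
#'
#' Holds, for each surface in [SURFACE_NAMES], an `n_bscans x n_ascans`
#' matrix of axial positions in um measured from a common volume
#' reference (`NA` = surface missing at that column, encoding band loss).
#' Missingness is per-surface per-column; the two boundaries of the EZ
#' band and of the RPE band are missing together (a band cannot lose a
#' single boundary).
#'
#' @param surfaces named list of five numeric matrices
#'   (`n_bscans x n_ascans`), names [SURFACE_NAMES]; values in um,
#'   `NA` = missing.
#' @param geometry a [make_geometry()] object matching the matrices.
#' @param fovea_center integer `c(bscan, ascan)` of the manually annotated
#'   foveal center (1-based, inside the lattice).
#' @param eye_id,patient_id identifiers; several eyes may share a
#'   `patient_id` (used by the mixed-effects models).
#' @param sdd_disrupted logical matrix flagging A-scan columns where an
#'   SDD visibly disrupts the EZ band (such columns count as EZ loss);
#'   `NULL` = none.
#' @param validate run [validate_surface_set()] (default `TRUE`).
#' @return An object of class `surface_set`.
#' @export
surface_set <- function(surfaces, geometry, fovea_center,
                        eye_id = "eye1", patient_id = "pat1",
                        sdd_disrupted = NULL, validate = TRUE) {
  stopifnot(inherits(geometry, "scan_geometry"))
  if (is.null(sdd_disrupted)) {
    sdd_disrupted <- matrix(FALSE, geometry$n_bscans, geometry$n_ascans)
  }
  obj <- structure(
    list(surfaces = surfaces, geometry = geometry,
         fovea_center = as.integer(fovea_center),
         eye_id = eye_id, patient_id = patient_id,
         device = geometry$device_label,
         sdd_disrupted = sdd_disrupted),
    class = "surface_set")
  if (validate) validate_surface_set(obj)
  obj
}

#' Validate a surface set
#'
#' Checks lattice shape, the anterior-to-posterior ordering
#' `ELM <= EZ_inner <= EZ_outer <= RPE_inner <= RPE_outer` wherever the
#' surfaces involved are present, paired missingness of the EZ and RPE
#' boundaries, and that the fovea center lies inside the lattice.
#' An ordering violation signals corrupt segmentation and is an error.
#'
#' @param x a [surface_set()] object.
#' @param tol ordering tolerance in um (floating-point slack).
#' @return `x`, invisibly.
#' @export
validate_surface_set <- function(x, tol = 1e-8) {
  stopifnot(inherits(x, "surface_set"))
  g <- x$geometry
  if (!identical(sort(names(x$surfaces)), sort(SURFACE_NAMES)))
    stop("surfaces must be named exactly: ",
         paste(SURFACE_NAMES, collapse = ", "))
  for (nm in SURFACE_NAMES) {
    m <- x$surfaces[[nm]]
    if (!is.matrix(m) || nrow(m) != g$n_bscans || ncol(m) != g$n_ascans)
      stop(sprintf("surface %s must be a %d x %d matrix",
                   nm, g$n_bscans, g$n_ascans))
    if (any(is.infinite(m)))
      stop("surface ", nm, " contains non-finite values")
  }
  if (!identical(dim(x$sdd_disrupted), dim(x$surfaces[[1]])))
    stop("sdd_disrupted must match the lattice dimensions")
  fc <- x$fovea_center
  if (length(fc) != 2 || any(is.na(fc)) ||
      fc[1] < 1L || fc[1] > g$n_bscans || fc[2] < 1L || fc[2] > g$n_ascans)
    stop("fovea_center must be c(bscan, ascan) inside the lattice")
  # paired missingness of band boundaries
  for (band in list(c("EZ_inner", "EZ_outer"), c("RPE_inner", "RPE_outer"))) {
    bad <- which(is.na(x$surfaces[[band[1]]]) != is.na(x$surfaces[[band[2]]]))
    if (length(bad))
      stop(sprintf("%s and %s must be missing together (first bad column: %d)",
                   band[1], band[2], bad[1]))
  }
  # ordering: running maximum over the present subset, anterior to posterior
  run <- matrix(-Inf, g$n_bscans, g$n_ascans)
  for (nm in SURFACE_NAMES) {
    m <- x$surfaces[[nm]]
    present <- !is.na(m)
    viol <- present & (m < run - tol)
    if (any(viol)) {
      idx <- which(viol)[1]
      stop(sprintf(
        "surface ordering violated at surface %s, bscan %d, ascan %d",
        nm, (idx - 1L) %% g$n_bscans + 1L, (idx - 1L) %/% g$n_bscans + 1L))
    }
    run[present] <- pmax(run[present], m[present])
  }
  invisible(x)
}

#' @export
print.surface_set <- function(x, ...) {
  g <- x$geometry
  n_missing <- vapply(x$surfaces, function(m) sum(is.na(m)), integer(1))
  cat(sprintf("<surface_set> eye %s (patient %s, %s, device %s)\n",
              x$eye_id, x$patient_id, g$laterality, x$device))
  cat(sprintf("  lattice %d B-scans x %d A-scans, fovea at (%d, %d)\n",
              g$n_bscans, g$n_ascans, x$fovea_center[1], x$fovea_center[2]))
  cat("  missing columns: ",
      paste(sprintf("%s=%d", names(n_missing), n_missing), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Fovea-registered en-face scalar map
#'
#' A 2-D scalar field on the B-scan x A-scan lattice: band thickness (um),
#' SDD thickness (um), a loss indicator, or a projected per-column volume.
#' `NA` marks missing columns (e.g. band loss for a thickness map).
#'
#' @param values `n_bscans x n_ascans` numeric matrix.
#' @param quantity short label of the mapped quantity
#'   (e.g. `"RPE_thickness_um"`).
#' @param geometry a [make_geometry()] object.
#' @param fovea_center 1-based `c(bscan, ascan)`.
#' @return An object of class `enface_map`.
#' @export
enface_map <- function(values, quantity, geometry, fovea_center) {
  stopifnot(inherits(geometry, "scan_geometry"), is.matrix(values))
  if (nrow(values) != geometry$n_bscans || ncol(values) != geometry$n_ascans)
    stop("values shape does not match geometry")
  structure(list(values = values, quantity = quantity,
                 geometry = geometry,
                 fovea_center = as.integer(fovea_center)),
            class = "enface_map")
}

#' @export
print.enface_map <- function(x, ...) {
  v <- x$values
  cat(sprintf("<enface_map> %s: %d x %d, %d missing\n", x$quantity,
              nrow(v), ncol(v), sum(is.na(v))))
  if (any(!is.na(v)))
    cat(sprintf("  range %.3f .. %.3f\n", min(v, na.rm = TRUE),
                max(v, na.rm = TRUE)))
  invisible(x)
}

#' Plot an en-face map
#'
#' Heat-map rendering with physically scaled axes (mm from the fovea);
#' image-up is the superior direction (B-scan 1 is the inferior-most
#' scan).
#'
#' @param x an [enface_map()] object.
#' @param ... passed to [graphics::image()].
#' @export
plot.enface_map <- function(x, ...) {
  g <- x$geometry
  xmm <- (seq_len(g$n_ascans) - x$fovea_center[2]) * lateral_spacing_um(g) / 1000
  ymm <- (seq_len(g$n_bscans) - x$fovea_center[1]) * g$bscan_spacing_um / 1000
  graphics::image(xmm, ymm, t(x$values), xlab = "mm (image left-right)",
                  ylab = "mm (inferior-superior)", main = x$quantity,
                  useRaster = TRUE, ...)
  invisible(x)
}
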