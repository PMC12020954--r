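#' Scan geometry of an OCT volume
#'
#' Describes the A-scan/B-scan lattice and physical calibration of one
#' fovea-centered OCT volume.  All downstream quantities (loss areas in
#' mm^2, SDD volumes in nL) derive from the lateral A-scan pitch and the
#' inter-B-scan slab width stored here.
#'
#' The default lateral calibration of 0.293 mm/degree makes 48 B-scan
#' intervals over a 20 degree field equal 122.08 um, i.e. the conventional
#' "122 um" spacing of a 49 B-scan volume scan.
#'
#' @param fov_deg field of view in degrees (square field assumed).
#' @param n_ascans number of A-scans per B-scan (>= 2).
#' @param n_bscans number of B-scans per volume (>= 2).
#' @param mm_per_deg lateral calibration in mm per degree.
#' @param bscan_spacing_um inter-B-scan slab width in um; derived as
#'   `fov_deg * mm_per_deg * 1000 / (n_bscans - 1)` when `NULL`.
#' @param axial_pitch_um axial um per pixel; only used to convert
#'   pixel-valued surfaces on ingestion (surfaces are stored in um).
#' @param laterality `"OD"` (right eye) or `"OS"` (left eye).
#' @param device_label free-text device tag (e.g. `"standard"`,
#'   `"high_res"`); carried through to reports, never used in computation.
#'
#' @return An object of class `scan_geometry`.
#' @examples
#' g <- make_geometry()
#' lateral_spacing_um(g)     # ~5.72 um
#' g$bscan_spacing_um        # ~122.08 um
#' column_cell_area_mm2(g)   # ~6.98e-4 mm^2
#' @export
make_geometry <- function(fov_deg = 20, n_ascans = 1024, n_bscans = 49,
                          mm_per_deg = 0.293, bscan_spacing_um = NULL,
                          axial_pitch_um = 3.87,
                          laterality = c("OD", "OS"),
                          device_label = "standard") {
  laterality <- match.arg(laterality)
  stopifnot(length(fov_deg) == 1, length(n_ascans) == 1, length(n_bscans) == 1)
  n_ascans <- as.integer(n_ascans)
  n_bscans <- as.integer(n_bscans)
  if (is.na(n_ascans) || n_ascans < 2L) stop("n_ascans must be an integer >= 2")
  if (is.na(n_bscans) || n_bscans < 2L) stop("n_bscans must be an integer >= 2")
  for (nm in c("fov_deg", "mm_per_deg", "axial_pitch_um")) {
    v <- get(nm)
    if (!is.numeric(v) || !is.finite(v) || v <= 0)
      stop(sprintf("%s must be a strictly positive finite number", nm))
  }
  if (is.null(bscan_spacing_um)) {
    bscan_spacing_um <- fov_deg * mm_per_deg * 1000 / (n_bscans - 1)
  }
  if (!is.numeric(bscan_spacing_um) || !is.finite(bscan_spacing_um) ||
      bscan_spacing_um <= 0)
    stop("bscan_spacing_um must be a strictly positive finite number")
  structure(
    list(n_ascans = n_ascans, n_bscans = n_bscans, fov_deg = fov_deg,
         mm_per_deg = mm_per_deg, bscan_spacing_um = bscan_spacing_um,
         axial_pitch_um = axial_pitch_um, laterality = laterality,
         device_label = device_label),
    class = "scan_geometry")
}

#' Lateral A-scan pitch in um
#'
#' `fov_deg * mm_per_deg * 1000 / (n_ascans - 1)`: the lateral width, in
#' um, of the strip represented by one A-scan column.
#'
#' @param geometry a [make_geometry()] object.
#' @return lateral spacing in um.
#' @export
lateral_spacing_um <- function(geometry) {
  stopifnot(inherits(geometry, "scan_geometry"))
  geometry$fov_deg * geometry$mm_per_deg * 1000 / (geometry$n_ascans - 1)
}

#' En-face area represented by one A-scan column
#'
#' Each A-scan column represents a rectangular en-face cell of the lateral
#' A-scan pitch times the inter-B-scan slab width (rectangle rule);
#' summing cells over a loss mask yields loss area in mm^2.
#'
#' @param geometry a [make_geometry()] object.
#' @return cell area in mm^2.
#' @export
column_cell_area_mm2 <- function(geometry) {
  lateral_spacing_um(geometry) * geometry$bscan_spacing_um / 1e6
}

#' Convert a volume from cubic micrometers to nanoliters
#'
#' 1 nL = 1e6 um^3 = 1e-3 mm^3 (an exact power-of-ten conversion).
#'
#' @param volume_um3 non-negative volume(s) in um^3.
#' @return volume(s) in nL.
#' @export
um3_to_nl <- function(volume_um3) {
  if (any(!is.finite(volume_um3)) || any(volume_um3 < 0))
    stop("volume_um3 must be finite and non-negative")
  volume_um3 / 1e6
}

#' Write / read a scan geometry JSON sidecar
#'
#' The sidecar stores the geometry fields under exactly the keys
#' `n_ascans, n_bscans, fov_deg, mm_per_deg, bscan_spacing_um,
#' axial_pitch_um, laterality, device_label`, plus `fovea_center` as
#' 0-based `[bscan, ascan]` indices when supplied.
#'
#' @param geometry a [make_geometry()] object.
#' @param path file path of the JSON sidecar.
#' @param fovea_center optional in-memory (1-based) `c(bscan, ascan)`
#'   fovea indices; written 0-based.
#' @return `write_geometry_json()` returns `path` invisibly;
#'   `read_geometry_json()` returns a list with elements `geometry` and
#'   (possibly `NULL`) `fovea_center` (1-based).
#' @export
write_geometry_json <- function(geometry, path, fovea_center = NULL) {
  stopifnot(inherits(geometry, "scan_geometry"))
  payload <- unclass(geometry)
  if (!is.null(fovea_center)) {
    stopifnot(length(fovea_center) == 2)
    payload$fovea_center <- as.integer(fovea_center) - 1L
  }
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_geometry_json
#' @export
read_geometry_json <- function(path) {
  if (!file.exists(path)) stop("geometry sidecar not found: ", path)
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  required <- c("n_ascans", "n_bscans", "fov_deg", "mm_per_deg",
                "bscan_spacing_um", "axial_pitch_um", "laterality",
                "device_label")
  missing <- setdiff(required, names(payload))
  if (length(missing))
    stop("geometry sidecar ", path, " lacks keys: ",
         paste(missing, collapse = ", "))
  geometry <- make_geometry(
    fov_deg = as.numeric(payload$fov_deg), n_ascans = payload$n_ascans,
    n_bscans = payload$n_bscans, mm_per_deg = as.numeric(payload$mm_per_deg),
    bscan_spacing_um = as.numeric(payload$bscan_spacing_um),
    axial_pitch_um = as.numeric(payload$axial_pitch_um),
    laterality = payload$laterality, device_label = payload$device_label)
  fovea <- NULL
  if (!is.null(payload$fovea_center))
    fovea <- as.integer(payload$fovea_center) + 1L
  list(geometry = geometry, fovea_center = fovea)
}

#' @export
print.scan_geometry <- function(x, ...) {
  cat(sprintf(
    "<scan_geometry> %d A-scans x %d B-scans, %g deg FOV (%s, %s)\n",
    x$n_ascans, x$n_bscans, x$fov_deg, x$laterality, x$device_label))
  cat(sprintf("  lateral pitch %.3f um, B-scan spacing %.2f um, cell %.3e mm^2\n",
              lateral_spacing_um(x), x$bscan_spacing_um,
              column_cell_area_mm2(x)))
  invisible(x)
}
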