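#' Write / read a surface table (TSV + JSON geometry sidecar)
#'
#' The on-disk exchange format for one eye on one device: a TSV with
#' header columns exactly
#' `eye_id, patient_id, device, bscan, ascan, elm_um, ez_inner_um,
#' ez_outer_um, rpe_inner_um, rpe_outer_um, sdd_disrupted`
#' (one row per A-scan column covering the lattice exactly once; empty
#' cell = missing surface; `bscan`/`ascan` are 0-based), plus a JSON
#' sidecar `<path without .tsv>.json` holding the [make_geometry()]
#' fields and the 0-based `fovea_center`.
#'
#' @param surfaces a [surface_set()].
#' @param path TSV file path; the sidecar path is derived from it.
#' @param digits decimal places for the um values (default 2).
#' @return `write_surface_table()` returns `path` invisibly;
#'   `read_surface_table()` returns a validated [surface_set()].
#' @export
write_surface_table <- function(surfaces, path, digits = 2) {
  stopifnot(inherits(surfaces, "surface_set"))
  g <- surfaces$geometry
  nb <- g$n_bscans; na_ <- g$n_ascans
  b <- rep(seq_len(nb) - 1L, times = na_)
  a <- rep(seq_len(na_) - 1L, each = nb)
  fmt <- function(m) {
    v <- round(as.vector(m), digits)
    out <- as.character(v)
    out[is.na(v)] <- ""
    out
  }
  df <- data.frame(
    eye_id = surfaces$eye_id, patient_id = surfaces$patient_id,
    device = surfaces$device, bscan = b, ascan = a,
    elm_um = fmt(surfaces$surfaces$ELM),
    ez_inner_um = fmt(surfaces$surfaces$EZ_inner),
    ez_outer_um = fmt(surfaces$surfaces$EZ_outer),
    rpe_inner_um = fmt(surfaces$surfaces$RPE_inner),
    rpe_outer_um = fmt(surfaces$surfaces$RPE_outer),
    sdd_disrupted = as.integer(as.vector(surfaces$sdd_disrupted)),
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  write_geometry_json(g, .sidecar_path(path), surfaces$fovea_center)
  invisible(path)
}

.sidecar_path <- function(path) paste0(tools::file_path_sans_ext(path), ".json")

SURFACE_TABLE_COLUMNS <- c(
  "eye_id", "patient_id", "device", "bscan", "ascan", "elm_um",
  "ez_inner_um", "ez_outer_um", "rpe_inner_um", "rpe_outer_um",
  "sdd_disrupted")

#' @rdname write_surface_table
#' @export
read_surface_table <- function(path) {
  if (!file.exists(path)) stop("surface table not found: ", path)
  sidecar <- .sidecar_path(path)
  if (!file.exists(sidecar))
    stop("geometry sidecar not found: ", sidecar)
  side <- read_geometry_json(sidecar)
  if (is.null(side$fovea_center))
    stop("geometry sidecar ", sidecar, " lacks fovea_center")
  g <- side$geometry
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          na.strings = "", stringsAsFactors = FALSE,
                          check.names = FALSE)
  if (!identical(names(df), SURFACE_TABLE_COLUMNS))
    stop("surface table header must be exactly: ",
         paste(SURFACE_TABLE_COLUMNS, collapse = ", "))
  nb <- g$n_bscans; na_ <- g$n_ascans
  if (nrow(df) != nb * na_)
    stop(sprintf("expected %d rows (%d B-scans x %d A-scans), found %d",
                 nb * na_, nb, na_, nrow(df)))
  key <- df$bscan * na_ + df$ascan
  if (anyDuplicated(key))
    stop("duplicate (bscan, ascan) at row ",
         which(duplicated(key))[1])
  if (any(df$bscan < 0 | df$bscan >= nb | df$ascan < 0 | df$ascan >= na_))
    stop("(bscan, ascan) outside the lattice at row ",
         which(df$bscan < 0 | df$bscan >= nb |
                 df$ascan < 0 | df$ascan >= na_)[1])
  o <- order(df$ascan, df$bscan)   # column-major: bscan fastest
  df <- df[o, , drop = FALSE]
  as_mat <- function(col) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(!is.na(df[[col]]) & is.na(v))
    if (length(bad))
      stop("non-numeric value in ", col, " at row ", o[bad[1]])
    matrix(v, nb, na_)
  }
  surfaces <- list(ELM = as_mat("elm_um"),
                   EZ_inner = as_mat("ez_inner_um"),
                   EZ_outer = as_mat("ez_outer_um"),
                   RPE_inner = as_mat("rpe_inner_um"),
                   RPE_outer = as_mat("rpe_outer_um"))
  surface_set(surfaces, g, side$fovea_center,
              eye_id = df$eye_id[1], patient_id = df$patient_id[1],
              sdd_disrupted = matrix(df$sdd_disrupted == 1, nb, na_))
}

#' Write the quantification outputs of one eye
#'
#' Emits per-band en-face TSV matrices (one file per quantity, missing =
#' `NA`) and a `summary.json` with the loss areas and SDD volume.
#'
#' @param quant a [quantify_eye()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_quant_result <- function(quant, dir) {
  stopifnot(inherits(quant, "quant_result"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wm <- function(m, name)
    utils::write.table(m, file.path(dir, paste0(name, ".tsv")), sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE,
                       na = "NA")
  summary <- list(eye_id = quant$eye_id, patient_id = quant$patient_id,
                  device = quant$device,
                  sdd_threshold_um = quant$sdd_threshold_um,
                  sdd_volume_nl = quant$sdd_volume_nl)
  for (b in BAND_NAMES) {
    wm(quant$bands[[b]]$thickness$values, paste0("thickness_", b))
    wm(quant$bands[[b]]$loss$values, paste0("loss_", b))
    summary[[paste0(b, "_loss_mm2")]] <- quant$bands[[b]]$loss_area_mm2
  }
  wm(quant$sdd_thickness$values, "sdd_thickness")
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
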