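#' Pipeline run configuration
#'
#' Bundles the tunable constants of a full pipeline run.  All defaults
#' reproduce the standard protocol: 4-um SDD threshold, ETDRS radii
#' 0.5/1.5/3.0 mm, 0.293 mm/deg lateral calibration, log-scale analysis
#' of the (right-skewed) whole-field loss areas, and Bonferroni
#' correction over each comparison family.
#'
#' @param sdd_threshold_um SDD registration threshold (um).
#' @param ring_radii_mm ETDRS ring radii (mm).
#' @param mm_per_deg lateral calibration used when geometries must be
#'   constructed.
#' @param log_outcomes outcomes compared on the log scale.
#' @param region_outcomes outcomes compared across ETDRS rings.
#' @param region_device device on which region comparisons run (`NULL`
#'   = last device in sort order, i.e. the higher-resolution device in
#'   the default two-device setup).
#' @param use_49_of_97 subsample 97-B-scan volumes to every second
#'   B-scan (49) before quantification.
#' @param seed seed recorded in the manifest (the pipeline itself is
#'   deterministic given its inputs).
#' @param keep_maps retain the full per-eye en-face maps in the result
#'   (memory-hungry for large cohorts; summaries are always kept).
#' @return An object of class `run_config`.
#' @export
run_config <- function(sdd_threshold_um = 4,
                       ring_radii_mm = c(0.5, 1.5, 3.0),
                       mm_per_deg = 0.293,
                       log_outcomes = c("ELM_MZ_loss_mm2", "EZ_loss_mm2",
                                        "RPE_loss_mm2"),
                       region_outcomes = c("EZ_thickness_um"),
                       region_device = NULL,
                       use_49_of_97 = TRUE,
                       seed = 1L,
                       keep_maps = FALSE) {
  stopifnot(sdd_threshold_um >= 0, length(ring_radii_mm) == 3,
            all(diff(ring_radii_mm) > 0))
  structure(as.list(environment()), class = "run_config")
}

# stable content hash (md5 of a version-2 serialization)
.hash_object <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, version = 2, compress = FALSE)
  unname(tools::md5sum(f))
}

#' Run the full quantification and comparison pipeline
#'
#' Orchestrates all stages over a cohort of surface sets: per-eye band
#' quantification ([quantify_eye()]), ETDRS subfield summaries
#' ([summarize_subfields()]), the cohort SDD distribution map, and — when
#' two devices and at least two patients are present — mixed-effects
#' device comparisons of the seven whole-field outcomes (three band
#' thicknesses, three loss areas on the log scale, SDD volume), ring
#' region comparisons, and SDD quadrant comparisons (center vs. each
#' quadrant and all quadrant pairs).  A manifest records input hashes,
#' the configuration and its hash, counts (including the total number of
#' quantified B-scans) and the package version, so a re-run on the same
#' inputs reproduces all outputs bit-identically.
#'
#' @param surface_sets list of [surface_set()] objects (>= 1), or a
#'   [generate_cohort()] result.
#' @param config a [run_config()].
#' @return An object of class `pipeline_result`: list with
#'   `measurements` (tidy whole-field + subfield table, one row per eye x
#'   device x subfield x outcome), `subfield_report`, `comparisons`
#'   (named list of `comparison_result`), `sdd_distribution`
#'   ([enface_map()]), `warnings` (e.g. 6-mm circle coverage), `manifest`
#'   and (if `keep_maps`) `quants`.
#' @export
run_pipeline <- function(surface_sets, config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  if (inherits(surface_sets, "phantom_cohort"))
    surface_sets <- surface_sets$surface_sets
  if (!length(surface_sets)) stop("empty input list")
  stopifnot(all(vapply(surface_sets, inherits, logical(1), "surface_set")))

  input_hashes <- vapply(surface_sets, .hash_object, character(1))
  quants <- list()
  meas_rows <- list()
  subfield_rows <- list()
  n_bscans_quantified <- 0L
  coverage <- NULL
  for (i in seq_along(surface_sets)) {
    ss <- surface_sets[[i]]
    if (config$use_49_of_97 && ss$geometry$n_bscans == 97L)
      ss <- subsample_bscans(ss, 2L)
    q <- quantify_eye(ss, config$sdd_threshold_um)
    grid <- etdrs_grid(q$fovea_center, q$geometry$laterality,
                       config$ring_radii_mm)
    rep_i <- summarize_subfields(q, grid)
    if (is.null(coverage))
      coverage <- etdrs_covered_fraction(grid, q$geometry)
    n_bscans_quantified <- n_bscans_quantified + q$geometry$n_bscans
    meas_rows[[i]] <- rbind(whole_field_measurements(q),
                            as.data.frame(rep_i))
    subfield_rows[[i]] <- rep_i
    quants[[paste(q$eye_id, q$device, sep = ".")]] <- q
  }
  measurements <- do.call(rbind, meas_rows)
  rownames(measurements) <- NULL
  subfield_report <- do.call(rbind, subfield_rows)
  rownames(subfield_report) <- NULL

  sdd_dist <- sdd_distribution_map(quants)

  devices <- unique(measurements$device)   # baseline = first-appearing
  n_patients <- length(unique(measurements$patient_id))
  comparisons <- list()
  if (length(devices) == 2 && n_patients >= 2) {
    wf_outcomes <- c("ELM_MZ_thickness_um", "EZ_thickness_um",
                     "RPE_thickness_um", "ELM_MZ_loss_mm2", "EZ_loss_mm2",
                     "RPE_loss_mm2", "SDD_volume_nl")
    for (oc in wf_outcomes) {
      comparisons[[paste0("device.", oc)]] <- fit_device_comparison(
        measurements, oc, subfield = "whole_field",
        log_scale = oc %in% config$log_outcomes, devices = devices,
        m = length(wf_outcomes))
    }
  }
  if (n_patients >= 2) {
    reg_dev <- config$region_device
    if (is.null(reg_dev)) reg_dev <- devices[length(devices)]
    rings <- c("center", "parafoveal_ring", "perifoveal_ring")
    for (oc in config$region_outcomes) {
      res <- tryCatch(
        fit_region_comparison(measurements, oc, rings, device = reg_dev),
        error = function(e) NULL)
      if (!is.null(res))
        for (nm in names(res))
          comparisons[[paste0("region.", oc, ".", nm)]] <- res[[nm]]
    }
    quad_regions <- c("quadrant_center", paste0("quadrant_",
                                                quadrant_labels))
    res <- tryCatch(
      fit_region_comparison(measurements, "SDD_volume_nl", quad_regions,
                            device = reg_dev),
      error = function(e) NULL)
    if (!is.null(res))
      for (nm in names(res))
        comparisons[[paste0("sdd.", nm)]] <- res[[nm]]
  }

  config_hash <- .hash_object(unclass(config))
  manifest <- list(
    n_surface_sets = length(surface_sets),
    n_eyes = length(unique(measurements$eye_id)),
    n_patients = n_patients,
    n_devices = length(devices),
    devices = devices,
    n_bscans_quantified = n_bscans_quantified,
    etdrs_covered_fraction = as.list(coverage),
    config = unclass(config),
    config_hash = config_hash,
    input_hashes = as.list(input_hashes),
    seed = config$seed,
    package_version = as.character(utils::packageVersion("octbands")))

  measurements$config_hash <- config_hash
  out <- list(measurements = measurements,
              subfield_report = subfield_report,
              comparisons = comparisons,
              sdd_distribution = sdd_dist,
              warnings = list(etdrs_covered_fraction = coverage),
              manifest = manifest)
  if (config$keep_maps) out$quants <- quants
  structure(out, class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  m <- x$manifest
  cat(sprintf("<pipeline_result> %d eyes of %d patients, %d device(s), %d quantified B-scans\n",
              m$n_eyes, m$n_patients, m$n_devices, m$n_bscans_quantified))
  cat(sprintf("  %d comparisons, config %s\n", length(x$comparisons),
              substr(m$config_hash, 1, 8)))
  invisible(x)
}

# flatten comparisons for TSV export
.comparisons_table <- function(comparisons) {
  if (!length(comparisons)) return(data.frame())
  do.call(rbind, lapply(names(comparisons), function(nm) {
    cr <- comparisons[[nm]]
    data.frame(id = nm, outcome = cr$outcome, contrast = cr$contrast,
               estimate = cr$estimate, ci_lower = cr$ci[1],
               ci_upper = cr$ci[2], p_raw = cr$p_raw,
               p_bonferroni = cr$p_bonferroni, scale = cr$scale,
               degraded = cr$degraded, n_eyes = cr$n_eyes,
               n_patients = cr$n_patients, stringsAsFactors = FALSE)
  }))
}

#' Write a pipeline result to a directory
#'
#' Emits `measurements.tsv` (carrying the config hash), `comparisons.tsv`,
#' `sdd_distribution.tsv` and `manifest.json`.
#'
#' @param result a [run_pipeline()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_pipeline_result <- function(result, dir) {
  stopifnot(inherits(result, "pipeline_result"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(result$measurements, file.path(dir, "measurements.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(.comparisons_table(result$comparisons),
                     file.path(dir, "comparisons.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(result$sdd_distribution$values,
                     file.path(dir, "sdd_distribution.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE,
                     na = "NA")
  jsonlite::write_json(result$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
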