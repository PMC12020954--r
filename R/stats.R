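#' Bonferroni correction
#'
#' `min(1, m * p)` elementwise, for an explicit family size `m` (which
#' may exceed the number of p-values passed, e.g. when correcting one
#' contrast out of a larger family).
#'
#' @param p p-values in `[0, 1]`.
#' @param m family size (>= 1); defaults to `length(p)`.
#' @return adjusted p-values.
#' @export
bonferroni_adjust <- function(p, m = length(p)) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  if (m < 1) stop("m must be >= 1")
  pmin(1, m * p)
}

#' Back-transform a log-scale mean and CI
#'
#' Elementwise exponentiation of a mean and confidence bounds estimated
#' on the natural-log scale; the back-transformed interval is asymmetric
#' about the mean.
#'
#' @param mean_log mean on the log scale.
#' @param ci_log length-2 confidence bounds on the log scale.
#' @return list with `mean` and `ci` on the original scale.
#' @export
back_transform_log <- function(mean_log, ci_log) {
  stopifnot(is.finite(mean_log), length(ci_log) == 2, all(is.finite(ci_log)))
  list(mean = exp(mean_log), ci = exp(ci_log))
}

# log-transform with documented zero handling: exact zeros are offset by
# half the smallest positive observed value (configurable upstream).
.log_with_zero_offset <- function(values, label = "outcome") {
  if (any(values < 0))
    stop(label, ": negative values cannot be log-transformed (rows ",
         paste(which(values < 0), collapse = ", "), ")")
  if (any(values == 0)) {
    pos <- values[values > 0]
    if (!length(pos))
      stop(label, ": all values are zero; log transform impossible")
    values[values == 0] <- min(pos) / 2
  }
  log(values)
}

# fit value ~ fixed + (1|patient) + (1|eye) (eyes nested in patients).
# On a singular two-level fit the intercept whose variance collapsed is
# dropped — flagged as degraded, never silently: typically the patient
# intercept when few patients contribute both eyes, which preserves the
# paired (within-eye) design.
.fit_mixed <- function(data, fixed) {
  data$patient_id <- factor(data$patient_id)
  data$eye_id <- factor(data$eye_id)
  two_level <- nlevels(data$eye_id) > nlevels(data$patient_id) &&
    any(table(data$eye_id) > 1)
  fit_formula <- function(f) {
    suppressMessages(suppressWarnings(
      lmerTest::lmer(stats::as.formula(f), data = data, REML = TRUE)))
  }
  try_fit <- function(f) {
    m <- tryCatch(fit_formula(f), error = function(e) NULL)
    if (!is.null(m) && lme4::isSingular(m, tol = 1e-4)) m <- NULL
    m
  }
  degraded <- FALSE
  model <- NULL
  if (two_level) {
    model <- try_fit(paste0("value ~ ", fixed,
                            " + (1 | patient_id) + (1 | eye_id)"))
    if (is.null(model)) {
      degraded <- TRUE
      model <- try_fit(paste0("value ~ ", fixed, " + (1 | eye_id)"))
    }
  }
  if (is.null(model)) {
    degraded <- degraded || two_level
    model <- fit_formula(paste0("value ~ ", fixed, " + (1 | patient_id)"))
  }
  list(model = model, degraded = degraded)
}

# one contrast L'beta with Satterthwaite df; returns estimate, CI, p
.contrast <- function(model, L, level = 0.95) {
  ct <- lmerTest::contest1D(model, L, confint = FALSE)
  df <- max(1, ct$df)
  q <- stats::qt(1 - (1 - level) / 2, df)
  list(estimate = ct$Estimate, se = ct$`Std. Error`, df = df,
       lower = ct$Estimate - q * ct$`Std. Error`,
       upper = ct$Estimate + q * ct$`Std. Error`,
       p = ct$`Pr(>|t|)`)
}

.new_comparison_result <- function(outcome, contrast, est, means, p_raw,
                                   m, scale, degraded, n_eyes, n_patients) {
  structure(
    list(outcome = outcome, contrast = contrast,
         estimate = est$estimate, ci = c(est$lower, est$upper),
         df = est$df, p_raw = p_raw,
         p_bonferroni = bonferroni_adjust(p_raw, m),
         scale = scale, means = means, degraded = degraded,
         n_eyes = n_eyes, n_patients = n_patients),
    class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("<comparison_result> %s: %s\n", x$outcome, x$contrast))
  cat(sprintf("  estimate %.4g (95%% CI %.4g to %.4g), p = %.4g (Bonferroni %.4g)%s\n",
              x$estimate, x$ci[1], x$ci[2], x$p_raw, x$p_bonferroni,
              if (x$degraded) " [degraded: eye-level intercept dropped]" else ""))
  if (!is.null(x$means)) {
    for (i in seq_len(nrow(x$means)))
      cat(sprintf("  %-18s %.4g (%.4g to %.4g)\n", x$means$level[i],
                  x$means$mean[i], x$means$lower[i], x$means$upper[i]))
  }
  cat(sprintf("  scale: %s, %d eyes of %d patients\n", x$scale,
              x$n_eyes, x$n_patients))
  invisible(x)
}

# common preparation for both comparison fitters
.prepare_table <- function(table, outcome, subfield) {
  need <- c("patient_id", "eye_id", "device", "subfield", "outcome", "value")
  miss <- setdiff(need, names(table))
  if (length(miss))
    stop("measurement table lacks columns: ", paste(miss, collapse = ", "))
  d <- table[table$outcome == outcome, , drop = FALSE]
  if (!is.null(subfield)) d <- d[d$subfield %in% subfield, , drop = FALSE]
  if (!nrow(d)) stop("no rows for outcome ", outcome)
  if (anyDuplicated(d[, c("eye_id", "device", "subfield", "outcome")]))
    stop("duplicate (eye, device, subfield, outcome) rows")
  d
}

#' Mixed-effects device comparison of one outcome
#'
#' Fits `value ~ device + (1 | patient) + (1 | eye)` by REML on a tidy
#' measurement table (one row per eye x device), returning the device
#' contrast and per-device model means with 95% CIs (Satterthwaite
#' degrees of freedom).  Eyes are nested in patients, accounting for
#' inclusion of both eyes of some patients; if the eye-level intercept
#' makes the fit singular it is dropped and the result is flagged
#' `degraded`.
#'
#' With `log_scale = TRUE` (used for right-skewed loss areas) the values
#' are log-transformed before fitting — exact zeros are offset by half
#' the smallest positive observed value — and the reported means, CIs
#' and contrast are back-transformed by exponentiation (the contrast
#' then is a ratio).
#'
#' @param table data frame with columns
#'   `patient_id, eye_id, device, subfield, outcome, value`.
#' @param outcome the outcome label to model.
#' @param subfield subfield to restrict to (default `"whole_field"`).
#' @param log_scale analyze on the natural-log scale.
#' @param devices optional length-2 character vector fixing the factor
#'   order; the contrast is `devices[2] - devices[1]`.
#' @param m Bonferroni family size for the adjusted p-value.
#' @return a `comparison_result`.
#' @export
fit_device_comparison <- function(table, outcome, subfield = "whole_field",
                                  log_scale = FALSE, devices = NULL, m = 1) {
  d <- .prepare_table(table, outcome, subfield)
  if (is.null(devices)) devices <- sort(unique(d$device))
  if (length(devices) != 2)
    stop("device comparison requires exactly two devices, got: ",
         paste(devices, collapse = ", "))
  d <- d[d$device %in% devices, , drop = FALSE]
  per_eye <- table(d$eye_id)
  if (any(per_eye != 2))
    stop("each eye must be measured on both devices; offending eyes: ",
         paste(names(per_eye)[per_eye != 2], collapse = ", "))
  if (length(unique(d$patient_id)) < 2)
    stop("insufficient grouping levels: need >= 2 patients")
  d$device <- factor(d$device, levels = devices)
  if (log_scale) d$value <- .log_with_zero_offset(d$value, outcome)
  fit <- .fit_mixed(d, "device")
  est <- .contrast(fit$model, c(0, 1))
  mean_rows <- lapply(seq_along(devices), function(i) {
    mi <- .contrast(fit$model, c(1, i - 1))
    data.frame(level = devices[i], mean = mi$estimate,
               lower = mi$lower, upper = mi$upper)
  })
  means <- do.call(rbind, mean_rows)
  scale <- "identity"
  if (log_scale) {
    means$mean <- exp(means$mean)
    means$lower <- exp(means$lower)
    means$upper <- exp(means$upper)
    est$estimate <- exp(est$estimate)
    est$lower <- exp(est$lower)
    est$upper <- exp(est$upper)
    scale <- "log-back-transformed"
  }
  .new_comparison_result(
    outcome, paste(devices[2], "-", devices[1]), est, means, est$p, m,
    scale, fit$degraded, length(unique(d$eye_id)),
    length(unique(d$patient_id)))
}

#' Mixed-effects comparison between regions (subfields)
#'
#' Fits `value ~ region + (1 | patient) + (1 | eye)` across the given
#' subfields and returns all pairwise region contrasts, Bonferroni-
#' corrected over the number of contrasts (by default
#' `choose(k, 2)`).
#'
#' @param table tidy measurement table (see [fit_device_comparison()]).
#' @param outcome outcome label to model.
#' @param regions character vector (>= 2) of subfield labels to compare.
#' @param device optional single device to restrict to.
#' @param log_scale analyze on the log scale (zeros offset as in
#'   [fit_device_comparison()]).
#' @param m Bonferroni family size (default: number of pairs).
#' @return list of `comparison_result`, one per region pair
#'   (`later - earlier` in the order of `regions`).
#' @export
fit_region_comparison <- function(table, outcome, regions,
                                  device = NULL, log_scale = FALSE,
                                  m = choose(length(regions), 2)) {
  stopifnot(length(regions) >= 2)
  d <- .prepare_table(table, outcome, regions)
  if (!is.null(device)) d <- d[d$device == device, , drop = FALSE]
  d <- d[!is.na(d$value), , drop = FALSE]
  empty <- setdiff(regions, unique(d$subfield))
  if (length(empty))
    stop("no non-missing values for region(s): ",
         paste(empty, collapse = ", "))
  have <- table(d$eye_id)
  if (any(have < 2))
    stop("each eye needs >= 2 regions present")
  if (length(unique(d$patient_id)) < 2)
    stop("insufficient grouping levels: need >= 2 patients")
  d$region <- factor(d$subfield, levels = regions)
  if (log_scale) d$value <- .log_with_zero_offset(d$value, outcome)
  fit <- .fit_mixed(d, "region")
  k <- length(regions)
  out <- list()
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      L <- numeric(k)        # coef order: intercept, region2..regionk
      if (j > 1) L[j] <- 1
      if (i > 1) L[i] <- -1
      est <- .contrast(fit$model, L)
      scale <- "identity"
      if (log_scale) {
        est$estimate <- exp(est$estimate)
        est$lower <- exp(est$lower)
        est$upper <- exp(est$upper)
        scale <- "log-back-transformed"
      }
      out[[paste(regions[j], "-", regions[i])]] <- .new_comparison_result(
        outcome, paste(regions[j], "-", regions[i]), est, NULL, est$p, m,
        scale, fit$degraded, length(unique(d$eye_id)),
        length(unique(d$patient_id)))
    }
  }
  out
}

#' Whole-field measurement rows of a quantified eye
#'
#' One tidy row per outcome (`subfield = "whole_field"`): mean band
#' thickness over non-missing columns (um), band loss areas (mm^2) and
#' the SDD volume (nL) — the per-eye inputs of the device comparison.
#'
#' @param quant a [quantify_eye()] result.
#' @return data frame with columns
#'   `eye_id, patient_id, device, subfield, outcome, value`.
#' @export
whole_field_measurements <- function(quant) {
  stopifnot(inherits(quant, "quant_result"))
  rows <- list()
  for (b in BAND_NAMES) {
    th <- quant$bands[[b]]$thickness$values
    rows[[paste0(b, "_thickness_um")]] <-
      if (any(!is.na(th))) mean(th, na.rm = TRUE) else NA_real_
    rows[[paste0(b, "_loss_mm2")]] <- quant$bands[[b]]$loss_area_mm2
  }
  rows[["SDD_volume_nl"]] <- quant$sdd_volume_nl
  data.frame(eye_id = quant$eye_id, patient_id = quant$patient_id,
             device = quant$device, subfield = "whole_field",
             outcome = names(rows), value = unlist(rows),
             row.names = NULL, stringsAsFactors = FALSE)
}
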