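# Reporting: sample-level positivity, dilution-series linearity and limit of
# detection, cohort sensitivity/specificity, longitudinal per-patient series.

#' Combine per-amplicon detection results into a sample-level call
#'
#' A sample is positive when at least one evaluable amplicon is called; the
#' reported sample ctDNA fraction is the maximum VAF among called amplicons
#' (robust to per-variant dropout; `fraction_method = "mean"` averages them
#' instead). Negative samples report `NA` — printed as "ND", not detected.
#' When results carry an `origin_label` (multi-tumour assays), a per-label
#' breakdown is included so recurrence can be attributed to a specific
#' tumour of origin.
#'
#' @param results data.frame of per-amplicon results with columns `called`,
#'   `vaf`, `status`, optionally `amplicon_id`, `p_value`, `origin_label`.
#' @param sample_id,timepoint Optional sample identifier and day relative to
#'   surgery.
#' @param fraction_method `"max"` (default) or `"mean"` over called
#'   amplicons.
#' @return List of class `sample_call`: `sample_id`, `timepoint`, `status`,
#'   `positive`, `ctdna_fraction`, `n_called`, `n_evaluable`, `results`,
#'   and `origin_breakdown` when labels are present.
#' @export
call_sample <- function(results, sample_id = NA_character_,
                        timepoint = NA_real_,
                        fraction_method = c("max", "mean")) {
  fraction_method <- match.arg(fraction_method)
  if (nrow(results) == 0L) stop("empty result set")
  ev <- results$status == "evaluable"
  out <- list(sample_id = sample_id, timepoint = timepoint,
              status = if (any(ev)) "evaluable" else "unevaluable",
              positive = FALSE, ctdna_fraction = NA_real_,
              n_called = 0L, n_evaluable = sum(ev), results = results)
  class(out) <- "sample_call"
  if (!any(ev)) return(out)
  called <- ev & results$called
  out$n_called <- sum(called)
  out$positive <- any(called)
  agg <- if (fraction_method == "max") max else mean
  if (out$positive) out$ctdna_fraction <- agg(results$vaf[called])
  if ("origin_label" %in% names(results)) {
    labs <- unique(results$origin_label)
    out$origin_breakdown <- data.frame(
      origin_label = labs,
      positive = vapply(labs, function(l)
        any(called & results$origin_label == l), logical(1)),
      ctdna_fraction = vapply(labs, function(l) {
        sel <- called & results$origin_label == l
        if (any(sel)) agg(results$vaf[sel]) else NA_real_
      }, numeric(1)),
      row.names = NULL
    )
  }
  out
}

#' @export
print.sample_call <- function(x, ...) {
  frac <- if (is.na(x$ctdna_fraction)) "ND" else
    format(x$ctdna_fraction, digits = 3)
  cat(sprintf("sample_call '%s': %s, ctDNA fraction %s (%d/%d amplicons called)\n",
              x$sample_id,
              if (x$status == "unevaluable") "unevaluable"
              else if (x$positive) "POSITIVE" else "negative",
              frac, x$n_called, x$n_evaluable))
  invisible(x)
}

#' Linearity of observed vs expected VAF across a dilution series
#'
#' Amplicons failing the `min_depth` filter at any point of the series are
#' excluded entirely; remaining amplicons need at least 3 dilution points.
#' Per amplicon, the Pearson correlation between expected and observed
#' variant frequencies is computed; an undefined correlation (constant
#' observed series) counts against the `r > r_threshold` criterion rather
#' than shrinking its denominator. The aggregate r-squared pools all
#' (expected, observed) pairs.
#'
#' @param series data.frame with columns `amplicon_id`, `expected`,
#'   `observed`, `depth` (one row per amplicon x ratio).
#' @param min_depth Depth required at every point (default 1000).
#' @param r_threshold Per-amplicon correlation criterion (default 0.95).
#' @return List of class `dilution_result`: `per_amplicon` (data.frame with
#'   `r`), `fraction_above_threshold`, `aggregate_r2`, `n_excluded_depth`.
#' @export
dilution_linearity <- function(series, min_depth = 1000L, r_threshold = 0.95) {
  sp <- split(series, series$amplicon_id)
  deep <- vapply(sp, function(d) all(d$depth >= min_depth), logical(1))
  sp <- sp[deep]
  sp <- sp[vapply(sp, nrow, integer(1)) >= 3L]
  if (!length(sp)) stop("no amplicon has >= 3 dilution points at required depth")
  r <- vapply(sp, function(d)
    suppressWarnings(cor(d$expected, d$observed)), numeric(1))
  pooled <- do.call(rbind, sp)
  structure(list(
    per_amplicon = data.frame(amplicon_id = names(sp), r = unname(r),
                              stringsAsFactors = FALSE),
    fraction_above_threshold = sum(r > r_threshold, na.rm = TRUE) / length(r),
    aggregate_r2 = suppressWarnings(cor(pooled$expected, pooled$observed))^2,
    n_excluded_depth = sum(!deep)),
    class = "dilution_result")
}

#' Detection proportions by expected-frequency bin with the binomial band
#'
#' Bins amplicon results by expected variant frequency and reports the
#' observed positive proportion per bin together with the band
#' `[1-(1-f_min)^G, 1-(1-f_max)^G]` — the probability that at least one
#' mutant template is drawn among `G` genome equivalents at the bin's lowest
#' and highest expected frequencies. Detection cannot beat this
#' template-sampling bound however deep the sequencing. Also reports
#' cumulative detection at-or-above and below each distinct expected
#' frequency.
#'
#' @param results data.frame with columns `expected_f` and `detected`
#'   (logical), evaluable amplicons only.
#' @param bin_edges Numeric vector of bin boundaries on the
#'   expected-frequency axis.
#' @param G Genome equivalents (default 3000).
#' @return List with `bins` and `cumulative` data.frames.
#' @export
detection_by_frequency_bins <- function(results, bin_edges, G = 3000) {
  bin <- cut(results$expected_f, bin_edges, include.lowest = TRUE)
  bins <- do.call(rbind, lapply(levels(bin), function(lv) {
    sel <- which(bin == lv)
    if (!length(sel)) {
      return(data.frame(bin = lv, n = 0L, positive_fraction = NA_real_,
                        f_min = NA_real_, f_max = NA_real_,
                        band_lower = NA_real_, band_upper = NA_real_))
    }
    fmin <- min(results$expected_f[sel]); fmax <- max(results$expected_f[sel])
    data.frame(bin = lv, n = length(sel),
               positive_fraction = mean(results$detected[sel]),
               f_min = fmin, f_max = fmax,
               band_lower = expected_detection_probability(fmin, G),
               band_upper = expected_detection_probability(fmax, G))
  }))
  fs <- sort(unique(results$expected_f))
  cumulative <- data.frame(
    expected_f = fs,
    detected_at_or_above = vapply(fs, function(f)
      mean(results$detected[results$expected_f >= f]), numeric(1)),
    detected_below = vapply(fs, function(f) {
      sel <- results$expected_f < f
      if (any(sel)) mean(results$detected[sel]) else NA_real_
    }, numeric(1)))
  list(bins = bins, cumulative = cumulative)
}

#' Cohort sensitivity and specificity at amplicon and sample level
#'
#' Amplicons with `status == "not_called"` (depth-failed) are excluded from
#' all denominators. Sensitivity is TP/(TP+FN) over expected-positive units,
#' specificity TN/(TN+FP) over expected-negative units, each with an exact
#' (Clopper-Pearson) 95% confidence interval; sample-level metrics call a
#' sample positive when any of its amplicons is called.
#'
#' @param calls data.frame with columns `called` (logical),
#'   `expected_positive` (logical), `status`, and optionally `sample_id`.
#' @return List with `per_amplicon` and (when `sample_id` present)
#'   `per_sample`, each `sensitivity`, `specificity`, counts and CIs.
#' @export
cohort_metrics <- function(calls) {
  ev <- calls[calls$status != "not_called", , drop = FALSE]
  level <- function(called, truth) {
    TP <- sum(called & truth); FN <- sum(!called & truth)
    TN <- sum(!called & !truth); FP <- sum(called & !truth)
    sens <- if (TP + FN > 0) TP / (TP + FN) else NA_real_
    spec <- if (TN + FP > 0) TN / (TN + FP) else NA_real_
    list(TP = TP, FP = FP, TN = TN, FN = FN,
         sensitivity = sens,
         sensitivity_ci = if (!is.na(sens))
           as.numeric(binom.test(TP, TP + FN)$conf.int) else c(NA, NA),
         specificity = spec,
         specificity_ci = if (!is.na(spec))
           as.numeric(binom.test(TN, TN + FP)$conf.int) else c(NA, NA))
  }
  out <- list(per_amplicon = level(ev$called, ev$expected_positive))
  if ("sample_id" %in% names(ev)) {
    bys <- split(ev, ev$sample_id)
    out$per_sample <- level(
      vapply(bys, function(d) any(d$called), logical(1)),
      vapply(bys, function(d) any(d$expected_positive), logical(1)))
  }
  out
}

#' Per-patient longitudinal detection series and lead times
#'
#' Orders each patient's sample calls by timepoint, optionally splits the
#' reported fraction by tumour-of-origin label, and computes the lead time
#' from the first positive sample at or before each clinical event to that
#' event (days). External marker columns (e.g. CEA) pass through untouched.
#'
#' @param sample_calls data.frame with columns `patient_id`, `timepoint`
#'   (days relative to surgery), `positive` (logical), `ctdna_fraction`, and
#'   any pass-through columns.
#' @param events Optional data.frame `patient_id`, `day`, `label` of clinical
#'   events (e.g. radiological recurrence).
#' @return List with `series` (ordered, with `duplicate_timepoint` flag) and
#'   `lead_times` (per event: `lead_time_days`, NA when never positive
#'   before the event).
#' @export
longitudinal_report <- function(sample_calls, events = NULL) {
  ord <- order(sample_calls$patient_id, sample_calls$timepoint)
  series <- sample_calls[ord, , drop = FALSE]
  dup <- stats::ave(series$timepoint, series$patient_id,
                    FUN = function(x) duplicated(x))
  series$duplicate_timepoint <- as.logical(dup)
  if (any(series$duplicate_timepoint)) {
    warning("duplicate timepoints flagged for: ",
            paste(unique(series$patient_id[series$duplicate_timepoint]),
                  collapse = ", "))
  }
  lead_times <- NULL
  if (!is.null(events) && nrow(events) > 0L) {
    lead_times <- do.call(rbind, lapply(seq_len(nrow(events)), function(i) {
      ev <- events[i, ]
      s <- series[series$patient_id == ev$patient_id &
                    series$positive & series$timepoint <= ev$day, ,
                  drop = FALSE]
      data.frame(patient_id = ev$patient_id, event_day = ev$day,
                 label = ev$label,
                 first_positive_day = if (nrow(s)) min(s$timepoint) else NA_real_,
                 lead_time_days = if (nrow(s)) ev$day - min(s$timepoint)
                 else NA_real_)
    }))
  }
  list(series = series, lead_times = lead_times)
}
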