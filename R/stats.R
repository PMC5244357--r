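# The error-correction statistic.
#
# Whether an amplicon's variant-read rate exceeds the background is decided
# by a one-tailed exact conditional test of the ratio of two Poisson rates:
# conditional on the total count m = k1 + k2, the sample count is
# Binomial(m, p0) with p0 = n1/(n1 + n2) under a rate ratio of 1, and the
# p-value is the inclusive upper tail P(X >= k1). The comparator is always
# the same-run negative control with the highest variant proportion, which
# absorbs overdispersion that three controls are too few to model
# parametrically.

#' Calling parameters
#'
#' @param alpha Significance cutoff on the exact test's p-value
#'   (default 0.01, the ROC-calibrated operating point of the assay).
#' @param min_depth Minimum informative read depth for an amplicon to be
#'   evaluable (default 1000).
#' @param n_controls_required Number of same-run negative controls expected,
#'   1-3.
#' @return List of class `call_parameters`.
#' @export
call_parameters <- function(alpha = 0.01, min_depth = 1000L,
                            n_controls_required = 3L) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (n_controls_required < 1L || n_controls_required > 3L) {
    stop("n_controls_required must be 1-3")
  }
  structure(list(alpha = alpha, min_depth = as.integer(min_depth),
                 n_controls_required = as.integer(n_controls_required)),
            class = "call_parameters")
}

#' One-tailed exact conditional test of the ratio of two Poisson rates
#'
#' Tests whether the event rate `k1/n1` exceeds `k2/n2`. Conditional on
#' `m = k1 + k2`, the sample count under the null (rate ratio 1) is
#' Binomial(`m`, `p0`) with `p0 = n1/(n1 + n2)`; the returned p-value is the
#' inclusive upper tail `P(X >= k1)`, computed with the regularised
#' incomplete beta identity (`pbinom`), numerically stable for totals well
#' beyond 1e6.
#'
#' @param k1,n1 Event count and exposure (read depth) in the sample.
#' @param k2,n2 Event count and exposure in the comparator (control).
#' @return One-sided p-value(s); vectorised over arguments.
#' @examples
#' poisson_rate_ratio_test(10, 1e4, 0, 1e4)   # 0.5^10
#' @export
poisson_rate_ratio_test <- function(k1, n1, k2, n2) {
  if (any(n1 <= 0) || any(n2 <= 0)) stop("exposures must be positive")
  if (any(k1 < 0) || any(k2 < 0)) stop("counts must be non-negative")
  if (any(k1 > n1) || any(k2 > n2)) stop("counts cannot exceed exposures")
  m <- k1 + k2
  p0 <- n1 / (n1 + n2)
  # P(X >= k1) inclusive; pbinom(k1-1, ..., lower.tail=FALSE); k1=0 -> 1
  pbinom(k1 - 1, m, p0, lower.tail = FALSE)
}

#' Select the reference negative control
#'
#' The comparator for the exact test is the control with the highest variant
#' proportion `k/n`; ties are broken towards the smallest depth, the more
#' conservative choice (a smaller control exposure raises `p0` and hence the
#' p-value).
#'
#' @param controls data.frame with columns `k` and `n`, one row per control
#'   (1-3 rows).
#' @return List `k2`, `n2`, `index` (row index of the chosen control).
#' @export
select_reference_control <- function(controls) {
  stopifnot(nrow(controls) >= 1L, nrow(controls) <= 3L)
  usable <- which(controls$n > 0)
  if (!length(usable)) stop("all controls have zero depth")
  prop <- controls$k[usable] / controls$n[usable]
  ord <- order(-prop, controls$n[usable])
  idx <- usable[ord[1L]]
  list(k2 = controls$k[idx], n2 = controls$n[idx], index = idx)
}

#' Call one amplicon against its negative controls
#'
#' Applies the depth filter, selects the maximum-proportion control, runs the
#' exact conditional Poisson rate-ratio test and calls the amplicon positive
#' iff `p < alpha` (strictly).
#'
#' @param count An `amplicon_count` (or list with `k`, `n`, optionally
#'   `amplicon_id`, `vaf`).
#' @param controls data.frame of control counts (`k`, `n`).
#' @param params A [call_parameters()] object.
#' @return List of class `detection_result`: `amplicon_id`, `k`, `n`,
#'   `control_k`, `control_n`, `control_index`, `p_value`, `called`,
#'   `vaf`, `status`.
#' @export
call_amplicon <- function(count, controls, params = call_parameters()) {
  res <- list(amplicon_id = count$amplicon_id %||% NA_character_,
              k = count$k, n = count$n,
              control_k = NA_integer_, control_n = NA_integer_,
              control_index = NA_integer_,
              p_value = NA_real_, called = FALSE,
              vaf = if (count$n > 0) count$k / count$n else NA_real_,
              status = "not_called")
  class(res) <- "detection_result"
  if (count$n < params$min_depth) return(res)
  ctrl <- select_reference_control(controls)
  res$control_k <- ctrl$k2; res$control_n <- ctrl$n2
  res$control_index <- ctrl$index
  res$p_value <- poisson_rate_ratio_test(count$k, count$n, ctrl$k2, ctrl$n2)
  res$called <- res$p_value < params$alpha
  res$status <- "evaluable"
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Per-base noise filtering of a sample pileup against control pileups
#'
#' The third error-correction stage: at every position, each non-reference
#' base call set in the sample is retained only if its proportion is
#' significantly higher (exact conditional Poisson test, `p < alpha`) than
#' the maximum proportion of that base across the same-run negative
#' controls; otherwise it is zeroed. Positions absent from a control are
#' treated as zero events at that control's median depth.
#'
#' @param sample_pileup Pileup matrix for the sample (from
#'   [build_pileup()]).
#' @param control_pileups List of 1-3 control pileup matrices over the same
#'   positions.
#' @param ref_seq Reference sequence of the contig.
#' @param params A [call_parameters()]; `alpha` is the retention threshold.
#' @return List with `filtered` (the sample pileup with non-significant
#'   non-reference counts zeroed), `tests` (per position/base test table),
#'   and `summary` (mean non-reference rate before and after filtering).
#' @export
base_noise_filter <- function(sample_pileup, control_pileups, ref_seq,
                              params = call_parameters()) {
  refb <- chars(ref_seq)
  L <- nrow(sample_pileup)
  filtered <- sample_pileup
  tests <- list()
  pre_num <- 0; post_num <- 0; den <- 0
  for (pos in seq_len(L)) {
    nonN <- sum(sample_pileup[pos, DNA_BASES])
    if (nonN == 0L) next
    den <- den + nonN
    for (b in setdiff(DNA_BASES, refb[pos])) {
      k1 <- sample_pileup[pos, b]
      if (k1 == 0L) next
      pre_num <- pre_num + k1
      ck <- vapply(control_pileups, function(cp) cp[pos, b], numeric(1))
      cn <- vapply(control_pileups,
                   function(cp) sum(cp[pos, DNA_BASES]), numeric(1))
      if (all(cn == 0)) {   # position unseen in controls: count 0 at median depth
        cn <- rep(max(1, stats::median(vapply(control_pileups, function(cp)
          stats::median(rowSums(cp[, DNA_BASES, drop = FALSE])), numeric(1)))),
          length(cn))
      }
      ctrl <- select_reference_control(data.frame(k = ck, n = cn))
      pv <- poisson_rate_ratio_test(k1, nonN, ctrl$k2, ctrl$n2)
      keep <- pv < params$alpha
      if (!keep) filtered[pos, b] <- 0L else post_num <- post_num + k1
      tests[[length(tests) + 1L]] <- data.frame(
        pos = pos, base = b, k = k1, n = nonN,
        control_k = ctrl$k2, control_n = ctrl$n2,
        p_value = pv, retained = keep
      )
    }
  }
  tests <- if (length(tests)) do.call(rbind, tests) else
    data.frame(pos = integer(0), base = character(0), k = integer(0),
               n = integer(0), control_k = integer(0), control_n = integer(0),
               p_value = numeric(0), retained = logical(0))
  list(filtered = filtered, tests = tests,
       summary = data.frame(
         pre_rate = if (den > 0) pre_num / den else NA_real_,
         post_rate = if (den > 0) post_num / den else NA_real_))
}

#' Calibrate the significance cutoff from labelled p-values
#'
#' Sweeps every distinct observed p-value as a candidate threshold (an
#' amplicon is called when `p < threshold`), tabulating TP/FP/TN/FN and
#' accuracy against the truth labels — the ROC construction used to fix the
#' assay's operating cutoff. Reports the first maximum-accuracy threshold,
#' the next larger candidate, and a recommended cutoff at their geometric
#' midpoint (the operating default stays user-chosen).
#'
#' @param p_values Numeric vector of per-amplicon p-values.
#' @param truth Logical vector: `TRUE` for expected-positive amplicons.
#' @return List of class `roc_curve`: `curve` (threshold table),
#'   `max_accuracy_threshold`, `next_threshold`, `recommended_cutoff`.
#' @export
calibrate_cutoff <- function(p_values, truth) {
  stopifnot(length(p_values) == length(truth))
  if (!any(truth) || all(truth)) {
    stop("calibration needs at least one positive and one negative label")
  }
  thr <- sort(unique(p_values))
  curve <- do.call(rbind, lapply(thr, function(t) {
    called <- p_values < t
    data.frame(threshold = t,
               TP = sum(called & truth), FP = sum(called & !truth),
               TN = sum(!called & !truth), FN = sum(!called & truth))
  }))
  curve$accuracy <- (curve$TP + curve$TN) / length(p_values)
  imax <- which.max(curve$accuracy)           # first maximum
  tmax <- curve$threshold[imax]
  tnext <- if (imax < nrow(curve)) curve$threshold[imax + 1L] else tmax
  structure(list(curve = curve,
                 max_accuracy_threshold = tmax,
                 next_threshold = tnext,
                 recommended_cutoff = sqrt(tmax * tnext)),
            class = "roc_curve")
}
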