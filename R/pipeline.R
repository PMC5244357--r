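# End-to-end convenience: FASTQ pairs -> merged reads -> per-amplicon counts
# -> exact-test calls -> sample call.

# merge + assign + count for one library; returns per-amplicon counts
counts_from_pairs <- function(pairs, p, min_overlap = 10L,
                              max_mismatch_fraction = 0.25,
                              min_length = 40L, max_primer_mismatches = 2L) {
  mg <- merge_pairs(pairs, min_overlap, max_mismatch_fraction)
  fl <- filter_short(mg$merged, min_length)
  asg <- assign_reads(fl$kept, p, max_primer_mismatches)
  a <- p$amplicons
  counts <- lapply(seq_len(nrow(a)), function(i) {
    grp <- asg$groups[[a$amplicon_id[i]]]
    if (is.null(grp)) grp <- data.frame(sequence = character(0))
    count_variant_reads(grp, a[i, ])
  })
  names(counts) <- a$amplicon_id
  list(counts = counts, merge_stats = mg$stats,
       n_short = nrow(fl$discarded), n_unassigned = asg$n_unassigned)
}

#' Run the full detection pipeline on one plasma sample
#'
#' Merges read pairs into masked consensus reads, drops short reads, assigns
#' reads to amplicons by forward primer, counts variant-supporting reads, and
#' calls each amplicon against the same-run negative controls with the exact
#' conditional Poisson rate-ratio test; finally aggregates to a sample-level
#' call.
#'
#' @param p A `ctdna_panel` with reference sequences.
#' @param sample_pairs data.frame of the plasma sample's read pairs (`id`,
#'   `mate1`, `mate2`), e.g. from [read_fastq_pairs()] or
#'   [simulate_reads()].
#' @param control_pairs List of 1-3 read-pair data.frames, one per same-run
#'   negative control.
#' @param params A [call_parameters()] object.
#' @param sample_id,timepoint Passed to [call_sample()].
#' @return List with `sample_call`, `amplicon_results` (data.frame), and
#'   per-library processing stats.
#' @export
detect_ctdna <- function(p, sample_pairs, control_pairs,
                         params = call_parameters(),
                         sample_id = "sample", timepoint = NA_real_) {
  if (length(control_pairs) < 1L || length(control_pairs) > 3L) {
    stop("between 1 and 3 negative controls are required")
  }
  smp <- counts_from_pairs(sample_pairs, p)
  ctl <- lapply(control_pairs, counts_from_pairs, p = p)
  a <- p$amplicons
  rows <- lapply(seq_len(nrow(a)), function(i) {
    id <- a$amplicon_id[i]
    controls <- data.frame(
      k = vapply(ctl, function(c) c$counts[[id]]$k, integer(1)),
      n = vapply(ctl, function(c) c$counts[[id]]$n, integer(1)))
    r <- call_amplicon(smp$counts[[id]], controls, params)
    data.frame(amplicon_id = id, k = r$k, n = r$n,
               control_k = r$control_k, control_n = r$control_n,
               p_value = r$p_value, called = r$called, vaf = r$vaf,
               status = r$status, origin_label = a$origin_label[i],
               stringsAsFactors = FALSE)
  })
  results <- do.call(rbind, rows)
  list(sample_call = call_sample(results, sample_id, timepoint),
       amplicon_results = results,
       sample_stats = smp[c("merge_stats", "n_short", "n_unassigned")],
       control_stats = lapply(ctl, `[`,
                              c("merge_stats", "n_short", "n_unassigned")))
}
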