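# Read counting: primer-anchored amplicon assignment, per-position pileups,
# variant-supporting read counts, the 1000X depth filter, and non-reference
# error-rate profiling.
#
# Merged reads from short amplicons start at the forward primer, so reads are
# anchored at contig position 0 and piled up ungapped; indel target variants
# are classified by haplotype matching around the variant footprint rather
# than by realignment.

PILEUP_COLS <- c("A", "C", "G", "T", "N", "del", "ins")

#' Assign merged reads to amplicons by forward primer
#'
#' A read is assigned to the unique amplicon whose forward primer matches the
#' read's 5' end within `max_primer_mismatches` mismatches; reads matching
#' zero or several amplicons are left unassigned.
#'
#' @param reads data.frame with a `sequence` column (merged reads).
#' @param p A `ctdna_panel`.
#' @param max_primer_mismatches Mismatch tolerance (default 2).
#' @return List with `groups` (named list of per-amplicon data.frames) and
#'   `n_unassigned`.
#' @export
assign_reads <- function(reads, p, max_primer_mismatches = 2L) {
  a <- p$amplicons
  n <- nrow(reads)
  nmatch <- integer(n)
  match_id <- rep(NA_character_, n)
  for (i in seq_len(nrow(a))) {
    primer <- chars(a$fwd_primer[i])
    plen <- length(primer)
    pre <- substr(reads$sequence, 1L, plen)
    full <- nchar(pre) == plen
    mm <- rep(plen, n)
    if (any(full)) {
      m <- matrix(unlist(strsplit(pre[full], "", fixed = TRUE)), nrow = plen)
      mm[full] <- colSums(m != primer)
    }
    hit <- mm <= max_primer_mismatches
    nmatch[hit] <- nmatch[hit] + 1L
    match_id[hit] <- a$amplicon_id[i]
  }
  assigned <- nmatch == 1L
  groups <- split(reads[assigned, , drop = FALSE], match_id[assigned])
  groups <- groups[intersect(a$amplicon_id, names(groups))]
  list(groups = groups, n_unassigned = sum(!assigned))
}

#' Build a per-position pileup for one amplicon
#'
#' Reads are stacked ungapped from contig position 1; per position the counts
#' of A, C, G, T and N calls are tabulated (`del`/`ins` columns are kept for
#' interface completeness and are zero under ungapped stacking). Column sums
#' per position equal the number of reads covering it.
#'
#' @param reads data.frame with a `sequence` column, assigned to this
#'   amplicon.
#' @param amplicon_length Contig length (rows of the pileup).
#' @return Integer matrix `amplicon_length x 7` with columns
#'   A, C, G, T, N, del, ins.
#' @export
build_pileup <- function(reads, amplicon_length) {
  mat <- matrix(0L, nrow = amplicon_length, ncol = length(PILEUP_COLS),
                dimnames = list(NULL, PILEUP_COLS))
  if (nrow(reads) == 0L) return(mat)
  lens <- pmin(nchar(reads$sequence), amplicon_length)
  ch <- strsplit(substr(reads$sequence, 1L, amplicon_length), "", fixed = TRUE)
  pos <- unlist(lapply(lens, seq_len))
  base <- unlist(ch)
  keep <- base %in% c("A", "C", "G", "T", "N")
  tab <- table(factor(base[keep], levels = c("A", "C", "G", "T", "N")),
               factor(pos[keep], levels = seq_len(amplicon_length)))
  mat[, 1:5] <- t(tab)
  mat
}

#' Count variant-supporting reads at an amplicon's target variant
#'
#' An SNV is supported by a read iff the read's base at the variant position
#' equals the alt allele; reads with `N` at the target position are excluded
#' from the depth denominator entirely (they are uninformative for either
#' allele). Indels are classified by matching the read against the reference
#' and the alt haplotype over the variant footprint plus a short downstream
#' anchor.
#'
#' @param reads data.frame of merged reads assigned to this amplicon.
#' @param amplicon One-row amplicon data.frame (from `panel$amplicons`),
#'   carrying `seq`, `variant_pos`, `ref`, `alt`.
#' @return List of class `amplicon_count`: `amplicon_id`, `k`
#'   (variant reads), `n` (informative depth), `ref_reads`, `other_reads`,
#'   `n_N` (reads masked at the target), `vaf`.
#' @export
count_variant_reads <- function(reads, amplicon) {
  a <- amplicon
  vpos <- a$variant_pos
  is_snv <- nchar(a$ref) == 1L && nchar(a$alt) == 1L
  seqs <- reads$sequence
  out <- list(amplicon_id = a$amplicon_id, k = 0L, n = 0L,
              ref_reads = 0L, other_reads = 0L, n_N = 0L, vaf = NA_real_)
  class(out) <- "amplicon_count"
  if (length(seqs) == 0L) return(out)
  if (is_snv) {
    covering <- nchar(seqs) > vpos
    base <- substr(seqs[covering], vpos + 1L, vpos + 1L)
    k <- sum(base == a$alt)
    ref_reads <- sum(base == a$ref)
    n_N <- sum(base == "N")
    other <- sum(covering) - k - ref_reads - n_N
  } else {
    anchor <- 6L
    ref_pat <- substr(a$seq, vpos + 1L, vpos + nchar(a$ref) + anchor)
    altseq <- alt_amplicon_seq(a)
    alt_pat <- substr(altseq, vpos + 1L, vpos + nchar(a$alt) + anchor)
    covering <- nchar(seqs) >= vpos + pmax(nchar(ref_pat), nchar(alt_pat))
    segs_ref <- substr(seqs[covering], vpos + 1L, vpos + nchar(ref_pat))
    segs_alt <- substr(seqs[covering], vpos + 1L, vpos + nchar(alt_pat))
    has_N <- grepl("N", substr(seqs[covering], vpos + 1L,
                               vpos + max(nchar(ref_pat), nchar(alt_pat))),
                   fixed = TRUE)
    k <- sum(segs_alt == alt_pat & !has_N)
    ref_reads <- sum(segs_ref == ref_pat & !has_N)
    n_N <- sum(has_N)
    other <- sum(covering) - k - ref_reads - n_N
  }
  n <- sum(covering) - n_N
  out$k <- as.integer(k); out$n <- as.integer(n)
  out$ref_reads <- as.integer(ref_reads)
  out$other_reads <- as.integer(other); out$n_N <- as.integer(n_N)
  out$vaf <- if (n > 0) k / n else NA_real_
  out
}

#' Apply the minimum read-depth filter
#'
#' Amplicons not reaching `min_depth` informative reads at the target (1000X
#' by default) are `not_called`: they enter neither sample positivity nor
#' sensitivity/specificity denominators.
#'
#' @param count An `amplicon_count` (or anything with `$n`).
#' @param min_depth Minimum depth (default 1000).
#' @return `"evaluable"` or `"not_called"`.
#' @export
apply_depth_filter <- function(count, min_depth = 1000L) {
  if (count$n >= min_depth) "evaluable" else "not_called"
}

#' Profile non-reference call rates from pileups
#'
#' For each included position, the non-reference proportion is the count of
#' non-reference, non-N calls over non-N calls. Sites of common population
#' variants are excluded first so germline polymorphism is not mistaken for
#' error. Reports the per-position profile, the mean rate, and the fraction
#' of positions with zero non-reference calls.
#'
#' @param pileups Named list of pileup matrices (one per amplicon contig).
#' @param ref_seqs Named character vector of contig reference sequences.
#' @param exclude_sites Optional data.frame `chrom`, `pos` (1-based) of sites
#'   to exclude (e.g. from [read_exclusion_sites()]).
#' @param region Optional named list of `c(start, end)` 1-based inclusive
#'   intervals restricting profiling (e.g. the insert, excluding
#'   primer-derived bases).
#' @return List with `profile` (data.frame `chrom`, `pos`, `depth`,
#'   `nonref`, `proportion`), `mean_rate`, `zero_error_fraction`.
#' @export
nonref_rate_profile <- function(pileups, ref_seqs, exclude_sites = NULL,
                                region = NULL) {
  rows <- list()
  for (chrom in names(pileups)) {
    pu <- pileups[[chrom]]
    refb <- chars(ref_seqs[[chrom]])
    pos <- seq_len(nrow(pu))
    if (!is.null(region) && chrom %in% names(region)) {
      pos <- pos[pos >= region[[chrom]][1] & pos <= region[[chrom]][2]]
    }
    if (!is.null(exclude_sites)) {
      excl <- exclude_sites$pos[exclude_sites$chrom == chrom]
      pos <- setdiff(pos, excl)
    }
    if (!length(pos)) next
    nonN <- rowSums(pu[pos, DNA_BASES, drop = FALSE])
    refc <- pu[cbind(pos, match(refb[pos], PILEUP_COLS))]
    rows[[chrom]] <- data.frame(
      chrom = chrom, pos = pos, depth = nonN, nonref = nonN - refc,
      proportion = ifelse(nonN > 0, (nonN - refc) / nonN, NA_real_)
    )
  }
  if (!length(rows)) {
    warning("all positions excluded; empty error profile")
    return(list(profile = data.frame(), mean_rate = NA_real_,
                zero_error_fraction = NA_real_))
  }
  profile <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  ok <- !is.na(profile$proportion)
  list(profile = profile,
       mean_rate = mean(profile$proportion[ok]),
       zero_error_fraction = mean(profile$proportion[ok] == 0))
}
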