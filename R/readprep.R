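# Read preparation: paired-end consensus merging with discordant-base
# masking, short-read filtering, and primer-dimer attribution.
#
# Merging is the first error-correction stage: a base call supported by both
# mates is ~e^2-rare to be wrong in the same way, so masking discordant
# overlap positions to N drops the substitution error floor by an order of
# magnitude for independent mate errors.

#' Read paired FASTQ files
#'
#' @param r1,r2 Paths to mate-1 and mate-2 FASTQ (optionally gzipped).
#' @return data.frame with columns `id`, `mate1`, `mate2`.
#' @export
read_fastq_pairs <- function(r1, r2) {
  s1 <- Biostrings::readDNAStringSet(r1, format = "fastq")
  s2 <- Biostrings::readDNAStringSet(r2, format = "fastq")
  if (length(s1) != length(s2)) stop("mate files differ in read count")
  ids <- sub("\\s.*$", "", names(s1))
  data.frame(id = ids, mate1 = as.character(s1), mate2 = as.character(s2),
             stringsAsFactors = FALSE)
}

# Merge one pair. a/b are character vectors: mate1 and revcomp(mate2).
# Offsets s (start of b relative to a, 0-based, may be negative) are scanned
# in order of decreasing overlap; the admissible offset maximising the count
# of concordant non-N positions wins, ties broken by longer overlap then
# leftmost (smallest) offset. Early exit: once best score >= the largest
# remaining overlap nothing can beat it.
merge_one <- function(a, b, min_overlap, max_mismatch_fraction) {
  la <- length(a); lb <- length(b)
  s_all <- seq(-(lb - min_overlap), la - min_overlap)
  ov_all <- pmin(la, s_all + lb) - pmax(0L, s_all)
  keep <- ov_all >= min_overlap
  s_all <- s_all[keep]; ov_all <- ov_all[keep]
  ord <- order(-ov_all, s_all)
  s_all <- s_all[ord]; ov_all <- ov_all[ord]
  best <- NULL; best_score <- -1L
  for (j in seq_along(s_all)) {
    L <- ov_all[j]
    if (L <= best_score) break
    s <- s_all[j]
    ia <- (pmax(0L, s) + 1L):pmin(la, s + lb)
    av <- a[ia]; bv <- b[ia - s]
    both <- av != "N" & bv != "N"
    eq <- av == bv
    conc <- sum(eq & both)
    mis <- sum(!eq & both)
    if (mis / L <= max_mismatch_fraction && conc > best_score) {
      best_score <- conc
      best <- list(s = s, ia = ia, av = av, bv = bv,
                   mask = !eq & both, L = L)
    }
  }
  if (is.null(best)) return(NULL)
  s <- best$s
  off <- -min(0L, s)
  len <- max(la, s + lb) - min(0L, s)
  res <- rep("N", len)
  res[off + s + seq_len(lb)] <- b
  res[off + seq_len(la)] <- a
  cons <- best$av
  cons[cons == "N"] <- best$bv[cons == "N"]   # one-mate N: take the other call
  cons[best$mask] <- "N"                      # discordant: mask
  res[off + best$ia] <- cons
  list(sequence = paste(res, collapse = ""), overlap_length = best$L,
       n_masked = sum(best$mask))
}

#' Merge read pairs into masked consensus reads
#'
#' Aligns each mate 1 against the reverse complement of its mate 2 at every
#' ungapped offset with at least `min_overlap` overlapping positions and at
#' most `max_mismatch_fraction` discordant overlap bases, keeping the offset
#' that maximises concordant positions. Discordant overlap positions are
#' masked to `N`; positions covered by only one mate keep that mate's call.
#' Pairs with no admissible overlap are returned unmerged.
#'
#' @param pairs data.frame with columns `id`, `mate1`, `mate2` (mate 2 as
#'   sequenced, i.e. reverse-complemented internally).
#' @param min_overlap Minimum overlap length (default 10).
#' @param max_mismatch_fraction Maximum fraction of discordant overlap
#'   positions (default 0.25; permissive, since masking rather than pair
#'   rejection is the error-control mechanism).
#'
#' @return List with `merged` (data.frame `id`, `sequence`, `overlap_length`,
#'   `n_masked`), `unmerged` (the input rows that failed), and `stats`
#'   (merged/unmerged/masked-base tallies).
#' @export
merge_pairs <- function(pairs, min_overlap = 10L, max_mismatch_fraction = 0.25) {
  n <- nrow(pairs)
  bad <- !nzchar(pairs$mate1) | !nzchar(pairs$mate2) |
    is.na(pairs$mate1) | is.na(pairs$mate2)
  if (any(bad)) {
    message(sum(bad), " malformed read pair(s) skipped")
  }
  rc2 <- character(n)
  rc2[!bad] <- revcomp(pairs$mate2[!bad])
  seqs <- character(n); ovl <- integer(n); msk <- integer(n)
  ok <- logical(n)
  for (i in which(!bad)) {
    m <- merge_one(chars(pairs$mate1[i]), chars(rc2[i]),
                   min_overlap, max_mismatch_fraction)
    if (!is.null(m)) {
      ok[i] <- TRUE
      seqs[i] <- m$sequence; ovl[i] <- m$overlap_length; msk[i] <- m$n_masked
    }
  }
  merged <- data.frame(id = pairs$id[ok], sequence = seqs[ok],
                       overlap_length = ovl[ok], n_masked = msk[ok],
                       stringsAsFactors = FALSE)
  list(merged = merged,
       unmerged = pairs[!ok & !bad, , drop = FALSE],
       stats = data.frame(n_input = n, n_merged = sum(ok),
                          n_unmerged = sum(!ok & !bad),
                          n_malformed = sum(bad),
                          n_masked_bases = sum(msk[ok])))
}

#' Split reads at a minimum-length threshold
#'
#' Reads shorter than `min_length` (default 40 nt) are set aside; in a
#' multiplex amplicon run these are dominated by primer dimers and are
#' screened with [scan_primer_dimers()].
#'
#' @param reads data.frame with a `sequence` column (e.g. `$merged` from
#'   [merge_pairs()]).
#' @param min_length Minimum length kept (default 40).
#' @return List with `kept` and `discarded` data.frames.
#' @export
filter_short <- function(reads, min_length = 40L) {
  short <- nchar(reads$sequence) < min_length
  list(kept = reads[!short, , drop = FALSE],
       discarded = reads[short, , drop = FALSE])
}

#' Attribute short reads to primer dimers and flag offending primers
#'
#' A discarded read is a dimer of primers (p, q) if it equals the
#' concatenation of p and the reverse complement of q within
#' `max_mismatches` mismatches (either orientation). Each dimer read credits
#' both contributing primers (a self-dimer credits its primer once); per-primer
#' fractions are computed over `total_reads`, and primers above
#' `flag_threshold` (default 20% of sequencing reads) are flagged for removal
#' from the multiplex.
#'
#' @param discarded data.frame of short reads (`sequence` column).
#' @param p A `ctdna_panel`; both primers of every amplicon are screened.
#' @param total_reads Total sequencing reads in the run (the denominator).
#' @param max_mismatches Mismatch tolerance per dimer match (default 2).
#' @param flag_threshold Flagging fraction (default 0.20).
#'
#' @return data.frame with per-primer `primer_id`, `primer_seq`,
#'   `dimer_reads`, `fraction`, `flagged`.
#' @export
scan_primer_dimers <- function(discarded, p, total_reads,
                               max_mismatches = 2L, flag_threshold = 0.20) {
  a <- p$amplicons
  primers <- data.frame(
    primer_id = c(paste0(a$amplicon_id, "_F"), paste0(a$amplicon_id, "_R")),
    seq = c(a$fwd_primer, a$rev_primer),
    stringsAsFactors = FALSE
  )
  np <- nrow(primers)
  if (np == 0L) stop("panel has no primers")
  hits <- setNames(integer(np), primers$primer_id)
  if (nrow(discarded) > 0L) {
    # candidate dimer sequences for every ordered primer pair
    grid <- expand.grid(i = seq_len(np), j = seq_len(np))
    dimer_seq <- paste0(primers$seq[grid$i], revcomp(primers$seq[grid$j]))
    dimer_len <- nchar(dimer_seq)
    for (r in discarded$sequence) {
      cand <- which(dimer_len == nchar(r))
      if (!length(cand)) next
      mm <- vapply(dimer_seq[cand], str_mismatches, integer(1), b = r)
      hit <- cand[mm <= max_mismatches]
      if (!length(hit)) next
      best <- hit[which.min(mm[match(hit, cand)])]
      credit <- unique(c(grid$i[best], grid$j[best]))
      hits[credit] <- hits[credit] + 1L
    }
  }
  frac <- hits / total_reads
  data.frame(primer_id = primers$primer_id, primer_seq = primers$seq,
             dimer_reads = as.integer(hits), fraction = frac,
             flagged = frac > flag_threshold,
             row.names = NULL, stringsAsFactors = FALSE)
}
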