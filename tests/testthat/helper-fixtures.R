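# Shared fixtures, built in code at test time.

# independent oracle for the exact conditional test: direct summation of
# Binomial(m, p0) probabilities in log space (no pbinom/dbinom tail calls)
binom_tail_oracle <- function(k1, n1, k2, n2) {
  m <- k1 + k2
  p0 <- n1 / (n1 + n2)
  if (k1 == 0) return(1)
  x <- k1:m
  sum(exp(lchoose(m, x) + x * log(p0) + (m - x) * log1p(-p0)))
}

# small deterministic panel (SNVs only unless asked otherwise)
fixture_panel <- function(n = 3, seed = 42, insert_range = c(60, 100),
                          p_indel = 0) {
  make_panel(n, insert_range, seed = seed, p_indel = p_indel)
}

# perfect (error-free) read pair for a given amplicon row, optionally with
# the alt allele substituted in
perfect_pair <- function(a, alt = FALSE, id = "read1", read_length = 150) {
  src <- if (alt) ctdnacall:::alt_amplicon_seq(a) else a$seq
  len <- nchar(src)
  data.frame(id = id,
             mate1 = substr(src, 1, min(read_length, len)),
             mate2 = ctdnacall:::revcomp(
               substr(src, max(1, len - read_length + 1), len)),
             stringsAsFactors = FALSE)
}

# pileup matrix with a given depth of reference calls everywhere, plus
# optional named substitutions list(list(pos=, base=, count=), ...)
ref_pileup <- function(ref_seq, depth, subs = list()) {
  L <- nchar(ref_seq)
  mat <- matrix(0L, L, 7, dimnames = list(NULL, c("A","C","G","T","N","del","ins")))
  refb <- strsplit(ref_seq, "")[[1]]
  mat[cbind(seq_len(L), match(refb, colnames(mat)))] <- depth
  for (s in subs) {
    mat[s$pos, s$base] <- mat[s$pos, s$base] + as.integer(s$count)
    mat[s$pos, refb[s$pos]] <- mat[s$pos, refb[s$pos]] - as.integer(s$count)
  }
  mat
}
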