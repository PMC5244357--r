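# Internal low-level helpers shared across modules.

DNA_BASES <- c("A", "C", "G", "T")

# reverse-complement a character vector of sequences (keeps N)
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

# Hamming distance between two equal-length strings
str_mismatches <- function(a, b) {
  sum(chars(a) != chars(b))
}

stopifnot_scalar_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop(sprintf("'%s' must be a single probability in [0, 1]", name),
         call. = FALSE)
  }
}

# Apply random substitution errors at per-base rate `rate` to a character
# vector of sequences. Substituted bases are drawn uniformly from the three
# alternatives. Vectorised over reads; only reads drawing >= 1 error are
# touched, so the common error-free case costs a single rbinom call.
add_substitutions <- function(seqs, rate) {
  if (rate <= 0 || length(seqs) == 0L) return(seqs)
  lens <- nchar(seqs)
  nerr <- rbinom(length(seqs), lens, rate)
  hit <- which(nerr > 0L)
  for (i in hit) {
    v <- chars(seqs[i])
    pos <- sample.int(lens[i], nerr[i])
    for (p in pos) {
      v[p] <- sample(setdiff(DNA_BASES, v[p]), 1L)
    }
    seqs[i] <- paste(v, collapse = "")
  }
  seqs
}

# Write reads as a 4-line-per-record FASTQ (optionally gzipped by extension).
# Constant Q30-equivalent qualities: the caller never uses base qualities.
write_fastq_records <- function(ids, seqs, path) {
  qual <- vapply(nchar(seqs), function(n) strrep("?", n), character(1))
  rec <- rbind(paste0("@", ids), seqs, "+", qual)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  writeLines(as.vector(rec), con)
  invisible(path)
}
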