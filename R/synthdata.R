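# Synthetic-data module.
#
# Generates panels, reference sequences and paired-end reads with the
# statistical structure the caller assumes: a two-stage sampling model in
# which mutant template molecules are first drawn from the genome-equivalents
# bottleneck, Binomial(G, f), and read pairs are then drawn uniformly from
# templates with independent per-base substitution errors. Read names encode
# the amplicon and template of origin so every downstream stage can be scored
# against ground truth.

#' Generate a synthetic patient panel with reference sequences
#'
#' Builds `n_amplicons` amplicons with random primers (18-22 nt), random
#' inserts, and one target variant (SNV or short indel) strictly inside each
#' insert. Each amplicon gets its own reference contig named after it; the
#' contig is the full PCR product (forward primer + insert + reverse-primer
#' binding site).
#'
#' @param n_amplicons Number of amplicons, 1-15 (a multiplex holds at most 15
#'   primer pairs / target variants).
#' @param insert_length_range Inclusive insert-length interval, within
#'   \[60, 150\] bp (the assay uses short amplicons so 2 x 150 bp reads
#'   overlap fully).
#' @param seed Integer seed; the same seed yields a byte-identical panel.
#' @param p_indel Probability that a target variant is a short (1-3 bp)
#'   insertion or deletion rather than an SNV.
#' @param patient_id Patient identifier.
#' @param dir Optional directory; when given, `panel.tsv` and `reference.fa`
#'   are written there.
#'
#' @return A `ctdna_panel` with reference sequences attached.
#' @export
make_panel <- function(n_amplicons = 10L, insert_length_range = c(60L, 150L),
                       seed = 1L, p_indel = 0, patient_id = "synthetic-patient",
                       dir = NULL) {
  if (n_amplicons < 1L || n_amplicons > 15L) {
    stop("n_amplicons must be between 1 and 15")
  }
  if (insert_length_range[1] < 60L || insert_length_range[2] > 150L ||
      insert_length_range[1] > insert_length_range[2]) {
    stop("insert_length_range must lie within [60, 150] bp")
  }
  set.seed(seed)
  rows <- vector("list", n_amplicons)
  primers_seen <- character(0)
  for (i in seq_len(n_amplicons)) {
    repeat {
      fwd <- random_dna(sample(18:22, 1))
      rev <- random_dna(sample(18:22, 1))
      if (!any(c(fwd, rev) %in% primers_seen)) break
    }
    primers_seen <- c(primers_seen, fwd, rev)
    ins_len <- sample(seq(insert_length_range[1], insert_length_range[2]), 1)
    insert <- random_dna(ins_len)
    amp_id <- sprintf("AMP%02d", i)
    seq <- paste0(fwd, insert, revcomp(rev))
    insert_start <- nchar(fwd)
    insert_end <- insert_start + ins_len
    # variant placed away from insert edges so indel footprints stay inside
    vpos <- insert_start + sample(5:(ins_len - 8L), 1)
    ref1 <- substr(seq, vpos + 1L, vpos + 1L)
    if (runif(1) < p_indel) {
      len <- sample(1:3, 1)
      if (runif(1) < 0.5) {                      # deletion, VCF-style anchor
        ref <- substr(seq, vpos + 1L, vpos + 1L + len)
        alt <- ref1
      } else {                                   # insertion
        ref <- ref1
        alt <- paste0(ref1, random_dna(len))
      }
    } else {
      ref <- ref1
      alt <- sample(setdiff(DNA_BASES, ref1), 1)
    }
    rows[[i]] <- data.frame(
      amplicon_id = amp_id, chrom = amp_id,
      insert_start = insert_start, insert_end = insert_end,
      fwd_primer = fwd, rev_primer = rev,
      variant_pos = vpos, ref = ref, alt = alt,
      gene = sprintf("GENE%02d", i), priority_class = "c",
      origin_label = "primary", seq = seq,
      stringsAsFactors = FALSE
    )
  }
  p <- panel(do.call(rbind, rows), patient_id = patient_id,
             metadata = list(seed = seed))
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_panel(p, file.path(dir, "panel.tsv"),
                reference_path = file.path(dir, "reference.fa"))
  }
  p
}

# amplicon sequence with the target variant substituted in
alt_amplicon_seq <- function(a) {
  paste0(substr(a$seq, 1L, a$variant_pos),
         a$alt,
         substr(a$seq, a$variant_pos + nchar(a$ref) + 1L, nchar(a$seq)))
}

#' Draw mutant-template counts from the genome-equivalents bottleneck
#'
#' The number of mutant template molecules entering each amplicon's PCR is
#' Binomial(`genome_equivalents`, `fraction`): with a 10 ng input (~3000
#' genome equivalents) an allele fraction of 0.1% leaves ~5% of amplicons
#' with no mutant template at all, regardless of sequencing depth.
#'
#' @param n Number of amplicons (replicates) to draw.
#' @param genome_equivalents Template molecules sampled per amplicon.
#' @param fraction Variant allele fraction in the input DNA.
#' @return Integer vector of mutant-template counts.
#' @export
draw_template_counts <- function(n, genome_equivalents = 3000,
                                 fraction = 0.001) {
  stopifnot(genome_equivalents >= 1)
  stopifnot_scalar_prob(fraction, "fraction")
  rbinom(n, genome_equivalents, fraction)
}

#' Probability that an allele fraction is represented in the template pool
#'
#' Closed form `1 - (1 - f)^G`: the chance that at least one of `G` sampled
#' genome equivalents carries the variant at allele fraction `f`. This is the
#' template-sampling ceiling on detection, independent of sequencing depth or
#' error correction.
#'
#' @param f Allele fraction(s) in \[0, 1\].
#' @param G Genome equivalents sampled (>= 1).
#' @return Probability vector, same length as `f`.
#' @examples
#' expected_detection_probability(0.001, 3000)  # ~0.9503
#' @export
expected_detection_probability <- function(f, G = 3000) {
  if (any(f < 0 | f > 1)) stop("f must be in [0, 1]")
  if (any(G < 1)) stop("G must be >= 1")
  -expm1(G * log1p(-f))
}

#' Simulate paired-end amplicon reads for one sample
#'
#' Two-stage sampling per amplicon: mutant templates ~ Binomial(G, f), then
#' `depth_per_amplicon` read pairs drawn uniformly from the G templates, with
#' per-base substitution errors applied per the error model. Mate 1 is the
#' first `read_length` bases of the amplicon; mate 2 the reverse complement
#' of the last `read_length` bases, so short amplicons overlap fully. Read
#' names encode `amplicon:template:mut|wt:readindex` as ground truth.
#'
#' @param p A `ctdna_panel` with reference sequences.
#' @param params A [sim_params()] object (`ctdna_fraction` scalar or one value
#'   per amplicon).
#' @param em An [error_model()].
#' @param out_prefix Optional path prefix; writes `<prefix>_R1.fastq.gz`,
#'   `<prefix>_R2.fastq.gz` and `<prefix>_truth.json`.
#'
#' @return List with `pairs` (data.frame `id`, `mate1`, `mate2`) and `truth`
#'   (per-amplicon mutant template and read tallies), plus file paths when
#'   `out_prefix` is given.
#' @export
simulate_reads <- function(p, params = sim_params(), em = error_model(),
                           out_prefix = NULL) {
  a <- p$amplicons
  if (anyNA(a$seq)) stop("panel carries no reference sequences")
  f <- rep_len(params$ctdna_fraction, nrow(a))
  set.seed(params$seed)
  G <- params$genome_equivalents
  D <- params$depth_per_amplicon
  rl <- params$read_length
  ids <- character(0); m1 <- character(0); m2 <- character(0)
  truth <- data.frame(amplicon_id = a$amplicon_id,
                      mutant_templates = 0L, mutant_reads = 0L, depth = D)
  for (i in seq_len(nrow(a))) {
    M <- rbinom(1L, G, f[i])
    tpl <- sample.int(G, D, replace = TRUE)
    mut <- tpl <= M
    refseq <- a$seq[i]
    altseq <- alt_amplicon_seq(a[i, ])
    src <- ifelse(mut, altseq, refseq)
    lens <- nchar(src)
    mate1 <- substr(src, 1L, pmin(rl, lens))
    mate2 <- revcomp(substr(src, pmax(1L, lens - rl + 1L), lens))
    e <- em$substitution_rate
    if (e > 0) {
      if (em$mate_error_mode == "correlated" && em$mate_error_correlation > 0) {
        w <- em$mate_error_correlation
        src_err <- add_substitutions(src, e * w)   # template-borne, shared
        lens2 <- nchar(src_err)
        mate1 <- substr(src_err, 1L, pmin(rl, lens2))
        mate2 <- revcomp(substr(src_err, pmax(1L, lens2 - rl + 1L), lens2))
        mate1 <- add_substitutions(mate1, e * (1 - w))
        mate2 <- add_substitutions(mate2, e * (1 - w))
      } else {
        mate1 <- add_substitutions(mate1, e)
        mate2 <- add_substitutions(mate2, e)
      }
    }
    rid <- sprintf("%s:t%05d:%s:r%06d", a$amplicon_id[i], tpl,
                   ifelse(mut, "mut", "wt"), seq_len(D))
    ids <- c(ids, rid); m1 <- c(m1, mate1); m2 <- c(m2, mate2)
    truth$mutant_templates[i] <- M
    truth$mutant_reads[i] <- sum(mut)
  }
  out <- list(pairs = data.frame(id = ids, mate1 = m1, mate2 = m2,
                                 stringsAsFactors = FALSE),
              truth = truth)
  if (!is.null(out_prefix)) {
    r1 <- paste0(out_prefix, "_R1.fastq.gz")
    r2 <- paste0(out_prefix, "_R2.fastq.gz")
    write_fastq_records(ids, m1, r1)
    write_fastq_records(ids, m2, r2)
    tj <- paste0(out_prefix, "_truth.json")
    jsonlite::write_json(truth, tj, dataframe = "rows")
    out$files <- c(R1 = r1, R2 = r2, truth = tj)
  }
  out
}

#' Simulate same-run negative controls
#'
#' Controls are variant-free libraries (cell-line DNA in the wet assay):
#' `ctdna_fraction = 0`, so variant-supporting reads arise only from the
#' error model. At most three controls share a sequencing run.
#'
#' @param p A `ctdna_panel`.
#' @param em An [error_model()].
#' @param n_controls Number of controls, 1-3.
#' @param params A [sim_params()]; its `ctdna_fraction` is ignored.
#' @param out_prefix Optional path prefix; control `i` is written as
#'   `<prefix>_ctrl<i>_R[12].fastq.gz`.
#' @return List of `simulate_reads()` results, one per control.
#' @export
simulate_controls <- function(p, em = error_model(), n_controls = 3L,
                              params = sim_params(), out_prefix = NULL) {
  if (n_controls < 1L || n_controls > 3L) {
    stop("n_controls must be between 1 and 3 (same-run negative controls)")
  }
  lapply(seq_len(n_controls), function(i) {
    pi <- params
    pi$ctdna_fraction <- 0
    pi$seed <- params$seed + i
    pre <- if (is.null(out_prefix)) NULL else sprintf("%s_ctrl%d", out_prefix, i)
    simulate_reads(p, pi, em, out_prefix = pre)
  })
}

#' Counts-level two-stage simulation (no reads)
#'
#' Same generative model as [simulate_reads()] but observed at the level of
#' per-amplicon variant/total read counts: mutant templates ~ Binomial(G, f),
#' variant reads ~ Binomial(depth, M/G), then substitution errors flip reads
#' into (rate e/3 towards the specific alt base) and out of (rate e) the
#' variant class. Useful for depth regimes where simulating every read would
#' be wasteful.
#'
#' @inheritParams simulate_reads
#' @return data.frame with per-amplicon `mutant_templates`, `k`, `n`, `vaf`.
#' @export
simulate_read_counts <- function(p, params = sim_params(), em = error_model()) {
  a <- p$amplicons
  f <- rep_len(params$ctdna_fraction, nrow(a))
  set.seed(params$seed)
  G <- params$genome_equivalents
  D <- params$depth_per_amplicon
  e <- em$substitution_rate
  M <- rbinom(nrow(a), G, f)
  k_true <- rbinom(nrow(a), D, M / G)
  flip_out <- rbinom(nrow(a), k_true, e)
  flip_in <- rbinom(nrow(a), D - k_true, e / 3)
  k <- k_true - flip_out + flip_in
  data.frame(amplicon_id = a$amplicon_id, mutant_templates = M,
             k = k, n = D, vaf = k / D, stringsAsFactors = FALSE)
}

#' Expected allele frequencies of a tumour/normal dilution series
#'
#' A ratio `1:r` mixes 1 part tumour DNA with `r` parts normal DNA; under the
#' `"parts"` convention the tumour mass fraction is `d = 1/(1+r)` (under
#' `"fraction"`, `d = 1/r`). The expected variant frequency per amplicon is
#' the mixture `d * tumour_vaf + (1-d) * normal_vaf`.
#'
#' @param p A `ctdna_panel`.
#' @param tumour_vafs,normal_vafs Per-amplicon allele fractions in the two
#'   tissues (recycled if scalar).
#' @param ratios Numeric vector of `r` in `1:r` (default the nine-step
#'   two-fold series 10, 20, ..., 2560).
#' @param ratio_convention `"parts"` (default) or `"fraction"`.
#' @return data.frame `amplicon_id`, `ratio`, `tumour_fraction`, `expected_f`.
#' @export
dilution_expected <- function(p, tumour_vafs, normal_vafs = 0,
                              ratios = c(10, 20, 40, 80, 160, 320, 640, 1280, 2560),
                              ratio_convention = c("parts", "fraction")) {
  if (length(ratios) == 0L) stop("ratio list must not be empty")
  ratio_convention <- match.arg(ratio_convention)
  a <- p$amplicons
  tv <- rep_len(tumour_vafs, nrow(a))
  nv <- rep_len(normal_vafs, nrow(a))
  if (any(tv < 0 | tv > 1 | nv < 0 | nv > 1)) stop("VAFs must be in [0, 1]")
  d <- if (ratio_convention == "parts") 1 / (1 + ratios) else 1 / ratios
  out <- expand.grid(amplicon_id = a$amplicon_id, ratio = ratios,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  i <- match(out$amplicon_id, a$amplicon_id)
  out$tumour_fraction <- d[match(out$ratio, ratios)]
  out$expected_f <- out$tumour_fraction * tv[i] +
    (1 - out$tumour_fraction) * nv[i]
  out
}

#' Simulate a tumour-in-normal dilution series
#'
#' One sample per dilution ratio, at the per-amplicon expected allele
#' frequency from [dilution_expected()]. `output = "counts"` runs the
#' counts-level simulator; `output = "reads"` generates full paired FASTQ
#' (and writes them when `dir` is given).
#'
#' @inheritParams dilution_expected
#' @param params A [sim_params()]; `ctdna_fraction` is overridden per ratio.
#' @param em An [error_model()].
#' @param output `"counts"` or `"reads"`.
#' @param dir Optional output directory for FASTQ when `output = "reads"`.
#' @return List with `expected` (the design table) and `samples` (one
#'   counts data.frame or `simulate_reads()` result per ratio).
#' @export
simulate_dilution_series <- function(p, tumour_vafs, normal_vafs = 0,
                                     ratios = c(10, 20, 40, 80, 160, 320, 640,
                                                1280, 2560),
                                     params = sim_params(), em = error_model(),
                                     ratio_convention = c("parts", "fraction"),
                                     output = c("counts", "reads"),
                                     dir = NULL) {
  output <- match.arg(output)
  design <- dilution_expected(p, tumour_vafs, normal_vafs, ratios,
                              ratio_convention)
  samples <- vector("list", length(ratios))
  names(samples) <- paste0("1:", ratios)
  for (j in seq_along(ratios)) {
    fj <- design$expected_f[design$ratio == ratios[j]]
    pj <- params
    pj$ctdna_fraction <- fj
    pj$seed <- params$seed + j
    if (output == "counts") {
      samples[[j]] <- simulate_read_counts(p, pj, em)
      samples[[j]]$ratio <- ratios[j]
    } else {
      pre <- if (is.null(dir)) NULL else file.path(dir, sprintf("dilution_1_%d", ratios[j]))
      if (!is.null(dir)) dir.create(dir, recursive = TRUE, showWarnings = FALSE)
      samples[[j]] <- simulate_reads(p, pj, em, out_prefix = pre)
    }
  }
  list(expected = design, samples = samples)
}
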