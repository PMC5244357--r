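# Synthetic panel and read generator: constraints, determinism, and the
# two-stage (template bottleneck, then reads) sampling model.

test_that("make_panel satisfies design constraints and bounds", {
  p <- make_panel(10, seed = 7)
  a <- p$amplicons
  expect_equal(nrow(a), 10L)
  ins <- a$insert_end - a$insert_start
  expect_true(all(ins >= 60 & ins <= 150))
  expect_false(anyDuplicated(c(a$fwd_primer, a$rev_primer)) > 0)
  expect_true(all(a$variant_pos > a$insert_start &
                    a$variant_pos + nchar(a$ref) < a$insert_end))
  # a multiplex holds at most 15 primer pairs
  expect_error(make_panel(16), "between 1 and 15")
  expect_error(make_panel(0), "between 1 and 15")
  expect_error(make_panel(5, insert_length_range = c(40, 100)), "\\[60, 150\\]")
  expect_error(make_panel(5, insert_length_range = c(100, 160)), "\\[60, 150\\]")
})

test_that("same seed gives byte-identical panel, FASTA and FASTQ", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  p1 <- make_panel(5, seed = 7, dir = d1)
  p2 <- make_panel(5, seed = 7, dir = d2)
  expect_identical(p1$amplicons, p2$amplicons)
  expect_identical(readBin(file.path(d1, "panel.tsv"), "raw", 1e6),
                   readBin(file.path(d2, "panel.tsv"), "raw", 1e6))
  expect_identical(readBin(file.path(d1, "reference.fa"), "raw", 1e6),
                   readBin(file.path(d2, "reference.fa"), "raw", 1e6))
  prm <- sim_params(depth_per_amplicon = 200, ctdna_fraction = 0.01, seed = 3)
  simulate_reads(p1, prm, error_model(), out_prefix = file.path(d1, "s"))
  simulate_reads(p2, prm, error_model(), out_prefix = file.path(d2, "s"))
  for (f in c("s_R1.fastq.gz", "s_R2.fastq.gz")) {
    expect_identical(
      readLines(gzfile(file.path(d1, f))), readLines(gzfile(file.path(d2, f))))
  }
})

test_that("expected_detection_probability matches the closed form", {
  expect_equal(expected_detection_probability(0, 3000), 0)
  expect_equal(expected_detection_probability(0.5, 1), 0.5)
  expect_equal(expected_detection_probability(0.001, 3000),
               1 - 0.999^3000)
  expect_equal(round(expected_detection_probability(0.001, 3000), 4), 0.9503)
  expect_error(expected_detection_probability(-0.1, 10), "\\[0, 1\\]")
  expect_error(expected_detection_probability(0.5, 0), ">= 1")
  # monotone non-decreasing in f and in G
  f <- seq(0, 0.01, length.out = 50)
  expect_true(all(diff(expected_detection_probability(f, 3000)) >= 0))
  G <- seq(1, 5000, by = 50)
  expect_true(all(diff(expected_detection_probability(1e-3, G)) >= 0))
})

test_that("template counts follow Binomial(G, f)", {
  set.seed(5)
  G <- 3000; f <- 1e-4; nrep <- 10000
  M <- draw_template_counts(nrep, G, f)
  # fraction of amplicons with >= 1 mutant template vs closed-form complement
  p1 <- 1 - (1 - f)^G                         # ~0.259
  se <- sqrt(p1 * (1 - p1) / nrep)
  expect_lt(abs(mean(M > 0) - p1), 4 * se)
  # chi-square goodness of fit at alpha = 0.01 (tail bins pooled to exp >= 5)
  M2 <- draw_template_counts(nrep, G, 1e-3)
  probs <- dbinom(0:12, G, 1e-3)
  expected <- nrep * c(probs, 1 - sum(probs))
  cut <- max(which(expected >= 5))
  obs <- tabulate(pmin(M2, cut - 1L) + 1L, nbins = cut)
  gof <- suppressWarnings(stats::chisq.test(
    obs, p = c(expected[1:(cut - 1)], sum(expected[cut:length(expected)])) / nrep))
  expect_gt(gof$p.value, 0.01)
})

test_that("simulated reads carry consistent ground truth and converge to f", {
  p <- fixture_panel(2, seed = 9)
  # no mutation and no error: zero variant-supporting reads anywhere
  clean <- simulate_reads(p, sim_params(depth_per_amplicon = 300, seed = 2),
                          error_model(substitution_rate = 0))
  expect_true(all(clean$truth$mutant_reads == 0))
  expect_false(any(grepl(":mut:", clean$pairs$id)))
  a1 <- p$amplicons[1, ]
  cnt <- count_variant_reads(
    data.frame(sequence = clean$pairs$mate1[grepl("AMP01", clean$pairs$id)]),
    a1)
  expect_equal(cnt$k, 0L)

  # read names reproduce the simulator's internal mutant tally exactly
  mut <- simulate_reads(
    p, sim_params(depth_per_amplicon = 500, ctdna_fraction = 0.05, seed = 4),
    error_model(substitution_rate = 0))
  named <- vapply(p$amplicons$amplicon_id, function(id)
    sum(grepl(paste0("^", id, ":t\\d+:mut:"), mut$pairs$id)), integer(1))
  expect_equal(unname(named), mut$truth$mutant_reads)

  # empirical VAF within 4 SD of f under two-stage sampling variance
  f <- 0.01; D <- 20000L; G <- 3000
  deep <- simulate_reads(
    fixture_panel(1, seed = 13),
    sim_params(depth_per_amplicon = D, ctdna_fraction = f, seed = 21,
               genome_equivalents = G),
    error_model(substitution_rate = 0))
  vhat <- deep$truth$mutant_reads / D
  sd2 <- sqrt(f * (1 - f) * (1 / G + 1 / D))
  expect_lt(abs(vhat - f), 4 * sd2)
})

test_that("negative controls are variant-free and recover the error rate", {
  p <- fixture_panel(1, seed = 3)
  expect_error(simulate_controls(p, n_controls = 0), "between 1 and 3")
  expect_error(simulate_controls(p, n_controls = 4), "between 1 and 3")

  ctl0 <- simulate_controls(p, error_model(substitution_rate = 0), 2,
                            sim_params(depth_per_amplicon = 200, seed = 5))
  for (c in ctl0) expect_true(all(c$truth$mutant_reads == 0))

  # mean per-position non-reference proportion ~ substitution rate
  e <- 1e-3
  ctl <- simulate_controls(p, error_model(substitution_rate = e), 3,
                           sim_params(depth_per_amplicon = 3000, seed = 6))
  a <- p$amplicons[1, ]
  rate <- vapply(ctl, function(c) {
    pu <- build_pileup(data.frame(sequence = c$pairs$mate1), nchar(a$seq))
    nonref_rate_profile(list(AMP01 = pu), c(AMP01 = a$seq))$mean_rate
  }, numeric(1))
  n_calls <- 3000 * nchar(a$seq)
  se <- sqrt(e / n_calls)
  expect_true(all(abs(rate - e) < 5 * se))
})

test_that("dilution design obeys the mixture formula and the series shape", {
  p <- fixture_panel(2, seed = 8)
  # 1:10 in parts means tumour mass fraction 1/11
  d <- dilution_expected(p, tumour_vafs = 0.11, normal_vafs = 0, ratios = 10)
  expect_equal(d$expected_f, rep(0.01, 2))
  # fraction convention: 1:10 -> d = 1/10
  d2 <- dilution_expected(p, 0.1, 0, ratios = 10,
                          ratio_convention = "fraction")
  expect_equal(d2$expected_f, rep(0.01, 2))
  # identical tissue VAFs: dilution changes nothing
  dd <- dilution_expected(p, 0.07, 0.07)
  expect_equal(dd$expected_f, rep(0.07, nrow(dd)))
  # the standard nine-ratio series at a 0.5/0.11 tumour VAF spans 0.0002-1%
  span <- dilution_expected(fixture_panel(2, seed = 8), c(0.5, 0.11), 0)
  expect_lte(min(span$expected_f), 2e-4)
  expect_gte(max(span$expected_f), 0.01)
  # monotone non-increasing along the series when tumour VAF > normal VAF
  one <- span[span$amplicon_id == "AMP01", ]
  expect_true(all(diff(one$expected_f[order(one$ratio)]) <= 0))
  expect_error(dilution_expected(p, 0.1, ratios = numeric(0)), "empty")
  expect_error(dilution_expected(p, 1.5), "\\[0, 1\\]")
})

test_that("counts-level simulator matches the generative expectations", {
  p <- fixture_panel(1, seed = 15)
  set.seed(1)
  reps <- do.call(rbind, lapply(1:300, function(i)
    simulate_read_counts(p, sim_params(depth_per_amplicon = 5000,
                                       ctdna_fraction = 0.01, seed = i),
                         error_model(substitution_rate = 0))))
  expect_lt(abs(mean(reps$vaf) - 0.01), 4 * sqrt(0.01 / (5000 * 300)) * 3)
  # error-free, fraction zero: identically zero
  null <- simulate_read_counts(p, sim_params(depth_per_amplicon = 5000,
                                             seed = 2),
                               error_model(substitution_rate = 0))
  expect_equal(null$k, 0L)
})
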