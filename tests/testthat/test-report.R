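# Sample-level calling, dilution linearity, frequency-bin detection,
# cohort metrics, longitudinal series.

res_row <- function(called, vaf, status = "evaluable", origin = "primary") {
  data.frame(amplicon_id = NA, called = called, vaf = vaf, status = status,
             origin_label = origin)
}

test_that("sample call is positive iff any amplicon is called; fraction = max VAF", {
  neg <- call_sample(rbind(res_row(FALSE, 0), res_row(FALSE, 2e-4)))
  expect_false(neg$positive)
  expect_true(is.na(neg$ctdna_fraction))           # reported as "ND"
  expect_output(print(neg), "ND")

  one <- call_sample(rbind(res_row(TRUE, 0.0022), res_row(FALSE, 0)),
                     sample_id = "130")
  expect_true(one$positive)
  expect_equal(one$ctdna_fraction, 0.0022)

  two <- call_sample(rbind(res_row(TRUE, 0.004), res_row(TRUE, 0.011)))
  expect_equal(two$ctdna_fraction, 0.011)
  mean2 <- call_sample(rbind(res_row(TRUE, 0.004), res_row(TRUE, 0.011)),
                       fraction_method = "mean")
  expect_equal(mean2$ctdna_fraction, 0.0075)

  # all amplicons depth-failed: the sample is unevaluable, not negative
  unev <- call_sample(rbind(res_row(FALSE, NA, "not_called"),
                            res_row(FALSE, NA, "not_called")))
  expect_equal(unev$status, "unevaluable")
  expect_error(call_sample(res_row(TRUE, 0.1)[0, ]), "empty")

  # positivity is monotone: adding a called amplicon never turns a positive
  # sample negative
  set.seed(8)
  for (i in 1:20) {
    base <- do.call(rbind, lapply(1:4, function(j)
      res_row(runif(1) < 0.5, runif(1, 0, 0.02))))
    before <- call_sample(base)$positive
    after <- call_sample(rbind(base, res_row(TRUE, 0.001)))$positive
    expect_true(after >= before)
  }
})

test_that("origin labels split the sample fraction per tumour of origin", {
  res <- rbind(res_row(TRUE, 0.004, origin = "colorectal-primary"),
               res_row(FALSE, 0, origin = "colorectal-primary"),
               res_row(TRUE, 0.02, origin = "second-primary"))
  sc <- call_sample(res)
  ob <- sc$origin_breakdown
  expect_equal(ob$ctdna_fraction[ob$origin_label == "colorectal-primary"], 0.004)
  expect_equal(ob$ctdna_fraction[ob$origin_label == "second-primary"], 0.02)
  # disjoint label sets are independent: dropping one label's amplicons does
  # not change the other's fraction
  sc2 <- call_sample(res[res$origin_label == "second-primary", , drop = FALSE])
  expect_equal(sc2$ctdna_fraction, 0.02)
})

test_that("dilution linearity: correlation, depth exclusion, NA convention", {
  expected <- rep(c(0.01, 0.005, 0.0025, 0.00125), 2)
  series <- data.frame(
    amplicon_id = rep(c("A1", "A2"), each = 4),
    expected = expected,
    observed = c(expected[1:4], 2 * expected[5:8]),  # scaled is still linear
    depth = 5000)
  out <- dilution_linearity(series)
  expect_equal(out$per_amplicon$r, c(1, 1))
  expect_equal(out$fraction_above_threshold, 1)

  # a constant observed series has undefined r and counts against the
  # criterion instead of shrinking its denominator
  series2 <- series
  series2$observed[series2$amplicon_id == "A2"] <- 0.001
  out2 <- dilution_linearity(series2)
  expect_true(is.na(out2$per_amplicon$r[out2$per_amplicon$amplicon_id == "A2"]))
  expect_equal(out2$fraction_above_threshold, 0.5)

  # an amplicon failing 1000X anywhere in the series is excluded entirely
  series3 <- series
  series3$depth[6] <- 999
  out3 <- dilution_linearity(series3)
  expect_equal(out3$per_amplicon$amplicon_id, "A1")
  expect_equal(out3$n_excluded_depth, 1L)
  expect_error(dilution_linearity(series3[series3$amplicon_id == "A2", ]),
               "dilution points")
})

test_that("frequency-bin detection reports the binomial template band", {
  res <- data.frame(expected_f = c(0.001, 0.004, 0.01, 0.0001),
                    detected = c(TRUE, TRUE, TRUE, FALSE))
  out <- detection_by_frequency_bins(res, bin_edges = c(0, 0.0005, 0.0009, 0.01))
  b3 <- out$bins[3, ]   # (0.0009, 0.01], spanning expected f 0.001-0.01
  expect_equal(b3$n, 3L)
  expect_equal(b3$band_lower, 1 - 0.999^3000)
  expect_equal(round(b3$band_lower, 4), 0.9503)
  expect_equal(b3$band_upper, 1 - 0.99^3000)
  # f_min = 0 edge gives a zero lower band
  out0 <- detection_by_frequency_bins(
    data.frame(expected_f = c(0, 0.001), detected = c(FALSE, TRUE)),
    bin_edges = c(0, 0.01))
  expect_equal(out0$bins$band_lower[1], 0)
  # empty bin reports NA
  expect_true(is.na(out$bins$positive_fraction[out$bins$n == 0][1]))
  # cumulative detection at-or-above each frequency
  expect_equal(out$cumulative$detected_at_or_above[out$cumulative$expected_f == 0.001], 1)
  expect_equal(out$cumulative$detected_below[out$cumulative$expected_f == 0.001], 0)
})

test_that("cohort metrics reproduce the aggregate sensitivity/specificity sums", {
  # 32 of 48 expected-positive amplicons detected; 1 of 554 expected-negative
  # amplicons called
  calls <- data.frame(
    called = c(rep(TRUE, 32), rep(FALSE, 16), rep(FALSE, 553), TRUE),
    expected_positive = c(rep(TRUE, 48), rep(FALSE, 554)),
    status = "evaluable")
  m <- cohort_metrics(calls)
  expect_equal(round(m$per_amplicon$sensitivity, 3), 0.667)
  expect_equal(m$per_amplicon$specificity, 553 / 554)
  expect_gt(m$per_amplicon$specificity, 0.99)
  expect_true(m$per_amplicon$sensitivity_ci[1] < 0.667 &
                m$per_amplicon$sensitivity_ci[2] > 0.667)

  # depth-failed amplicons leave the denominators
  calls2 <- rbind(calls, data.frame(called = FALSE, expected_positive = TRUE,
                                    status = "not_called"))
  expect_equal(cohort_metrics(calls2)$per_amplicon$FN, 16)

  # perfect calls; and per-sample aggregation over amplicons
  perfect <- data.frame(called = c(TRUE, TRUE, FALSE),
                        expected_positive = c(TRUE, TRUE, FALSE),
                        status = "evaluable",
                        sample_id = c("s1", "s1", "s2"))
  mp <- cohort_metrics(perfect)
  expect_equal(mp$per_amplicon$sensitivity, 1)
  expect_equal(mp$per_amplicon$specificity, 1)
  expect_equal(mp$per_sample$sensitivity, 1)
  expect_equal(mp$per_sample$specificity, 1)
})

test_that("longitudinal report orders series and computes lead times", {
  sc <- data.frame(
    patient_id = c("P1", "P1", "P1", "P2"),
    timepoint = c(-255, -100, 30, 12),
    positive = c(TRUE, FALSE, TRUE, FALSE),
    ctdna_fraction = c(0.002, NA, 0.01, NA))
  events <- data.frame(patient_id = c("P1", "P2"), day = c(0, 40),
                       label = "recurrence")
  out <- longitudinal_report(sc, events)
  expect_equal(out$series$timepoint[out$series$patient_id == "P1"],
               c(-255, -100, 30))
  lt <- out$lead_times
  expect_equal(lt$lead_time_days[lt$patient_id == "P1"], 255)
  expect_true(is.na(lt$lead_time_days[lt$patient_id == "P2"]))

  # a single negative timepoint still yields a one-row series
  solo <- longitudinal_report(sc[4, , drop = FALSE])
  expect_equal(nrow(solo$series), 1L)
  expect_false(solo$series$positive)

  # duplicate timepoints are flagged, not dropped
  dup <- sc; dup$timepoint[2] <- -255
  expect_warning(out2 <- longitudinal_report(dup), "duplicate")
  expect_equal(sum(out2$series$duplicate_timepoint), 1L)
})
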