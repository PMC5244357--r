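---
title: "Methods: error-corrected amplicon ctDNA detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: error-corrected amplicon ctDNA detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctdnacall)
```

## The detection model

`ctdnacall` detects patient-specific somatic mutations in plasma from
multiplex PCR amplicon deep sequencing. Three error-reduction stages stand
between raw reads (~2.8 × 10⁻³ non-reference calls per base) and calls at
allele fractions down to a few 10⁻⁴:

1. **Consensus merging** (`merge_pairs`). Each mate 1 is aligned ungapped
   against the reverse complement of its mate 2; discordant overlap bases
   are masked to `N`. If per-mate substitution errors are independent at
   rate *e*, a masked position arises at rate ≈ 2*e*(1−*e*) and a
   *concordant* error survives only at ≈ *e*²/3 — the source of the ~10-fold
   error-floor reduction that merging buys on short amplicons where mates
   overlap fully.
2. **Depth filtering and counting** (`assign_reads`, `count_variant_reads`,
   `apply_depth_filter`). Reads are assigned to amplicons by their forward
   primer (unique match within 2 mismatches; ambiguous reads dropped),
   stacked ungapped from the primer anchor, and the target variant counted.
   Amplicons with fewer than 1000 informative reads at the target are
   `not_called` and leave every downstream denominator.
3. **Control-calibrated exact testing** (`poisson_rate_ratio_test`,
   `call_amplicon`, `base_noise_filter`). The variant count x₁ at depth n₁
   is tested against the count x₂/n₂ of the same-run negative control with
   the *highest* variant proportion. Conditional on m = x₁ + x₂, the sample
   count under equal Poisson rates is Binomial(m, p₀) with
   p₀ = n₁/(n₁ + n₂); the one-sided p-value is the inclusive upper tail
   P(X ≥ x₁). Using the maximum-proportion control is a deliberately
   conservative substitute for overdispersion modelling: with only three
   controls per run a negative-binomial fit is not identifiable, whereas
   the max-control comparison absorbs between-library variability directly.

A sample is positive when at least one evaluable amplicon has p < α.
Multiplexing ~10 variants per patient is what makes partial per-variant
sensitivity acceptable: at a per-amplicon detection rate of 0.76
(representative of 0.1% allele fraction), a 10-amplicon panel detects
1 − 0.24¹⁰ > 99.99% of positive samples under independence.

## Assumptions

- Amplicons are short (60–150 bp inserts) so 2 × 150 bp mates overlap the
  target; positions covered by a single mate carry that mate's call
  unmasked.
- Errors are substitution-dominated; base qualities are never used (the
  masking consensus is binary), and no strand-bias filter is applied —
  merged reads are single-stranded consensus.
- Negative controls are processed in the same run as the sample and are
  variant-free at the panel sites, so their non-reference proportions
  estimate the position-specific error ceiling.
- Calls at sites of common population variants must be excluded from error
  profiling (`read_exclusion_sites`); germline signal is not error.

## Tunable parameters

| Parameter | Default | Where | Why |
|---|---|---|---|
| `alpha` | 0.01 | `call_parameters` | ROC-calibrated operating cutoff; sits between the maximum-accuracy threshold and the next candidate on labelled calibration data (`calibrate_cutoff` reports the geometric midpoint of that pair). |
| `min_depth` | 1000× | `call_parameters`, `dilution_linearity` | Below ~1000 informative reads the exact test has little power at 10⁻³-scale fractions; amplicons failing it are `not_called`, not negative. |
| tissue verification depth | 100× | `qc_amplicons_by_tissue_vaf` | Minimum tumour/normal tissue depth for verifying a designed amplicon; separate from the plasma 1000× filter. |
| `fold_threshold` | 2 | `qc_amplicons_by_tissue_vaf` | Amplicons whose tumour VAF is < 2-fold the matched-normal VAF carry no usable somatic contrast; exactly 2-fold is kept (strict `<`). |
| `min_length` | 40 nt | `filter_short` | Shorter merged products are primer-dimer material, not target. |
| dimer flag | > 20% | `scan_primer_dimers` | A primer consuming more than a fifth of sequencing reads as dimer is removed from the multiplex. |
| `min_overlap`, `max_mismatch_fraction` | 10, 0.25 | `merge_pairs` | Permissive by design: masking, not pair rejection, is the error-control mechanism. |
| `genome_equivalents` | 3000 | `sim_params` | ~10 ng cell-free DNA input at ~3.3 pg per haploid genome. |
| `substitution_rate` | 2.8 × 10⁻³ | `error_model` | The raw-read non-reference regime the assay class operates in. |

## The synthetic-data generator

`simulate_reads` implements two-stage sampling per amplicon: mutant
templates M ~ Binomial(G, f), then read pairs drawn uniformly from the G
templates with per-base substitution errors. This reproduces the two
features of real cell-free DNA data that drive the assay's operating
characteristics — the template bottleneck (detection can never exceed
1 − (1−f)^G, `expected_detection_probability`) and the raw error floor.
Read names carry the template of origin, so counting is testable against
exact ground truth. `simulate_read_counts` observes the same generative
model at count level for depth regimes where materialising reads is
wasteful; the dilution-series linearity checks run at depth 5000 on this
counts path, while the read-level path is exercised end-to-end at depth
3000 (the spec-scale 50 000× examples are run reduced to fit a desk-scale
CPU budget; the 3-standard-error tolerance logic is unchanged).

What the generator does **not** emulate: PCR-cycle error phylogenies
(errors are i.i.d. per base call, not jackpotted), quality-score profiles
(qualities are constant Q30), amplification bias between templates,
structural variants, and fragment-length variation. Consequently a green
test establishes the *statistical* behaviour of the pipeline under its own
assumptions — calibration under the null, linearity, template-bottleneck
detection — not robustness to PCR jackpots or quality pathologies. The
`correlated` mate-error mode exists precisely to show the boundary: with
shared (template-borne) errors, consensus merging cannot reach the
independent-error e²/3 floor, which is why real merged-read floors
(~2.6 × 10⁻⁴) sit above the naive prediction.

## Numerical and design choices

- **Exact test tail**: inclusive upper tail P(X ≥ x₁), the standard
  convention for one-sided exact conditional tests; computed via the
  regularised-beta form of the binomial tail (`pbinom`), stable for
  m ≫ 10⁶. Tests cross-check against independent log-space term summation
  to 10⁻¹⁰ relative error.
- **Strict cutoff**: `called` requires p < α, so p exactly equal to the
  cutoff is not called (the conservative reading).
- **Control ties**: equal proportions resolve to the smallest control
  depth — the smaller exposure gives the larger p₀ and hence the larger
  p-value.
- **N at the target position** is excluded from the depth denominator
  entirely, keeping the Poisson exposures equal to informative depth; a
  masked base supports neither allele.
- **Merge ties** resolve by most concordant positions, then longest
  overlap, then leftmost offset; the admissibility rule (≥10 bp overlap,
  ≤25% discordance) is this package's own, standing in for the external
  merger's statistical overlap test, which is not re-specified here.
- **Dilution ratios**: "1:r" is read as tumour:normal *parts*, tumour mass
  fraction d = 1/(1+r); `ratio_convention = "fraction"` gives d = 1/r.
  Both fit the published 0.0002–1% expected-frequency span, so the choice
  is exposed rather than hidden.
- **Sample ctDNA fraction** is the maximum VAF among called amplicons —
  robust to per-variant dropout; `fraction_method = "mean"` is available.
  Undefined per-amplicon dilution correlations (constant observed series)
  count *against* the r > 0.95 criterion rather than shrinking its
  denominator, to avoid inflating linearity claims.
- **Degenerate inputs**: zero exposures error; zero-depth controls are
  unusable (all-zero-depth errors); all-`not_called` samples are
  `unevaluable`, never negative; empty candidate lists rank to empty
  selections.

## Limitations

- Primer-anchored ungapped assignment replaces genome alignment; it is
  exact for the synthetic world and for clean amplicon data, but reads
  with indel sequencing errors near the anchor would be mis-stacked (the
  default indel error rate is 0, matching the substitution-dominated
  regime).
- The pileup is ungapped: reads carrying an indel *target* variant are
  classified correctly by haplotype matching in `count_variant_reads`, but
  their frame-shifted tails are not realigned in the pileup used for error
  profiling; profiling should use variant-free libraries (controls), as
  done here.
- No multiple-testing correction across amplicons or timepoints: sample
  positivity is "any amplicon called", matching per-amplicon calling
  practice for this assay class; the per-sample false-positive rate
  therefore grows with panel size and is controlled by the calibrated α.
- Clinical-cohort quantities (recurrence lead-time distributions, CEA
  comparisons) are reported only as bookkeeping over supplied tables;
  no survival or outcome modelling is attempted.
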