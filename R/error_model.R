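#' Sequencing error model for the synthetic-read generator
#'
#' Describes the substitution-error regime of the simulated sequencer. The
#' default substitution rate of 2.8e-3 per base call matches the raw
#' (pre-merging) non-reference call rate observed on healthy-donor plasma with
#' this assay class.
#'
#' @param substitution_rate Per-base-call probability of a substitution error.
#' @param mate_error_mode `"independent"` (default) draws errors independently
#'   on the two mates; `"correlated"` shares a fraction
#'   `mate_error_correlation` of the error process between mates, emulating
#'   template-borne (e.g. PCR) errors that paired-end consensus cannot remove.
#'   With correlation 1 both mates carry identical errors.
#' @param mate_error_correlation Weight in \[0, 1\] of the shared error
#'   component; only used in correlated mode.
#' @param indel_rate Per-base-call probability of a sequencing indel
#'   (default 0; the assay's error floor is substitution-dominated).
#'
#' @return An object of class `error_model`.
#' @examples
#' error_model()                         # raw-read regime
#' error_model(substitution_rate = 0)    # error-free reads
#' @export
error_model <- function(substitution_rate = 2.8e-3,
                        mate_error_mode = c("independent", "correlated"),
                        mate_error_correlation = 0,
                        indel_rate = 0) {
  mate_error_mode <- match.arg(mate_error_mode)
  stopifnot_scalar_prob(substitution_rate, "substitution_rate")
  stopifnot_scalar_prob(mate_error_correlation, "mate_error_correlation")
  stopifnot_scalar_prob(indel_rate, "indel_rate")
  structure(
    list(substitution_rate = substitution_rate,
         mate_error_mode = mate_error_mode,
         mate_error_correlation = mate_error_correlation,
         indel_rate = indel_rate),
    class = "error_model"
  )
}

#' Simulation parameters: template bottleneck, depth and tumour fraction
#'
#' @param genome_equivalents Number of independently sampled template
#'   molecules per amplicon. Default 3000, the number of haploid genome
#'   equivalents in a 10 ng cell-free DNA input; this bottleneck, not read
#'   depth, bounds sensitivity at low allele fractions.
#' @param depth_per_amplicon Target read pairs per amplicon.
#' @param ctdna_fraction Variant allele fraction of the tumour signal, scalar
#'   or one value per amplicon.
#' @param read_length Read length of each mate (2 x 150 bp chemistry).
#' @param seed Integer seed making the simulation reproducible.
#'
#' @return An object of class `sim_params`.
#' @export
sim_params <- function(genome_equivalents = 3000,
                       depth_per_amplicon = 2000,
                       ctdna_fraction = 0,
                       read_length = 150,
                       seed = 1L) {
  if (genome_equivalents < 1) stop("genome_equivalents must be >= 1")
  if (depth_per_amplicon < 1) stop("depth_per_amplicon must be >= 1")
  if (any(ctdna_fraction < 0) || any(ctdna_fraction > 1)) {
    stop("ctdna_fraction must be in [0, 1]")
  }
  structure(
    list(genome_equivalents = as.integer(genome_equivalents),
         depth_per_amplicon = as.integer(depth_per_amplicon),
         ctdna_fraction = ctdna_fraction,
         read_length = as.integer(read_length),
         seed = as.integer(seed)),
    class = "sim_params"
  )
}
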