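#' Delta-Ct ratio statistics
#'
#' The three ratio read-outs used throughout the cleavage-efficiency
#' experiments, each a single exponentiated Ct difference at amplification
#' efficiency `E` (perfect doubling, `E = 2`, by default):
#'
#' * `uncleaved_total_ratio(ct_total, ct_uncleaved)` = `E^(total - uncleaved)`
#'   - the fraction of nuclear transcripts not yet cleaved at the PAS; a
#'   larger value means less efficient 3'-end processing.
#' * `fraction_release_ratio(ct_chromatin, ct_nucleoplasm)` =
#'   `E^(chromatin - nucleoplasm)` - relative abundance of PAS-uncleaved
#'   pre-mRNA in the nucleoplasm vs on chromatin; high values indicate
#'   release from chromatin before PAS cleavage (post-transcriptional,
#'   CoTC-type processing).
#' * `rip_enrichment(ct_input, ct_ip)` = `E^(input - ip)` - RNA-IP recovery
#'   as a fraction of input.
#'
#' Each satisfies `f(a, a) = 1` and `f(a, b) * f(b, a) = 1` exactly, and is
#' increasing in its first argument and decreasing in its second. Non-finite
#' Ct values give `NA`.
#'
#' @param ct_total,ct_uncleaved,ct_chromatin,ct_nucleoplasm,ct_input,ct_ip
#'   Quantification cycles (vectors recycle).
#' @param efficiency Per-cycle amplification factor in `(1, 2]` (default 2).
#' @return Numeric vector of dimensionless ratios.
#' @name delta_ct_ratios
NULL

ct_ratio <- function(a, b, efficiency) {
  stopifnot(efficiency > 1, efficiency <= 2)
  out <- efficiency^(a - b)
  out[!is.finite(a) | !is.finite(b)] <- NA_real_
  out
}

#' @rdname delta_ct_ratios
#' @export
uncleaved_total_ratio <- function(ct_total, ct_uncleaved, efficiency = 2) {
  ct_ratio(ct_total, ct_uncleaved, efficiency)
}

#' @rdname delta_ct_ratios
#' @export
fraction_release_ratio <- function(ct_chromatin, ct_nucleoplasm,
                                   efficiency = 2) {
  ct_ratio(ct_chromatin, ct_nucleoplasm, efficiency)
}

#' @rdname delta_ct_ratios
#' @export
rip_enrichment <- function(ct_input, ct_ip, efficiency = 2) {
  ct_ratio(ct_input, ct_ip, efficiency)
}

#' Relative expression between two conditions (delta-delta-Ct)
#'
#' `E^-((ct_target_a - ct_ref_a) - (ct_target_b - ct_ref_b))`: the fold
#' change of the target in condition `a` relative to condition `b`, each
#' normalized to a reference amplicon.
#'
#' @param ct_target_a,ct_ref_a Target and reference Ct in condition a.
#' @param ct_target_b,ct_ref_b Target and reference Ct in condition b.
#' @param efficiency Per-cycle amplification factor (default 2).
#' @return Fold change (condition a over condition b).
#' @export
relative_expression <- function(ct_target_a, ct_ref_a,
                                ct_target_b, ct_ref_b, efficiency = 2) {
  if (any(!is.finite(ct_ref_a)) || any(!is.finite(ct_ref_b)))
    stop("missing reference Ct")
  ct_ratio(ct_target_b - ct_ref_b, ct_target_a - ct_ref_a, efficiency)
}

#' Aggregate replicate ratios
#'
#' Replicates are combined on the delta-Ct (log) scale - the mean of the
#' per-replicate Ct differences is exponentiated - which is exactly the
#' geometric mean of the per-replicate ratios. Arithmetic-scale averaging is
#' available behind `scale = "ratio"`.
#'
#' @param ratios Per-replicate ratios (positive).
#' @param scale `"log"` (default, geometric mean) or `"ratio"` (arithmetic).
#' @return Scalar aggregate ratio.
#' @export
aggregate_ratios <- function(ratios, scale = c("log", "ratio")) {
  scale <- match.arg(scale)
  ratios <- ratios[is.finite(ratios)]
  if (!length(ratios)) return(NA_real_)
  if (scale == "log") exp(mean(log(ratios))) else mean(ratios)
}
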