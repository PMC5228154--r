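#' Simulate probe conversion-quality scores
#'
#' Draws an in-silico conversion score in `[0,1]` for the forward and reverse
#' probe of every SNP, emulating the per-probe quality metric array vendors
#' assign before fabrication (higher scores predict cleaner genotype
#' clusters). Scores are Beta-distributed; the defaults are calibrated so
#' that, after thresholding at the package default `tau = 0.6` and keeping
#' the better probe, the retained probe set has a mean score near 0.71 with
#' about 97% of scores above 0.65.
#'
#' @param snps A `snp_pool` data.frame or anything with a `snp_id` column.
#' @param shape1,shape2 Beta parameters of the per-probe score distribution.
#' @param seed Integer seed; fixed seed gives identical scores.
#' @return data.frame `snp_id`, `pconvert_fwd`, `pconvert_rev`.
#' @export
simulate_pconvert <- function(snps, shape1 = 83.4, shape2 = 36.6, seed = 1L) {
  if (!is.numeric(shape1) || !is.numeric(shape2) ||
      shape1 <= 0 || shape2 <= 0) {
    stop_config("Beta parameters must be positive")
  }
  ids <- if (is.data.frame(snps)) snps$snp_id else as.character(snps)
  if (length(ids) == 0) stop_config("no SNPs supplied")
  with_seed(seed, {
    data.frame(
      snp_id = ids,
      pconvert_fwd = stats::rbeta(length(ids), shape1, shape2),
      pconvert_rev = stats::rbeta(length(ids), shape1, shape2),
      stringsAsFactors = FALSE
    )
  })
}
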