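#' Kosambi mapping function
#'
#' Convert a recombination fraction to additive genetic distance under the
#' Kosambi mapping function, \eqn{d = 25 \ln\{(1+2r)/(1-2r)\}} centiMorgans,
#' which allows for moderate crossover interference.
#'
#' @param r Recombination fraction(s) in `[0, 0.5)`.
#' @return Genetic distance in centiMorgans, same length as `r`.
#' @seealso [kosambi_inverse()]
#' @examples
#' kosambi(0.25)            # 27.465 cM
#' kosambi_inverse(50)      # 0.3808
#' @export
kosambi <- function(r) {
  if (any(is.na(r)) || any(r < 0) || any(r >= 0.5)) {
    stop_config("recombination fraction must lie in [0, 0.5); got %s",
                paste(utils::head(r[is.na(r) | r < 0 | r >= 0.5], 3),
                      collapse = ", "))
  }
  25 * log((1 + 2 * r) / (1 - 2 * r))
}

#' Inverse Kosambi mapping function
#'
#' Convert a genetic distance in centiMorgans back to a recombination
#' fraction: \eqn{r = \tanh(d/50)/2}. Round-trips with [kosambi()] to
#' machine precision.
#'
#' @param d_cM Genetic distance(s) in centiMorgans, non-negative.
#' @return Recombination fraction(s) in `[0, 0.5)`.
#' @export
kosambi_inverse <- function(d_cM) {
  if (any(is.na(d_cM)) || any(d_cM < 0)) {
    stop_config("genetic distance must be non-negative")
  }
  0.5 * tanh(d_cM / 50)
}
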