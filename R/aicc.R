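#' Second-order Akaike Information Criterion
#'
#' `AICc = -2 LL + 2k + 2k(k+1)/(n - k - 1)`; as n grows the correction term
#' vanishes and AICc approaches AIC.
#'
#' @param logLik maximized log-likelihood (numeric vector).
#' @param k number of estimated parameters.
#' @param n sample size (likelihood-contributing observations).
#' @return numeric vector.
#' @export
aicc <- function(logLik, k, n) {
  if (any(n - k - 1 <= 0)) stop("AICc undefined: n <= k + 1", call. = FALSE)
  -2 * logLik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Akaike weights from AICc values
#'
#' `w_i = exp(-dAICc_i / 2) / sum_j exp(-dAICc_j / 2)`.
#'
#' @param aicc_values numeric vector of AICc scores.
#' @return numeric vector of weights summing to 1.
#' @export
akaike_weights <- function(aicc_values) {
  d <- aicc_values - min(aicc_values)
  w <- exp(-d / 2)
  w / sum(w)
}
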