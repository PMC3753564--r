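#' Phred quality arithmetic
#'
#' Convert between phred-scaled integer qualities and error probabilities.
#' A phred score q encodes an error probability of 10^(-q/10), so q = 0
#' means "always wrong is possible" (probability 1) and q = 30 means 1 in
#' 1000.
#'
#' @param q non-negative phred score(s); need not be integer.
#' @param p error probability(ies) in (0, 1].
#' @return `phred_to_prob` returns the error probability 10^(-q/10);
#'   `prob_to_phred` returns -10*log10(p).
#' @examples
#' phred_to_prob(30)        # 0.001
#' prob_to_phred(0.1)       # 10
#' @export
phred_to_prob <- function(q) {
  if (any(!is.finite(q)) || any(q < 0))
    stop("phred scores must be finite and >= 0")
  10^(-q / 10)
}

#' @rdname phred_to_prob
#' @export
prob_to_phred <- function(p) {
  if (any(p <= 0) || any(p > 1))
    stop("probabilities must lie in (0, 1]")
  -10 * log10(p)
}

# internal, no validation: hot path used per read
.phred_err <- function(q) 10^(-q / 10)
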