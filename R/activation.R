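# Sigmoid population activation and its derivatives.

#' Sigmoid activation function of a neural population
#'
#' Maps synaptic input to a population firing rate via the logistic form
#' `F(in) = M / (1 + ((M - B)/B) * exp(-4 in / M))`, so that `F(0) = B`
#' exactly, `F` is strictly increasing, and the range is the open interval
#' `(0, M)`. The slope at zero input is `4B(M - B)/M^2`, and more generally
#' `F'(in) = 4 F (M - F) / M^2`.
#'
#' @param input Synaptic input (spk/s); vectorised.
#' @param M Maximum firing rate (spk/s), `M > B`.
#' @param B Baseline firing rate at zero input (spk/s), `B > 0`.
#' @return Firing rate(s) in `(0, M)`.
#' @examples
#' activation(0, 300, 10)          # = 10, the baseline
#' activation(c(-1e3, 1e3), 300, 10)
#' @export
activation <- function(input, M, B) {
  if (!all(is.finite(input))) stop("non-finite synaptic input")
  if (!(is.finite(M) && is.finite(B) && B > 0 && B < M)) {
    stop("activation constants must satisfy 0 < B < M")
  }
  M / (1 + ((M - B) / B) * exp(-4 * input / M))
}

#' Derivatives of the sigmoid activation
#'
#' Closed-form derivatives expressed through the value `F = activation(input)`:
#' `F'   = 4 F (M - F) / M^2`,
#' `F''  = 16 F (M - F)(M - 2F) / M^4`,
#' `F''' = 64 F (M - F)(M^2 - 6 M F + 6 F^2) / M^6`.
#'
#' @inheritParams activation
#' @param order Derivative order, 1, 2 or 3.
#' @return Derivative value(s) with respect to the input.
#' @export
activation_deriv <- function(input, M, B, order = 1) {
  F <- activation(input, M, B)
  switch(as.character(order),
    "1" = 4 * F * (M - F) / M^2,
    "2" = 16 * F * (M - F) * (M - 2 * F) / M^4,
    "3" = 64 * F * (M - F) * (M^2 - 6 * M * F + 6 * F^2) / M^6,
    stop("order must be 1, 2 or 3")
  )
}
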