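#' Shifted Hill regulatory function
#'
#' `H^S(X, lambda, n) = lambda + (1 - lambda) / (1 + (X / X0)^n)`, the
#' standard fold-change form used for transcriptional regulation in
#' Notch-Delta-Jagged models. It equals 1 at `X = 0`, tends to `lambda` for
#' large `X`, and is monotone in `X` (increasing for `lambda > 1`,
#' decreasing for `lambda < 1`, constant for `lambda = 1`).
#'
#' @param X Regulator level (molecules), any nonnegative vector.
#' @param X0 Reference threshold (molecules), strictly positive scalar.
#' @param lambda Limiting fold-change, `>= 0`. Values below 1 encode
#'   down-regulation, above 1 up-regulation.
#' @param n Hill exponent, strictly positive.
#' @return Dimensionless factor(s), between `min(1, lambda)` and
#'   `max(1, lambda)`.
#' @examples
#' shifted_hill(0, 200, 0.1, 2)    # 1: no regulator, no effect
#' shifted_hill(200, 200, 0.5, 4)  # 0.75: halfway at the threshold
#' @export
shifted_hill <- function(X, X0, lambda, n) {
  if (!is.numeric(X0) || length(X0) != 1L || !is.finite(X0) || X0 <= 0)
    stop("X0 must be a single strictly positive number", call. = FALSE)
  if (!is.numeric(n) || length(n) != 1L || !is.finite(n) || n <= 0)
    stop("n must be a single strictly positive number", call. = FALSE)
  if (!is.numeric(lambda) || length(lambda) != 1L || lambda < 0)
    stop("lambda must be a single number >= 0", call. = FALSE)
  if (any(X < 0)) stop("X must be nonnegative", call. = FALSE)
  lambda + (1 - lambda) / (1 + (X / X0)^n)
}
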