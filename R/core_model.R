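#' Psychometric-function parameters
#'
#' Container for the four parameters of a lapse-contaminated
#' cumulative-Gaussian psychometric function: the empirical bias `B`
#' (degrees; the horizontal shift, i.e. the stimulus value at which both
#' choices are equally likely in the absence of lapses), the sensitivity
#' noise `S` (degrees; SD of the cumulative Gaussian, the inverse slope),
#' and the leftward/rightward lapse rates `lambda1`, `lambda2`.
#'
#' @param B empirical bias in degrees.
#' @param S sensitivity noise in degrees; must be strictly positive.
#' @param lambda1 leftward lapse rate in `[0, 1]`.
#' @param lambda2 rightward lapse rate in `[0, 1]`.
#' @return An object of class `psy_params`.
#' @examples
#' psy_params(B = 10, S = 15)
#' @export
psy_params <- function(B, S, lambda1 = 0, lambda2 = 0) {
  stopifnot(is.numeric(B), length(B) == 1, is.finite(B))
  if (!is.numeric(S) || length(S) != 1 || !is.finite(S) || S <= 0)
    stop("sensitivity noise S must be a single positive number")
  if (lambda1 < 0 || lambda2 < 0 || lambda1 + lambda2 >= 1)
    stop("lapse rates must satisfy 0 <= lambda1 + lambda2 < 1")
  structure(list(B = B, S = S, lambda1 = lambda1, lambda2 = lambda2),
            class = "psy_params")
}

#' Probability of a rightward choice
#'
#' Evaluates the psychometric function
#' \deqn{\theta(\omega) = \lambda_1 + (1 - \lambda_1 - \lambda_2)\,
#'   \Phi\!\left(\frac{\omega - B}{S}\right)}
#' where \eqn{\Phi} is the standard normal CDF.  `theta` is nondecreasing
#' in `omega` and bounded in `[lambda1, 1 - lambda2]`.
#'
#' @param omega stimulus direction(s) in degrees; vectorized.
#' @param params a [psy_params()] object.
#' @return Probability of choosing rightward, same length as `omega`.
#' @examples
#' choice_probability(0, psy_params(B = 0, S = 15))  # 0.5
#' @export
choice_probability <- function(omega, params) {
  if (!inherits(params, "psy_params")) params <- do.call(psy_params, as.list(params))
  params$lambda1 +
    (1 - params$lambda1 - params$lambda2) *
      pnorm((omega - params$B) / params$S)
}

#' Draw a Bernoulli 2AFC choice
#'
#' @param theta probability of a rightward choice, in `[0, 1]`; vectorized.
#' @return Choices coded `+1` (right) / `-1` (left).
#' @export
sample_choice <- function(theta) {
  if (any(!is.finite(theta)) || any(theta < 0) || any(theta > 1))
    stop("theta must lie in [0, 1]")
  ifelse(runif(length(theta)) < theta, 1L, -1L)
}

#' Perceptual/decision bias set
#'
#' The decomposition of the three per-context empirical biases into two
#' perceptual components and a shared decision component:
#' `BL = PL + D`, `BN = D`, `BR = PR + D`.  The neutral context is assumed
#' to carry no perceptual bias, so its empirical bias identifies `D`.
#'
#' @param PL leftward-context perceptual bias, degrees.
#' @param PR rightward-context perceptual bias, degrees.
#' @param D decision bias shared by all contexts, degrees.
#' @return An object of class `bias_set`.
#' @export
bias_set <- function(PL, PR, D) {
  stopifnot(is.finite(PL), is.finite(PR), is.finite(D))
  structure(list(PL = PL, PR = PR, D = D), class = "bias_set")
}

#' @export
print.bias_set <- function(x, ...) {
  cat(sprintf("bias_set: PL = %g, PR = %g, D = %g (deg)\n", x$PL, x$PR, x$D))
  invisible(x)
}

#' Decompose empirical biases into perceptual and decision components
#'
#' @param BL,BN,BR empirical biases (degrees) in the leftward, neutral and
#'   rightward contexts.
#' @return A [bias_set()] with `PL = BL - BN`, `PR = BR - BN`, `D = BN`.
#' @examples
#' decompose_biases(30, 10, 0)  # PL = 20, PR = -10, D = 10
#' @export
decompose_biases <- function(BL, BN, BR) {
  bias_set(PL = BL - BN, PR = BR - BN, D = BN)
}

#' Compose empirical biases from a bias set
#'
#' Exact inverse of [decompose_biases()].
#'
#' @param biases a [bias_set()].
#' @return Named numeric vector `c(BL, BN, BR)`.
#' @export
compose_empirical <- function(biases) {
  stopifnot(inherits(biases, "bias_set"))
  c(BL = biases$PL + biases$D, BN = biases$D, BR = biases$PR + biases$D)
}
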