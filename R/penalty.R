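#' LASSO penalty
#'
#' The L1 penalty `lambda * |b|` added to the negative log-likelihood for
#' each penalized coefficient.
#'
#' @param b Coefficient value(s).
#' @param lambda Nonnegative tuning parameter.
#' @return Penalty value(s).
#' @export
#' @examples
#' lasso_penalty(-2, 0.5)
lasso_penalty <- function(b, lambda) {
  stopifnot(all(lambda >= 0))
  lambda * abs(b)
}

#' SCAD penalty derivative
#'
#' First derivative of the smoothly clipped absolute deviation penalty of
#' Fan and Li: `lambda` for `|b| < lambda`, then linearly decaying as
#' `(a*lambda - |b|)_+ / (a - 1)` and exactly zero for `|b| >= a*lambda`, so
#' large coefficients are left unpenalized (near-unbiasedness) while small
#' ones are shrunk to zero.
#'
#' @param b Nonnegative coefficient magnitude(s).
#' @param lambda Nonnegative tuning parameter.
#' @param a Shape parameter, must exceed 2 (conventional default 3.7).
#' @return Derivative value(s).
#' @export
#' @examples
#' scad_derivative(c(0.3, 1.0, 3.0), lambda = 0.5, a = 3.7)
scad_derivative <- function(b, lambda, a = 3.7) {
  stopifnot(all(b >= 0), all(lambda >= 0))
  if (a <= 2) stop("SCAD shape `a` must be > 2", call. = FALSE)
  ifelse(b < lambda, lambda, pmax(a * lambda - b, 0) / (a - 1))
}

#' SCAD penalty
#'
#' The SCAD penalty function itself (the integral of [scad_derivative()]):
#' `lambda*|b|` near zero, a quadratic blend on `[lambda, a*lambda]`, and the
#' constant `lambda^2 (a + 1) / 2` beyond `a*lambda`.
#'
#' @inheritParams scad_derivative
#' @return Penalty value(s).
#' @export
scad_penalty <- function(b, lambda, a = 3.7) {
  stopifnot(all(b >= 0), all(lambda >= 0))
  if (a <= 2) stop("SCAD shape `a` must be > 2", call. = FALSE)
  out <- ifelse(
    b < lambda,
    lambda * b,
    ifelse(
      b < a * lambda,
      -(b^2 - 2 * a * lambda * b + lambda^2) / (2 * (a - 1)),
      lambda^2 * (a + 1) / 2
    )
  )
  out
}

#' Specify a penalty for the penalized mixture cure fit
#'
#' @param family `"none"`, `"lasso"` or `"scad"`.
#' @param lambda Nonnegative tuning parameter.
#' @param a SCAD shape parameter (> 2), default 3.7.
#' @return A `penalty_spec` list.
#' @export
penalty_spec <- function(family = c("none", "lasso", "scad"), lambda = 0,
                         a = 3.7) {
  family <- match.arg(family)
  stopifnot(length(lambda) == 1L, lambda >= 0)
  if (family == "scad" && a <= 2) {
    stop("SCAD shape `a` must be > 2", call. = FALSE)
  }
  structure(list(family = family, lambda = lambda, a = a),
            class = "penalty_spec")
}

# Derivative-of-penalty closure used in the LQA M-steps; NULL means
# unpenalized. The penalized objective is -loglik + n * sum p_lambda(|b|),
# so lambda lives on the per-observation scale where the SCAD branch
# thresholds (lambda, a*lambda) are commensurate with coefficient
# magnitudes; the closure carries the factor n.
penalty_deriv_fun <- function(spec, n = 1) {
  if (is.null(spec) || spec$family == "none" || spec$lambda == 0) return(NULL)
  if (spec$family == "lasso") {
    function(b) rep(n * spec$lambda, length(b))
  } else {
    function(b) n * scad_derivative(b, spec$lambda, spec$a)
  }
}

penalty_value <- function(spec, b, n = 1) {
  if (is.null(spec) || spec$family == "none" || spec$lambda == 0) return(0)
  if (spec$family == "lasso") n * sum(lasso_penalty(abs(b), spec$lambda))
  else n * sum(scad_penalty(abs(b), spec$lambda, spec$a))
}
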