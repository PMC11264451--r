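#' Tune the penalty parameter over a lambda grid by AIC/BIC
#'
#' Fits the penalized mixture cure model over a grid of `lambda` values and
#' scores each fit by `AIC = -2 loglik + 2 df` and
#' `BIC = -2 loglik + log(n) df`, where `df` counts the nonzero coefficients
#' across both components (intercept included) and `loglik` is the
#' unpenalized observed-data log-likelihood at the penalized estimates. The
#' selected `lambda` minimizes the requested criterion; ties are broken
#' toward the larger `lambda` (the sparser model).
#'
#' @param cohort A `cohort` tibble.
#' @param target_cause Cause of interest (others recoded to censoring).
#' @param family `"scad"` or `"lasso"`.
#' @param lambda Optional explicit grid of nonnegative values. By default a
#'   log-spaced grid of `nlambda` values from `lambda_max` (the smallest
#'   value zeroing every penalized coefficient, computed from the null-model
#'   score) down to `lambda_min_ratio * lambda_max`.
#' @param nlambda,lambda_min_ratio Default grid size (30) and span (0.001).
#' @param criterion `"bic"` (default) or `"aic"`: the criterion whose
#'   minimizer is reported as the selected fit.
#' @param a SCAD shape parameter.
#' @param control A [cure_control()].
#' @return A `cure_tune` object: `$path` (tibble: lambda, df, loglik, aic,
#'   bic, converged, selected_aic, selected_bic), `$fits` (list of
#'   `cure_fit`), `$selected` (named list of selected lambdas), `$criterion`,
#'   `$family`. `best_fit()` extracts the selected fit; `tidy()` returns the
#'   path.
#' @export
tune_cure_model <- function(cohort, target_cause = NULL,
                            family = c("scad", "lasso"), lambda = NULL,
                            nlambda = 30L, lambda_min_ratio = 0.001,
                            criterion = c("bic", "aic"), a = 3.7,
                            control = cure_control()) {
  family <- match.arg(family)
  criterion <- match.arg(criterion)
  if (!is.null(target_cause)) {
    cohort <- recode_cause_specific(cohort, target_cause)
  }
  assert_binary_cause(cohort)
  if (is.null(lambda)) {
    lmax <- lambda_max(cohort)
    lambda <- exp(seq(log(lmax), log(lambda_min_ratio * lmax),
                      length.out = nlambda))
  }
  stopifnot(length(lambda) >= 1L, all(lambda >= 0))
  lambda <- sort(unique(lambda), decreasing = TRUE)

  # walk the path from the sparse end with warm starts: the first fit
  # starts from the null model (intercept-only incidence, beta = 0) and
  # each subsequent lambda starts from the previous solution, keeping the
  # fits on the sparse branch of the nonconvex SCAD objective; zeroed
  # coefficients re-enter via the KKT check in the M-steps
  fits <- vector("list", length(lambda))
  init <- list(
    theta = c(`(Intercept)` = stats::qlogis(
      pmin(pmax(mean(cohort$cause), 0.01), 0.99))),
    beta = numeric(0)
  )
  for (k in seq_along(lambda)) {
    fit_k <- tryCatch(
      suppressWarnings(
        fit_cure_model(cohort, penalty = family, lambda = lambda[k], a = a,
                       control = control, init = init)
      ),
      error = function(e) NULL
    )
    fits[k] <- list(fit_k)  # [[<- would drop the element on NULL
    # separation-capped solutions are poison as warm starts: keep the last
    # regular solution instead
    if (!is.null(fit_k) && !identical(fit_k$convergence, "capped")) {
      init <- list(theta = fit_k$theta, beta = fit_k$beta)
    }
  }
  ok <- !vapply(fits, is.null, logical(1))
  if (!any(ok) || !any(vapply(fits[ok], function(f) f$converged, logical(1)))) {
    stop("no lambda value produced a converged fit", call. = FALSE)
  }
  path <- purrr::map2_dfr(fits, lambda, function(f, l) {
    if (is.null(f)) {
      return(tibble::tibble(lambda = l, df = NA_integer_,
                            loglik = NA_real_, aic = NA_real_,
                            bic = NA_real_, converged = FALSE))
    }
    tibble::tibble(lambda = l, df = f$df, loglik = f$loglik, aic = f$aic,
                   bic = f$bic, converged = f$converged)
  })
  # grid is descending in lambda: which.min takes the first (largest-lambda)
  # minimizer, the documented tie-break toward the sparser model
  sel_aic <- path$lambda[which.min(path$aic)]
  sel_bic <- path$lambda[which.min(path$bic)]
  path$selected_aic <- path$lambda == sel_aic
  path$selected_bic <- path$lambda == sel_bic
  structure(list(path = path, fits = stats::setNames(fits, lambda),
                 lambda = lambda,
                 selected = list(aic = sel_aic, bic = sel_bic),
                 criterion = criterion, family = family),
            class = "cure_tune")
}

# Smallest lambda zeroing all penalized coefficients: the largest
# per-observation score, over both components, at the fitted null model
# (intercept-only incidence, beta = 0 latency) with its converged E-step
# weights, on standardized covariates.
lambda_max <- function(cohort, control = cure_control()) {
  Z <- cohort_matrix(cohort)
  Z <- prune_collinear_quiet(Z)
  sdv <- apply(Z, 2, stats::sd)
  sdv[sdv == 0] <- 1
  Zstd <- sweep(sweep(Z, 2, colMeans(Z)), 2, sdv, "/")
  d <- cohort$cause
  n <- nrow(Zstd)

  # intercept-only EM null fit
  null_cohort <- new_cohort(cohort[c("id", "time", "cause")],
                            covariates = character(0),
                            causes = cohort_causes(cohort))
  nf <- suppressWarnings(fit_cure_model(null_cohort, control = control))
  X0 <- matrix(1, n, 1)
  Z0 <- matrix(numeric(0), n, 0)
  w <- e_step(cohort$time, d, X0, Z0, nf$theta, nf$beta, nf$baseline)
  pi0 <- expit(nf$theta[[1L]])

  # logistic score for each candidate incidence coefficient
  g_inc <- abs(drop(crossprod(Zstd, w - pi0)))
  # weighted Cox score at beta = 0 (censored subjects weighted by w)
  srt <- cox_sort(cohort$time)
  Zs <- Zstd[srt$ord, , drop = FALSE]
  ds <- d[srt$ord] == 1
  ws <- w[srt$ord]
  S0 <- rev(cumsum(rev(ws)))[srt$firstidx]
  Zbar <- rev_cumsum_cols(ws * Zs)[srt$firstidx, , drop = FALSE] / S0
  g_lat <- abs(colSums(Zs[ds, , drop = FALSE] - Zbar[ds, , drop = FALSE]))
  # 2% headroom so the grid top sits strictly above every score even after
  # EM convergence noise, guaranteeing the empty model is on the path
  1.02 * max(c(g_inc, g_lat, 1e-8)) / n
}

prune_collinear_quiet <- function(Z) {
  suppressWarnings(prune_collinear(Z))$Z
}

#' Extract the criterion-selected fit from a tuning path
#'
#' @param tune A `cure_tune`.
#' @param criterion `"bic"` or `"aic"`; defaults to the criterion the path
#'   was tuned for.
#' @return The selected `cure_fit`.
#' @export
best_fit <- function(tune, criterion = tune$criterion) {
  criterion <- match.arg(criterion, c("bic", "aic"))
  sel <- tune$selected[[criterion]]
  tune$fits[[match(sel, tune$lambda)]]
}

#' @export
print.cure_tune <- function(x, ...) {
  cat(sprintf("Penalty tuning path (%s), %d lambda values\n",
              toupper(x$family), nrow(x$path)))
  cat(sprintf("  selected lambda: %.4g (AIC), %.4g (BIC)\n",
              x$selected$aic, x$selected$bic))
  print(x$path)
  invisible(x)
}

#' @export
#' @method tidy cure_tune
tidy.cure_tune <- function(x, ...) x$path

#' @export
#' @method glance cure_tune
glance.cure_tune <- function(x, ...) {
  best <- best_fit(x)
  tibble::tibble(family = x$family, criterion = x$criterion,
                 lambda = x$selected[[x$criterion]], df = best$df,
                 loglik = best$loglik, aic = best$aic, bic = best$bic)
}

#' @export
#' @method autoplot cure_tune
autoplot.cure_tune <- function(object, ...) {
  df <- tidyr::pivot_longer(object$path, c("aic", "bic"),
                            names_to = "criterion", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = log(.data$lambda), y = .data$value,
                                   colour = .data$criterion)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "log(lambda)", y = "Criterion value",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
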