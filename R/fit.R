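#' Control parameters for the mixture cure EM
#'
#' @param tol EM convergence tolerance on the maximum absolute parameter
#'   change (default 1e-6).
#' @param maxit Maximum EM iterations (default 500).
#' @param mstep_tol,mstep_maxit Inner Newton tolerance and iteration cap for
#'   each M-step.
#' @param cap Absolute bound on coefficients; estimates hitting it are capped
#'   with a separation warning.
#' @param thresh Hard-threshold below which penalized coefficients are set
#'   exactly to zero.
#' @param standardize Standardize covariates (mean 0, sd 1) internally before
#'   penalization and back-transform the coefficients. Only applied to
#'   penalized fits.
#' @param ll_tol Relative log-likelihood stall tolerance: iteration also
#'   stops once the observed-data log-likelihood change falls below
#'   `ll_tol * (1 + |loglik|)` (after 10 iterations), which ends the
#'   indefinite drift of quasi-separated coefficients along a flat ridge.
#' @return A list of class `cure_control`.
#' @export
cure_control <- function(tol = 1e-6, maxit = 500L, mstep_tol = 1e-8,
                         mstep_maxit = 100L, cap = 50, thresh = 1e-6,
                         standardize = TRUE, ll_tol = 1e-10) {
  structure(list(tol = tol, maxit = as.integer(maxit), mstep_tol = mstep_tol,
                 mstep_maxit = as.integer(mstep_maxit), cap = cap,
                 thresh = thresh, standardize = isTRUE(standardize),
                 ll_tol = ll_tol),
            class = "cure_control")
}

#' Fit a semi-parametric mixture cure model, optionally penalized
#'
#' Fits the two-component mixture cure model to a binary-cause cohort: a
#' logistic incidence submodel for the probability `pi(x)` of being
#' susceptible, and a Cox proportional-hazards latency submodel with a
#' nonparametric Breslow baseline for the event time of susceptibles. The
#' population survival is `S_pop(t|x) = 1 - pi(x) + pi(x) S_u(t|x)`.
#' Estimation is by EM: the E-step computes each censored subject's posterior
#' probability of being uncured; the M-steps maximize the weighted logistic
#' likelihood and the weighted Cox partial likelihood (censored subjects
#' enter risk sets with their posterior weight). With `penalty = "lasso"` or
#' `"scad"` both components' non-intercept coefficients are penalized via a
#' local quadratic approximation inside the M-steps, giving exact zeros.
#' Identifiability of the cure fraction uses the zero-tail constraint:
#' conditional susceptible survival is set to zero beyond the largest event
#' time.
#'
#' @param cohort A `cohort` tibble (from [as_cohort()], [read_cohort()] or
#'   [simulate_cohort()]).
#' @param target_cause Cause of interest; other causes are recoded as
#'   censoring. Omit for an already-binary cohort.
#' @param penalty `"none"` (the full model), `"lasso"` or `"scad"`.
#' @param lambda Penalty tuning parameter, on the per-observation scale:
#'   the penalized objective is `-loglik + n * sum(p_lambda(|coef|))`.
#' @param a SCAD shape parameter, default 3.7.
#' @param force_susceptible If `TRUE`, the cure fraction is forced to zero
#'   (everyone susceptible) and the fit reduces to an ordinary Cox model.
#' @param control A [cure_control()] list.
#' @param init Optional warm start: a list with named `theta` and `beta`
#'   vectors on the raw covariate scale (used by [tune_cure_model()] to walk
#'   the lambda path from the sparse end).
#' @return An object of class `cure_fit` with components `theta` (incidence
#'   coefficients, leading intercept), `beta` (latency coefficients),
#'   `baseline` (Breslow increments tibble), `loglik` (observed-data,
#'   unpenalized), `df`, `aic`, `bic`, `n`, `n_event`, `converged`, `iter`,
#'   `trace` (per-iteration tibble), `penalty`, and bookkeeping fields.
#'   Supports `tidy()`, `glance()`, `predict()`, `autoplot()`.
#' @export
#' @examples
#' truth <- cohort_truth(
#'   covariates = list(x1 = list(type = "binary", p = 0.5)),
#'   theta = c(`(Intercept)` = 0.5, x1 = 1),
#'   beta_event = c(x1 = -0.5),
#'   base_event = list(shape = 1, scale = 10),
#'   censoring = list(rate = 0.01, horizon = 120)
#' )
#' ch <- simulate_cohort(truth, n = 300, seed = 1)
#' fit <- fit_cure_model(ch, target_cause = 1)
#' tidy(fit)
#' glance(fit)
fit_cure_model <- function(cohort, target_cause = NULL,
                           penalty = c("none", "lasso", "scad"),
                           lambda = 0, a = 3.7,
                           force_susceptible = FALSE,
                           control = cure_control(), init = NULL) {
  penalty <- match.arg(penalty)
  spec <- penalty_spec(penalty, lambda = lambda, a = a)
  if (!is.null(target_cause)) {
    cohort <- recode_cause_specific(cohort, target_cause)
  }
  assert_binary_cause(cohort)
  time <- cohort$time
  status <- cohort$cause
  n <- length(time)

  Z <- cohort_matrix(cohort)
  pr <- prune_collinear(Z)
  Z <- pr$Z
  p <- ncol(Z)
  if (!force_susceptible && n <= p) {
    stop("need more subjects than covariates", call. = FALSE)
  }

  penalized <- spec$family != "none" && spec$lambda > 0
  std <- NULL
  if (penalized && control$standardize && p > 0L) {
    std <- list(center = colMeans(Z), scale = apply(Z, 2, stats::sd))
    std$scale[std$scale == 0] <- 1
    Z <- sweep(sweep(Z, 2, std$center), 2, std$scale, "/")
  }
  X <- cbind(`(Intercept)` = 1, Z)
  pen_fun <- penalty_deriv_fun(spec, n = n)

  if (force_susceptible) {
    w <- rep(1, n)
    lat <- m_step_latency(time, status, Z, w, pen_fun = pen_fun,
                          tol = control$mstep_tol,
                          maxit = control$mstep_maxit, cap = control$cap,
                          thresh = control$thresh)
    theta <- c(control$cap, numeric(p))
    fit <- build_cure_fit(theta, lat, time, status, X, Z, std, spec, cohort,
                          n, loglik = NA_real_, trace = NULL, iter = 0L,
                          converged = lat$converged, control = control,
                          dropped = pr$dropped, force_susceptible = TRUE)
    return(fit)
  }

  if (!is.null(init)) {
    # warm start on the raw scale; align by name, absent terms start at zero
    theta <- c(init$theta[["(Intercept)"]],
               vapply(colnames(Z), function(nm) {
                 if (nm %in% names(init$theta)) init$theta[[nm]] else 0
               }, numeric(1)))
    beta <- vapply(colnames(Z), function(nm) {
      if (nm %in% names(init$beta)) init$beta[[nm]] else 0
    }, numeric(1))
    if (!is.null(std)) {
      beta <- beta * std$scale
      theta[1L] <- theta[1L] + sum(theta[-1L] * std$center)
      theta[-1L] <- theta[-1L] * std$scale
    }
    baseline <- breslow_baseline(time, status, Z, rep(1, n), beta)
  } else {
    # initialization: logistic fit of the event indicator; naive Cox fit
    init_inc <- m_step_incidence(X, status, pen_fun = NULL,
                                 tol = control$mstep_tol,
                                 maxit = control$mstep_maxit,
                                 cap = control$cap)
    theta <- init_inc$theta
    lat <- m_step_latency(time, status, Z, rep(1, n), pen_fun = NULL,
                          tol = control$mstep_tol,
                          maxit = control$mstep_maxit, cap = control$cap)
    beta <- lat$beta
    baseline <- lat$baseline
  }

  trace <- vector("list", control$maxit)
  convergence <- "none"
  iter <- 0L
  ll_prev <- -Inf
  for (it in seq_len(control$maxit)) {
    iter <- it
    w <- e_step(time, status, X, Z, theta, beta, baseline)
    inc <- m_step_incidence(X, w, theta0 = theta, pen_fun = pen_fun,
                            tol = control$mstep_tol,
                            maxit = control$mstep_maxit, cap = control$cap,
                            thresh = control$thresh)
    lat <- m_step_latency(time, status, Z, w, beta0 = beta,
                          pen_fun = pen_fun, tol = control$mstep_tol,
                          maxit = control$mstep_maxit, cap = control$cap,
                          thresh = control$thresh)
    delta <- max(abs(c(inc$theta - theta, lat$beta - beta)))
    theta <- inc$theta
    beta <- lat$beta
    baseline <- lat$baseline
    ll <- observed_loglik(time, status, X, Z, theta, beta, baseline)
    trace[[it]] <- c(iteration = it, loglik = ll, max_change = delta)
    if (inc$separation || lat$capped) { convergence <- "capped"; break }
    if (delta < control$tol) { convergence <- "params"; break }
    # quasi-separated coefficients can drift along a flat likelihood ridge
    # indefinitely; a stalled likelihood is accepted as convergence
    if (it >= 10L && abs(ll - ll_prev) < control$ll_tol * (1 + abs(ll))) {
      convergence <- "loglik"
      break
    }
    ll_prev <- ll
  }
  converged <- convergence != "none"
  trace <- tibble::as_tibble(do.call(rbind, trace[seq_len(iter)]))
  ll <- trace$loglik[nrow(trace)]

  fit <- build_cure_fit(theta, list(beta = beta, baseline = baseline), time,
                        status, X, Z, std, spec, cohort, n, loglik = ll,
                        trace = trace, iter = iter, converged = converged,
                        control = control, dropped = pr$dropped,
                        force_susceptible = FALSE)
  fit$convergence <- convergence
  fit
}

prune_collinear <- function(Z) {
  if (ncol(Z) == 0L) return(list(Z = Z, dropped = character(0)))
  qd <- qr(cbind(1, Z))
  rank <- qd$rank
  dropped <- character(0)
  if (rank < ncol(Z) + 1L) {
    keep_piv <- qd$pivot[seq_len(rank)]
    keep <- sort(keep_piv[keep_piv > 1L] - 1L)
    dropped <- colnames(Z)[setdiff(seq_len(ncol(Z)), keep)]
    warning("collinear covariate column(s) dropped: ",
            paste(dropped, collapse = ", "), call. = FALSE)
    Z <- Z[, keep, drop = FALSE]
  }
  list(Z = Z, dropped = dropped)
}

build_cure_fit <- function(theta, lat, time, status, X, Z, std, spec, cohort,
                           n, loglik, trace, iter, converged, control,
                           dropped, force_susceptible) {
  beta <- lat$beta
  baseline <- tibble::as_tibble(lat$baseline)
  covs <- colnames(Z)
  names(theta) <- colnames(X)
  names(beta) <- covs
  if (!is.null(std)) {
    # back-transform standardized coefficients; the baseline absorbs the
    # centering constant
    c_off <- sum(beta * std$center / std$scale)
    beta <- beta / std$scale
    theta[-1L] <- theta[-1L] / std$scale
    theta[1L] <- theta[1L] - sum((theta[-1L]) * std$center)
    baseline$increment <- baseline$increment * exp(-c_off)
    baseline$cumhaz <- cumsum(baseline$increment)
  }
  df <- sum(theta != 0) + sum(beta != 0)
  if (force_susceptible) df <- sum(beta != 0)
  structure(list(
    theta = theta, beta = beta, baseline = baseline,
    loglik = loglik, df = df,
    aic = if (is.na(loglik)) NA_real_ else -2 * loglik + 2 * df,
    bic = if (is.na(loglik)) NA_real_ else -2 * loglik + log(n) * df,
    n = n, n_event = sum(status), converged = converged, iter = iter,
    trace = trace, penalty = spec, covariates = covs, dropped = dropped,
    force_susceptible = force_susceptible, control = control
  ), class = "cure_fit")
}

#' @export
print.cure_fit <- function(x, ...) {
  cat("Semi-parametric mixture cure model",
      if (x$penalty$family != "none")
        sprintf("(%s, lambda = %.4g)", toupper(x$penalty$family),
                x$penalty$lambda)
      else "(unpenalized)", "\n")
  cat(sprintf("  n = %d, events = %d, EM iterations = %d%s\n",
              x$n, x$n_event, x$iter,
              if (x$converged) "" else " (NOT converged)"))
  cat(sprintf("  loglik = %.3f, df = %d, AIC = %.2f, BIC = %.2f\n",
              x$loglik, x$df, x$aic, x$bic))
  cat("\nIncidence (cure) component:\n")
  print(round(x$theta, 4))
  cat("\nLatency (hazard) component:\n")
  if (length(x$beta)) print(round(x$beta, 4)) else cat("  (none)\n")
  invisible(x)
}

#' Tidy a mixture cure fit
#'
#' @param x A `cure_fit`.
#' @param ... Unused.
#' @return A tibble with one row per coefficient: `component` ("incidence"
#'   or "latency"), `term`, `estimate`, and `effect` (odds ratio
#'   `exp(estimate)` for incidence terms, hazard ratio for latency terms).
#' @export
#' @method tidy cure_fit
tidy.cure_fit <- function(x, ...) {
  dplyr::bind_rows(
    tibble::tibble(component = "incidence", term = names(x$theta),
                   estimate = unname(x$theta)),
    tibble::tibble(component = "latency", term = names(x$beta),
                   estimate = unname(x$beta))
  ) |>
    dplyr::mutate(effect = exp(.data$estimate))
}

#' @export
#' @method glance cure_fit
glance.cure_fit <- function(x, ...) {
  tibble::tibble(n = x$n, n_event = x$n_event, df = x$df, loglik = x$loglik,
                 aic = x$aic, bic = x$bic, converged = x$converged,
                 iter = x$iter, penalty = x$penalty$family,
                 lambda = x$penalty$lambda)
}

#' @export
#' @method autoplot cure_fit
autoplot.cure_fit <- function(object, ...) {
  df <- tidy(object)
  df <- df[df$term != "(Intercept)", ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$estimate, y = .data$term)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~.data$component) +
    ggplot2::labs(x = "Coefficient estimate", y = NULL) +
    ggplot2::theme_minimal()
}

#' Incidence probability of being susceptible
#'
#' Logistic incidence `pi(x) = expit(theta_0 + x' theta)`, computed
#' overflow-safely. `x` is the covariate vector (or matrix, rows =
#' subjects); the intercept in `theta` is supplied separately as its first
#' element.
#'
#' @param x Numeric covariate vector, or matrix with one row per subject.
#' @param theta Coefficient vector with leading intercept.
#' @return Probability (or vector of probabilities) in (0, 1).
#' @export
#' @examples
#' incidence_probability(1, c(-0.34, -1.14))
incidence_probability <- function(x, theta) {
  X <- design_with_intercept(x, length(theta))
  drop(expit(X %*% theta))
}

#' Cure probability
#'
#' The complement `1 - pi(x)` of [incidence_probability()]; the two sum to
#' one exactly.
#'
#' @inheritParams incidence_probability
#' @return Probability (or vector) in (0, 1).
#' @export
cure_probability <- function(x, theta) {
  X <- design_with_intercept(x, length(theta))
  drop(expit(-(X %*% theta)))
}

design_with_intercept <- function(x, p1) {
  if (is.matrix(x)) X <- cbind(1, x) else X <- matrix(c(1, x), nrow = 1)
  if (ncol(X) != p1) {
    stop("covariate vector has length ", ncol(X) - 1L,
         " but theta expects ", p1 - 1L, call. = FALSE)
  }
  X
}

#' Conditional survival of susceptible subjects
#'
#' `S_u(t|x) = S_0(t)^{exp(x' beta)}` from the Breslow baseline, with the
#' zero-tail constraint: zero beyond the largest event time.
#'
#' @param t Nonnegative time(s).
#' @param x Covariate vector (latency covariates, no intercept).
#' @param fit A `cure_fit`, or a list with `beta` and `baseline` fields.
#' @return Survival probability (vector over `t`).
#' @export
conditional_survival <- function(t, x, fit) {
  if (any(t < 0)) stop("negative time", call. = FALSE)
  beta <- fit$beta
  if (length(beta) != length(x)) {
    stop("covariate vector length must match beta", call. = FALSE)
  }
  eta <- sum(x * beta)
  susceptible_survival(t, rep(eta, length(t)), fit$baseline)
}

#' Population (marginal) survival of the mixture
#'
#' `S_pop(t|x) = 1 - pi(x) + pi(x) S_u(t|x)`; equals 1 at `t = 0` and
#' plateaus at the cure probability `1 - pi(x)` beyond the largest event
#' time.
#'
#' @inheritParams conditional_survival
#' @return Survival probability (vector over `t`).
#' @export
population_survival <- function(t, x, fit) {
  pi <- incidence_probability(x, fit$theta)
  Su <- conditional_survival(t, x, fit)
  1 - pi + pi * Su
}

#' Predictions from a mixture cure fit
#'
#' @param object A `cure_fit`.
#' @param newdata A data frame or `cohort` containing the fit's covariate
#'   columns (defaults required).
#' @param type `"cure"` (cure probability), `"incidence"` (susceptibility
#'   probability), `"survival"` (conditional susceptible survival at
#'   `times`), or `"population"` (marginal survival at `times`).
#' @param times Evaluation times for the survival types.
#' @param ... Unused.
#' @return A tibble: one row per subject (`type = "cure"`/`"incidence"`) or
#'   per subject-time (`"survival"`/`"population"`).
#' @export
predict.cure_fit <- function(object, newdata,
                             type = c("cure", "incidence", "survival",
                                      "population"),
                             times = NULL, ...) {
  type <- match.arg(type)
  covs <- object$covariates
  missing_cols <- setdiff(covs, names(newdata))
  if (length(missing_cols)) {
    stop("newdata lacks covariate column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  Z <- as.matrix(tibble::as_tibble(newdata)[covs])
  pi <- incidence_probability(Z, object$theta)
  id <- if ("id" %in% names(newdata)) as.character(newdata$id)
        else as.character(seq_len(nrow(Z)))
  if (type %in% c("cure", "incidence")) {
    return(tibble::tibble(
      id = id,
      estimate = if (type == "cure") 1 - pi else pi
    ))
  }
  if (is.null(times)) stop("`times` required for survival predictions",
                           call. = FALSE)
  eta <- drop(Z %*% object$beta)
  purrr::map_dfr(seq_along(times), function(k) {
    Su <- susceptible_survival(rep(times[k], nrow(Z)), eta, object$baseline)
    tibble::tibble(
      id = id, time = times[k],
      estimate = if (type == "survival") Su else 1 - pi + pi * Su
    )
  })
}
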