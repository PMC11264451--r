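#' Nonparametric bootstrap confidence intervals for a mixture cure fit
#'
#' Resamples subjects with replacement `B` times, refits the model on each
#' resample, and forms percentile intervals at the requested level from the
#' replicate coefficient distributions. Replicates whose fit errors or fails
#' to converge are dropped and counted; more than 50% unusable replicates is
#' an error. Coefficients whose column becomes collinear in a resample are
#' recorded as missing for that replicate and excluded from its quantiles.
#'
#' @param cohort A `cohort` tibble.
#' @param target_cause Cause of interest (others recoded to censoring).
#' @param B Number of bootstrap replicates (>= 2; conventional choice 1000).
#' @param level Confidence level in (0, 1), default 0.95.
#' @param seed Integer seed; the replicate resamples are drawn from it, so a
#'   fixed seed reproduces the interval table exactly.
#' @param penalty,lambda,a Passed to [fit_cure_model()] for each refit.
#' @param control A [cure_control()].
#' @param fitter Optional replacement fitter: a function taking a resampled
#'   `cohort` and returning a named coefficient vector. The default refits
#'   the mixture cure model and returns `c(inc:..., lat:...)` coefficients.
#' @return A tibble with one row per coefficient: `component`, `term`,
#'   `estimate` (point fit), `conf.low`, `conf.high`, `n_used` (replicates
#'   contributing). The number of dropped replicates is in
#'   `attr(, "n_failed")` and the replicate draws in `attr(, "replicates")`.
#' @export
bootstrap_ci <- function(cohort, target_cause = NULL, B = 1000L,
                         level = 0.95, seed = NULL,
                         penalty = "none", lambda = 0, a = 3.7,
                         control = cure_control(), fitter = NULL) {
  stopifnot(B >= 2, level > 0, level < 1)
  if (!is.null(target_cause)) {
    cohort <- recode_cause_specific(cohort, target_cause)
  }
  assert_binary_cause(cohort)
  if (is.null(fitter)) {
    fitter <- function(ch) {
      res <- suppressWarnings(suppressMessages(
        fit_cure_model(ch, penalty = penalty, lambda = lambda, a = a,
                       control = control)
      ))
      if (!res$converged) stop("replicate fit did not converge")
      stats::setNames(c(res$theta, res$beta),
                      c(paste0("inc:", names(res$theta)),
                        paste0("lat:", names(res$beta))))
    }
  }
  point <- fitter(cohort)
  terms <- names(point)
  n <- nrow(cohort)

  if (!is.null(seed)) set.seed(seed)
  idx <- matrix(sample.int(n, n * B, replace = TRUE), nrow = n, ncol = B)

  reps <- matrix(NA_real_, nrow = B, ncol = length(terms),
                 dimnames = list(NULL, terms))
  n_failed <- 0L
  for (b in seq_len(B)) {
    res <- tryCatch(fitter(cohort[idx[, b], ]), error = function(e) NULL)
    if (is.null(res)) {
      n_failed <- n_failed + 1L
      next
    }
    reps[b, intersect(names(res), terms)] <- res[intersect(names(res), terms)]
  }
  if (n_failed > B / 2) {
    stop("more than half of the bootstrap replicates failed (",
         n_failed, "/", B, ")", call. = FALSE)
  }

  probs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  qs <- apply(reps, 2, stats::quantile, probs = probs, na.rm = TRUE)
  component <- ifelse(startsWith(terms, "inc:"), "incidence",
                      ifelse(startsWith(terms, "lat:"), "latency", "other"))
  out <- tibble::tibble(
    component = component,
    term = sub("^(inc|lat):", "", terms),
    estimate = unname(point),
    conf.low = unname(qs[1, ]),
    conf.high = unname(qs[2, ]),
    n_used = colSums(!is.na(reps))
  )
  structure(out, n_failed = n_failed, B = B, level = level,
            replicates = reps, class = c("cure_boot", class(out)))
}
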