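#' Kaplan-Meier estimate for one cause
#'
#' Product-limit estimator of survival from the event of interest, with every
#' other cause treated as censoring (cause-specific recoding applied
#' internally). Ties between events and censorings at the same time are
#' resolved events-first, the standard survival convention.
#'
#' @param cohort A `cohort` tibble.
#' @param target_cause Cause code or label of the event of interest. Omit for
#'   an already-binary cohort.
#' @return A tibble of class `km_tbl` with columns `time`, `n_risk`,
#'   `n_event`, `n_censor`, `estimate` (right-continuous step values; the
#'   curve is 1 before the first row). The plateau value — the estimate at
#'   the largest observed time — is stored in `attr(, "plateau")`.
#' @export
kaplan_meier <- function(cohort, target_cause = NULL) {
  if (nrow(cohort) == 0L) stop("empty cohort", call. = FALSE)
  status <- cause_indicator(cohort, target_cause)
  sf <- survival::survfit(survival::Surv(cohort$time, status) ~ 1)
  out <- tibble::tibble(
    time = sf$time, n_risk = sf$n.risk, n_event = sf$n.event,
    n_censor = sf$n.censor, estimate = sf$surv
  )
  structure(out, plateau = out$estimate[nrow(out)],
            class = c("km_tbl", class(out)))
}

cause_indicator <- function(cohort, target_cause) {
  if (is.null(target_cause)) {
    if (!all(cohort$cause %in% c(0L, 1L))) {
      stop("supply `target_cause` for a multi-cause cohort", call. = FALSE)
    }
    return(cohort$cause)
  }
  tc <- resolve_cause(target_cause, cohort_causes(cohort))
  as.integer(cohort$cause == tc)
}

#' Plateau of a Kaplan-Meier curve
#'
#' @param km A `km_tbl` from [kaplan_meier()].
#' @return The survival estimate at the largest observed time.
#' @export
km_plateau <- function(km) attr(km, "plateau")

#' Aalen-Johansen cumulative incidence functions
#'
#' One cumulative incidence function (CIF) per declared event cause. At every
#' time the CIFs and the all-cause Kaplan-Meier survival sum to one.
#'
#' @param cohort A `cohort` tibble with at least one event of any cause.
#' @return A tibble of class `cif_tbl` with columns `time`, `cause` (label),
#'   `estimate`, covering all event causes at every jump time; the all-cause
#'   Kaplan-Meier step function is stored in `attr(, "km_all")` as a
#'   two-column tibble (`time`, `estimate`). Step functions are
#'   right-continuous and start at 0 (CIF) / 1 (survival).
#' @export
aalen_johansen_cif <- function(cohort) {
  if (nrow(cohort) == 0L) stop("empty cohort", call. = FALSE)
  causes <- cohort_causes(cohort)
  ev_codes <- sort(causes[causes >= 1L])
  ev_labels <- names(ev_codes)
  if (all(cohort$cause == 0L)) {
    # no events at all: every CIF is identically zero
    tms <- sort(unique(cohort$time))
    out <- tidyr::expand_grid(time = tms, cause = ev_labels)
    out$estimate <- 0
    km_all <- tibble::tibble(time = tms, estimate = 1)
    return(structure(out, km_all = km_all,
                     class = c("cif_tbl", class(out))))
  }
  state <- factor(cohort$cause, levels = c(0L, unname(ev_codes)),
                  labels = c("censor", ev_labels))
  sf <- survival::survfit(survival::Surv(cohort$time, state) ~ 1)
  states <- sf$states
  # first state is the initial (event-free) state
  cif <- lapply(ev_labels, function(lb) {
    tibble::tibble(time = sf$time, cause = lb,
                   estimate = sf$pstate[, match(lb, states)])
  })
  out <- dplyr::bind_rows(cif)
  km_all <- tibble::tibble(time = sf$time, estimate = sf$pstate[, 1L])
  structure(out, km_all = km_all, class = c("cif_tbl", class(out)))
}

#' Evaluate a right-continuous step function stored as a tibble
#'
#' @param steps A tibble with `time` and `estimate` columns (jump times
#'   increasing).
#' @param t Times at which to evaluate.
#' @param initial Value before the first jump (1 for survival, 0 for a CIF).
#' @return Numeric vector of step values at `t`.
#' @export
step_at <- function(steps, t, initial) {
  idx <- findInterval(t, steps$time)
  ifelse(idx == 0L, initial, steps$estimate[pmax(idx, 1L)])
}

#' Maller-Zhou check for sufficient follow-up and a cured fraction
#'
#' Implements the interval-count statistic of Maller and Zhou (1992): with
#' `t*` the largest uncensored (event) time and `t_max` the largest observed
#' time, `q_n = N_n / n` where `N_n` counts event times in the interval
#' `(2 t* - t_max, t*]`, and the approximate p-value for the null of
#' insufficient follow-up is `alpha_n = (1 - q_n)^n`. A small `alpha_n`
#' supports sufficient follow-up, which licenses reading the Kaplan-Meier
#' plateau as a cured fraction. Evidence of a nonzero cured fraction is
#' reported when the plateau is positive and the largest observation is
#' censored. The p-value is a conservative approximation.
#'
#' @param cohort A `cohort` tibble.
#' @param target_cause Cause of interest (others treated as censoring).
#' @return A list of class `maller_zhou` with elements `n`, `n_interval`
#'   (`N_n`), `q_n`, `alpha_n`, `t_star`, `t_max`, `plateau`,
#'   `sufficient_follow_up` (logical, at `level`), `cured_fraction_evidence`
#'   (logical), and `level`.
#' @param level Significance level for the follow-up verdict (default 0.05).
#' @export
maller_zhou_test <- function(cohort, target_cause = NULL, level = 0.05) {
  status <- cause_indicator(cohort, target_cause)
  if (sum(status) == 0L) stop("no events: Maller-Zhou check undefined", call. = FALSE)
  n <- nrow(cohort)
  t_star <- max(cohort$time[status == 1L])
  t_max <- max(cohort$time)
  lower <- 2 * t_star - t_max
  n_interval <- sum(status == 1L & cohort$time > lower & cohort$time <= t_star)
  q_n <- n_interval / n
  alpha_n <- (1 - q_n)^n
  km <- kaplan_meier(cohort, target_cause)
  plateau <- km_plateau(km)
  last_censored <- t_max > t_star || any(status == 0L & cohort$time == t_max)
  structure(list(
    n = n, n_interval = n_interval, q_n = q_n, alpha_n = alpha_n,
    t_star = t_star, t_max = t_max, plateau = plateau,
    sufficient_follow_up = alpha_n <= level,
    cured_fraction_evidence = plateau > 0 && last_censored,
    level = level
  ), class = "maller_zhou")
}

#' @export
print.maller_zhou <- function(x, ...) {
  cat("Maller-Zhou sufficient follow-up check\n")
  cat(sprintf("  n = %d, events in (2t* - t_max, t*] = %d, q_n = %.4f\n",
              x$n, x$n_interval, x$q_n))
  cat(sprintf("  alpha_n = (1 - q_n)^n = %.4g  (level %.2f)\n", x$alpha_n, x$level))
  cat("  verdict:",
      if (x$sufficient_follow_up) "follow-up appears sufficient"
      else "no evidence of sufficient follow-up", "\n")
  cat("  KM plateau:", format(x$plateau, digits = 4), "-",
      if (x$cured_fraction_evidence) "consistent with a nonzero cured fraction"
      else "no evidence of a cured fraction", "\n")
  invisible(x)
}

#' @export
#' @method tidy maller_zhou
tidy.maller_zhou <- function(x, ...) {
  tibble::tibble(n = x$n, n_interval = x$n_interval, q_n = x$q_n,
                 alpha_n = x$alpha_n, t_star = x$t_star, t_max = x$t_max,
                 plateau = x$plateau,
                 sufficient_follow_up = x$sufficient_follow_up,
                 cured_fraction_evidence = x$cured_fraction_evidence)
}

#' @export
#' @method autoplot km_tbl
autoplot.km_tbl <- function(object, ...) {
  df <- dplyr::bind_rows(tibble::tibble(time = 0, estimate = 1),
                         object[, c("time", "estimate")])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$estimate)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Time (months)", y = "Survival probability") +
    ggplot2::theme_minimal()
}

#' @export
#' @method autoplot cif_tbl
autoplot.cif_tbl <- function(object, ...) {
  zero <- dplyr::distinct(object, .data$cause)
  zero$time <- 0
  zero$estimate <- 0
  df <- dplyr::bind_rows(zero, object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$estimate,
                                   colour = .data$cause)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "Time (months)", y = "Cumulative incidence",
                  colour = "Cause") +
    ggplot2::theme_minimal()
}
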