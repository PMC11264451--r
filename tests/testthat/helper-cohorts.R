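# Small cohort builders and independent oracles shared across the suite.

tiny_cohort <- function(times, causes, ...) {
  covs <- list(...)
  df <- data.frame(time = times, cause = causes)
  if (length(covs) == 0L) covs <- list(x = rep(0, length(times)))
  for (nm in names(covs)) df[[nm]] <- covs[[nm]]
  suppressMessages(as_cohort(df))
}

# random small binary-cause cohort for property-style tests
random_small_cohort <- function(seed, n = NULL, p = 2L) {
  set.seed(seed)
  if (is.null(n)) n <- sample(15:40, 1)
  df <- data.frame(
    time = round(rexp(n, 0.2) + 0.1, 2),
    cause = rbinom(n, 1, 0.55)
  )
  for (j in seq_len(p)) df[[paste0("x", j)]] <- rbinom(n, 1, 0.5)
  if (sum(df$cause) == 0) df$cause[1] <- 1L
  suppressMessages(as_cohort(df, causes = c(censored = 0L, event = 1L)))
}

# random multi-cause cohort for competing-risks properties
random_cr_cohort <- function(seed, n = 30L) {
  set.seed(seed)
  df <- data.frame(
    time = round(rexp(n, 0.2) + 0.1, 2),
    cause = sample(0:2, n, replace = TRUE, prob = c(0.4, 0.35, 0.25)),
    x = rbinom(n, 1, 0.5)
  )
  suppressMessages(as_cohort(df))
}

# brute-force product-limit estimator over risk sets (events-first at ties)
km_oracle <- function(time, status, eval_times = sort(unique(time))) {
  vapply(eval_times, function(t) {
    ev_times <- sort(unique(time[status == 1 & time <= t]))
    prod(vapply(ev_times, function(u) {
      d <- sum(time == u & status == 1)
      r <- sum(time >= u)
      1 - d / r
    }, numeric(1)))
  }, numeric(1))
}

# weighted logistic log-likelihood for grid oracles
wlogis_loglik <- function(theta, X, w) {
  eta <- drop(X %*% theta)
  sum(w * eta - (pmax(eta, 0) + log1p(exp(-abs(eta)))))
}

# nested (coarse-to-fine) grid maximizer, an optimizer-free oracle
grid_maximize <- function(f, lower, upper, steps = 11L, refinements = 6L) {
  for (r in seq_len(refinements)) {
    grids <- Map(function(lo, hi) seq(lo, hi, length.out = steps),
                 lower, upper)
    pts <- as.matrix(expand.grid(grids))
    vals <- apply(pts, 1, f)
    best <- pts[which.max(vals), ]
    span <- (upper - lower) / (steps - 1)
    lower <- best - span
    upper <- best + span
  }
  best
}

# frozen small truths used by fitting and bootstrap tests
recovery_truth <- function(n = 1000L) {
  cohort_truth(
    covariates = list(x1 = list(type = "binary", p = 0.5)),
    theta = c(`(Intercept)` = 0.5, x1 = 1.0),
    beta_event = c(x1 = -0.8),
    base_event = list(shape = 1, scale = 10),
    censoring = list(rate = 0.01, horizon = 120),
    n = n
  )
}

coverage_truth <- function(n = 120L) {
  cohort_truth(
    covariates = list(x1 = list(type = "binary", p = 0.5)),
    theta = c(`(Intercept)` = 0.3, x1 = 0.8),
    beta_event = c(x1 = -0.5),
    base_event = list(shape = 1, scale = 8),
    censoring = list(rate = 0.01, horizon = 80),
    n = n
  )
}

null_truth <- function(n = 1000L) {
  covs <- lapply(1:6, function(i) list(type = "binary", p = 0.5))
  names(covs) <- paste0("x", 1:6)
  cohort_truth(
    covariates = covs,
    theta = c(`(Intercept)` = 0.4),
    beta_event = numeric(0),
    base_event = list(shape = 1, scale = 6),
    censoring = list(rate = 0.008, horizon = 100),
    n = n
  )
}
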