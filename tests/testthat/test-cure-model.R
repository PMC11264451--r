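test_that("incidence and cure probabilities follow the logistic form and
          sum to one", {
  expect_equal(incidence_probability(numeric(0), 0), 0.5)
  expect_equal(cure_probability(numeric(0), 0), 0.5)

  # intercept-only incidence at -0.37: pi = 0.4086, cure 0.5914
  expect_equal(incidence_probability(numeric(0), -0.37), 0.40855,
               tolerance = 1e-4)
  expect_equal(cure_probability(numeric(0), -0.37), 0.59145,
               tolerance = 1e-4)
  # one indicator: expit(-0.34 - 1.14) = expit(-1.48)
  expect_equal(incidence_probability(1, c(-0.34, -1.14)), 0.18543,
               tolerance = 1e-4)
  # intercept-only cure at -0.75
  expect_equal(cure_probability(numeric(0), -0.75), 0.67918,
               tolerance = 1e-4)

  # conservation, exactly
  for (eta in c(-30, -2, 0, 1.7, 25)) {
    x <- c(1, 0.5)
    th <- c(eta, 0.3, -0.2)
    expect_equal(incidence_probability(x, th) + cure_probability(x, th), 1)
  }
  # overflow safety
  expect_equal(incidence_probability(numeric(0), 800), 1)
  expect_equal(incidence_probability(numeric(0), -800), 0)
  expect_error(incidence_probability(c(1, 2), c(0, 1)), "length")
})

test_that("conditional and population survival follow the mixture with the
          zero-tail constraint", {
  params <- list(
    theta = c(`(Intercept)` = qlogis(0.4)),
    beta = numeric(0),
    baseline = tibble::tibble(time = c(1, 2), increment = c(1 / 3, 1 / 2),
                              cumhaz = cumsum(c(1 / 3, 1 / 2)))
  )
  expect_equal(conditional_survival(0, numeric(0), params), 1)
  expect_equal(conditional_survival(1.5, numeric(0), params), exp(-1 / 3))
  # zero tail beyond the last event time
  expect_equal(conditional_survival(2.5, numeric(0), params), 0)
  expect_error(conditional_survival(-1, numeric(0), params), "negative")

  # population mixture: pi = 0.4, S_u = exp(-1/3) at t = 1.5
  expect_equal(population_survival(0, numeric(0), params), 1)
  expect_equal(population_survival(1.5, numeric(0), params),
               0.6 + 0.4 * exp(-1 / 3))
  # plateau equals the cure probability
  expect_equal(population_survival(10, numeric(0), params), 0.6)

  # explicit arithmetic: pi = 0.4, S_u = 0.5 -> 0.8
  params2 <- params
  params2$baseline <- tibble::tibble(time = 1, increment = log(2),
                                     cumhaz = log(2))
  expect_equal(population_survival(1, numeric(0), params2),
               0.6 + 0.4 * 0.5)
})

test_that("E-step weights are the posterior uncured probabilities", {
  baseline <- tibble::tibble(time = c(2, 4), increment = c(0.2, 0.4),
                             cumhaz = c(0.2, 0.6))
  X <- matrix(1, 3, 1)
  Z <- matrix(numeric(0), 3, 0)
  # event; censored before first event time (S_u = 1); censored past tail
  w <- cureselect:::e_step(time = c(3, 1, 5), status = c(1, 0, 0),
                           X = X, Z = Z, theta = 0, beta = numeric(0),
                           baseline = baseline)
  expect_equal(w[1], 1)
  expect_equal(w[2], 0.5)   # pi = 0.5, S_u = 1
  expect_equal(w[3], 0)     # zero tail
  expect_true(all(w >= 0 & w <= 1))
})

test_that("incidence M-step solves the weighted logistic score", {
  # symmetric weights, no covariates -> intercept 0
  X0 <- matrix(1, 10, 1)
  r <- cureselect:::m_step_incidence(X0, rep(0.5, 10))
  expect_equal(r$theta, 0, tolerance = 1e-8)

  # all weights 1 -> separation, capped with a warning
  expect_warning(
    r1 <- cureselect:::m_step_incidence(X0, rep(1, 10)),
    "separation"
  )
  expect_equal(abs(r1$theta), 50)

  # 20-row two-covariate fixture vs nested-grid oracle
  set.seed(7)
  X <- cbind(1, rbinom(20, 1, 0.5), rnorm(20))
  w <- runif(20)
  fit <- cureselect:::m_step_incidence(X, w)
  oracle <- grid_maximize(function(th) wlogis_loglik(th, X, w),
                          lower = c(-3, -3, -3), upper = c(3, 3, 3))
  expect_equal(unname(fit$theta), unname(oracle), tolerance = 1e-3)
})

test_that("latency M-step reproduces hand Breslow increments and reference
          Cox fits", {
  # beta = 0 (no covariates), times (1,2,3), events (1,1,0), w = 1:
  # increments 1/3 and 1/2
  r <- cureselect:::m_step_latency(c(1, 2, 3), c(1, 1, 0),
                                   matrix(numeric(0), 3, 0), rep(1, 3))
  expect_equal(r$baseline$time, c(1, 2))
  expect_equal(r$baseline$increment, c(1 / 3, 1 / 2))

  # weights all 1 reduces to a standard Cox fit (coxph as reference oracle)
  set.seed(11)
  n <- 20
  Z <- cbind(z1 = rnorm(n), z2 = rbinom(n, 1, 0.5))
  t <- round(rexp(n, 0.3), 2)
  d <- rbinom(n, 1, 0.7); d[1] <- 1L
  m <- cureselect:::m_step_latency(t, d, Z, rep(1, n))
  cf <- survival::coxph(survival::Surv(t, d) ~ Z, ties = "breslow")
  expect_equal(unname(m$beta), unname(coef(cf)), tolerance = 1e-6)
  bh <- survival::basehaz(cf, centered = FALSE)
  expect_equal(max(m$baseline$cumhaz), max(bh$hazard), tolerance = 1e-6)

  # fractional weights match coxph case weights
  w <- runif(n, 0.2, 1); w[d == 1] <- 1
  m2 <- cureselect:::m_step_latency(t, d, Z, w)
  cf2 <- survival::coxph(survival::Surv(t, d) ~ Z, weights = w,
                         ties = "breslow")
  expect_equal(unname(m2$beta), unname(coef(cf2)), tolerance = 1e-6)

  # single covariate vs an independent 1-d score root finder
  t3 <- c(1, 2, 3); d3 <- c(1, 1, 1); x3 <- c(1, 0, 1)
  score <- function(b) {
    risk <- function(at) which(t3 >= at)
    sum(vapply(which(d3 == 1), function(i) {
      r <- risk(t3[i])
      x3[i] - sum(x3[r] * exp(b * x3[r])) / sum(exp(b * x3[r]))
    }, numeric(1)))
  }
  root <- uniroot(score, c(-10, 10), tol = 1e-10)$root
  m3 <- cureselect:::m_step_latency(t3, d3, cbind(x = x3), rep(1, 3))
  expect_equal(unname(m3$beta), root, tolerance = 1e-6)

  expect_error(
    cureselect:::m_step_latency(c(1, 2), c(0, 0),
                                matrix(numeric(0), 2, 0), c(1, 1)),
    "no events"
  )
})

test_that("the full EM recovers generating parameters on a simulated cohort", {
  ch <- simulate_cohort(recovery_truth(), seed = 42)
  fit <- fit_cure_model(ch)
  expect_true(fit$converged)
  expect_lt(abs(fit$theta[["(Intercept)"]] - 0.5), 0.15)
  expect_lt(abs(fit$theta[["x1"]] - 1.0), 0.15)
  expect_lt(abs(fit$beta[["x1"]] + 0.8), 0.15)
  # criteria bookkeeping is consistent
  expect_equal(fit$aic, -2 * fit$loglik + 2 * fit$df)
  expect_equal(fit$bic, -2 * fit$loglik + log(fit$n) * fit$df)
})

test_that("degenerate cohorts trigger separation and collinearity handling", {
  # zero censoring: everyone susceptible, incidence intercept diverges
  df <- data.frame(time = round(rexp(40, 0.2) + 0.1, 2),
                   cause = 1L, x = rbinom(40, 1, 0.5))
  ch <- suppressMessages(as_cohort(df, causes = c(censored = 0, event = 1)))
  expect_warning(fit <- fit_cure_model(ch), "separation")
  expect_equal(abs(fit$theta[["(Intercept)"]]), 50)

  # duplicated covariate column: warning, fit proceeds on the pruned matrix
  ch2 <- simulate_cohort(recovery_truth(n = 150), seed = 3)
  ch2$x_dup <- ch2$x1
  attr(ch2, "covariates") <- c("x1", "x_dup")
  expect_warning(fit2 <- fit_cure_model(ch2), "collinear")
  expect_equal(fit2$covariates, "x1")
  expect_true(fit2$converged)
})

test_that("EM ascends the observed-data log-likelihood and keeps weights in
          range", {
  for (seed in 1:10) {
    ch <- random_small_cohort(seed)
    fit <- suppressWarnings(fit_cure_model(ch))
    ll <- fit$trace$loglik
    # the final iteration of a separation-capped run is an explicit
    # intervention (snap to the cap), not an EM step
    if (fit$convergence == "capped") ll <- ll[-length(ll)]
    d <- diff(ll)
    tol <- 1e-8 * (1 + max(abs(fit$trace$loglik)))
    expect_true(all(d >= -tol))
    w <- cureselect:::e_step(ch$time, ch$cause,
                             cbind(1, cureselect:::cohort_matrix(ch)),
                             cureselect:::cohort_matrix(ch),
                             fit$theta, fit$beta, fit$baseline)
    expect_true(all(w >= 0 & w <= 1))
    expect_true(all(w[ch$cause == 1] == 1))
  }
})

test_that("population survival is nonincreasing with plateau at the cure
          probability", {
  ch <- simulate_cohort(recovery_truth(n = 300), seed = 9)
  fit <- fit_cure_model(ch)
  for (x in list(0, 1)) {
    ts <- seq(0, 150, by = 1)
    s <- population_survival(ts, x, fit)
    expect_true(all(diff(s) <= 1e-12))
    expect_equal(s[length(s)], cure_probability(x, fit$theta))
  }
})

test_that("forcing everyone susceptible reduces the fit to ordinary Cox", {
  ch <- simulate_cohort(recovery_truth(n = 400), seed = 5)
  fit <- fit_cure_model(ch, force_susceptible = TRUE)
  cf <- survival::coxph(survival::Surv(time, cause) ~ x1, data = ch,
                        ties = "breslow")
  expect_equal(unname(fit$beta), unname(coef(cf)), tolerance = 1e-4)
})

test_that("tidy, glance and predict expose the fit as tibbles", {
  ch <- simulate_cohort(recovery_truth(n = 250), seed = 13)
  fit <- fit_cure_model(ch)
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_equal(td$effect, exp(td$estimate))
  expect_setequal(unique(td$component), c("incidence", "latency"))
  gl <- glance(fit)
  expect_equal(gl$n, 250)
  expect_equal(gl$df, fit$df)

  pr <- predict(fit, ch[1:5, ], type = "cure")
  expect_equal(nrow(pr), 5)
  expect_true(all(pr$estimate > 0 & pr$estimate < 1))
  ps <- predict(fit, ch[1:2, ], type = "population", times = c(0, 5, 1e6))
  expect_equal(nrow(ps), 6)
  expect_equal(ps$estimate[ps$time == 0], c(1, 1))
})
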