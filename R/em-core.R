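# Numerical core of the mixture cure EM: overflow-safe logistic pieces,
# weighted Newton solvers for the incidence (logistic) and latency (Cox
# partial likelihood, Breslow ties) M-steps, the Breslow baseline, the
# E-step posterior weights, and the observed-data log-likelihood.
#
# Conventions: X is the incidence design matrix WITH a leading intercept
# column; Z is the latency covariate matrix WITHOUT an intercept. Event
# subjects carry weight exactly 1 in the EM; censored subjects carry their
# posterior uncured probability w in [0, 1].

expit <- function(eta) {
  out <- numeric(length(eta))
  pos <- !is.na(eta) & eta >= 0
  out[pos] <- 1 / (1 + exp(-eta[pos]))
  e <- exp(eta[!pos])
  out[!pos] <- e / (1 + e)
  out[is.na(eta)] <- NA_real_
  out
}

log1pexp <- function(eta) pmax(eta, 0) + log1p(exp(-abs(eta)))

rev_cumsum_cols <- function(m) {
  if (nrow(m) <= 1L || ncol(m) == 0L) return(m)
  rev_cumsum_cols_cpp(m)
}

# Weighted logistic M-step: maximizes sum_i w_i eta_i - log(1 + e^eta_i)
# (the expected complete-data incidence log-likelihood), optionally with a
# local-quadratic penalty approximation re-linearized each Newton step.
# `pen_fun(b)` returns the penalty derivative at |b| for each non-intercept
# coefficient (NULL for the unpenalized step).
m_step_incidence <- function(X, w, theta0 = NULL, pen_fun = NULL,
                             tol = 1e-8, maxit = 100L, cap = 50,
                             thresh = 1e-6) {
  p1 <- ncol(X)
  theta <- if (is.null(theta0)) numeric(p1) else theta0
  separation <- FALSE
  conv <- FALSE
  obj <- function(th, E) {
    eta <- drop(X %*% th)
    sum(w * eta - log1pexp(eta)) - 0.5 * sum(E * th^2)
  }
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% theta)
    p <- expit(eta)
    g <- drop(crossprod(X, w - p))
    v <- pmax(p * (1 - p), 1e-300)
    H <- crossprod(X * v, X)
    E <- numeric(p1)
    if (!is.null(pen_fun) && p1 > 1L) {
      theta[-1L] <- lqa_reactivate(theta[-1L], g[-1L], diag(H)[-1L], pen_fun)
      E[-1L] <- lqa_weights(theta[-1L], pen_fun)
    }
    gp <- g - E * theta
    diag(H) <- diag(H) + E
    step <- solve_ridge(H, gp)
    f0 <- obj(theta, E)
    alpha <- 1
    repeat {
      theta_new <- theta + alpha * step
      if (isTRUE(obj(theta_new, E) >= f0 - 1e-12)) break
      if (alpha < 1e-6) { theta_new <- theta; break }  # no ascent: reject
      alpha <- alpha / 2
    }
    # beyond |30| the fitted probabilities are numerically 0/1: the
    # coefficient is divergent; report it at the declared cap
    sep_bound <- min(30, cap)
    if (any(abs(theta_new) > sep_bound)) {
      div <- abs(theta_new) > sep_bound
      theta_new[div] <- sign(theta_new[div]) * cap
      separation <- TRUE
    }
    if (!is.null(pen_fun) && p1 > 1L) {
      small <- c(FALSE, abs(theta_new[-1L]) < thresh)
      theta_new[small] <- 0
    }
    delta <- max(abs(theta_new - theta))
    theta <- theta_new
    if (separation) break
    if (delta < tol) { conv <- TRUE; break }
  }
  if (separation) {
    warning("separation in incidence M-step: coefficient capped at |",
            cap, "|", call. = FALSE)
  }
  list(theta = theta, converged = conv || separation, separation = separation)
}

# Local-quadratic-approximation penalty weights: E_jj = p\'(|b_j|)/|b_j|.
# Coefficients at exactly zero are held there by an effectively infinite
# weight; lqa_reactivate() first frees any zero coefficient whose
# unpenalized score violates the KKT condition |g_j| <= p\'(0), giving it a
# one-coordinate soft-threshold kick so the quadratic step can pick it up.
lqa_weights <- function(b, pen_fun) {
  ab <- abs(b)
  ifelse(ab < 1e-12, 1e12, pen_fun(ab) / (ab + 1e-8))
}

lqa_reactivate <- function(b, g, hdiag, pen_fun) {
  pd0 <- pen_fun(rep(0, length(b)))
  viol <- abs(b) < 1e-12 & abs(g) > pd0 * (1 + 1e-8)
  if (any(viol)) {
    b[viol] <- sign(g[viol]) * (abs(g[viol]) - pd0[viol]) /
      pmax(hdiag[viol], 1e-8)
  }
  b
}

# Risk-set bookkeeping for the weighted Cox partial likelihood. Returns the
# sorted arrays and, for each sorted position, the first index of its tied
# time group (so reverse cumulative sums evaluated there cover the full
# risk set {k : t_k >= t_i}).
cox_sort <- function(time) {
  ord <- order(time)
  ts <- time[ord]
  first <- which(!duplicated(ts))
  grp_sizes <- diff(c(first, length(ts) + 1L))
  firstidx <- rep(first, grp_sizes)
  list(ord = ord, time = ts, firstidx = firstidx)
}

# Weighted Cox M-step (Breslow ties): censored subjects enter risk sets with
# multiplier w_i; events contribute with weight 1 (or their given weight).
# Returns beta, the Breslow baseline increments, and the achieved weighted
# partial log-likelihood. Handles p = 0 (baseline-only) cleanly.
m_step_latency <- function(time, status, Z, w, beta0 = NULL, pen_fun = NULL,
                           tol = 1e-8, maxit = 100L, cap = 50,
                           thresh = 1e-6) {
  if (sum(status) == 0) stop("no events: latency M-step undefined", call. = FALSE)
  p <- ncol(Z)
  srt <- cox_sort(time)
  ts <- srt$time
  ds <- status[srt$ord]
  ws <- w[srt$ord]
  Zs <- if (p > 0L) Z[srt$ord, , drop = FALSE] else matrix(numeric(0), length(ts), 0)
  fidx <- srt$firstidx
  ev <- ds == 1

  pl_parts <- function(beta) {
    eta <- if (p > 0L) drop(Zs %*% beta) else numeric(length(ts))
    c_off <- max(eta)
    s <- ws * exp(eta - c_off)
    S0 <- rev(cumsum(rev(s)))[fidx]
    list(eta = eta, c_off = c_off, s = s, S0 = S0)
  }
  pl_value <- function(parts) {
    sum(ws[ev] * (parts$eta[ev] - parts$c_off -
                    log(pmax(parts$S0[ev], 1e-300))))
  }

  beta <- if (is.null(beta0) || p == 0L) numeric(p) else beta0
  conv <- p == 0L
  capped <- FALSE
  if (p > 0L) {
    Zev <- Zs[ev, , drop = FALSE]
    wev <- ws[ev]
    fev <- fidx[ev]
    ZZ <- Zs[, rep(seq_len(p), times = p), drop = FALSE] *
      Zs[, rep(seq_len(p), each = p), drop = FALSE]
    for (it in seq_len(maxit)) {
      parts <- pl_parts(beta)
      S0ev <- parts$S0[ev]
      Zbar <- rev_cumsum_cols(parts$s * Zs)[fev, , drop = FALSE] / S0ev
      g <- drop(crossprod(Zev - Zbar, wev))
      S2 <- rev_cumsum_cols(parts$s * ZZ)[fev, , drop = FALSE]
      H <- matrix(colSums(wev * (S2 / S0ev)), p, p)
      H <- H - crossprod(sqrt(wev) * Zbar)
      E <- numeric(p)
      if (!is.null(pen_fun)) {
        beta <- lqa_reactivate(beta, g, diag(H), pen_fun)
        E <- lqa_weights(beta, pen_fun)
      }
      gp <- g - E * beta
      diag(H) <- diag(H) + E
      step <- solve_ridge(H, gp)
      f0 <- pl_value(parts) - 0.5 * sum(E * beta^2)
      alpha <- 1
      repeat {
        beta_new <- beta + alpha * step
        f1 <- pl_value(pl_parts(beta_new)) - 0.5 * sum(E * beta_new^2)
        if (isTRUE(f1 >= f0 - 1e-12)) break
        if (alpha < 1e-6) { beta_new <- beta; break }  # no ascent: reject
        alpha <- alpha / 2
      }
      sep_bound <- min(30, cap)
      if (any(abs(beta_new) > sep_bound)) {
        # relative risks are numerically saturated: divergent coefficient,
        # reported at the declared cap
        div <- abs(beta_new) > sep_bound
        beta_new[div] <- sign(beta_new[div]) * cap
        capped <- TRUE
      }
      if (!is.null(pen_fun)) beta_new[abs(beta_new) < thresh] <- 0
      delta <- max(abs(beta_new - beta))
      beta <- beta_new
      if (capped) break
      if (delta < tol) { conv <- TRUE; break }
    }
    if (capped) {
      warning("latency coefficient capped at |", cap, "|", call. = FALSE)
    }
  }

  parts <- pl_parts(beta)
  ut <- unique(ts[ev])
  d_k <- drop(rowsum(ws[ev], group = ts[ev]))  # ts ascending: matches ut
  S0_k <- parts$S0[match(ut, ts)] * exp(parts$c_off)
  increments <- unname(d_k / S0_k)
  # plain list: this runs thousands of times inside the EM; the public fit
  # object converts it to a tibble once
  baseline <- list(time = ut, increment = increments,
                   cumhaz = cumsum(increments))
  list(beta = beta, baseline = baseline,
       partial_loglik = pl_value(parts),
       converged = conv || capped, capped = capped)
}

# Cumulative baseline hazard H0(t), with the zero-tail convention handled by
# callers (H0 is finite everywhere; S_u is forced to zero beyond the last
# event time where the cure fraction requires it).
baseline_cumhaz <- function(baseline, t) {
  idx <- findInterval(t, baseline$time)
  out <- baseline$cumhaz[pmax(idx, 1L)]
  out[idx == 0L] <- 0
  out
}

# Conditional susceptible survival S_u(t | z) = exp(-H0(t) e^{z beta}) with
# the zero-tail constraint: 0 beyond the largest event time.
susceptible_survival <- function(time, eta_z, baseline, zero_tail = TRUE) {
  H <- baseline_cumhaz(baseline, time)
  S <- exp(-H * exp(eta_z))
  nb <- length(baseline$time)
  if (zero_tail && nb > 0L) {
    S[time > baseline$time[nb]] <- 0
  }
  S
}

# E-step: posterior uncured probabilities. Events are exactly 1; censored
# subjects get pi * S_u / (1 - pi + pi * S_u), zero beyond the last event
# time (zero-tail).
e_step <- function(time, status, X, Z, theta, beta, baseline) {
  eta_x <- drop(X %*% theta)
  pi <- expit(eta_x)
  eta_z <- if (ncol(Z) > 0L) drop(Z %*% beta) else numeric(length(time))
  Su <- susceptible_survival(time, eta_z, baseline)
  denom <- pmax(1 - pi + pi * Su, 1e-300)
  w <- pi * Su / denom
  w[status == 1] <- 1
  pmin(pmax(w, 0), 1)
}

# Observed-data log-likelihood under the discrete Breslow baseline: events
# contribute log pi + log dH0(t) + eta_z - H0(t) e^{eta_z}; censored subjects
# contribute log(1 - pi + pi S_u(t)).
observed_loglik <- function(time, status, X, Z, theta, beta, baseline) {
  eta_x <- drop(X %*% theta)
  log_pi <- -log1pexp(-eta_x)
  pi <- expit(eta_x)
  eta_z <- if (ncol(Z) > 0L) drop(Z %*% beta) else numeric(length(time))
  H <- baseline_cumhaz(baseline, time)
  ll <- numeric(length(time))
  ev <- status == 1
  dH <- baseline$increment[match(time[ev], baseline$time)]
  ll[ev] <- log_pi[ev] + log(pmax(dH, 1e-300)) + eta_z[ev] - H[ev] * exp(eta_z[ev])
  Su <- susceptible_survival(time[!ev], eta_z[!ev], baseline)
  ll[!ev] <- log(pmax(1 - pi[!ev] + pi[!ev] * Su, 1e-300))
  sum(ll)
}

# Breslow baseline at fixed beta (no Newton updates)
breslow_baseline <- function(time, status, Z, w, beta) {
  m_step_latency(time, status, Z, w, beta0 = beta, maxit = 0L)$baseline
}

# Newton solve with escalating ridge jitter on singular Hessians; a zero
# step (stalling this update) is the last resort
solve_ridge <- function(H, g) {
  out <- tryCatch(solve(H, g), error = function(e) NULL)
  if (!is.null(out)) return(out)
  scale <- max(abs(diag(H)), 1)
  for (jit in c(1e-8, 1e-5, 1e-2)) {
    Hj <- H
    diag(Hj) <- diag(Hj) + jit * scale
    out <- tryCatch(solve(Hj, g), error = function(e) NULL)
    if (!is.null(out)) return(out)
  }
  numeric(length(g))
}
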