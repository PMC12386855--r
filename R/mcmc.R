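# MCMC machinery for the overdispersed binomial logistic model:
#   s_i ~ Binomial(n_i, p_i),  logit(p_i) = eta_i,  eta_i = beta_{t(i)} + u_i,
#   u_i ~ Normal(0, sigma^2),
#   beta_t ~ Normal(0, prior_sd^2),  sigma ~ half-Normal(0, sigma_prior_sd).
#
# The chain works on the row linear predictors eta directly (centred
# parameterisation): eta_i has a data-dominated full conditional and is
# updated by a bank of independent adaptive Metropolis moves; beta_t is then
# conjugate given eta and sigma (normal-normal) and is drawn exactly, which
# is what gives the sampler its mixing; sigma moves by a random walk on the
# log scale. With sigma fixed at 0 the rows collapse onto their treatment
# logit and beta is updated by vectorised Metropolis on the binomial
# likelihood directly.

run_chain <- function(s, n, tidx, n_treat, prior_sd, sigma_prior_sd,
                      sigma_fixed, warmup, keep) {
  nrow_ <- length(s)
  flat <- !is.finite(prior_sd)
  est_sigma <- is.null(sigma_fixed)
  sigma <- if (est_sigma) 0.5 else sigma_fixed
  collapse <- !est_sigma && sigma == 0
  m_t <- tabulate(tidx, n_treat)
  loglik_row <- function(eta) stats::dbinom(s, n, stats::plogis(eta),
                                            log = TRUE)
  # dispersed moment-style initial values
  emp <- stats::qlogis((s + 0.5) / (n + 1))
  beta <- as.numeric(tapply(emp, tidx, mean)) + stats::rnorm(n_treat, 0, 0.5)
  eta <- if (collapse) beta[tidx] else emp + stats::rnorm(nrow_, 0, 0.1)
  ll_row <- loglik_row(eta)
  ls_eta <- rep(log(0.3), nrow_)
  ls_beta <- rep(log(0.3), n_treat)
  ls_sigma <- log(0.5)
  acc_target <- 0.44
  batch <- 50L
  out_beta <- matrix(NA_real_, n_treat, keep)
  out_u <- matrix(NA_real_, nrow_, keep)
  out_sigma <- numeric(keep)
  acc_eta <- numeric(nrow_); acc_beta <- numeric(n_treat); acc_sigma <- 0
  for (it in seq_len(warmup + keep)) {
    if (collapse) {
      # --- no random effect: vectorised Metropolis on beta ---
      prop <- beta + stats::rnorm(n_treat, 0, exp(ls_beta))
      ll_prop <- loglik_row(prop[tidx])
      d <- as.numeric(rowsum(ll_prop - ll_row, tidx))
      if (!flat)
        d <- d + stats::dnorm(prop, 0, prior_sd, log = TRUE) -
          stats::dnorm(beta, 0, prior_sd, log = TRUE)
      ok <- log(stats::runif(n_treat)) < d
      ok[is.na(ok)] <- FALSE
      if (any(ok)) {
        beta[ok] <- prop[ok]
        rows_ok <- ok[tidx]
        ll_row[rows_ok] <- ll_prop[rows_ok]
        acc_beta[ok] <- acc_beta[ok] + 1
      }
      eta <- beta[tidx]
    } else {
      # --- eta block: independent adaptive Metropolis per row ---
      prop <- eta + stats::rnorm(nrow_, 0, exp(ls_eta))
      ll_prop <- loglik_row(prop)
      d <- ll_prop - ll_row +
        stats::dnorm(prop, beta[tidx], sigma, log = TRUE) -
        stats::dnorm(eta, beta[tidx], sigma, log = TRUE)
      ok <- log(stats::runif(nrow_)) < d
      ok[is.na(ok)] <- FALSE
      if (any(ok)) {
        eta[ok] <- prop[ok]
        ll_row[ok] <- ll_prop[ok]
        acc_eta[ok] <- acc_eta[ok] + 1
      }
      # --- beta block: exact normal-normal Gibbs draw given eta, sigma ---
      ybar <- as.numeric(rowsum(eta, tidx)) / m_t
      prec_lik <- m_t / sigma^2
      prec_pri <- if (flat) 0 else 1 / prior_sd^2
      post_var <- 1 / (prec_lik + prec_pri)
      post_mean <- post_var * (prec_lik * ybar)
      beta <- stats::rnorm(n_treat, post_mean, sqrt(post_var))
      # --- sigma: random walk on log(sigma), half-normal prior, Jacobian ---
      if (est_sigma) {
        u <- eta - beta[tidx]
        lsig_p <- log(sigma) + stats::rnorm(1, 0, exp(ls_sigma))
        sig_p <- exp(lsig_p)
        d <- sum(stats::dnorm(u, 0, sig_p, log = TRUE)) -
          sum(stats::dnorm(u, 0, sigma, log = TRUE)) +
          stats::dnorm(sig_p, 0, sigma_prior_sd, log = TRUE) -
          stats::dnorm(sigma, 0, sigma_prior_sd, log = TRUE) +
          lsig_p - log(sigma)
        if (is.finite(d) && log(stats::runif(1)) < d) {
          sigma <- sig_p
          acc_sigma <- acc_sigma + 1
        }
      }
    }
    if (it <= warmup && it %% batch == 0L) {
      gam <- min(0.25, 1 / sqrt(it / batch))
      ls_eta <- ls_eta + gam * sign(acc_eta / batch - acc_target)
      ls_beta <- ls_beta + gam * sign(acc_beta / batch - acc_target)
      ls_sigma <- ls_sigma + gam * sign(acc_sigma / batch - acc_target)
      acc_eta[] <- 0; acc_beta[] <- 0; acc_sigma <- 0
    }
    if (it > warmup) {
      j <- it - warmup
      out_beta[, j] <- beta
      out_u[, j] <- eta - beta[tidx]
      out_sigma[j] <- sigma
    }
  }
  list(beta = out_beta, u = out_u, sigma = out_sigma)
}

# Split-Rhat of Gelman et al.: each chain halved, potential scale reduction
# across the 2*chains half-chains.
split_rhat <- function(draws_by_chain) {
  halves <- unlist(lapply(draws_by_chain, function(x) {
    m <- length(x) %/% 2L
    list(x[seq_len(m)], x[m + seq_len(m)])
  }), recursive = FALSE)
  n <- length(halves[[1]])
  if (n < 2L) return(NA_real_)
  means <- vapply(halves, mean, numeric(1))
  vars <- vapply(halves, stats::var, numeric(1))
  W <- mean(vars)
  B <- n * stats::var(means)
  if (W == 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

# Effective sample size via Geyer's initial positive sequence on the
# chain-averaged autocovariance, between-chain variance included.
ess_basic <- function(draws_by_chain) {
  n <- length(draws_by_chain[[1]])
  m <- length(draws_by_chain)
  if (n < 4L) return(NA_real_)
  acov <- lapply(draws_by_chain, function(x) {
    xc <- x - mean(x)
    stats::acf(xc, lag.max = min(n - 1L, 200L), plot = FALSE,
               demean = FALSE, type = "covariance")$acf[, 1, 1]
  })
  mean_acov <- Reduce(`+`, acov) / m
  var_plus <- mean_acov[1] * (n - 1) / n +
    if (m > 1) stats::var(vapply(draws_by_chain, mean, numeric(1))) else 0
  if (var_plus == 0) return(m * n)
  rho <- 1 - (mean_acov[1] - mean_acov[-1]) / var_plus
  ess_sum <- 0
  t <- 1L
  while (t + 1L <= length(rho)) {
    pair <- rho[t] + rho[t + 1L]
    if (pair < 0) break
    ess_sum <- ess_sum + pair
    t <- t + 2L
  }
  max(1, m * n / (1 + 2 * ess_sum))
}
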