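# Independent oracles used across the suite. These never call the code
# paths they check.

# Exhaustive day-by-day enumeration of the two-stage competing-risk chain
# used by the cohort simulator, with the same within-day ordering (pupae
# update before larvae join). Returns the exact state distribution of one
# individual at the horizon, with blocked pupae folded into pupal deaths
# the way the simulator tallies them.
enumerate_two_stage <- function(lm, ld, pm, pd, ei = 0, horizon = 15L) {
  L <- 1; P <- 0; A <- 0; DL <- 0; DP <- 0; B <- 0
  for (day in seq_len(horizon)) {
    DP <- DP + P * pd
    A <- A + P * pm * (1 - ei)
    B <- B + P * pm * ei
    P <- P * (1 - pd - pm)
    DL <- DL + L * ld
    P <- P + L * lm
    L <- L * (1 - ld - lm)
  }
  list(p_emerge = A, p_ldeath = DL, p_ndeath = DP + B, p_blocked = B,
       p_censored = L + P,
       # completion probabilities of each stage ignoring the horizon
       product_no_horizon = (lm / (lm + ld)) *
         (pm * (1 - ei) / (pm + pd)))
}

# Grid posterior mean of a shared binomial probability under a flat prior
# on the logit (sigma -> 0 limit of the mixed model, one treatment).
grid_posterior_mean_p <- function(s, n, lo = -12, hi = 12, step = 0.002) {
  beta <- seq(lo, hi, by = step)
  ll <- vapply(beta, function(b)
    sum(dbinom(s, n, plogis(b), log = TRUE)), numeric(1))
  w <- exp(ll - max(ll))
  sum(plogis(beta) * w) / sum(w)
}

# Monte-Carlo standard error of a posterior mean given draws and an ESS.
mcse_mean <- function(draws, ess) sd(draws) / sqrt(ess)

# A tiny deterministic treatment posterior built from constant draws.
constant_treatment_posterior <- function(values, n_draws = 100L) {
  m <- matrix(rep(unlist(values), each = n_draws), ncol = n_draws,
              byrow = TRUE)
  rownames(m) <- names(values)
  structure(list(draws = m, treatment_labels = names(values)),
            class = "sit_treatment_posterior")
}

# Small canonical cohort fixture: 2 treatments x 2 replicates.
tiny_cohorts <- function() {
  data.frame(
    cage_id = c("c1", "c2", "s1", "s2"),
    replicate_id = c(1, 2, 1, 2),
    treatment = c("control", "control", "SIT5", "SIT5"),
    eggs_total = c(220, 240, 210, 230),
    eggs_hatched = c(205, 228, 52, 60),
    e_meta = c(205, 228, 52, 60),
    l_death = c(30, 35, 8, 10),
    n_death = c(10, 12, 3, 4),
    n_meta = c(150, 165, 38, 42),
    censored = c(15, 16, 3, 4),
    stringsAsFactors = FALSE)
}
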