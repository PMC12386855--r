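test_that("symmetric treatments get symmetric posteriors", {
  fit <- fit_binomial_mixed(successes = c(30, 32, 30, 32),
                            trials = c(100, 100, 100, 100),
                            treatment = c("A", "A", "B", "B"),
                            n_draws = 4000, chains = 2, warmup = 500,
                            seed = 2)
  Tp <- aggregate_by_treatment(fit)
  means <- rowMeans(Tp$draws)
  se <- apply(Tp$draws, 1, sd)
  expect_lt(abs(means[1] - means[2]), 2 * max(se))
})

test_that("sigma->0 flat-prior posterior matches the grid oracle", {
  s <- c(24, 26, 23, 27)
  n <- rep(100L, 4)
  # a single treatment level is legal for oracle use but warns about rank
  expect_warning(
    fit <- fit_binomial_mixed(s, n, rep("only", 4), n_draws = 8000,
                              chains = 2, warmup = 500, seed = 3,
                              sigma_fixed = 0, prior_sd = Inf),
    "one treatment level")
  p_draws <- fit$draws[1, ]
  ess <- fit$diagnostics$ess[1]
  oracle <- grid_posterior_mean_p(s, n)
  expect_lt(abs(mean(p_draws) - oracle), 2 * mcse_mean(p_draws, ess))
  expect_lt(abs(mean(p_draws) - 0.25), 0.02)
})

test_that("sigma->0 flat-prior posterior matches the IRLS (glm) fit", {
  set.seed(8)
  s <- c(40, 45, 160, 150)
  n <- c(200, 200, 200, 200)
  tr <- c("A", "A", "B", "B")
  fit <- fit_binomial_mixed(s, n, tr, n_draws = 8000, chains = 2,
                            warmup = 500, seed = 4, sigma_fixed = 0,
                            prior_sd = Inf)
  ml <- glm(cbind(s, n - s) ~ 0 + factor(tr), family = binomial())
  p_ml <- plogis(coef(ml))
  Tp <- aggregate_by_treatment(fit)
  for (j in 1:2) {
    draws <- Tp$draws[j, ]
    ess <- fit$diagnostics$ess[j]
    expect_lt(abs(mean(draws) - p_ml[j]),
              2 * mcse_mean(draws, ess) + 5e-4)
  }
})

test_that("the mixed fit tracks the lme4 Laplace fit on overdispersed data", {
  skip_if_not_installed("lme4")
  set.seed(77)
  n_rows <- 12
  tr <- rep(c("A", "B"), each = n_rows / 2)
  u <- rnorm(n_rows, 0, 0.4)
  eta <- ifelse(tr == "A", 0.5, -0.8) + u
  n <- rep(250L, n_rows)
  s <- rbinom(n_rows, n, plogis(eta))
  fit <- fit_binomial_mixed(s, n, tr, n_draws = 6000, chains = 2,
                            warmup = 800, seed = 5)
  g <- lme4::glmer(cbind(s, n - s) ~ 0 + factor(tr) + (1 | obs),
                   data = data.frame(s = s, n = n, tr = tr,
                                     obs = factor(seq_len(n_rows))),
                   family = binomial())
  beta_hat <- lme4::fixef(g)
  beta_post <- rowMeans(fit$beta)
  expect_lt(max(abs(beta_post - beta_hat)), 0.25)
  sigma_hat <- sqrt(unlist(lme4::VarCorr(g))[1])
  expect_lt(abs(mean(fit$sigma) - sigma_hat), 0.3)
})

test_that("separated cohorts stay finite and get flagged", {
  s <- c(0, 0, 0, 0, 210, 215, 220, 208)
  n <- c(57, 60, 55, 58, 228, 230, 235, 220)
  tr <- rep(c("SIT5", "control"), each = 4)
  fit <- fit_binomial_mixed(s, n, tr, n_draws = 4000, chains = 2,
                            warmup = 500, seed = 6)
  expect_true(all(is.finite(fit$beta)))
  expect_true(all(fit$draws > 0 & fit$draws < 1))
  lv <- vapply(fit$flags, `[[`, character(1), "level")
  expect_true("row" %in% lv)
  expect_true("treatment" %in% lv)
})

test_that("detect_separation applies the three-level rules", {
  # exact zero row flags at row level; SIT5 pooled 0 flags at treatment level
  flags <- detect_separation(c(0, 215), c(57, 228), c("SIT5", "control"))
  lv <- vapply(flags, `[[`, character(1), "level")
  fl <- vapply(flags, `[[`, character(1), "flag")
  expect_true(any(lv == "row" & fl == "all-failures"))
  expect_true(any(lv == "treatment" & fl == "near-separation"))
  # 215/228 = 0.943: no row flag, no treatment flag for control
  details <- vapply(flags, `[[`, character(1), "detail")
  expect_false(any(grepl("control", details)))
  # all rows at 50%: silent
  expect_length(detect_separation(c(50, 50), c(100, 100), c("A", "B")), 0L)
})

test_that("aggregation is an order-invariant unweighted row mean", {
  set.seed(10)
  m <- matrix(runif(5 * 200), nrow = 5)
  tr <- c("A", "A", "B", "B", "B")
  agg <- aggregate_by_treatment(m, treatment = tr)
  expect_equal(agg$draws["A", ], colMeans(m[1:2, ]))
  expect_equal(agg$draws["B", ], colMeans(m[3:5, ]))
  perm <- sample(5)
  agg2 <- aggregate_by_treatment(m[perm, ], treatment = tr[perm])
  expect_equal(agg2$draws, agg$draws)
  # constant rows at 0.2/0.4 aggregate to 0.3
  m2 <- rbind(rep(0.2, 50), rep(0.4, 50))
  expect_equal(unname(aggregate_by_treatment(m2, c("X", "X"))$draws[1, ]),
               rep(0.3, 50))
  expect_error(aggregate_by_treatment(m, treatment = tr[1:3]))
})

test_that("summaries are means with equal-tailed quantiles", {
  Tp <- constant_treatment_posterior(list(control = 0.936))
  s <- summarize_posterior(Tp)
  expect_equal(s$mean, 0.936)
  expect_equal(s$ll, 0.936)
  expect_equal(s$ul, 0.936)
  # uniform draws: closed-form 2.5%/97.5% quantiles
  set.seed(11)
  u <- matrix(runif(10000), nrow = 1)
  rownames(u) <- "U"
  Tu <- structure(list(draws = u, treatment_labels = "U"),
                  class = "sit_treatment_posterior")
  su <- summarize_posterior(Tu)
  expect_lt(abs(su$ll - 0.025), 0.01)
  expect_lt(abs(su$ul - 0.975), 0.01)
  # alpha = 1 degenerates to the median
  s1 <- summarize_posterior(Tu, alpha = 1)
  expect_equal(s1$ll, s1$ul)
  expect_equal(s1$ll, median(u), tolerance = 1e-9)
})

test_that("posterior draws never touch 0 or 1 and runs are reproducible", {
  coh <- tiny_cohorts()
  fit1 <- fit_binomial_mixed(coh$eggs_hatched, coh$eggs_total, coh$treatment,
                             n_draws = 2000, chains = 2, warmup = 300,
                             seed = 12)
  fit2 <- fit_binomial_mixed(coh$eggs_hatched, coh$eggs_total, coh$treatment,
                             n_draws = 2000, chains = 2, warmup = 300,
                             seed = 12)
  expect_identical(fit1$draws, fit2$draws)
  expect_true(all(fit1$draws > 0 & fit1$draws < 1))
  expect_equal(ncol(fit1$draws), 2000L)
  expect_error(fit_binomial_mixed(5, 3, "A"), "successes <= trials")
})
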