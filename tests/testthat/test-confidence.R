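test_that("the flat-prior posterior behaves like the normal CDF", {
  expect_equal(bayes_p_correct(0, 1), 0.5)
  expect_equal(bayes_p_correct(0.1 * sqrt(2), 2), pnorm(1))
  e <- seq(-0.3, 0.3, by = 0.05)
  expect_equal(bayes_p_correct(e, 1.3) + bayes_p_correct(-e, 1.3),
               rep(1, length(e)))
  expect_error(bayes_p_correct(0.1, 0), "t")
})

test_that("LDC confidence has the logistic form and its limits", {
  p0 <- ldc_params(alpha = 0, beta = 0)
  expect_equal(ldc_confidence(c(-0.2, 0, 0.4), c(0.5, 1, 2), 1, p0),
               rep(0.5, 3))
  p <- ldc_params(alpha = 17, beta = 0)
  expect_equal(ldc_confidence(0.1, 1, 1, p), 1 / (1 + exp(-1.7)),
               tolerance = 1e-12)
  # complement symmetry at beta = 0
  e <- seq(-0.3, 0.3, by = 0.1)
  expect_equal(ldc_confidence(e, 1.7, 1, p) + ldc_confidence(-e, 1.7, 1, p),
               rep(1, length(e)))
  # saturation for large alpha
  expect_gt(ldc_confidence(0.05, 1, 1, ldc_params(1e4, 0)), 0.999)
  # monotone in beta, and the beta effect shrinks with time
  pb <- function(b, t) ldc_confidence(0.05, t, 1, ldc_params(10, b))
  expect_gt(pb(1, 1), pb(0, 1))
  expect_gt(pb(1, 1) - pb(0, 1), pb(1, 4) - pb(0, 4))
  expect_error(ldc_confidence(0.1, -1, 1, p), "t")
  expect_error(ldc_confidence(0.1, 1, 2, p), "x")
})

test_that("the logistic-probit constant search finds ~1.7", {
  fl <- fit_lambda()
  expect_equal(signif(fl$lambda, 2), 1.7)
  expect_lt(abs(fl$max_dev - 0.0095), 5e-4)
  # argmin property: nearby constants do worse on the same grid
  z <- seq(-10, 10, by = 1e-3)
  dev_at <- function(l) max(abs(pnorm(z) - plogis(l * z)))
  expect_gte(dev_at(fl$lambda - 0.05), fl$max_dev)
  expect_gte(dev_at(fl$lambda + 0.05), fl$max_dev)
  expect_lt(dev_at(1.702), 0.01)
  expect_equal(logistic_probit_approx(0), 0.5)
  expect_error(fit_lambda(interval = c(2, 1)), "interval")
})

test_that("the confidence mapping reduces to the probit approximation", {
  # alpha = lambda / sigma, beta = 0 recovers logistic(lambda * e/(sigma sqrt(t)))
  lam <- 1.702
  sigma <- 0.1
  p <- ldc_params(alpha = lam / sigma, beta = 0)
  grid <- expand.grid(e = seq(-0.3, 0.3, by = 0.03),
                      t = c(0.2, 0.5, 1, 2, 5))
  a <- ldc_confidence(grid$e, grid$t, 1, p)
  b <- logistic_probit_approx(grid$e / (sigma * sqrt(grid$t)), lam)
  expect_lt(max(abs(a - b)), 1e-12)
})

test_that("the drift-mixture readout matches its closed forms", {
  dd <- baseline_ddm()
  expect_equal(bayes_readout_mixture(0, 1, dd), 0.5)
  # single drift level: 1 / (1 + exp(-2 v e / sigma^2))
  dd1 <- ddm_params(v = 0.12, a = 0.1, ter = 0.3)
  e <- seq(-0.25, 0.25, by = 0.05)
  expect_equal(bayes_readout_mixture(e, 0.8, dd1),
               1 / (1 + exp(-2 * 0.12 * e / 0.01)), tolerance = 1e-10)
  # strictly increasing in evidence at fixed time
  p <- bayes_readout_mixture(seq(-0.2, 0.2, by = 0.01), 1.2, dd)
  expect_true(all(diff(p) > 0))
  expect_error(bayes_readout_mixture(0.1, 1, dd, prior = c(1, 1, 1)), "prior")
})

test_that("least squares on the logit scale recovers the mapping", {
  set.seed(11)
  n <- 5000
  u <- runif(n, -0.2, 0.3)
  t <- runif(n, 0.3, 3)
  x <- sample(c(-1, 1), n, replace = TRUE)
  truth <- ldc_params(alpha = 23, beta = -0.4)
  target <- ldc_confidence(x * u, t, x, truth)  # e = x*u so x*e = u
  fit <- fit_ldc_to_posterior(x * u, t, x, target)
  expect_equal(fit$alpha, 23, tolerance = 1e-6)
  expect_equal(fit$beta, -0.4, tolerance = 1e-6)
  # targets from the flat-prior posterior give alpha ~ lambda/sigma, beta ~ 0
  # (on the central range where the logistic-probit approximation is tight;
  # in the far tails logit(pnorm(z)) grows faster than any straight line)
  u2 <- runif(n, -0.15, 0.15)
  t2 <- runif(n, 0.5, 3)
  target2 <- bayes_p_correct(u2, t2)
  fit2 <- fit_ldc_to_posterior(x * u2, t2, x, target2)
  expect_lt(abs(fit2$alpha - 17), 1)
  expect_lt(abs(fit2$beta), 0.1)
  expect_error(fit_ldc_to_posterior(rep(0.1, 5), rep(1, 5), rep(1, 5),
                                    rep(0.6, 5)), "degenerate")
})

test_that("heatmap cells estimate the readout posterior", {
  set.seed(12)
  dd <- ddm_params(v = 0.12, a = 0.1, ter = 0.3)
  tab <- simulate_trials(dd, baseline_ldc(),
                         trial_design(n_per_cell = 60000, n_difficulty = 1))
  hm <- build_heatmap(tab, ter = 0.3, min_count = 200)
  df <- as.data.frame(hm)
  df <- df[!is.na(df$p_correct), ]
  u_mid <- (df$e_low + df$e_high) / 2
  t_mid <- (df$t_low + df$t_high) / 2
  p_theory <- bayes_readout_mixture(u_mid, t_mid, dd)
  se <- sqrt(pmax(p_theory * (1 - p_theory), 1e-4) / df$count)
  # cells agree with the closed-form mixture within binomial error
  expect_gt(mean(abs(df$p_correct - p_theory) < 3 * se + 0.01), 0.95)
  # near-zero evidence is uninformative
  near0 <- abs(u_mid) < 0.01
  if (any(near0)) expect_lt(max(abs(df$p_correct[near0] - 0.5)), 0.15)
  expect_error(build_heatmap(tab[1:10, ], ter = 0.3, min_count = 50), "undefined")
})
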