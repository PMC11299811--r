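test_that("the SSE-based BIC matches arithmetic and penalizes parameters", {
  expect_equal(bic_sse(36, k = 3, n = 36), 3 * log(36))
  expect_equal(bic_sse(0.36, k = 2, n = 36), 2 * log(36) + 36 * log(0.01))
  expect_lt(abs(bic_sse(0.36, 2, 36) - (-158.62)), 0.01)
  expect_lt(bic_sse(0.5, 2, 36), bic_sse(0.5, 3, 36))
  expect_error(bic_sse(0, 2, 36), "SSE")
})

test_that("delta-BIC tables handle single candidates, ties and gaps", {
  m1 <- matrix(c(-10, -12), 2, 1, dimnames = list(NULL, "only"))
  expect_equal(delta_bic_table(m1)$delta_bic, 0)
  m2 <- cbind(a = c(-10, -12), b = c(-10, -12))
  expect_equal(delta_bic_table(m2)$delta_bic, c(0, 0))
  m3 <- cbind(a = c(-10, -12), b = c(-8, NA))
  expect_error(delta_bic_table(m3), "missing")
  m4 <- cbind(good = c(-20, -22), bad = c(-10, -12))
  tab <- delta_bic_table(m4)
  expect_equal(tab$delta_bic[tab$candidate == "good"], 0)
  expect_equal(tab$delta_bic[tab$candidate == "bad"], 10)
})

test_that("confidence contrasts follow their arithmetic definition", {
  tab <- data.frame(
    condition = rep(c("baseline", "plus", "minus"), each = 4),
    accuracy = rep(c(1, 1, 0, 0), 3),
    rating = c(4, 5, 2, 3, 4, 5, 2, 3, 4, 4, 2, 3))
  cc <- confidence_contrast(tab)
  expect_equal(unname(cc["correct"]), 4.5 - 4.0)
  expect_equal(unname(cc["error"]), 0)
  expect_equal(unname(cc["interaction"]), 0.5)
  tab$rating <- 4
  expect_equal(unname(confidence_contrast(tab)), c(0, 0, 0))
  expect_error(confidence_contrast(tab[tab$condition != "minus", ]),
               "missing condition")
})

make_fake_fit <- function(alphas, betas, n_per_cell = 40, seed = 51) {
  tab <- sim_conditions_table(n_per_cell = n_per_cell, alphas = alphas,
                              betas = betas, seed = seed)
  conds <- names(alphas)
  structure(list(
    ddm = baseline_ddm(),
    ldc_by_condition = stats::setNames(lapply(seq_along(conds), function(i) {
      ldc_params(alphas[[i]], betas[[i]])
    }), conds),
    conditions = sort(conds), trials = tab, control = ldc_control()),
    class = "ldc_fit")
}

test_that("bootstrap contrasts are deterministic with order-statistic CIs", {
  fit <- make_fake_fit(alphas = list(minus = 18, baseline = 18, plus = 18),
                       betas = list(minus = -0.8, baseline = 0, plus = 0.8))
  b1 <- bootstrap_contrasts(fit, reps = 4, seed = 3)
  b2 <- bootstrap_contrasts(fit, reps = 4, seed = 3)
  expect_identical(b1$draws, b2$draws)
  b <- bootstrap_contrasts(fit, reps = 2, seed = 4)
  expect_equal(b$ci[1, ], apply(b$draws, 2, min))
  expect_equal(b$ci[2, ], apply(b$draws, 2, max))
  expect_error(bootstrap_contrasts(fit, reps = 1), "reps")
})

test_that("beta-structured models move corrects and errors together", {
  # moderate alpha keeps ratings off the scale ceiling, where a pure beta
  # shift moves corrects and errors by comparable amounts
  fit <- make_fake_fit(alphas = list(minus = 8, baseline = 8, plus = 8),
                       betas = list(minus = -1, baseline = 0, plus = 1),
                       n_per_cell = 150, seed = 52)
  b <- bootstrap_contrasts(fit, reps = 40, seed = 5)
  m <- colMeans(b$draws)
  expect_gt(m["correct"], 0)
  expect_gt(m["error"], 0)
  # the shared beta shift dominates: the accuracy interaction is small
  # relative to the common effect (a pure beta shift still bends slightly
  # where confidence sits closer to the scale ends)
  expect_lt(abs(m["interaction"]), min(m["correct"], m["error"]))
})

test_that("random-effects model selection behaves at its fixed points", {
  # symmetric evidence: uniform frequencies and EPs, elevated omnibus risk
  m <- matrix(-5, nrow = 12, ncol = 3)
  set.seed(61)
  r <- rfx_bms(m)
  expect_equal(unname(r$frequencies), rep(1 / 3, 3), tolerance = 1e-6)
  expect_lt(max(abs(r$ep - 1 / 3)), 0.02)
  expect_gt(r$bor, 0.5)
  expect_equal(sum(r$ep), 1, tolerance = 1e-9)
  # dominance: one candidate better by delta-BIC 20 everywhere
  m2 <- cbind(best = rep(0, 12), worse = rep(-10, 12))  # -BIC/2 scale
  set.seed(62)
  r2 <- rfx_bms(m2)
  expect_gt(r2$ep["best"], 0.99)
  expect_lt(r2$bor, 0.05)
  expect_error(rfx_bms(cbind(c(1, NA), c(0, 0))), "finite")
})

test_that("two-candidate exceedance matches the Beta closed form", {
  set.seed(63)
  m <- cbind(a = rnorm(10, 0.5), b = rnorm(10))
  set.seed(64)
  r <- rfx_bms(m, n_samples = 2e5)
  exact <- stats::pbeta(0.5, r$alpha[2], r$alpha[1])  # P(r_a > r_b)
  expect_lt(abs(r$ep["a"] - exact), 0.01)
})

test_that("adding a constant to all log evidences changes nothing", {
  set.seed(65)
  m <- matrix(rnorm(30), 10, 3)
  set.seed(66)
  r1 <- rfx_bms(m)
  set.seed(66)
  r2 <- rfx_bms(m + 123.4)
  expect_equal(r1$alpha, r2$alpha, tolerance = 1e-8)
  expect_equal(r1$ep, r2$ep)
  expect_equal(r1$bor, r2$bor, tolerance = 1e-6)
})
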