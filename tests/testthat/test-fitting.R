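test_that("quantile summaries match the enumeration oracle and normalize", {
  tab <- data.frame(accuracy = 1, decision_rt = 1:10, rating = 5)
  s <- summarize_trials(tab)
  expect_equal(s$rt_props["correct", ], c(.1, .2, .2, .2, .2, .1))
  expect_equal(s$rt_props["error", ], rep(0, 6))
  expect_true(anyNA(s$rt_cutoffs$error))
  # random table: joint proportions normalize and marginalize to accuracy
  tab2 <- sim_table(n_per_cell = 80)
  s2 <- summarize_trials(tab2)
  expect_equal(sum(s2$rt_props), 1)
  expect_equal(sum(s2$conf_props), 1)
  expect_equal(sum(s2$rt_props["correct", ]), mean(tab2$accuracy))
  expect_equal(sum(s2$conf_props["correct", ]), mean(tab2$accuracy))
  expect_error(summarize_trials(tab2[0, ]), "at least one")
})

test_that("the SSE objective is a symmetric nonnegative distance", {
  s <- summarize_trials(sim_table(n_per_cell = 60))
  expect_equal(sse_summary(s, s), 0)
  s2 <- s
  s2$rt_props[1, 1] <- s2$rt_props[1, 1] + 0.1
  s2$conf_props[2, 3] <- s2$conf_props[2, 3] - 0.1
  expect_equal(sse_summary(s, s2), 0.02)
  expect_equal(sse_summary(s, s2), sse_summary(s2, s))
  bad <- s
  bad$rt_props <- bad$rt_props[, 1:3]
  expect_error(sse_summary(s, bad), "shape")
})

test_that("predictions at the generating parameters reproduce the data", {
  dd <- baseline_ddm()
  lp <- baseline_ldc()
  set.seed(21)
  tab <- simulate_trials(dd, lp, trial_design(n_per_cell = 700))
  obs <- summarize_trials(tab)
  set.seed(22)
  pred <- predict_summary(dd, lp, tab, oversample = 10)
  expect_lt(sse_summary(obs, pred), 0.01)
  # predicted accuracy close to the closed-form absorption mixture
  p_theory <- mean(1 / (1 + exp(-2 * dd$v * dd$a / dd$sigma^2)))
  expect_lt(abs(sum(pred$rt_props["correct", ]) - p_theory), 0.02)
  # determinism given the RNG state
  set.seed(22)
  pred2 <- predict_summary(dd, lp, tab, oversample = 10)
  expect_identical(pred, pred2)
  tab_na <- tab
  tab_na$confidence_rt[1] <- NA
  expect_error(predict_summary(dd, lp, tab_na), "confidence RTs")
})

test_that("the joint fit is deterministic and dominates random candidates", {
  tab <- sim_table(n_per_cell = 70, seed = 31)
  ctl <- fast_control()
  fit <- ldc_fit(tab, control = ctl, seed = 5)
  fit2 <- ldc_fit(tab, control = ctl, seed = 5)
  expect_identical(fit$sse, fit2$sse)
  expect_identical(coef(fit), coef(fit2))
  # optimizer dominance: no random in-bounds candidate beats the optimum
  # on the same deterministic surface
  set.seed(5)
  fd <- ldcm:::build_fit_data(tab, ctl)
  set.seed(99)
  rand_sse <- replicate(100, {
    th <- runif(length(fd$lower), fd$lower, fd$upper)
    ldcm:::eval_objective(th, fd, ctl, 1L)$sse
  })
  expect_true(all(fit$sse <= rand_sse + 1e-4))
  expect_s3_class(fit$ddm, "ddm_params")
  expect_equal(fit$n, 48 * 1)
})

test_that("fitted drifts preserve the difficulty ordering on clean data", {
  tab <- sim_table(n_per_cell = 216, seed = 32)
  fit <- ldc_fit(tab, control = ldc_control(oversample = 5, max_gen = 20),
                 seed = 6)
  v <- coef(fit)[c("v1", "v3")]
  expect_gt(v["v3"], v["v1"])
  expect_lt(abs(coef(fit)["ter"] - 0.3), 0.1)
})

test_that("two-stage fitting shares stage-1 parameters and nests SSEs", {
  tab <- sim_conditions_table(
    n_per_cell = 70,
    alphas = list(minus = 10, baseline = 25, plus = 25),
    betas = list(minus = 0, baseline = 0, plus = 0), seed = 33)
  ts <- two_stage_fit(tab, control = fast_control(), seed = 8)
  ks <- vapply(ts$candidates, `[[`, integer(1), "k")
  expect_equal(ks[c("null", "alpha_free", "beta_free", "full",
                    "bayes_fixed", "bayes_free")],
               c(null = 2L, alpha_free = 4L, beta_free = 4L, full = 6L,
                 bayes_fixed = 0L, bayes_free = 9L))
  expect_true(all(vapply(ts$candidates, `[[`, integer(1), "n") == 36L))
  sses <- vapply(ts$candidates, `[[`, numeric(1), "sse")
  # nesting: the richer structures cannot do worse than null
  expect_lte(sses["full"], sses["null"] + 1e-8)
  expect_lte(sses["alpha_free"], sses["null"] + 1e-8)
  # on alpha-structured data the alpha-free candidate beats null clearly
  expect_lt(sses["alpha_free"], sses["null"])
})

test_that("fit variants count their free parameters correctly", {
  tab <- sim_conditions_table(
    n_per_cell = 40,
    alphas = list(baseline = 18, minus = 18, plus = 18),
    betas = list(baseline = 0, minus = -0.5, plus = 0.5), seed = 34)
  ctl <- fast_control(max_gen = 3)
  f_null <- ldc_fit(tab, variant = "null", control = ctl, seed = 9)
  expect_equal(f_null$k, 2 + 3 + 2)
  ab <- t(vapply(f_null$ldc_by_condition, function(p) c(p$alpha, p$beta),
                 numeric(2)))
  expect_equal(ab[1, ], ab[2, ])  # shared confidence parameters
  f_bf <- ldc_fit(tab, variant = "beta_free", control = ctl, seed = 9)
  expect_equal(f_bf$k, 2 + 3 + 4)
  al <- vapply(f_bf$ldc_by_condition, function(p) p$alpha, numeric(1))
  expect_true(all(al == al[1]))  # alpha shared, beta free
})
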