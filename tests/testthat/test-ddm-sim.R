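test_that("parameter containers validate their invariants", {
  expect_error(ddm_params(v = 0.1, a = -1, ter = 0.3), "bound")
  expect_error(ddm_params(v = 0.1, a = 0.1, ter = -0.1), "non-decision")
  expect_error(ddm_params(v = 0.1, a = 0.1, ter = 0.3, z = 1), "starting")
  expect_error(ddm_params(v = Inf, a = 0.1, ter = 0.3))
  expect_error(ldc_params(alpha = -1), "alpha")
  expect_error(ldc_params(alpha = 1, gamma = 0), "gamma")
  expect_s3_class(ddm_params(v = c(0.1, 0.2), a = 0.1, ter = 0), "ddm_params")
})

test_that("symmetric walks split choices evenly and drift breaks the tie", {
  set.seed(101)
  dd0 <- ddm_params(v = 0, a = 0.1, ter = 0.3)
  tab <- simulate_trials(dd0, baseline_ldc(),
                         trial_design(n_per_cell = 4000, n_difficulty = 1))
  expect_lt(abs(mean(tab$accuracy) - 0.5), 0.025)
  # positive drift: accuracy near the two-barrier absorption probability
  set.seed(102)
  w <- ldcm:::cpp_walk_trials(rep(0.1, 50000), 0.1, 0, 0.1, 0.001, 20)
  p_theory <- 1 / (1 + exp(-2 * 0.1 * 0.1 / 0.01))
  # tolerance covers the ~0.004 discrete-step overshoot bias plus MC noise
  expect_lt(abs(mean(w[, 1] == 1) - p_theory), 0.01)
})

test_that("halving the bound speeds decisions and lowers accuracy", {
  set.seed(103)
  wa <- ldcm:::cpp_walk_trials(rep(0.1, 20000), 0.1, 0, 0.1, 0.001, 20)
  wb <- ldcm:::cpp_walk_trials(rep(0.1, 20000), 0.05, 0, 0.1, 0.001, 20)
  expect_lt(mean(wb[, 2]), mean(wa[, 2]))
  expect_lt(mean(wb[, 1] == 1), mean(wa[, 1] == 1))
})

test_that("scaling v, a, sigma by a common factor preserves accuracy", {
  set.seed(104)
  w1 <- ldcm:::cpp_walk_trials(rep(0.1, 30000), 0.1, 0, 0.1, 0.001, 20)
  w2 <- ldcm:::cpp_walk_trials(rep(0.2, 30000), 0.2, 0, 0.2, 0.001, 20)
  p1 <- mean(w1[, 1] == 1)
  p2 <- mean(w2[, 1] == 1)
  se <- sqrt(2 * p1 * (1 - p1) / 30000)
  expect_lt(abs(p1 - p2), 4 * se)
})

test_that("trial records respect timing and threshold invariants", {
  tab <- sim_table(n_per_cell = 100)
  expect_true(all(tab$decision_rt > 0.3))
  expect_true(all(abs(tab$evidence_at_decision) == 0.1))
  expect_identical(tab$accuracy, as.integer(tab$choice == tab$stim_sign))
  expect_true(all(tab$rating %in% 1:6))
})

test_that("post-decision accumulation matches the Wiener mean and identity", {
  dd <- baseline_ddm()
  rec <- data.frame(evidence_at_decision = rep(0.1, 50000),
                    evidence_total = rep(0.1, 50000))
  r0 <- post_decision_accumulate(rec, 0, 0.2, dd)
  expect_identical(r0$evidence_total, rec$evidence_at_decision)
  set.seed(105)
  r1 <- post_decision_accumulate(rec, 0.8, 0.2, dd)
  se <- 0.1 * sqrt(0.8) / sqrt(50000)
  expect_lt(abs(mean(r1$evidence_total) - (0.1 + 0.2 * 0.8)), 4 * se)
  # disconfirming drift pulls evidence below the bound on average
  set.seed(106)
  r2 <- post_decision_accumulate(rec, 0.8, -0.2, dd)
  expect_lt(mean(r2$evidence_total), 0.1)
  expect_error(post_decision_accumulate(rec, -1, 0.2, dd), ">= 0")
})

test_that("the dataset generator is seed-reproducible with full schema", {
  t1 <- sim_table(n_per_cell = 216)
  t2 <- sim_table(n_per_cell = 216)
  expect_identical(t1, t2)
  expect_equal(nrow(t1), 648)
  expect_true(all(c("participant", "condition", "difficulty", "stim_sign",
                    "choice", "accuracy", "decision_rt", "confidence_rt",
                    "rating") %in% names(t1)))
  expect_error(simulate_trials(baseline_ddm(), baseline_ldc(),
                               data.frame(condition = character(0),
                                          difficulty = integer(0),
                                          n = integer(0))),
               "empty design")
})

test_that("ratings track accuracy under the generative model", {
  tab <- sim_table(n_per_cell = 3400, seed = 7)  # ~10k trials
  expect_gt(mean(tab$rating[tab$accuracy == 1]),
            mean(tab$rating[tab$accuracy == 0]))
})

test_that("non-terminating walks raise the degenerate-parameter guard", {
  dd <- ddm_params(v = 0, a = 1, ter = 0.3, max_t = 2)
  set.seed(107)
  expect_error(simulate_trial(dd, 1, 1), "did not terminate")
})
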