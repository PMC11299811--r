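test_that("feedback specs validate and expose the named presets", {
  expect_error(feedback_spec(-0.1, 0.2), "pilot_bound")
  expect_error(feedback_spec(0.1, -0.2), "pilot_drift")
  ps <- feedback_presets()
  expect_named(ps, c("baseline", "alpha_minus", "alpha_plus", "beta_minus",
                     "beta_plus"))
  expect_equal(ps$baseline$fb$alpha, 18)
  expect_equal(ps$alpha_minus$fb$alpha, 9)
  expect_equal(ps$alpha_plus$fb$alpha, 36)
  expect_equal(ps$beta_minus$fb$beta, -1)
  expect_equal(ps$beta_plus$fb$beta, 1)
})

test_that("feedback is deterministic given the seed and monotone in beta", {
  ps <- feedback_presets()
  set.seed(81)
  f1 <- generate_feedback(0.8, 0.5, 1, ps$baseline)
  set.seed(81)
  f2 <- generate_feedback(0.8, 0.5, 1, ps$baseline)
  expect_identical(f1, f2)
  set.seed(81)
  f3 <- generate_feedback(0.8, 0.5, 1, ps$beta_plus)
  expect_gt(f3, f1)  # same walk, higher beta
  expect_error(generate_feedback(0, 0.5, 1, ps$baseline), "durations")
  expect_error(generate_feedback(0.8, -0.5, 1, ps$baseline), "durations")
})

test_that("alpha moves feedback on corrects only; beta moves both", {
  ps <- feedback_presets()
  n <- 20000
  set.seed(82)
  drt <- runif(n, 0.4, 1.2)
  crt <- rlnorm(n, log(0.55), 0.4)
  acc <- rbinom(n, 1, 0.8)
  fb <- function(spec, seed) {
    set.seed(seed)
    generate_feedback(drt, crt, acc, spec)
  }
  f9 <- fb(ps$alpha_minus, 83)
  f36 <- fb(ps$alpha_plus, 83)
  d_cor <- mean(f36[acc == 1]) - mean(f9[acc == 1])
  d_err <- mean(f36[acc == 0]) - mean(f9[acc == 0])
  expect_gt(d_cor, 0.1)
  expect_lt(abs(d_err), d_cor / 3)
  fm <- fb(ps$beta_minus, 83)
  fp <- fb(ps$beta_plus, 83)
  expect_gt(mean(fp[acc == 1]) - mean(fm[acc == 1]), 0.05)
  expect_gt(mean(fp[acc == 0]) - mean(fm[acc == 0]), 0.05)
})

test_that("training phases are closed-loop, bounded and calibrated", {
  dd <- ddm_params(v = 0.15, a = 0.1, ter = 0.3)
  spec <- feedback_spec(0.1, 0.15)  # pilot matches the generative process
  set.seed(84)
  tr <- simulate_training_phase(dd, baseline_ldc(), spec, n_trials = 120)
  expect_equal(nrow(tr), 120)
  expect_true(all(tr$feedback > 0 & tr$feedback < 1))
  set.seed(85)
  big <- simulate_training_phase(dd, baseline_ldc(), spec, n_trials = 10000)
  # the response-time convention (decision RT incl. non-decision time) makes
  # baseline feedback slightly conservative relative to realized accuracy
  expect_lt(abs(mean(big$feedback) - mean(big$accuracy)), 0.08)
})
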