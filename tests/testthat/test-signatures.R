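sig_tab <- sim_table(n_per_cell = 3400, seed = 71)  # ~10k baseline trials
sigs <- signature_curves(sig_tab)

test_that("confidence predicts accuracy on baseline simulations", {
  d <- sigs[sigs$curve == "conf_by_accuracy", ]
  expect_gt(d$mean[d$group == "correct"], d$mean[d$group == "error"])
})

test_that("the folded X-pattern emerges across evidence strengths", {
  d <- sigs[sigs$curve == "folded_x", ]
  cor_means <- d$mean[d$group == "correct"][order(d$x[d$group == "correct"])]
  err_means <- d$mean[d$group == "error"][order(d$x[d$group == "error"])]
  expect_true(all(diff(cor_means) > 0))
  expect_true(all(diff(err_means) < 0))
})

test_that("high-confidence halves are more accurate at every strength", {
  d <- sigs[sigs$curve == "conditional_accuracy", ]
  for (x in unique(d$x)) {
    hi <- d$mean[d$x == x & d$group == "high"]
    lo <- d$mean[d$x == x & d$group == "low"]
    n <- min(d$n[d$x == x])
    expect_gt(hi, lo - 3 * sqrt(0.25 / n))
  }
})

test_that("confidence decreases over successive RT bins", {
  d <- sigs[sigs$curve == "conf_by_rt_bin", ]
  expect_true(all(diff(d$mean[order(d$x)]) < 0))
})

test_that("driftless single-difficulty data collapse the strength axis", {
  set.seed(72)
  dd0 <- ddm_params(v = 0, a = 0.1, ter = 0.3)
  tab <- simulate_trials(dd0, baseline_ldc(),
                         trial_design(n_per_cell = 2000, n_difficulty = 1))
  s <- signature_curves(tab)
  fx <- s[s$curve == "folded_x", ]
  expect_equal(length(unique(fx$x)), 1)
})

test_that("empty cells are flagged rather than raising", {
  tab <- sig_tab[sig_tab$accuracy == 1, ][1:500, ]
  s <- signature_curves(tab)
  d <- s[s$curve == "conf_by_accuracy" & s$group == "error", ]
  expect_true(is.na(d$mean))
  expect_equal(d$n, 0)
})
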