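# Shared fixtures: small baseline parameter sets and a cached simulated table.

baseline_ddm <- function(v = c(0.05, 0.1, 0.2), a = 0.1, ter = 0.3) {
  ddm_params(v = v, a = a, ter = ter)
}

baseline_ldc <- function(alpha = 18, beta = 0) ldc_params(alpha, beta)

sim_table <- function(n_per_cell = 216, alpha = 18, beta = 0, seed = 42,
                      ddm = baseline_ddm(), conditions = "baseline") {
  set.seed(seed)
  simulate_trials(ddm, ldc_params(alpha, beta),
                  trial_design(conditions, n_per_cell = n_per_cell,
                               n_difficulty = length(ddm$v)))
}

# quick 3-condition table with condition-specific confidence parameters
sim_conditions_table <- function(n_per_cell, alphas, betas, seed = 42,
                                 ddm = baseline_ddm()) {
  set.seed(seed)
  conds <- names(alphas)
  ldcs <- stats::setNames(lapply(seq_along(alphas), function(i) {
    ldc_params(alphas[[i]], betas[[i]])
  }), conds)
  simulate_trials(ddm, ldcs,
                  trial_design(conds, n_per_cell = n_per_cell,
                               n_difficulty = length(ddm$v)))
}

fast_control <- function(...) {
  args <- utils::modifyList(list(oversample = 3, max_gen = 10), list(...))
  do.call(ldc_control, args)
}
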