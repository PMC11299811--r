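#' Specification of model-generated feedback
#'
#' Holds the quantities the online feedback algorithm needs: the average
#' decision bound and drift magnitude from a pilot session (the assumed
#' evidence-accumulation process of the current trial) and the fixed
#' `(alpha, beta)` pairing used to turn total evidence and total time into a
#' feedback value.
#'
#' @param pilot_bound Average pilot decision threshold (> 0, evidence units).
#' @param pilot_drift Average pilot drift magnitude (>= 0, evidence units/s).
#' @param alpha,beta Confidence-mapping parameters generating the feedback.
#' @param condition Condition label.
#' @param gamma Time exponent of the mapping.
#'
#' @return An object of class `"feedback_spec"`.
#' @export
feedback_spec <- function(pilot_bound, pilot_drift, alpha = 18, beta = 0,
                          condition = "baseline", gamma = 0.5) {
  if (!is.finite(pilot_bound) || pilot_bound <= 0) stop("`pilot_bound` must be > 0")
  if (!is.finite(pilot_drift) || pilot_drift < 0) stop("`pilot_drift` must be >= 0")
  structure(list(pilot_bound = pilot_bound, pilot_drift = pilot_drift,
                 fb = ldc_params(alpha, beta, gamma = gamma),
                 condition = condition),
            class = "feedback_spec")
}

#' @export
print.feedback_spec <- function(x, ...) {
  cat(sprintf("Feedback spec '%s': alpha = %g, beta = %g (pilot a = %g, v = %g)\n",
              x$condition, x$fb$alpha, x$fb$beta, x$pilot_bound, x$pilot_drift))
  invisible(x)
}

#' Named feedback presets for the five feedback conditions
#'
#' The baseline condition uses the near-optimal mapping (`alpha = 18`,
#' `beta = 0`); the alpha-minus/alpha-plus conditions halve/double `alpha`
#' (9 and 36); the beta-minus/beta-plus conditions shift `beta` to -1 and 1.
#'
#' @param pilot_bound,pilot_drift Pilot averages shared by all presets.
#' @return Named list of [feedback_spec()] objects.
#' @export
feedback_presets <- function(pilot_bound = 0.1, pilot_drift = 0.15) {
  list(
    baseline = feedback_spec(pilot_bound, pilot_drift, 18, 0, "baseline"),
    alpha_minus = feedback_spec(pilot_bound, pilot_drift, 9, 0, "alpha_minus"),
    alpha_plus = feedback_spec(pilot_bound, pilot_drift, 36, 0, "alpha_plus"),
    beta_minus = feedback_spec(pilot_bound, pilot_drift, 18, -1, "beta_minus"),
    beta_plus = feedback_spec(pilot_bound, pilot_drift, 18, 1, "beta_plus")
  )
}

#' Generate model-based probabilistic feedback for observed trials
#'
#' Implements the online feedback algorithm: evidence at the decision is set
#' to the pilot bound in the frame of the chosen option; a post-decisional
#' random walk runs for the observed confidence RT with drift
#' `+pilot_drift` on correct trials and `-pilot_drift` on errors; feedback
#' is the LDC confidence of the resulting total evidence at the total time
#' (decision RT plus confidence RT). Uses R's RNG.
#'
#' @param decision_rt,confidence_rt Observed RTs in seconds (> 0).
#'   Vectorized.
#' @param accuracy 0/1 per trial.
#' @param spec A [feedback_spec()].
#' @param sigma,tau Noise and step of the post-decisional walk.
#'
#' @return Feedback values in (0, 1).
#' @export
generate_feedback <- function(decision_rt, confidence_rt, accuracy, spec,
                              sigma = 0.1, tau = 0.001) {
  if (!inherits(spec, "feedback_spec")) stop("`spec` must be a feedback_spec")
  n <- max(length(decision_rt), length(confidence_rt), length(accuracy))
  decision_rt <- rep_len(decision_rt, n)
  confidence_rt <- rep_len(confidence_rt, n)
  accuracy <- rep_len(accuracy, n)
  if (any(decision_rt <= 0) || any(confidence_rt <= 0)) {
    stop("durations must be > 0")
  }
  drift <- ifelse(accuracy == 1, spec$pilot_drift, -spec$pilot_drift)
  e_total <- cpp_post_walk(rep(spec$pilot_bound, n), drift, confidence_rt,
                           sigma, tau)
  # total time is decision RT + confidence RT, mirroring the experiment
  ldc_confidence(e_total, decision_rt + confidence_rt, 1, spec$fb)
}

#' Simulate a closed-loop training phase with model-generated feedback
#'
#' Simulates a participant's decisions from their DDM parameters, their
#' confidence reports from their LDC parameters, and the trial-by-trial
#' feedback from the (possibly manipulated) feedback specification.
#'
#' @param ddm Participant [ddm_params()].
#' @param ldc Participant [ldc_params()] (the reported confidence).
#' @param spec A [feedback_spec()] generating the feedback.
#' @param n_trials Number of training trials (default 120).
#' @param conf_rt Confidence-RT source as in [simulate_trials()].
#' @param condition Condition label on the rows (defaults to the spec's).
#'
#' @return A trial table with an added `feedback` column.
#' @export
simulate_training_phase <- function(ddm, ldc, spec, n_trials = 120,
                                    conf_rt = NULL, condition = NULL) {
  if (n_trials < 1) stop("`n_trials` must be >= 1")
  ddm <- as_ddm_params(ddm)
  nlev <- length(ddm$v)
  per <- ceiling(n_trials / nlev)
  design <- trial_design(condition %||% spec$condition, n_per_cell = per,
                         n_difficulty = nlev)
  tab <- simulate_trials(ddm, ldc, design, conf_rt = conf_rt)
  tab <- tab[seq_len(n_trials), ]
  tab$feedback <- generate_feedback(tab$decision_rt, tab$confidence_rt,
                                    tab$accuracy, spec,
                                    sigma = ddm$sigma, tau = ddm$tau)
  tab
}
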