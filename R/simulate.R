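#' Map continuous confidence to a 6-point rating
#'
#' `[0, 1]` is split into 6 equal-width, right-closed intervals; confidence
#' exactly at an internal edge falls in the lower bin.
#'
#' @param conf Confidence in `[0, 1]`. Vectorized.
#' @return Integer ratings in 1..6.
#' @export
rating_from_conf <- function(conf) {
  if (any(conf < 0 | conf > 1, na.rm = TRUE)) stop("confidence must be in [0, 1]")
  pmin(pmax(as.integer(ceiling(conf * 6)), 1L), 6L)
}

#' Simulate a single decision trial
#'
#' Runs one bounded random walk of the discrete drift-diffusion
#' approximation: evidence changes by `v * tau + sigma * sqrt(tau) * N(0, 1)`
#' per step from `z * a` until it reaches `+a` or `-a`. The evidence at the
#' decision is recorded as exactly the signed bound (overshoot is clipped).
#' Uses R's RNG; seed with [set.seed()] for reproducibility.
#'
#' @param ddm A [ddm_params()] object.
#' @param difficulty Index into `ddm$v`.
#' @param stim_sign True stimulus direction, `-1` or `1`.
#' @param condition Condition label stored on the record.
#'
#' @return A one-row data frame (a trial record) with columns `condition`,
#'   `difficulty`, `stim_sign`, `choice`, `accuracy`, `decision_rt`,
#'   `evidence_at_decision`, `evidence_total`.
#' @export
#' @examples
#' set.seed(1)
#' simulate_trial(ddm_params(v = 0.1, a = 0.1, ter = 0.3), 1, 1)
simulate_trial <- function(ddm, difficulty, stim_sign, condition = "baseline") {
  ddm <- as_ddm_params(ddm)
  if (difficulty < 1 || difficulty > length(ddm$v)) stop("invalid difficulty index")
  if (!stim_sign %in% c(-1, 1)) stop("`stim_sign` must be -1 or 1")
  w <- cpp_walk_trials(stim_sign * ddm$v[difficulty], ddm$a, ddm$z, ddm$sigma,
                       ddm$tau, ddm$max_t)
  if (is.na(w[1, 1])) {
    stop(sprintf("walk did not terminate within max_t = %g s (degenerate parameters)",
                 ddm$max_t))
  }
  data.frame(condition = condition, difficulty = as.integer(difficulty),
             stim_sign = as.integer(stim_sign), choice = as.integer(w[1, 1]),
             accuracy = as.integer(w[1, 1] == stim_sign),
             decision_rt = w[1, 2] + ddm$ter,
             evidence_at_decision = w[1, 3], evidence_total = w[1, 3])
}

#' Post-decisional evidence accumulation
#'
#' Continues accumulation after the decision as an unbounded random walk of
#' the given signed drift for `duration` seconds, starting from the evidence
#' at the decision. A duration of 0 is the identity.
#'
#' @param record A trial record from [simulate_trial()] (or any data frame
#'   with an `evidence_at_decision` column).
#' @param duration Post-decisional duration in seconds, `>= 0`. Recycled.
#' @param drift_signed Signed drift of the post-decisional walk (evidence
#'   units per second). Recycled.
#' @param ddm A [ddm_params()] object supplying `sigma` and `tau`.
#'
#' @return The record with `evidence_total` updated.
#' @export
post_decision_accumulate <- function(record, duration, drift_signed, ddm) {
  ddm <- as_ddm_params(ddm)
  if (is.null(record$evidence_at_decision)) {
    stop("`record` lacks an `evidence_at_decision` column")
  }
  n <- nrow(record)
  duration <- rep_len(duration, n)
  drift_signed <- rep_len(drift_signed, n)
  if (any(duration < 0)) stop("`duration` must be >= 0")
  record$evidence_total <- cpp_post_walk(record$evidence_at_decision,
                                         drift_signed, duration,
                                         ddm$sigma, ddm$tau)
  record
}

#' Trial layout for the synthetic generator
#'
#' @param conditions Character vector of condition labels.
#' @param n_per_cell Trials per (condition, difficulty) cell.
#' @param n_difficulty Number of difficulty levels.
#'
#' @return A data frame with columns `condition`, `difficulty`, `n`.
#' @export
#' @examples
#' trial_design("baseline", n_per_cell = 216, n_difficulty = 3)  # 648 trials
trial_design <- function(conditions = "baseline", n_per_cell = 216,
                         n_difficulty = 3) {
  if (length(conditions) < 1 || n_per_cell < 1 || n_difficulty < 1) {
    stop("empty design")
  }
  g <- expand.grid(difficulty = seq_len(n_difficulty), condition = conditions,
                   stringsAsFactors = FALSE)
  data.frame(condition = g$condition, difficulty = as.integer(g$difficulty),
             n = as.integer(n_per_cell))
}

#' Simulate a full trial table from the generative LDC model
#'
#' Composes the bounded decision walk, post-decisional accumulation for a
#' confidence-RT duration, and the LDC confidence mapping binned into the
#' 6-point rating scale. Post-decisional drift follows the true stimulus
#' drift (errors accumulate disconfirming evidence). Uses R's RNG.
#'
#' @param ddm A [ddm_params()] object.
#' @param ldc An [ldc_params()] object, or a named list of them (one per
#'   condition label in `design`).
#' @param design A data frame from [trial_design()] (columns `condition`,
#'   `difficulty`, `n`).
#' @param conf_rt Source of confidence RTs: a function of `n` returning
#'   durations in seconds, or a numeric vector sampled with replacement.
#'   Default: log-normal with median 0.55 s and sdlog 0.4, a realistic
#'   confidence-report latency.
#' @param participant Participant id stored on the rows.
#' @param time Which elapsed time enters the confidence mapping:
#'   `"accumulation"` (decision time net of `ter`, plus the post-decisional
#'   duration) or `"response"` (decision RT plus confidence RT).
#'
#' @return A trial table: one row per trial with columns `participant`,
#'   `condition`, `difficulty`, `stim_sign`, `choice`, `accuracy`,
#'   `decision_rt`, `confidence_rt`, `rating`, plus the latent columns
#'   `evidence_at_decision`, `evidence_total` and the continuous model
#'   confidence `conf`.
#' @export
#' @examples
#' set.seed(1)
#' dd <- ddm_params(v = c(0.05, 0.1, 0.2), a = 0.1, ter = 0.3)
#' tab <- simulate_trials(dd, ldc_params(18, 0), trial_design(n_per_cell = 20))
#' nrow(tab)  # 60
simulate_trials <- function(ddm, ldc, design, conf_rt = NULL,
                            participant = 1L,
                            time = c("accumulation", "response")) {
  ddm <- as_ddm_params(ddm)
  time <- match.arg(time)
  if (is.null(design) || nrow(design) == 0 || sum(design$n) == 0) {
    stop("empty design")
  }
  if (inherits(ldc, "ldc_params")) {
    ldc <- stats::setNames(rep(list(ldc), length(unique(design$condition))),
                           unique(design$condition))
  }
  if (is.null(conf_rt)) {
    conf_rt <- function(n) stats::rlnorm(n, meanlog = log(0.55), sdlog = 0.4)
  }
  cond <- rep(design$condition, design$n)
  diff <- rep(design$difficulty, design$n)
  if (any(diff < 1 | diff > length(ddm$v))) stop("invalid difficulty index in design")
  n <- length(cond)
  # balanced stimulus signs within each cell
  stim <- unlist(lapply(design$n, function(k) {
    s <- rep(c(1, -1), length.out = k)
    sample(s)
  }), use.names = FALSE)
  v_signed <- stim * ddm$v[diff]
  w <- cpp_walk_trials(v_signed, ddm$a, ddm$z, ddm$sigma, ddm$tau, ddm$max_t)
  if (anyNA(w[, 1])) {
    stop(sprintf("%d walk(s) did not terminate within max_t = %g s",
                 sum(is.na(w[, 1])), ddm$max_t))
  }
  dur <- if (is.function(conf_rt)) conf_rt(n) else
    sample(as.numeric(conf_rt), n, replace = TRUE)
  if (any(dur < 0)) stop("confidence RTs must be >= 0")
  e_total <- cpp_post_walk(w[, 3], v_signed, dur, ddm$sigma, ddm$tau)
  dt <- w[, 2]
  t_conf <- if (time == "accumulation") dt + dur else dt + ddm$ter + dur
  choice <- w[, 1]
  conf <- numeric(n)
  for (cn in unique(cond)) {
    idx <- cond == cn
    p <- ldc[[as.character(cn)]]
    if (is.null(p)) stop(sprintf("no LDC parameters supplied for condition '%s'", cn))
    conf[idx] <- ldc_confidence(e_total[idx], t_conf[idx], choice[idx], p)
  }
  data.frame(participant = participant, condition = cond,
             difficulty = as.integer(diff), stim_sign = as.integer(stim),
             choice = as.integer(choice),
             accuracy = as.integer(choice == stim), decision_rt = dt + ddm$ter,
             confidence_rt = dur, rating = rating_from_conf(conf),
             evidence_at_decision = w[, 3], evidence_total = e_total,
             conf = conf)
}
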