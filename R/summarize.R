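#' Quantile/bin summary of a trial table
#'
#' Computes the joint proportions that enter the fitting objective: trials
#' are grouped by the .1/.3/.5/.7/.9 RT quantiles within each accuracy class
#' (6 groups per class) and by the 6 confidence-rating levels within each
#' accuracy class. Proportions are joint over (accuracy x group), so they sum
#' to 1 over all 12 cells and the correct-side mass equals the empirical
#' accuracy. An accuracy class with no trials contributes zero proportions
#' and undefined (NA) cutoffs.
#'
#' @param trials Trial table with columns `accuracy`, `decision_rt`,
#'   `rating` (ratings in 1..6).
#' @param cutoffs Optional externally supplied RT cutoffs: a list with
#'   elements `correct` and `error`, each 5 increasing values (or NA).
#'
#' @return An object of class `"trial_summary"`: `rt_props` and `conf_props`
#'   (2 x 6 matrices, rows `error`/`correct`), `rt_cutoffs`, `n_trials`.
#' @export
#' @examples
#' tab <- data.frame(accuracy = 1, decision_rt = 1:10, rating = 5)
#' summarize_trials(tab)$rt_props["correct", ]  # .1 .2 .2 .2 .2 .1
summarize_trials <- function(trials, cutoffs = NULL) {
  if (nrow(trials) < 1) stop("need at least one trial")
  if (!all(trials$rating %in% 1:6)) stop("ratings must be integers in 1..6")
  n <- nrow(trials)
  probs <- c(.1, .3, .5, .7, .9)
  classes <- list(error = trials$accuracy == 0, correct = trials$accuracy == 1)
  rt_props <- matrix(0, 2, 6, dimnames = list(c("error", "correct"), NULL))
  conf_props <- matrix(0, 2, 6, dimnames = list(c("error", "correct"), NULL))
  rt_cutoffs <- list(error = rep(NA_real_, 5), correct = rep(NA_real_, 5))
  for (cl in names(classes)) {
    idx <- classes[[cl]]
    if (!any(idx)) next
    cuts <- if (!is.null(cutoffs)) cutoffs[[cl]] else
      stats::quantile(trials$decision_rt[idx], probs, names = FALSE)
    if (!anyNA(cuts)) {
      rt_cutoffs[[cl]] <- cuts
      grp <- findInterval(trials$decision_rt[idx], cuts, left.open = TRUE) + 1L
      rt_props[cl, ] <- tabulate(grp, 6) / n
    }
    conf_props[cl, ] <- tabulate(trials$rating[idx], 6) / n
  }
  structure(list(rt_props = rt_props, conf_props = conf_props,
                 rt_cutoffs = rt_cutoffs, n_trials = n),
            class = "trial_summary")
}

#' @export
print.trial_summary <- function(x, ...) {
  cat(sprintf("Trial summary (%d trials, accuracy %.3f)\n", x$n_trials,
              sum(x$rt_props["correct", ])))
  cat("RT group proportions (joint):\n")
  print(round(x$rt_props, 3))
  cat("Confidence level proportions (joint):\n")
  print(round(x$conf_props, 3))
  invisible(x)
}

#' Sum of squared errors between two trial summaries
#'
#' The fitting objective: squared differences of the 12 RT-group joint
#' proportions plus the 12 confidence-level joint proportions.
#'
#' @param observed,predicted `"trial_summary"` objects of matching shape.
#' @return A nonnegative scalar.
#' @export
sse_summary <- function(observed, predicted) {
  if (!inherits(observed, "trial_summary") ||
      !inherits(predicted, "trial_summary")) {
    stop("arguments must be `trial_summary` objects")
  }
  if (!identical(dim(observed$rt_props), dim(predicted$rt_props)) ||
      !identical(dim(observed$conf_props), dim(predicted$conf_props))) {
    stop("summary shapes do not match")
  }
  sum((observed$rt_props - predicted$rt_props)^2) +
    sum((observed$conf_props - predicted$conf_props)^2)
}

# Flatten a trial_summary into the 12-vectors used by the C++ objective
# (corrects groups 1..6 then errors 1..6).
flatten_summary <- function(s) {
  list(rt = c(s$rt_props["correct", ], s$rt_props["error", ]),
       cj = c(s$conf_props["correct", ], s$conf_props["error", ]),
       cut_cor = s$rt_cutoffs$correct, cut_err = s$rt_cutoffs$error)
}

#' Model-predicted trial summary
#'
#' Simulates `oversample` times the observed number of trials at the given
#' parameters, matching the observed difficulty mix, with post-decisional
#' durations drawn from the observed confidence RTs such that each empirical
#' value is used exactly `oversample` times (sampling without replacement).
#' Model confidence is binned into 6 equal-width bins and proportions are
#' computed against the observed RT cutoffs. Uses R's RNG for the noise pool
#' and the duration assignment; seed with [set.seed()].
#'
#' @param ddm A [ddm_params()] object.
#' @param ldc An [ldc_params()] object.
#' @param observed Observed trial table (columns `difficulty`, `accuracy`,
#'   `decision_rt`, `confidence_rt`, `rating`).
#' @param oversample Simulated trials per observed trial (default 20).
#' @param time Elapsed-time convention for the confidence mapping, as in
#'   [simulate_trials()].
#' @param pool_size Size of the pre-drawn noise pool.
#'
#' @return A `"trial_summary"` of the predicted proportions.
#' @export
predict_summary <- function(ddm, ldc, observed, oversample = 20,
                            time = c("accumulation", "response"),
                            pool_size = 2^22) {
  ddm <- as_ddm_params(ddm)
  ldc <- as_ldc_params(ldc)
  time <- match.arg(time)
  if (oversample < 1) stop("`oversample` must be >= 1")
  if (is.null(observed$confidence_rt) || anyNA(observed$confidence_rt)) {
    stop("observed table lacks confidence RTs")
  }
  obs_sum <- summarize_trials(observed)
  n_obs <- nrow(observed)
  sim_diff <- rep(observed$difficulty, times = oversample)
  dur <- sample(rep(observed$confidence_rt, times = oversample))
  pool <- cpp_make_pool(stats::rnorm(pool_size))
  theta <- c(ddm$ter, ddm$a, ddm$v)
  feats <- cpp_sim_features(theta, as.integer(sim_diff) - 1L, dur, pool,
                            1000003L, ddm$z, ddm$sigma, ddm$tau, ddm$max_t,
                            TRUE)
  if (anyNA(feats[, 1])) {
    stop(sprintf("simulated walk(s) did not terminate within max_t = %g s",
                 ddm$max_t))
  }
  acc <- as.integer(feats[, 1])
  rt <- feats[, 2]
  t_conf <- if (time == "accumulation") feats[, 3] else feats[, 4]
  n_sim <- length(acc)
  rt_props <- matrix(0, 2, 6, dimnames = list(c("error", "correct"), NULL))
  for (cl in c("error", "correct")) {
    sel <- if (cl == "correct") acc == 1L else acc == 0L
    if (!any(sel)) next
    cuts <- obs_sum$rt_cutoffs[[cl]]
    if (anyNA(cuts)) {
      # observed class empty: spread this class's mass equally over groups
      rt_props[cl, ] <- sum(sel) / n_sim / 6
    } else {
      grp <- findInterval(rt[sel], cuts, left.open = TRUE) + 1L
      rt_props[cl, ] <- tabulate(grp, 6) / n_sim
    }
  }
  conf <- ldc_confidence(feats[, 5], t_conf, 1, ldc)
  cp <- cpp_bin_props(conf, acc)
  conf_props <- rbind(error = cp[7:12], correct = cp[1:6])
  structure(list(rt_props = rt_props, conf_props = conf_props,
                 rt_cutoffs = obs_sum$rt_cutoffs, n_trials = n_sim),
            class = "trial_summary")
}
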