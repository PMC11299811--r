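#' Parameter ranges for sampling synthetic participants
#'
#' Brackets the parameter values the feedback presets and fitting bounds
#' imply: ordered drift magnitudes, moderate bounds and non-decision times,
#' and confidence parameters spanning the manipulated feedback settings
#' (alpha 9-36, beta -1..1) with headroom.
#'
#' @return Named list of `c(min, max)` ranges for `v`, `a`, `ter`, `alpha`,
#'   `beta`.
#' @export
recovery_ranges <- function() {
  list(v = c(0.05, 0.4), a = c(0.06, 0.16), ter = c(0.2, 0.5),
       alpha = c(5, 40), beta = c(-1.5, 1.5))
}

#' Synthetic-experiment design
#'
#' @param n_participants Number of simulated participants.
#' @param n_per_difficulty Trials per difficulty level per participant.
#' @param n_difficulty Number of difficulty levels (drift rates).
#' @param ranges Parameter ranges as from [recovery_ranges()].
#' @param conditions Condition labels (confidence parameters are shared
#'   across conditions in the generator).
#' @return A list of class `"experiment_design"`.
#' @export
#' @examples
#' experiment_design(20)  # 20 participants x 648 trials
experiment_design <- function(n_participants = 20, n_per_difficulty = 216,
                              n_difficulty = 3, ranges = recovery_ranges(),
                              conditions = "baseline") {
  if (n_participants < 1 || n_per_difficulty < 1 || n_difficulty < 1) {
    stop("counts must be >= 1")
  }
  for (nm in c("v", "a", "ter", "alpha", "beta")) {
    r <- ranges[[nm]]
    if (is.null(r) || length(r) != 2 || !all(is.finite(r)) || r[1] > r[2]) {
      stop("invalid range for ", nm)
    }
  }
  structure(list(n_participants = n_participants,
                 n_per_difficulty = n_per_difficulty,
                 n_difficulty = n_difficulty, ranges = ranges,
                 conditions = conditions),
            class = "experiment_design")
}

#' Generate a synthetic cohort with known ground truth
#'
#' Samples each participant's parameters uniformly from the design ranges
#' (drift magnitudes sorted so difficulty levels are ordered), simulates
#' their trial table, and returns the tables alongside the generating
#' parameters. Uses R's RNG; per-participant sub-streams are derived from
#' the surrounding seed by simulation order, so a fixed seed gives a
#' bit-identical cohort.
#'
#' @param design An [experiment_design()].
#' @param time Elapsed-time convention passed to [simulate_trials()].
#' @return A list: `trials` (one table, all participants), `truth` (one row
#'   of generating parameters per participant).
#' @export
generate_cohort <- function(design, time = "accumulation") {
  stopifnot(inherits(design, "experiment_design"))
  r <- design$ranges
  tabs <- vector("list", design$n_participants)
  truth <- vector("list", design$n_participants)
  for (p in seq_len(design$n_participants)) {
    v <- sort(stats::runif(design$n_difficulty, r$v[1], r$v[2]))
    a <- stats::runif(1, r$a[1], r$a[2])
    ter <- stats::runif(1, r$ter[1], r$ter[2])
    alpha <- stats::runif(1, r$alpha[1], r$alpha[2])
    beta <- stats::runif(1, r$beta[1], r$beta[2])
    ddm <- ddm_params(v = v, a = a, ter = ter)
    ldc <- ldc_params(alpha, beta)
    des <- trial_design(design$conditions,
                        n_per_cell = design$n_per_difficulty,
                        n_difficulty = design$n_difficulty)
    tabs[[p]] <- simulate_trials(ddm, ldc, des, participant = p, time = time)
    truth[[p]] <- data.frame(participant = p, ter = ter, a = a,
                             t(stats::setNames(v, paste0("v", seq_along(v)))),
                             alpha = alpha, beta = beta)
  }
  list(trials = do.call(rbind, tabs), truth = do.call(rbind, truth))
}

#' Simulation-and-refit parameter recovery study
#'
#' Generates a cohort at known parameters, fits every participant with
#' [ldc_fit()], and reports per-parameter correlations between generating
#' and recovered values plus the cross-correlation between recovered alpha
#' and beta (which should be near zero if the two confidence parameters do
#' not trade off).
#'
#' @param design An [experiment_design()]; the default is the desk-scale
#'   study (20 participants, 648 trials each).
#' @param control An [ldc_control()]; ignored fields are overridden by
#'   `full`.
#' @param seed Master seed; the cohort and each participant's fit derive
#'   sub-seeds from it.
#' @param full If `TRUE`, run at full scale: 200 participants, oversample
#'   20, and the stagnation-ruled optimizer (hours of CPU time).
#'
#' @return An object of class `"ldc_recovery"`: `truth`, `recovered`,
#'   `correlations` (named, one per parameter), `alpha_beta_cor`,
#'   `failures`.
#' @export
recovery_study <- function(design = NULL, control = ldc_control(),
                           seed = 1L, full = FALSE) {
  if (full) {
    if (is.null(design)) design <- experiment_design(n_participants = 200)
    control$oversample <- 20
    control$max_gen <- 1000
    control$stagnation <- 100
  } else if (is.null(design)) {
    design <- experiment_design(n_participants = 20)
  }
  set.seed(seed)
  cohort <- generate_cohort(design)
  nlev <- design$n_difficulty
  par_names <- c("ter", "a", paste0("v", seq_len(nlev)), "alpha", "beta")
  rec <- vector("list", design$n_participants)
  failures <- character(0)
  for (p in seq_len(design$n_participants)) {
    tab <- cohort$trials[cohort$trials$participant == p, ]
    fit <- tryCatch(ldc_fit(tab, variant = "full", control = control,
                            seed = seed + p),
                    error = function(e) e)
    if (inherits(fit, "error")) {
      failures <- c(failures, sprintf("participant %d: %s", p,
                                      conditionMessage(fit)))
      next
    }
    cf <- coef(fit)
    names(cf) <- sub("\\.(.*)$", "", names(cf))
    rec[[p]] <- data.frame(participant = p,
                           t(cf[c("ter", "a", paste0("v", seq_len(nlev)),
                                  "alpha", "beta")]))
  }
  recovered <- do.call(rbind, rec)
  keep <- cohort$truth$participant %in% recovered$participant
  truth <- cohort$truth[keep, ]
  correlations <- vapply(par_names, function(nm) {
    stats::cor(truth[[nm]], recovered[[nm]])
  }, numeric(1))
  structure(list(truth = truth, recovered = recovered,
                 correlations = correlations,
                 alpha_beta_cor = stats::cor(recovered$alpha, recovered$beta),
                 failures = failures, design = design, seed = seed,
                 full = full),
            class = "ldc_recovery")
}

#' @export
print.ldc_recovery <- function(x, ...) {
  cat(sprintf("Parameter recovery: %d participants fitted (%d failures)\n",
              nrow(x$recovered), length(x$failures)))
  cat("generating vs recovered correlations:\n")
  print(round(x$correlations, 3))
  cat(sprintf("recovered alpha-beta correlation: %.3f\n", x$alpha_beta_cor))
  invisible(x)
}

#' @export
plot.ldc_recovery <- function(x, ...) {
  pn <- names(x$correlations)
  op <- graphics::par(mfrow = c(2, ceiling(length(pn) / 2)),
                      mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  for (nm in pn) {
    graphics::plot(x$truth[[nm]], x$recovered[[nm]], pch = 19,
                   xlab = "generating", ylab = "recovered",
                   main = sprintf("%s (r = %.2f)", nm, x$correlations[nm]))
    graphics::abline(0, 1, col = 2)
  }
  invisible(x)
}
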