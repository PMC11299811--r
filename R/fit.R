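#' Control settings for LDC model fitting
#'
#' Defaults are the desk-scale settings used throughout the package;
#' `full = TRUE` in [recovery_study()] switches to the stagnation-ruled
#' optimizer at full scale.
#'
#' @param oversample Simulated trials per observed trial in the objective.
#' @param pop_factor Differential-evolution population size as a multiple of
#'   the number of dimensions searched.
#' @param max_gen Hard cap on DE generations.
#' @param stagnation Stop after this many generations without improvement.
#' @param f,cr DE mutation weight and crossover rate.
#' @param strategy DE mutation strategy: `"local-to-best"` (the cited
#'   implementation's canonical default, faster convergence on these
#'   surfaces) or `"rand"` (rand/1/bin).
#' @param gamma Time exponent of the confidence mapping.
#' @param lambda Probit-approximation constant.
#' @param sigma,tau,z,max_t Fixed DDM simulation settings (noise, step,
#'   starting fraction, maximum walk duration).
#' @param time Elapsed-time convention for the confidence mapping during
#'   fitting: `"accumulation"` (default) or `"response"`.
#' @param pool_size Size of the pre-drawn noise pool (common random numbers).
#' @param bounds Named list of parameter bounds: `ter`, `a`, `v`, `alpha`,
#'   `beta`; `ter` upper bound NA means 0.9 times the minimum observed RT.
#'
#' @return A list of class `"ldc_control"`.
#' @export
ldc_control <- function(oversample = 20, pop_factor = 10, max_gen = 30,
                        stagnation = 100, f = 0.8, cr = 0.9,
                        strategy = c("local-to-best", "rand"), gamma = 0.5,
                        lambda = 1.702, sigma = 0.1, tau = 0.001, z = 0,
                        max_t = 20, time = c("accumulation", "response"),
                        pool_size = 2^23,
                        bounds = list(ter = c(0.05, NA), a = c(0.01, 0.3),
                                      v = c(0, 1), alpha = c(0, 100),
                                      beta = c(-5, 5))) {
  time <- match.arg(time)
  strategy <- match.arg(strategy)
  structure(list(oversample = oversample, pop_factor = pop_factor,
                 max_gen = max_gen, stagnation = stagnation, f = f, cr = cr,
                 strategy = strategy,
                 gamma = gamma, lambda = lambda, sigma = sigma, tau = tau,
                 z = z, max_t = max_t, time = time, pool_size = pool_size,
                 stride = 1000003L, bounds = bounds),
            class = "ldc_control")
}

validate_trials <- function(trials, need_rating = TRUE) {
  req <- c("condition", "difficulty", "accuracy", "decision_rt",
           "confidence_rt")
  if (need_rating) req <- c(req, "rating")
  miss <- setdiff(req, names(trials))
  if (length(miss)) stop("trial table lacks column(s): ",
                         paste(miss, collapse = ", "))
  if (nrow(trials) == 0) stop("empty trial table")
  if (need_rating && !all(trials$rating %in% 1:6)) {
    stop("ratings must be integers in 1..6")
  }
  invisible(trials)
}

# Assemble everything the C++ objective needs from an observed table.
# Durations are drawn so each observed confidence RT is used exactly
# `oversample` times, shuffled within condition. R RNG state at call time
# determines the pool and the shuffle.
build_fit_data <- function(trials, control) {
  conds <- sort(unique(as.character(trials$condition)))
  nlev <- max(trials$difficulty)
  os <- control$oversample
  probs <- c(.1, .3, .5, .7, .9)
  sim_diff <- integer(0)
  sim_cond <- integer(0)
  sim_dur <- numeric(0)
  obs_rt <- matrix(0, length(conds), 12 * nlev)
  obs_cj <- matrix(0, length(conds), 12 * nlev)
  obs_cj_pooled <- matrix(0, length(conds), 12)
  cut_cor <- matrix(NA_real_, length(conds), 5 * nlev)
  cut_err <- matrix(NA_real_, length(conds), 5 * nlev)
  summaries <- list()
  for (ci in seq_along(conds)) {
    sel <- trials$condition == conds[ci]
    ct <- trials[sel, ]
    s <- summarize_trials(ct)
    summaries[[conds[ci]]] <- s
    obs_cj_pooled[ci, ] <- flatten_summary(s)$cj
    # difficulty-resolved summaries: joint proportions over
    # (difficulty x accuracy x group/level), RT cutoffs per
    # (difficulty, accuracy)
    for (d in seq_len(nlev)) {
      for (acc in c(1L, 0L)) {
        seld <- ct$difficulty == d & ct$accuracy == acc
        off <- 12L * (d - 1L) + if (acc == 1L) 0L else 6L
        if (!any(seld)) next
        rts <- ct$decision_rt[seld]
        cuts <- stats::quantile(rts, probs, names = FALSE)
        if (acc == 1L) cut_cor[ci, 5L * (d - 1L) + 1:5] <- cuts
        else cut_err[ci, 5L * (d - 1L) + 1:5] <- cuts
        grp <- findInterval(rts, cuts, left.open = TRUE) + 1L
        obs_rt[ci, off + 1:6] <- tabulate(grp, 6) / nrow(ct)
        obs_cj[ci, off + 1:6] <- tabulate(ct$rating[seld], 6) / nrow(ct)
      }
    }
    sim_diff <- c(sim_diff, rep(ct$difficulty, times = os))
    sim_cond <- c(sim_cond, rep(ci - 1L, nrow(ct) * os))
    sim_dur <- c(sim_dur, sample(rep(ct$confidence_rt, times = os)))
  }
  pool <- cpp_make_pool(stats::rnorm(control$pool_size))
  b <- control$bounds
  ter_hi <- if (is.na(b$ter[2])) 0.9 * min(trials$decision_rt) else b$ter[2]
  list(conds = conds, nlev = nlev, summaries = summaries,
       sim_diff = as.integer(sim_diff) - 1L, sim_cond = as.integer(sim_cond),
       sim_dur = sim_dur, pool = pool,
       obs_rt = obs_rt, obs_cj = obs_cj, obs_cj_pooled = obs_cj_pooled,
       cut_cor = cut_cor, cut_err = cut_err,
       lower = c(b$ter[1], b$a[1], rep(b$v[1], nlev)),
       upper = c(ter_hi, b$a[2], rep(b$v[2], nlev)),
       ab_bounds = c(b$alpha, b$beta))
}

eval_objective <- function(theta, fd, control, mode, ab = NULL,
                           dense = FALSE) {
  if (is.null(ab)) ab <- matrix(0, length(fd$conds), 2)
  res <- cpp_fit_objective(theta, fd$sim_diff, fd$sim_cond, fd$sim_dur,
                           fd$pool, fd$stride %||% 1000003L, control$z,
                           control$sigma, control$tau, control$max_t,
                           control$gamma, fd$cut_cor, fd$cut_err, fd$obs_rt,
                           fd$obs_cj, mode, ab, fd$ab_bounds,
                           if (control$time == "accumulation") 0L else 1L,
                           as.integer(dense))
  if (!isTRUE(res$ok)) res$sse <- 1e6
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Closed-form EZ-style moment estimates of (ter, a, v per difficulty) used to
# seed the DE population: per difficulty, drift and bound from edge-corrected
# accuracy and the variance of RTs, non-decision time from the mean RT minus
# the implied mean decision time.
ez_estimates <- function(trials, sigma, lower, upper) {
  s2 <- sigma^2
  levs <- sort(unique(trials$difficulty))
  v <- a <- ter <- rep(NA_real_, length(levs))
  for (i in seq_along(levs)) {
    sel <- trials$difficulty == levs[i]
    n <- sum(sel)
    pc <- mean(trials$accuracy[sel])
    pc <- min(max(pc, 0.5 + 1 / (2 * n)), 1 - 1 / (2 * n))
    vrt <- stats::var(trials$decision_rt[sel])
    mrt <- mean(trials$decision_rt[sel])
    L <- stats::qlogis(pc)
    x <- L * (L * pc^2 - L * pc + pc - 0.5) / vrt
    v[i] <- sigma * x^(1 / 4)
    a[i] <- s2 * L / v[i]
    mdt <- (a[i] / (2 * v[i])) * tanh(v[i] * a[i] / s2)
    ter[i] <- mrt - mdt
  }
  init <- c(mean(ter, na.rm = TRUE), mean(a, na.rm = TRUE), v)
  init[!is.finite(init)] <- (lower + upper)[!is.finite(init)] / 2
  pmin(pmax(init, lower), upper)
}

#' Fit the LDC model to a participant's trial table
#'
#' Jointly fits the drift-diffusion decision parameters (non-decision time,
#' bound, one drift rate per difficulty level) and the LDC confidence
#' parameters (`alpha`, `beta`, per condition as dictated by `variant`) by
#' minimizing the quantile/bin sum-of-squared-errors objective with a
#' differential-evolution optimizer. The objective is evaluated on a fixed
#' noise pool (common random numbers), so it is deterministic given `seed`
#' and DE minimizes a fixed surface.
#'
#' Because `alpha` and `beta` do not influence the simulated walks, they are
#' profiled out inside each objective evaluation (grid plus Nelder-Mead on
#' the confidence term); the minimized objective is identical to the joint
#' SSE over all parameters, while DE searches only the DDM dimensions.
#' Variants whose confidence-parameter sharing prevents per-condition
#' profiling (`"alpha_free"`, `"beta_free"`) carry their confidence
#' parameters in the DE vector instead.
#'
#' @param trials Trial table (see [simulate_trials()] for the schema).
#' @param variant Confidence-parameter structure across conditions:
#'   `"full"` (alpha and beta free per condition), `"null"` (both shared),
#'   `"alpha_free"` (alpha per condition, beta shared), `"beta_free"` (beta
#'   per condition, alpha shared).
#' @param control An [ldc_control()] object.
#' @param seed Integer seed fixing the noise pool, duration assignment and
#'   DE initialization.
#'
#' @return An object of class `"ldc_fit"` with components `ddm`
#'   ([ddm_params()]), `ldc_by_condition` (named list of [ldc_params()]),
#'   `sse`, `sse_rt`, `sse_cj`, `k`, `n`, `bic`, `variant`, `seed`, `trace`,
#'   `observed` (per-condition summaries) and the optimizer diagnostics.
#' @seealso [two_stage_fit()] for the model-comparison fitting scheme,
#'   [recovery_study()] for the simulation-and-refit validation.
#' @export
ldc_fit <- function(trials, variant = c("full", "null", "alpha_free",
                                        "beta_free"),
                    control = ldc_control(), seed = 1L) {
  variant <- match.arg(variant)
  validate_trials(trials)
  set.seed(seed)
  fd <- build_fit_data(trials, control)
  nc <- length(fd$conds)
  nlev <- fd$nlev
  b <- control$bounds
  if (variant %in% c("full", "null") || nc == 1L) {
    if (nc == 1L) variant_mode <- 1L
    else variant_mode <- if (variant == "full") 1L else 2L
    obj <- function(theta) eval_objective(theta, fd, control, variant_mode)$sse
    de <- de_optimize(obj, fd$lower, fd$upper,
                      np = control$pop_factor * length(fd$lower),
                      max_gen = control$max_gen,
                      stagnation = control$stagnation,
                      f = control$f, cr = control$cr,
                      strategy = control$strategy %||% "rand",
                      init = ez_estimates(trials, control$sigma, fd$lower,
                                          fd$upper))
    # local polish of the decision parameters on the same deterministic
    # surface; the evolutionary stage is a global search, Nelder-Mead
    # converges the last distance
    pol <- stats::optim(de$par, function(th) {
      obj(pmin(pmax(th, fd$lower), fd$upper))
    }, method = "Nelder-Mead", control = list(maxit = 150, reltol = 1e-9))
    theta <- pmin(pmax(pol$par, fd$lower), fd$upper)
    if (obj(theta) > de$value) theta <- de$par
    final <- eval_objective(theta, fd, control, variant_mode, dense = TRUE)
    ab <- final$ab
  } else {
    # confidence parameters inside the DE vector
    if (variant == "alpha_free") {
      lower <- c(fd$lower, rep(b$alpha[1], nc), b$beta[1])
      upper <- c(fd$upper, rep(b$alpha[2], nc), b$beta[2])
      expand_ab <- function(x) cbind(x[seq_len(nc)], rep(x[nc + 1], nc))
    } else {
      lower <- c(fd$lower, b$alpha[1], rep(b$beta[1], nc))
      upper <- c(fd$upper, b$alpha[2], rep(b$beta[2], nc))
      expand_ab <- function(x) cbind(rep(x[1], nc), x[1 + seq_len(nc)])
    }
    nd <- length(fd$lower)
    obj <- function(par) {
      eval_objective(par[seq_len(nd)], fd, control, 3L,
                     ab = expand_ab(par[-seq_len(nd)]))$sse
    }
    init <- c(ez_estimates(trials, control$sigma, fd$lower, fd$upper),
              (lower + upper)[-seq_len(nd)] / 2)
    de <- de_optimize(obj, lower, upper,
                      np = control$pop_factor * length(lower),
                      max_gen = control$max_gen,
                      stagnation = control$stagnation,
                      f = control$f, cr = control$cr,
                      strategy = control$strategy %||% "rand", init = init)
    theta <- de$par[seq_len(nd)]
    ab <- expand_ab(de$par[-seq_len(nd)])
    final <- eval_objective(theta, fd, control, 3L, ab = ab)
  }
  k_conf <- switch(variant, full = 2L * nc, null = 2L,
                   alpha_free = nc + 1L, beta_free = nc + 1L)
  if (nc == 1L) k_conf <- 2L
  k <- 2L + nlev + k_conf
  n <- (12L * nlev + 12L) * nc
  ddm <- ddm_params(v = theta[-(1:2)], a = theta[2], ter = theta[1],
                    z = control$z, sigma = control$sigma, tau = control$tau,
                    max_t = control$max_t)
  ldc_by_condition <- stats::setNames(lapply(seq_len(nc), function(ci) {
    ldc_params(alpha = ab[ci, 1], beta = ab[ci, 2], gamma = control$gamma,
               lambda = control$lambda)
  }), fd$conds)
  structure(list(ddm = ddm, ldc_by_condition = ldc_by_condition,
                 variant = variant, sse = final$sse, sse_rt = final$sse_rt,
                 sse_cj = final$sse_cj, k = k, n = n,
                 bic = if (final$sse > 0) bic_sse(final$sse, k, n) else NA_real_,
                 seed = seed, trace = de$trace,
                 generations = de$generations, nfeval = de$nfeval,
                 converged = de$converged, conditions = fd$conds,
                 observed = fd$summaries, control = control,
                 trials = trials),
            class = "ldc_fit")
}

#' @export
print.ldc_fit <- function(x, ...) {
  cat(sprintf("LDC model fit (variant '%s'), %d conditions\n", x$variant,
              length(x$conditions)))
  cat(sprintf("  SSE = %.5f (RT %.5f + confidence %.5f), k = %d, n = %d, BIC = %.2f\n",
              x$sse, x$sse_rt, x$sse_cj, x$k, x$n, x$bic))
  cat(sprintf("  ter = %.3f s, a = %.4f, v = %s\n", x$ddm$ter, x$ddm$a,
              paste(signif(x$ddm$v, 3), collapse = ", ")))
  for (cn in names(x$ldc_by_condition)) {
    p <- x$ldc_by_condition[[cn]]
    cat(sprintf("  [%s] alpha = %.2f, beta = %.3f\n", cn, p$alpha, p$beta))
  }
  invisible(x)
}

#' @export
summary.ldc_fit <- function(object, ...) {
  print(object)
  cat(sprintf("  optimizer: %d generations, %d evaluations, %s\n",
              object$generations, object$nfeval,
              if (object$converged) "stagnation stop" else "generation cap"))
  invisible(object)
}

#' @export
coef.ldc_fit <- function(object, ...) {
  out <- c(ter = object$ddm$ter, a = object$ddm$a,
           stats::setNames(object$ddm$v,
                           paste0("v", seq_along(object$ddm$v))))
  for (cn in names(object$ldc_by_condition)) {
    p <- object$ldc_by_condition[[cn]]
    out[paste0("alpha.", cn)] <- p$alpha
    out[paste0("beta.", cn)] <- p$beta
  }
  out
}

#' Predicted quantile/bin summaries from a fitted model
#'
#' @param object An `"ldc_fit"`.
#' @param oversample Simulated trials per observed trial.
#' @param seed Seed for the prediction simulation.
#' @param ... Unused.
#' @return Named list (one `"trial_summary"` per condition).
#' @export
predict.ldc_fit <- function(object, oversample = NULL, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  os <- oversample %||% object$control$oversample
  out <- list()
  for (cn in object$conditions) {
    sel <- object$trials$condition == cn
    out[[cn]] <- predict_summary(object$ddm, object$ldc_by_condition[[cn]],
                                 object$trials[sel, ], oversample = os,
                                 time = object$control$time)
  }
  out
}

#' Simulate datasets of the observed design from a fitted model
#'
#' Reproduces the observed per-condition difficulty mix and resamples the
#' observed confidence RTs (with replacement) per condition, then generates
#' choices, RTs and ratings from the fitted parameters.
#'
#' @param object An `"ldc_fit"`.
#' @param nsim Number of datasets.
#' @param seed Optional seed.
#' @param ... Unused.
#' @return A list of `nsim` trial tables.
#' @export
simulate.ldc_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  obs <- object$trials
  designs <- list()
  rts <- list()
  for (cn in object$conditions) {
    sel <- obs$condition == cn
    tab <- table(obs$difficulty[sel])
    designs[[cn]] <- data.frame(condition = cn,
                                difficulty = as.integer(names(tab)),
                                n = as.integer(tab))
    rts[[cn]] <- obs$confidence_rt[sel]
  }
  lapply(seq_len(nsim), function(i) {
    do.call(rbind, lapply(object$conditions, function(cn) {
      simulate_trials(object$ddm, object$ldc_by_condition[[cn]],
                      designs[[cn]], conf_rt = rts[[cn]],
                      time = object$control$time)
    }))
  })
}

#' @export
residuals.ldc_fit <- function(object, ...) {
  pred <- predict(object, ...)
  out <- list()
  for (cn in object$conditions) {
    out[[cn]] <- list(
      rt = object$observed[[cn]]$rt_props - pred[[cn]]$rt_props,
      conf = object$observed[[cn]]$conf_props - pred[[cn]]$conf_props)
  }
  out
}

#' @export
plot.ldc_fit <- function(x, seed = NULL, ...) {
  pred <- predict(x, seed = seed)
  op <- graphics::par(mfrow = c(length(x$conditions), 2),
                      mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  for (cn in x$conditions) {
    o <- x$observed[[cn]]
    p <- pred[[cn]]
    graphics::matplot(1:6, t(rbind(o$conf_props, p$conf_props)),
                      type = "b", pch = c(1, 1, 19, 19),
                      col = c(2, 4, 2, 4), lty = c(1, 1, 2, 2),
                      xlab = "confidence level", ylab = "joint proportion",
                      main = sprintf("%s: confidence", cn))
    graphics::legend("topleft", bty = "n", cex = 0.8,
                     legend = c("obs err", "obs cor", "pred err", "pred cor"),
                     col = c(2, 4, 2, 4), pch = c(1, 1, 19, 19))
    graphics::matplot(1:6, t(rbind(o$rt_props, p$rt_props)),
                      type = "b", pch = c(1, 1, 19, 19),
                      col = c(2, 4, 2, 4), lty = c(1, 1, 2, 2),
                      xlab = "RT group", ylab = "joint proportion",
                      main = sprintf("%s: RT", cn))
  }
  invisible(x)
}
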