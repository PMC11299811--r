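#' Bayesian probability correct given evidence and time
#'
#' Under the drift-diffusion model with a flat prior over the sign of the
#' drift, the posterior probability that the drift is positive given signed
#' accumulated evidence `e` after accumulation time `t` is
#' `Phi(e / (sigma * t^gamma))` with `gamma = 0.5` (the Wiener-process
#' posterior). Conditioning on the choice toward positive evidence makes this
#' the probability that the choice is correct.
#'
#' @param e Signed accumulated evidence (evidence units). Vectorized.
#' @param t Accumulation time in seconds, `t > 0`. Vectorized.
#' @param sigma Within-trial noise of the accumulator.
#' @param gamma Time exponent (0.5 gives the exact Wiener posterior).
#'
#' @return Probability in (0, 1), same length as the inputs.
#' @export
#' @examples
#' bayes_p_correct(0, 1)            # uninformative evidence: 0.5
#' bayes_p_correct(0.1, 1)          # pnorm(1) with sigma = 0.1
bayes_p_correct <- function(e, t, sigma = 0.1, gamma = 0.5) {
  if (any(!is.finite(t)) || any(t <= 0)) stop("`t` must be > 0")
  if (!is.finite(sigma) || sigma <= 0) stop("`sigma` must be > 0")
  stats::pnorm(e / (sigma * t^gamma))
}

#' LDC confidence
#'
#' The low-dimensional confidence mapping
#' `1 / (1 + exp(-(x * alpha * e + beta) / t^gamma))`, where `x` in `{-1, 1}`
#' is the choice, `e` the signed accumulated evidence and `t` the elapsed
#' time. Monotone increasing in `x * e` and in `beta`; the influence of
#' `beta` shrinks as `t` grows.
#'
#' @param e Signed accumulated evidence. Vectorized.
#' @param t Elapsed time in seconds, `t > 0`. Vectorized.
#' @param x Choice, `-1` or `1`. Vectorized.
#' @param params An [ldc_params()] object.
#'
#' @return Confidence in (0, 1).
#' @export
#' @examples
#' p <- ldc_params(alpha = 17, beta = 0)
#' ldc_confidence(0.1, 1, 1, p)     # ~ 0.8455
ldc_confidence <- function(e, t, x, params) {
  params <- as_ldc_params(params)
  if (any(!is.finite(t)) || any(t <= 0)) stop("`t` must be > 0")
  if (!all(x %in% c(-1, 1))) stop("`x` must be -1 or 1")
  stats::plogis((x * params$alpha * e + params$beta) / t^params$gamma)
}

#' Logistic approximation of the probit function
#'
#' `1 / (1 + exp(-lambda * z))`, the tractable logistic stand-in for the
#' standard normal CDF. With `lambda ~ 1.702` the maximum absolute deviation
#' from `pnorm(z)` is below 0.01 over the real line.
#'
#' @param z Standardized evidence. Vectorized.
#' @param lambda Scaling constant, `lambda > 0`.
#'
#' @return Probability in (0, 1).
#' @export
logistic_probit_approx <- function(z, lambda = 1.702) {
  if (!is.finite(lambda) || lambda <= 0) stop("`lambda` must be > 0")
  stats::plogis(lambda * z)
}

#' Optimal probit-logistic scaling constant
#'
#' Grid search for the constant `lambda` minimizing the maximum absolute
#' deviation between `plogis(lambda * z)` and `pnorm(z)` over a dense grid of
#' `z`. The deviation is symmetric in `z`, so only the positive half-line is
#' scanned.
#'
#' @param interval Search interval for `lambda` (must contain the minimizer).
#' @param lambda_step Grid resolution for `lambda`.
#' @param z_max Half-width of the `z` grid.
#' @param z_step Grid resolution for `z`.
#'
#' @return A list with `lambda` (the minimizer) and `max_dev` (the minimized
#'   maximum absolute deviation).
#' @export
#' @examples
#' fit_lambda()$lambda   # ~ 1.702
fit_lambda <- function(interval = c(1.5, 2), lambda_step = 1e-4,
                       z_max = 10, z_step = 1e-3) {
  if (length(interval) != 2 || !all(is.finite(interval)) ||
      diff(interval) <= 0) {
    stop("`interval` must be a finite increasing pair")
  }
  cpp_fit_lambda(interval[1], interval[2], lambda_step, z_max, z_step)
}

#' Bayesian readout over a discrete mixture of drift magnitudes
#'
#' Exact posterior probability that the drift sign matches the choice under
#' equiprobable signed drifts at known magnitudes: for a choice toward
#' positive evidence,
#' `sum_i pi_i N(e; v_i t, sigma^2 t) / sum_i pi_i (N(e; v_i t, sigma^2 t) +
#'  N(e; -v_i t, sigma^2 t))`.
#' This is the readout used by the Bayesian-readout candidate models, with
#' the prior over difficulty levels taken from the trial mix.
#'
#' @param e Signed accumulated evidence in the frame of the chosen option
#'   (i.e. `x * e`). Vectorized.
#' @param t Accumulation time in seconds, `t > 0`. Vectorized.
#' @param ddm A [ddm_params()] object supplying drift magnitudes and `sigma`.
#' @param prior Weights over the difficulty levels; must sum to 1.
#'
#' @return Probability in (0, 1).
#' @export
bayes_readout_mixture <- function(e, t, ddm, prior = NULL) {
  ddm <- as_ddm_params(ddm)
  if (any(!is.finite(t)) || any(t <= 0)) stop("`t` must be > 0")
  nlev <- length(ddm$v)
  if (is.null(prior)) prior <- rep(1 / nlev, nlev)
  if (length(prior) != nlev || any(prior < 0) ||
      abs(sum(prior) - 1) > 1e-8) {
    stop("`prior` must be nonnegative weights over difficulty levels summing to 1")
  }
  n <- max(length(e), length(t))
  e <- rep_len(e, n)
  t <- rep_len(t, n)
  # log-sum-exp over the 2*nlev mixture components for numerical stability
  lw_match <- matrix(NA_real_, n, nlev)
  lw_other <- matrix(NA_real_, n, nlev)
  sd_t <- ddm$sigma * sqrt(t)
  for (i in seq_len(nlev)) {
    lw_match[, i] <- log(prior[i]) + stats::dnorm(e, ddm$v[i] * t, sd_t, log = TRUE)
    lw_other[, i] <- log(prior[i]) + stats::dnorm(e, -ddm$v[i] * t, sd_t, log = TRUE)
  }
  lse <- function(m) {
    mx <- apply(m, 1, max)
    mx + log(rowSums(exp(m - mx)))
  }
  num <- lse(lw_match)
  den <- lse(cbind(lw_match, lw_other))
  exp(num - den)
}

#' Fit LDC parameters to posterior-probability targets
#'
#' Least-squares fit of `(alpha, beta)` on the logit scale: with targets
#' `p_i` and the mapping `logit(p) = (x * alpha * e + beta) / t^gamma`, the
#' problem `logit(p_i) * t_i^gamma ~ alpha * (x_i * e_i) + beta` is linear in
#' the parameters and solved by the normal equations. Targets are clipped to
#' `[1e-6, 1 - 1e-6]` before the logit.
#'
#' @param e Signed accumulated evidence per trial.
#' @param t Elapsed time per trial (seconds, > 0).
#' @param x Choice per trial, `-1` or `1`.
#' @param target Posterior probability-correct targets per trial.
#' @param gamma Time exponent.
#'
#' @return An [ldc_params()] object with the fitted `alpha` and `beta`.
#' @export
fit_ldc_to_posterior <- function(e, t, x, target, gamma = 0.5) {
  if (any(!is.finite(t)) || any(t <= 0)) stop("`t` must be > 0")
  if (!all(x %in% c(-1, 1))) stop("`x` must be -1 or 1")
  u <- x * e
  if (length(unique(u)) < 2) stop("degenerate design: all x * e identical")
  p <- pmin(pmax(target, 1e-6), 1 - 1e-6)
  y <- stats::qlogis(p) * t^gamma
  fit <- stats::lm.fit(cbind(u = u, intercept = 1), y)
  alpha <- unname(fit$coefficients["u"])
  beta <- unname(fit$coefficients["intercept"])
  if (!is.finite(alpha) || !is.finite(beta)) stop("linear solve failed")
  ldc_params(alpha = max(alpha, 0), beta = beta, gamma = gamma)
}
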