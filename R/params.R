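#' Drift-diffusion process parameters
#'
#' Container for the generative decision-process parameters of the discrete
#' random-walk approximation of the drift-diffusion model (DDM). Evidence is
#' unitless under the convention that the within-trial noise is fixed at
#' `sigma = 0.1`; time is in seconds.
#'
#' @param v Numeric vector of drift magnitudes (evidence units per second),
#'   one per difficulty level, ordered from hardest to easiest or in any fixed
#'   order the design refers to.
#' @param a Decision bound (evidence units); responses are issued when the
#'   accumulator reaches `+a` or `-a`.
#' @param ter Non-decision time (seconds), added to the first-passage time.
#' @param z Relative starting point in (-1, 1); 0 is unbiased.
#' @param sigma Within-trial noise (evidence units per square-root second).
#' @param tau Step size of the random walk (seconds).
#' @param max_t Maximum simulated duration of a single walk (seconds); a walk
#'   that has not terminated by then signals degenerate parameters and is an
#'   error in the user-facing simulators.
#'
#' @return An object of class `"ddm_params"`.
#' @export
#' @examples
#' ddm_params(v = c(0.05, 0.1, 0.2), a = 0.1, ter = 0.3)
ddm_params <- function(v, a, ter, z = 0, sigma = 0.1, tau = 0.001,
                       max_t = 20) {
  stopifnot(is.numeric(v), length(v) >= 1, all(is.finite(v)))
  if (!is.finite(a) || a <= 0) stop("bound `a` must be > 0")
  if (!is.finite(ter) || ter < 0) stop("non-decision time `ter` must be >= 0")
  if (!is.finite(z) || abs(z) >= 1) stop("starting fraction `z` must be in (-1, 1)")
  if (!is.finite(sigma) || sigma <= 0) stop("noise `sigma` must be > 0")
  if (!is.finite(tau) || tau <= 0) stop("step `tau` must be > 0")
  if (!is.finite(max_t) || max_t <= tau) stop("`max_t` must exceed `tau`")
  structure(list(v = as.numeric(v), a = a, ter = ter, z = z, sigma = sigma,
                 tau = tau, max_t = max_t),
            class = "ddm_params")
}

#' @export
print.ddm_params <- function(x, ...) {
  cat("DDM parameters\n")
  cat("  drift rates v:", paste(signif(x$v, 4), collapse = ", "), "\n")
  cat(sprintf("  bound a: %.4g   ter: %.4g s   z: %.3g\n", x$a, x$ter, x$z))
  cat(sprintf("  sigma: %.3g   tau: %.4g s\n", x$sigma, x$tau))
  invisible(x)
}

#' Low-dimensional confidence (LDC) mapping parameters
#'
#' Parameters of the logistic mapping from accumulated evidence, elapsed time
#' and choice onto confidence:
#' `conf = 1 / (1 + exp(-(x * alpha * e + beta) / t^gamma))`.
#' `alpha` weighs the evidence (the observer's estimate of evidence
#' reliability, in inverse evidence units), `beta` is a stimulus-independent
#' confidence bias on the logit scale. The time exponent `gamma` defaults to
#' 0.5, the value under which the mapping is calibrated to the flat-prior
#' Bayesian posterior of a Wiener process; `lambda` is the probit-logistic
#' constant used by the equivalence `alpha = lambda / sigma`.
#'
#' @param alpha Evidence reliability weight, `alpha >= 0`.
#' @param beta Stimulus-independent bias (unbounded).
#' @param gamma Time exponent, `gamma > 0`.
#' @param lambda Probit-approximation constant, `lambda > 0`.
#'
#' @return An object of class `"ldc_params"`.
#' @export
#' @examples
#' ldc_params(alpha = 18, beta = 0)
ldc_params <- function(alpha, beta = 0, gamma = 0.5, lambda = 1.702) {
  if (!is.finite(alpha) || alpha < 0) stop("`alpha` must be >= 0")
  if (!is.finite(beta)) stop("`beta` must be finite")
  if (!is.finite(gamma) || gamma <= 0) stop("`gamma` must be > 0")
  if (!is.finite(lambda) || lambda <= 0) stop("`lambda` must be > 0")
  structure(list(alpha = alpha, beta = beta, gamma = gamma, lambda = lambda),
            class = "ldc_params")
}

#' @export
print.ldc_params <- function(x, ...) {
  cat(sprintf("LDC parameters: alpha = %.4g, beta = %.4g (gamma = %.3g, lambda = %.4g)\n",
              x$alpha, x$beta, x$gamma, x$lambda))
  invisible(x)
}

as_ddm_params <- function(x) {
  if (inherits(x, "ddm_params")) return(x)
  stop("expected a `ddm_params` object")
}

as_ldc_params <- function(x) {
  if (inherits(x, "ldc_params")) return(x)
  stop("expected an `ldc_params` object")
}
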