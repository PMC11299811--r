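#' BIC from a sum of squared errors
#'
#' `BIC = k * ln(n) + n * ln(SSE / n)`, the Bayesian information criterion
#' under normally distributed model errors with zero mean.
#'
#' @param sse Sum of squared errors, strictly positive.
#' @param k Number of free parameters.
#' @param n Number of data points.
#' @return The BIC value.
#' @export
#' @examples
#' bic_sse(0.36, k = 2, n = 36)  # ~ -158.62
bic_sse <- function(sse, k, n) {
  if (any(n <= 0) || any(k < 0)) stop("need n > 0 and k >= 0")
  if (any(sse <= 0)) stop("SSE must be > 0 (an exactly saturated fit has no BIC)")
  k * log(n) + n * log(sse / n)
}

#' Mean-BIC distance table across candidate models
#'
#' Mean BIC per candidate over participants, minus the minimum mean BIC; the
#' best candidate(s) show 0 (ties all reported as 0).
#'
#' @param bic Either a participants x candidates numeric matrix of BIC
#'   values, or a list (per participant) of named lists of `"ldc_fit"`
#'   objects.
#' @return A data frame with columns `candidate`, `mean_bic`, `delta_bic`.
#' @export
delta_bic_table <- function(bic) {
  m <- as_bic_matrix(bic)
  if (anyNA(m)) stop("missing BIC cells: every participant needs every candidate")
  mb <- colMeans(m)
  data.frame(candidate = colnames(m), mean_bic = mb, delta_bic = mb - min(mb),
             row.names = NULL)
}

as_bic_matrix <- function(bic) {
  if (is.matrix(bic)) {
    if (is.null(colnames(bic))) {
      colnames(bic) <- paste0("model", seq_len(ncol(bic)))
    }
    return(bic)
  }
  cands <- names(bic[[1]])
  m <- t(vapply(bic, function(p) {
    vapply(cands, function(cn) {
      if (is.null(p[[cn]])) NA_real_ else p[[cn]]$bic
    }, numeric(1))
  }, numeric(length(cands))))
  colnames(m) <- cands
  m
}

#' Confidence contrast between feedback conditions
#'
#' Mean confidence over the pooled baseline-and-plus conditions minus the
#' minus condition, computed separately for correct and error trials; the
#' interaction is the difference between the two contrasts.
#'
#' @param trials Trial table with `condition`, `accuracy` and the confidence
#'   column named by `value`.
#' @param value Column holding the confidence measure (`"rating"` for
#'   6-point reports, `"conf"` or `"feedback"` for continuous values).
#' @param minus,pooled Condition labels of the minus condition and of the
#'   pooled reference conditions.
#' @return Named numeric vector `(correct, error, interaction)`.
#' @export
confidence_contrast <- function(trials, value = "rating", minus = "minus",
                                pooled = c("baseline", "plus")) {
  if (!value %in% names(trials)) stop("no column `", value, "` in trial table")
  have <- unique(as.character(trials$condition))
  need <- c(minus, pooled)
  if (!all(need %in% have)) {
    stop("missing condition(s): ", paste(setdiff(need, have), collapse = ", "))
  }
  if (!all(c(0, 1) %in% trials$accuracy)) {
    stop("both accuracy classes must be present")
  }
  v <- trials[[value]]
  ctr <- function(acc) {
    mean(v[trials$condition %in% pooled & trials$accuracy == acc]) -
      mean(v[trials$condition == minus & trials$accuracy == acc])
  }
  cc <- ctr(1)
  ce <- ctr(0)
  c(correct = cc, error = ce, interaction = cc - ce)
}

#' Bootstrap distribution of the confidence contrasts under a fitted model
#'
#' Simulates `reps` datasets of the observed design from the fitted
#' parameters, computes the confidence contrasts of each, and returns the
#' distribution with its .025/.975 quantiles (type-1 quantiles, so at small
#' `reps` the interval endpoints are order statistics).
#'
#' @param fit An `"ldc_fit"` covering the minus/baseline/plus conditions.
#' @param reps Number of simulated datasets (default 500).
#' @param seed Optional seed.
#' @param value Confidence column to contrast in the simulated tables.
#' @inheritParams confidence_contrast
#' @return A list of class `"ldc_bootstrap"`: `draws` (reps x 3 matrix) and
#'   `ci` (2 x 3 matrix of the quantiles).
#' @export
bootstrap_contrasts <- function(fit, reps = 500, seed = NULL,
                                value = "rating", minus = "minus",
                                pooled = c("baseline", "plus")) {
  if (reps < 2) stop("`reps` must be >= 2")
  if (!all(c(minus, pooled) %in% fit$conditions)) {
    stop("fit lacks required conditions")
  }
  if (!is.null(seed)) set.seed(seed)
  sims <- simulate(fit, nsim = reps)
  draws <- t(vapply(sims, confidence_contrast, numeric(3), value = value,
                    minus = minus, pooled = pooled))
  ci <- apply(draws, 2, stats::quantile, probs = c(.025, .975), type = 1)
  structure(list(draws = draws, ci = ci, reps = reps),
            class = "ldc_bootstrap")
}

#' @export
print.ldc_bootstrap <- function(x, ...) {
  cat(sprintf("Bootstrap confidence contrasts (%d replicates)\n", x$reps))
  print(round(rbind(mean = colMeans(x$draws), x$ci), 4))
  invisible(x)
}

#' Random-effects Bayesian model selection
#'
#' Variational Dirichlet scheme over model frequencies in the population:
#' candidate models are treated as random effects, per-participant model
#' evidence (e.g. `-BIC/2`) feeds a fixed-point update of the Dirichlet
#' parameters, exceedance probabilities are estimated by Dirichlet sampling,
#' and the Bayesian omnibus risk (BOR) compares the frequency model against
#' the equal-frequency null via their free energies.
#'
#' @param log_evidence Participants x candidates matrix of log model
#'   evidence (finite).
#' @param n_samples Dirichlet draws for the exceedance probabilities.
#' @param alpha0 Prior Dirichlet parameters (default flat, all 1).
#' @param tol,max_iter Convergence tolerance and iteration cap of the
#'   fixed-point update.
#' @return A list: `alpha` (posterior Dirichlet parameters), `frequencies`
#'   (expected model frequencies), `ep` (exceedance probabilities), `bor`,
#'   and `posterior` (participants x candidates assignment probabilities).
#' @export
rfx_bms <- function(log_evidence, n_samples = 1e5, alpha0 = NULL,
                    tol = 1e-6, max_iter = 500) {
  m <- as.matrix(log_evidence)
  if (ncol(m) < 2) stop("need at least 2 candidates")
  if (any(!is.finite(m))) stop("log evidences must be finite")
  ns <- nrow(m)
  nk <- ncol(m)
  if (is.null(alpha0)) alpha0 <- rep(1, nk)
  alpha <- alpha0
  u <- matrix(0, ns, nk)
  for (it in seq_len(max_iter)) {
    elr <- digamma(alpha) - digamma(sum(alpha))  # E[log r_k]
    lu <- sweep(m, 2, elr, "+")
    lu <- lu - apply(lu, 1, max)
    u <- exp(lu) / rowSums(exp(lu))
    alpha_new <- alpha0 + colSums(u)
    if (max(abs(alpha_new - alpha)) < tol) {
      alpha <- alpha_new
      break
    }
    alpha <- alpha_new
  }
  elr <- digamma(alpha) - digamma(sum(alpha))
  # free energy of the random-effects model
  f1 <- sum(u * sweep(m, 2, elr, "+")) - sum(u * log(pmax(u, 1e-300))) +
    lgamma(sum(alpha0)) - sum(lgamma(alpha0)) -
    lgamma(sum(alpha)) + sum(lgamma(alpha)) +
    sum((alpha0 - alpha) * elr)
  # free energy of the equal-frequency null
  f0 <- sum(apply(m, 1, function(r) {
    mx <- max(r)
    mx + log(mean(exp(r - mx)))
  }))
  bor <- 1 / (1 + exp(f1 - f0))
  # exceedance probabilities via Dirichlet sampling
  g <- matrix(stats::rgamma(n_samples * nk, shape = rep(alpha, each = n_samples)),
              n_samples, nk)
  win <- max.col(g, ties.method = "random")
  ep <- tabulate(win, nk) / n_samples
  names(ep) <- colnames(m)
  freq <- alpha / sum(alpha)
  names(freq) <- colnames(m)
  names(alpha) <- colnames(m)
  list(alpha = alpha, frequencies = freq, ep = ep, bor = bor, posterior = u)
}
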