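#' Statistical signatures of Bayesian confidence
#'
#' Computes the four signature curves from a trial table:
#' \enumerate{
#'   \item mean confidence by accuracy (confidence predicts accuracy),
#'   \item mean confidence by evidence strength and accuracy (the folded
#'     X-pattern: increasing with strength on corrects, decreasing on
#'     errors),
#'   \item accuracy by evidence strength and confidence half (median split;
#'     high-confidence trials are more accurate at every strength),
#'   \item mean confidence by decision-RT quantile bin (confidence decreases
#'     with RT).
#' }
#' Evidence strength is the difficulty level (the observable proxy for drift
#' magnitude). The median split and the RT bins are computed within
#' participant when a `participant` column is present; trials at the median
#' rating go to the lower half.
#'
#' @param trials Trial table with `difficulty`, `accuracy`, `rating`,
#'   `decision_rt` (and optionally `participant`).
#' @param n_rt_bins Number of RT quantile bins for the fourth curve.
#'
#' @return A data frame of class `"ldc_signatures"` with columns `curve`,
#'   `x`, `group`, `mean`, `sem`, `n`. Cells with no trials appear with
#'   `NA` means.
#' @export
signature_curves <- function(trials, n_rt_bins = 6) {
  validate_trials(trials)
  if (is.null(trials$participant)) trials$participant <- 1L
  cell <- function(curve, x, group, v) {
    data.frame(curve = curve, x = x, group = group,
               mean = if (length(v)) mean(v) else NA_real_,
               sem = if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else NA_real_,
               n = length(v))
  }
  out <- list()
  # 1: confidence by accuracy
  for (acc in 0:1) {
    v <- trials$rating[trials$accuracy == acc]
    out[[length(out) + 1]] <- cell("conf_by_accuracy", acc,
                                   if (acc == 1) "correct" else "error", v)
  }
  # 2: folded X
  for (d in sort(unique(trials$difficulty))) for (acc in 0:1) {
    v <- trials$rating[trials$difficulty == d & trials$accuracy == acc]
    out[[length(out) + 1]] <- cell("folded_x", d,
                                   if (acc == 1) "correct" else "error", v)
  }
  # 3: conditional accuracy by confidence half (median split per
  # participant). On the discrete scale, trials at the median rating go to
  # the lower half; if that leaves the upper half empty (median at the top
  # rating), they go to the upper half instead.
  half <- rep(NA_character_, nrow(trials))
  for (p in unique(trials$participant)) {
    sel <- trials$participant == p
    med <- stats::median(trials$rating[sel])
    hp <- ifelse(trials$rating[sel] > med, "high", "low")
    if (!any(hp == "high")) hp[trials$rating[sel] == med] <- "high"
    half[sel] <- hp
  }
  for (d in sort(unique(trials$difficulty))) for (h in c("low", "high")) {
    v <- trials$accuracy[trials$difficulty == d & half == h]
    out[[length(out) + 1]] <- cell("conditional_accuracy", d, h, v)
  }
  # 4: confidence by RT quantile bin (within participant)
  rtbin <- rep(NA_integer_, nrow(trials))
  for (p in unique(trials$participant)) {
    sel <- trials$participant == p
    br <- unique(stats::quantile(trials$decision_rt[sel],
                                 probs = seq(0, 1, length.out = n_rt_bins + 1)))
    rtbin[sel] <- as.integer(cut(trials$decision_rt[sel], breaks = br,
                                 include.lowest = TRUE))
  }
  for (b in seq_len(n_rt_bins)) {
    v <- trials$rating[!is.na(rtbin) & rtbin == b]
    out[[length(out) + 1]] <- cell("conf_by_rt_bin", b, "all", v)
  }
  res <- do.call(rbind, out)
  class(res) <- c("ldc_signatures", "data.frame")
  res
}

#' @export
plot.ldc_signatures <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  panel <- function(curve, xlab, ylab, main) {
    d <- x[x$curve == curve, ]
    groups <- unique(d$group)
    cols <- stats::setNames(seq_along(groups) + 1, groups)
    graphics::plot(range(d$x), range(c(d$mean - d$sem, d$mean + d$sem),
                                     na.rm = TRUE),
                   type = "n", xlab = xlab, ylab = ylab, main = main)
    for (g in groups) {
      dg <- d[d$group == g, ]
      graphics::lines(dg$x, dg$mean, type = "b", col = cols[g], pch = 19)
      graphics::arrows(dg$x, dg$mean - dg$sem, dg$x, dg$mean + dg$sem,
                       angle = 90, code = 3, length = 0.02, col = cols[g])
    }
    graphics::legend("bottomleft", legend = groups, col = cols, pch = 19,
                     bty = "n", cex = 0.8)
  }
  panel("conf_by_accuracy", "accuracy", "mean rating", "confidence ~ accuracy")
  panel("folded_x", "evidence strength", "mean rating", "folded X-pattern")
  panel("conditional_accuracy", "evidence strength", "accuracy",
        "accuracy by confidence half")
  panel("conf_by_rt_bin", "RT bin", "mean rating", "confidence ~ RT")
  invisible(x)
}
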