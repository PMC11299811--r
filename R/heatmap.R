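#' Empirical probability-correct heatmap over (evidence, time)
#'
#' Bins simulated trials on the plane spanned by total accumulated evidence
#' (folded into the frame of the chosen option, `x * e`) and accumulation
#' time (decision time net of non-decision time, plus the post-decisional
#' duration), and computes the fraction of correct choices per cell. This is
#' the empirical counterpart of the Bayesian readout of confidence.
#'
#' @param trials Trial table carrying `evidence_total`, `choice`, `accuracy`,
#'   `decision_rt`, `confidence_rt`.
#' @param ter Non-decision time subtracted from `decision_rt` to obtain
#'   accumulation time.
#' @param evidence_edges,time_edges Strictly increasing grid edges; by
#'   default 50 equal-width cells spanning the observed ranges.
#' @param min_count Cells with fewer trials are flagged undefined (NA).
#'
#' @return An object of class `"ldc_heatmap"`: `evidence_edges`,
#'   `time_edges`, `p_correct` (matrix, evidence x time), `counts`.
#' @export
build_heatmap <- function(trials, ter = 0, evidence_edges = NULL,
                          time_edges = NULL, min_count = 50) {
  u <- trials$choice * trials$evidence_total
  t_acc <- (trials$decision_rt - ter) + trials$confidence_rt
  if (any(t_acc <= 0)) stop("nonpositive accumulation time; check `ter`")
  if (is.null(evidence_edges)) {
    evidence_edges <- seq(min(u), max(u), length.out = 51)
  }
  if (is.null(time_edges)) {
    time_edges <- seq(min(t_acc), max(t_acc), length.out = 51)
  }
  if (any(diff(evidence_edges) <= 0) || any(diff(time_edges) <= 0)) {
    stop("grid edges must be strictly increasing")
  }
  ei <- findInterval(u, evidence_edges, rightmost.closed = TRUE)
  ti <- findInterval(t_acc, time_edges, rightmost.closed = TRUE)
  ne <- length(evidence_edges) - 1
  nt <- length(time_edges) - 1
  keep <- ei >= 1 & ei <= ne & ti >= 1 & ti <= nt
  cell <- (ti[keep] - 1L) * ne + ei[keep]
  counts <- matrix(tabulate(cell, ne * nt), ne, nt)
  hits <- matrix(tabulate(cell[trials$accuracy[keep] == 1], ne * nt), ne, nt)
  p <- hits / counts
  p[counts < min_count] <- NA_real_
  if (all(is.na(p))) stop("all heatmap cells undefined; lower `min_count`")
  structure(list(evidence_edges = evidence_edges, time_edges = time_edges,
                 p_correct = p, counts = counts, min_count = min_count),
            class = "ldc_heatmap")
}

#' @export
print.ldc_heatmap <- function(x, ...) {
  cat(sprintf("Probability-correct heatmap: %d x %d cells, %d defined\n",
              nrow(x$p_correct), ncol(x$p_correct), sum(!is.na(x$p_correct))))
  invisible(x)
}

#' @export
as.data.frame.ldc_heatmap <- function(x, ...) {
  ne <- nrow(x$p_correct)
  nt <- ncol(x$p_correct)
  data.frame(
    e_low = rep(x$evidence_edges[seq_len(ne)], nt),
    e_high = rep(x$evidence_edges[-1], nt),
    t_low = rep(x$time_edges[seq_len(nt)], each = ne),
    t_high = rep(x$time_edges[-1], each = ne),
    p_correct = as.vector(x$p_correct),
    count = as.vector(x$counts)
  )
}

#' @export
plot.ldc_heatmap <- function(x, ...) {
  graphics::image(
    x = x$time_edges, y = x$evidence_edges, z = t(x$p_correct),
    xlab = "accumulation time (s)", ylab = "evidence (chosen-option frame)",
    main = "P(correct | evidence, time)",
    col = grDevices::hcl.colors(64, "viridis"), ...)
  invisible(x)
}
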