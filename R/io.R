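#' Read and validate a trial table from CSV
#'
#' The on-disk schema has one row per trial with columns `participant`,
#' `condition`, `difficulty`, `stim_sign`, `choice`, `accuracy`,
#' `decision_rt`, `confidence_rt`, `rating`. Validation errors name the
#' offending column and row.
#'
#' @param path Path to a CSV file with a header.
#' @return A trial table data frame.
#' @export
read_trials <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("participant", "condition", "difficulty", "stim_sign", "choice",
           "accuracy", "decision_rt", "confidence_rt", "rating")
  miss <- setdiff(req, names(tab))
  if (length(miss)) stop("missing required column(s): ",
                         paste(miss, collapse = ", "))
  if (nrow(tab) == 0) stop("empty trial table (header only): ", path)
  bad <- which(!tab$rating %in% 1:6)
  if (length(bad)) stop(sprintf("column `rating`: value %s at row %d not in 1..6",
                                tab$rating[bad[1]], bad[1]))
  for (cl in c("decision_rt", "confidence_rt")) {
    bad <- which(!is.finite(tab[[cl]]) | tab[[cl]] < 0)
    if (length(bad)) stop(sprintf("column `%s`: negative or non-finite value at row %d",
                                  cl, bad[1]))
  }
  bad <- which(!tab$choice %in% c(-1, 1) | !tab$stim_sign %in% c(-1, 1))
  if (length(bad)) stop(sprintf("column `choice`/`stim_sign`: value not in {-1, 1} at row %d",
                                bad[1]))
  bad <- which(tab$accuracy != as.integer(tab$choice == tab$stim_sign))
  if (length(bad)) stop(sprintf("column `accuracy`: inconsistent with choice/stim_sign at row %d",
                                bad[1]))
  tab
}

#' Write a trial table to CSV
#'
#' @param table Trial table.
#' @param path Destination path.
#' @return `path`, invisibly.
#' @export
write_trials <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' Read a configuration file (YAML or JSON)
#'
#' Configuration files hold fitting settings recognized by [ldc_control()]
#' (bounds, DE settings, oversample factor, gamma, time convention, ...);
#' unknown keys are rejected.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return An [ldc_control()] object.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  known <- names(formals(ldc_control))
  unknown <- setdiff(names(cfg), known)
  if (length(unknown)) stop("unknown config key(s): ",
                            paste(unknown, collapse = ", "))
  if (!is.null(cfg$bounds)) cfg$bounds <- lapply(cfg$bounds, as.numeric)
  do.call(ldc_control, cfg)
}

#' Serialize a fitted model to JSON (plus optimizer trace as CSV)
#'
#' Writes the fitted parameters, objective value, parameter/data counts,
#' BIC, variant and seed as JSON; if the fit carries an optimizer trace, it
#' is written next to it as `<path>.trace.csv`.
#'
#' @param fit An `"ldc_fit"` object.
#' @param path Destination `.json` path.
#' @return `path`, invisibly.
#' @export
write_fit <- function(fit, path) {
  stopifnot(inherits(fit, "ldc_fit"))
  out <- list(variant = fit$variant, coefficients = as.list(coef(fit)),
              sse = fit$sse, sse_rt = fit$sse_rt, sse_cj = fit$sse_cj,
              k = fit$k, n = fit$n, bic = fit$bic, seed = fit$seed,
              generations = fit$generations, converged = fit$converged,
              conditions = fit$conditions)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  if (!is.null(fit$trace)) {
    utils::write.csv(fit$trace, paste0(path, ".trace.csv"),
                     row.names = FALSE)
  }
  invisible(path)
}
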