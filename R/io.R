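# Table input, result output.

# round-half-up to the nearest multiple of `granularity`
round_half_up <- function(x, granularity) {
  floor(x / granularity + 0.5) * granularity
}

#' Read a long-format time course from a CSV/TSV file
#'
#' One row per observation.  The separator is taken from the file
#' extension (`.csv` = comma, anything else = tab) unless given.  An
#' optional rounding granularity coarsens the time variable (round-half-up
#' to the nearest multiple) before grouping -- e.g. granularity 5 maps an
#' OGTT value of 103 to 105 and 102 to 100.
#'
#' @param path input file.
#' @param time_col,response_col column names.
#' @param mode `"continuous"` or `"binary"`.
#' @param granularity optional rounding granularity for the time variable.
#' @param sep field separator; default inferred from the extension.
#' @return a [time_course()].
#' @export
read_timecourse <- function(path, time_col = "time", response_col = "y",
                            mode = "continuous", granularity = NULL,
                            sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(df) == 0) stop("empty file: ", path, call. = FALSE)
  for (col in c(time_col, response_col))
    if (!col %in% names(df))
      stop(sprintf("column '%s' not found in %s", col, path), call. = FALSE)
  tm <- df[[time_col]]; rs <- df[[response_col]]
  bad <- which(!is.finite(suppressWarnings(as.numeric(tm))) |
               !is.finite(suppressWarnings(as.numeric(rs))))
  if (length(bad))
    stop(sprintf("unparseable numeric value at data row %d", bad[1]),
         call. = FALSE)
  tm <- as.numeric(tm); rs <- as.numeric(rs)
  if (!is.null(granularity)) tm <- round_half_up(tm, granularity)
  time_course(tm, rs, mode = mode)
}

#' Write fit (and optional inference) results to files
#'
#' Writes `<prefix>_blocks.tsv` (one row per block: index range, time range,
#' observation count, estimate, and the p-value of the junction with the
#' next block), `<prefix>_pointwise.tsv` (time, estimate, optional CI
#' bounds) and `<prefix>_summary.json` (alpha, method, objective,
#' sigma2_hat, change-points, optional F statistic and permutation p-value,
#' seeds, package version), all at full precision.
#'
#' @param fit an `ap_fit`.
#' @param prefix output path prefix.
#' @param perm optional `ap_permtest`.
#' @param boot optional `ap_bootstrap`.
#' @return invisibly, the paths written.
#' @export
write_results <- function(fit, prefix, perm = NULL, boot = NULL) {
  paths <- c(blocks = paste0(prefix, "_blocks.tsv"),
             pointwise = paste0(prefix, "_pointwise.tsv"),
             summary = paste0(prefix, "_summary.json"))
  blocks <- fit$blocks
  blocks$next_junction_pvalue <- c(fit$junction_pvalues, NA_real_)
  utils::write.table(format(blocks, digits = 17, trim = TRUE),
                     paths[["blocks"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  pw <- data.frame(time = fit$times, estimate = fit$pointwise_estimates)
  if (!is.null(boot)) { pw$lower <- boot$lower; pw$upper <- boot$upper }
  utils::write.table(format(pw, digits = 17, trim = TRUE),
                     paths[["pointwise"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  summ <- list(package = "adpart",
               version = as.character(utils::packageVersion("adpart")),
               method = fit$method, mode = fit$mode, alpha = fit$alpha,
               alternative = fit$spec$alternative,
               n_blocks = nrow(fit$blocks), objective = fit$objective,
               sigma2_hat = fit$sigma2_hat,
               change_points = as.list(fit$change_points),
               feasible = fit$feasible)
  if (!is.null(perm))
    summ$permutation <- list(f_observed = perm$f_observed,
                             pvalue = perm$pvalue, B = perm$B,
                             seed = perm$seed,
                             conservative = perm$conservative)
  if (!is.null(boot))
    summ$bootstrap <- list(level = boot$level, B = boot$B, seed = boot$seed)
  jsonlite::write_json(summ, paths[["summary"]], auto_unbox = TRUE,
                       digits = I(17), null = "null")
  invisible(paths)
}
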