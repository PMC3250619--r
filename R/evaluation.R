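#' Summarise estimator bias
#'
#' Per-group mean bias with standard error and a t-based 95% confidence
#' interval, from the raw results of [run_scenario_grid()]. Rows with a
#' missing estimate (unresolved selection rules or estimator failures) are
#' excluded and counted. Because every method is applied to the same
#' simulated datasets, confidence intervals of different methods share the
#' dataset effect and are therefore correlated across rows.
#'
#' @param results Raw results tibble (needs a `bias` column plus the
#'   grouping columns).
#' @param group_by Character vector of grouping columns (default
#'   `"method"`).
#' @param conf_level Confidence level of the interval.
#' @return Tibble with `mean_bias`, `se`, `lb`, `ub`, `n_datasets`,
#'   `n_missing`, sorted by descending mean bias within groups; groups with
#'   fewer than 2 observations get `NA` intervals.
#' @export
bias_summary <- function(results, group_by = "method", conf_level = 0.95) {
  if (nrow(results) == 0L)
    stop_genecut("empty results table", "genecut_argument_error")
  q <- 1 - (1 - conf_level) / 2
  results |>
    dplyr::group_by(dplyr::across(dplyr::all_of(group_by))) |>
    dplyr::summarise(
      n_missing = sum(is.na(.data$bias)),
      n_datasets = sum(!is.na(.data$bias)),
      mean_bias = mean(.data$bias, na.rm = TRUE),
      se = stats::sd(.data$bias, na.rm = TRUE) / sqrt(.data$n_datasets),
      .groups = "drop") |>
    dplyr::mutate(
      tcrit = ifelse(.data$n_datasets >= 2L,
                     stats::qt(q, pmax(.data$n_datasets - 1L, 1L)),
                     NA_real_),
      lb = .data$mean_bias - .data$tcrit * .data$se,
      ub = .data$mean_bias + .data$tcrit * .data$se) |>
    dplyr::select(-"tcrit") |>
    dplyr::arrange(dplyr::across(dplyr::all_of(setdiff(group_by, "method"))),
                   dplyr::desc(.data$mean_bias))
}

#' Render a bias-summary report
#'
#' @param summaries Tibble from [bias_summary()].
#' @param format `"tsv"` or `"markdown"`.
#' @param path Optional file to write to.
#' @return The rendered document as a character string (invisibly when
#'   written to file).
#' @export
benchmark_report <- function(summaries, format = c("tsv", "markdown"),
                             path = NULL) {
  format <- match.arg(format)
  if (nrow(summaries) == 0L)
    stop_genecut("empty summary table", "genecut_argument_error")
  num <- vapply(summaries, is.numeric, logical(1))
  fmt <- summaries
  fmt[num] <- lapply(fmt[num], function(v)
    ifelse(is.na(v), "NA",
           ifelse(v == round(v), format(v, trim = TRUE),
                  sprintf("%.2f", v))))
  fmt[] <- lapply(fmt, as.character)
  doc <- if (format == "tsv") {
    paste(c(paste(names(fmt), collapse = "\t"),
            apply(fmt, 1L, paste, collapse = "\t")), collapse = "\n")
  } else {
    header <- paste0("| ", paste(names(fmt), collapse = " | "), " |")
    rule <- paste0("|", paste(rep("---", ncol(fmt)), collapse = "|"), "|")
    body <- apply(fmt, 1L, function(r)
      paste0("| ", paste(r, collapse = " | "), " |"))
    paste(c(header, rule, body,
            "",
            paste("Note: methods share simulated datasets, so",
                  "confidence intervals are correlated across methods.")),
          collapse = "\n")
  }
  if (!is.null(path)) {
    writeLines(doc, path)
    return(invisible(doc))
  }
  doc
}
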