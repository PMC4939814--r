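#' Render a catastrophic-payment table
#'
#' Lays out a list of [catastrophic_measures()] results as the field's
#' standard report: measure rows by threshold columns, covering head
#' count, concentration index of the incidence, rank-weighted head count,
#' mean overshoot, concentration index of the overshoot, rank-weighted
#' overshoot and mean positive overshoot. Percentages are rounded only at
#' render time (text format); the underlying data frame and JSON keep full
#' precision.
#'
#' @param results list of `catastrophic_result` (e.g. from
#'   [catastrophic_table()]).
#' @param format `"data"` (tibble, full precision), `"csv"`, `"json"` or
#'   `"text"`.
#' @param path output file for `"csv"`/`"json"` (required); ignored
#'   otherwise.
#' @return the tibble (data/csv), JSON string (json), or character vector
#'   of table lines (text), invisibly for file outputs.
#' @export
render_catastrophic <- function(results, format = c("data", "csv", "json", "text"),
                                path = NULL) {
  format <- match.arg(format)
  if (length(results) == 0) abort("empty result list", class = "finprot_input_error")
  measures <- c(head_count = "head_count", ci_incidence = "ci_incidence",
                weighted_head_count = "weighted_head_count",
                mean_overshoot = "mean_overshoot", ci_overshoot = "ci_overshoot",
                weighted_overshoot = "weighted_overshoot",
                mean_positive_overshoot = "mpo")
  cols <- lapply(results, function(r) {
    setNames(vapply(measures, function(m) r[[m]], numeric(1)), names(measures))
  })
  labels <- vapply(results, function(r) {
    sprintf("%s_%g", ifelse(r$denominator == "total_expenditure", "total", "ctp"),
            100 * r$threshold)
  }, character(1))
  tab <- tibble::tibble(measure = names(measures))
  for (i in seq_along(cols)) tab[[labels[i]]] <- unname(cols[[i]])
  .emit_table(tab, format, path,
              percent_rows = !grepl("^ci_", tab$measure))
}

#' Render an impoverishment comparison
#'
#' Gross / net / absolute / relative columns per measure, one panel per
#' poverty line, mirroring the standard pre/post-OOP poverty table.
#'
#' @param comparisons one `impoverishment_comparison` or a list of them
#'   (one per poverty line).
#' @inheritParams render_catastrophic
#' @export
render_impoverishment <- function(comparisons, format = c("data", "csv", "json", "text"),
                                  path = NULL) {
  format <- match.arg(format)
  if (inherits(comparisons, "impoverishment_comparison"))
    comparisons <- list(comparisons)
  if (length(comparisons) == 0) abort("empty result list",
                                      class = "finprot_input_error")
  tabs <- lapply(comparisons, function(cmp) {
    tab <- cmp$table
    tab$line <- cmp$line$label
    tab[, c("line", "measure", "gross", "net", "absolute", "relative")]
  })
  tab <- dplyr::bind_rows(tabs)
  .emit_table(tab, format, path, percent_rows = tab$measure != "gap")
}

.emit_table <- function(tab, format, path, percent_rows = NULL) {
  if (format == "data") return(tab)
  if (format == "csv") {
    if (is.null(path)) abort("path required for csv output",
                             class = "finprot_config_error")
    readr::write_csv(tab, path, progress = FALSE)
    return(invisible(tab))
  }
  if (format == "json") {
    json <- jsonlite::toJSON(tab, dataframe = "rows", digits = NA, na = "null",
                             pretty = TRUE)
    if (!is.null(path)) {
      writeLines(json, path)
      return(invisible(json))
    }
    return(json)
  }
  # text: percentages to 2 decimals, indices to 3
  shown <- tab
  num <- vapply(shown, is.numeric, logical(1))
  for (j in which(num)) {
    vals <- shown[[j]]
    out <- character(length(vals))
    pct <- percent_rows %||% rep(TRUE, length(vals))
    out[pct] <- ifelse(is.na(vals[pct]), "—",
                       sprintf("%.2f %%", 100 * vals[pct]))
    out[!pct] <- ifelse(is.na(vals[!pct]), "—", sprintf("%.3f", vals[!pct]))
    shown[[j]] <- out
  }
  lines <- utils::capture.output(print(as.data.frame(shown), row.names = FALSE))
  lines
}

#' Published Mongolia 2012 financial-protection estimates
#'
#' The headline estimates published from the (restricted) Mongolian
#' Household Socio-Economic Survey 2012 financial-protection analysis,
#' shipped as a small reference table: catastrophic head counts,
#' concentration indices and rank-weighted head counts per
#' threshold/denominator, overshoot measures, and the gross/net poverty
#' panel for the national and World Bank lines. Percentages are stored as
#' printed (e.g. `5.5` for 5.5%), indices and MNT amounts on their natural
#' scale. Used by the worked examples and consistency checks of the
#' rank-weighted and poverty-gap arithmetic; the underlying microdata are
#' not included.
#'
#' @return tibble with columns `block`, `measure`, `denominator`,
#'   `threshold_pct`, `line`, `value`, `unit`.
#' @export
published_mongolia2012 <- function() {
  path <- system.file("extdata", "mongolia2012_published_measures.csv",
                      package = "finprot", mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}
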