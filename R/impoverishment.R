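#' Poverty line
#'
#' A per-person, per-period expenditure level below which a person counts
#' as poor, in the same currency units and period as the survey
#' expenditures.
#'
#' @param value positive per-capita amount.
#' @param label free-text label.
#' @return a `poverty_line` list with `value` and `label`.
#' @export
poverty_line <- function(value, label = "custom") {
  if (!is.numeric(value) || length(value) != 1 || value <= 0)
    abort("poverty line must be a single positive number",
          class = "finprot_config_error")
  structure(list(value = as.numeric(value), label = label),
            class = "poverty_line")
}

#' Named poverty-line presets
#'
#' Two lines relevant to the Mongolian 2012 setting ship as presets:
#' `"mongolia_national_2012"`, the national line of 118,668 MNT per person
#' per month, and `"worldbank_190ppp_2012"`, the World Bank $1.90/day (2011
#' PPP) line expressed as 34,769.6 MNT per month at 2012 prices. Any other
#' numeric line can be built with [poverty_line()].
#'
#' @param name preset name.
#' @return a [poverty_line()].
#' @export
poverty_line_preset <- function(name = c("mongolia_national_2012",
                                         "worldbank_190ppp_2012")) {
  name <- match.arg(name)
  switch(name,
         mongolia_national_2012 = poverty_line(118668, name),
         worldbank_190ppp_2012 = poverty_line(34769.6, name))
}

.basis_per_capita <- function(dataset, basis, floor_net_at_zero = FALSE) {
  y <- per_capita_expenditure(dataset, net_of_oop = (basis == "net"))
  if (basis == "net" && floor_net_at_zero) y <- pmax(y, 0)
  y
}

#' Poverty head count
#'
#' Person-weighted fraction of the population below the poverty line:
#' HP = sum(s_i w_i p_i) / sum(s_i w_i), with p_i = 1 when per-capita
#' expenditure (gross, or net of OOP health payments) is strictly below the
#' line. Household OOP is spread evenly over members for the net basis.
#'
#' @param dataset a [survey_dataset()].
#' @param line a [poverty_line()] in the same units as expenditures.
#' @param basis `"gross"` (expenditure as observed) or `"net"`
#'   (expenditure minus OOP health payments).
#' @param weights_mode `"none"` or `"sampling"` (weights multiply household
#'   size in all person-weighted sums).
#' @return head count in `[0, 1]`.
#' @export
poverty_head_count <- function(dataset, line, basis = c("gross", "net"),
                               weights_mode = c("none", "sampling")) {
  basis <- match.arg(basis)
  weights_mode <- match.arg(weights_mode)
  stopifnot(inherits(line, "poverty_line"))
  y <- .basis_per_capita(dataset, basis)
  sw <- dataset$size * (if (weights_mode == "sampling") dataset$weight else 1)
  sum(sw * (y < line$value)) / sum(sw)
}

#' Poverty gap measures
#'
#' Individual gap g_i = p_i * (PL - y_i); the population gap G is the
#' person-weighted mean of g_i over everyone, poor or not. Normalized gap
#' NG = G / PL; normalized mean positive gap NMPG = NG / HP (average
#' shortfall among the poor, as a fraction of the line), undefined when
#' nobody is poor.
#'
#' @inheritParams poverty_head_count
#' @param floor_net_at_zero floor net per-capita expenditure at 0 before
#'   the gap computation (only relevant under permissive validation
#'   policies; default validation makes negatives impossible).
#' @return list with `gap` (currency), `normalized_gap`, `nmpg`,
#'   `nmpg_defined`, `head_count`.
#' @export
poverty_gap <- function(dataset, line, basis = c("gross", "net"),
                        weights_mode = c("none", "sampling"),
                        floor_net_at_zero = FALSE) {
  basis <- match.arg(basis)
  weights_mode <- match.arg(weights_mode)
  stopifnot(inherits(line, "poverty_line"))
  y <- .basis_per_capita(dataset, basis, floor_net_at_zero)
  sw <- dataset$size * (if (weights_mode == "sampling") dataset$weight else 1)
  poor <- y < line$value
  g_i <- ifelse(poor, line$value - y, 0)
  hp <- sum(sw * poor) / sum(sw)
  g <- sum(sw * g_i) / sum(sw)
  list(gap = g,
       normalized_gap = g / line$value,
       nmpg = if (hp > 0) g / (line$value * hp) else NA_real_,
       nmpg_defined = hp > 0,
       head_count = hp)
}

#' All poverty measures for one basis
#'
#' @inheritParams poverty_gap
#' @return a `poverty_result` list: `head_count`, `gap`, `normalized_gap`,
#'   `nmpg`, `nmpg_defined`, `basis`, `line`.
#' @export
poverty_measures <- function(dataset, line, basis = c("gross", "net"),
                             weights_mode = c("none", "sampling"),
                             floor_net_at_zero = FALSE) {
  basis <- match.arg(basis)
  pg <- poverty_gap(dataset, line, basis, weights_mode, floor_net_at_zero)
  structure(list(head_count = pg$head_count, gap = pg$gap,
                 normalized_gap = pg$normalized_gap,
                 nmpg = pg$nmpg, nmpg_defined = pg$nmpg_defined,
                 basis = basis, line = line),
            class = "poverty_result")
}

#' Impoverishing effect of OOP health payments
#'
#' Poverty measured gross and net of OOP health payments, with the absolute
#' (net - gross) and relative ((net - gross) / gross) change per measure.
#' Subtracting OOP can only lower expenditure, so net poverty is at least
#' gross poverty; the difference is the impoverishment attributable to
#' health payments.
#'
#' @inheritParams poverty_gap
#' @return an `impoverishment_comparison`: list with `gross` and `net`
#'   [poverty_measures()] results, a tidy `table` (tibble with one row per
#'   measure: gross, net, absolute, relative), and `line`. Relative changes
#'   are `NA` where the gross measure is 0.
#' @export
impoverishment_effect <- function(dataset, line,
                                  weights_mode = c("none", "sampling"),
                                  floor_net_at_zero = FALSE) {
  weights_mode <- match.arg(weights_mode)
  gross <- poverty_measures(dataset, line, "gross", weights_mode)
  net <- poverty_measures(dataset, line, "net", weights_mode, floor_net_at_zero)
  measures <- c("head_count", "gap", "normalized_gap", "nmpg")
  tab <- tibble::tibble(
    measure = measures,
    gross = unname(vapply(measures, function(m) gross[[m]], numeric(1))),
    net = unname(vapply(measures, function(m) net[[m]], numeric(1))))
  tab$absolute <- tab$net - tab$gross
  tab$relative <- ifelse(tab$gross == 0, NA_real_, tab$absolute / tab$gross)
  structure(list(gross = gross, net = net, table = tab, line = line),
            class = "impoverishment_comparison")
}

#' @export
print.impoverishment_comparison <- function(x, ...) {
  cat(sprintf("<impoverishment_comparison> line = %s (%g per person per period)\n",
              x$line$label, x$line$value))
  print(x$table)
  invisible(x)
}

#' People pushed into poverty by OOP payments
#'
#' Scales the absolute head-count change to a population size supplied by
#' the caller (no national population figure is bundled).
#'
#' @param absolute_head_count_change net-minus-gross head-count change, a
#'   fraction.
#' @param population total population the survey represents.
#' @return number of people, rounded to the nearest integer.
#' @export
impoverished_population <- function(absolute_head_count_change, population) {
  if (!is.numeric(population) || population <= 0)
    abort("population must be positive", class = "finprot_input_error")
  round(absolute_head_count_change * population)
}
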