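#' Assign households to expenditure quintiles
#'
#' Households are sorted by the living-standard variable (ties broken by
#' input order), the cumulative (weighted) share is computed, and each
#' household lands in the quintile containing the midpoint of its weight
#' interval — so with equal weights and distinct values the split is exact
#' fifths, and a household straddling a 20% boundary goes to the quintile
#' holding its midpoint.
#'
#' @param dataset a [survey_dataset()].
#' @param rank_variable `"per_capita_expenditure"` (default) or
#'   `"total_expenditure"`.
#' @param weights_mode `"none"` or `"sampling"`.
#' @return a `quintile_assignment`: list with `quintile` (integer 1..5 per
#'   household, 1 = poorest, input order), `cutoffs` (upper rank-variable
#'   value of quintiles 1–4) and `rank_variable`.
#' @export
assign_quintiles <- function(dataset,
                             rank_variable = c("per_capita_expenditure",
                                               "total_expenditure"),
                             weights_mode = c("none", "sampling")) {
  rank_variable <- match.arg(rank_variable)
  weights_mode <- match.arg(weights_mode)
  if (nrow(dataset) < 5)
    abort("need at least 5 households for quintiles", class = "finprot_input_error")
  x <- switch(rank_variable,
              per_capita_expenditure = per_capita_expenditure(dataset),
              total_expenditure = dataset$total_expenditure)
  w <- if (weights_mode == "sampling") dataset$weight else rep(1, nrow(dataset))
  r <- fractional_rank(x, weights = w)          # midpoint cumulative share
  q <- pmin(floor(r * 5) + 1L, 5L)
  cutoffs <- vapply(1:4, function(k) max(x[q <= k]), numeric(1))
  structure(list(quintile = as.integer(q), cutoffs = cutoffs,
                 rank_variable = rank_variable),
            class = "quintile_assignment")
}

#' Health service utilization by quintile (and overall / strata)
#'
#' Per-group proportion of households reporting use of the indicated
#' service, with counts, plus a Pearson chi-square test of independence
#' (group x indicator) p-value. The test is computed without continuity
#' correction; it is skipped (degenerate flag) when the indicator does not
#' vary.
#'
#' @param dataset a [survey_dataset()].
#' @param assignment a [assign_quintiles()] result matching `dataset`.
#' @param indicator `"outpatient"` (use in the past month) or
#'   `"inpatient"` (past year).
#' @param strata optional extra grouping column, currently `"urban"`.
#' @return list with `table` (tibble: group, n, users, proportion — the
#'   quintile rows plus an "all" row and, with strata, urban/rural rows),
#'   `p_value`, `statistic`, `df` and `degenerate`.
#' @export
utilization_by_group <- function(dataset, assignment,
                                 indicator = c("outpatient", "inpatient"),
                                 strata = NULL) {
  indicator <- match.arg(indicator)
  col <- paste0("used_", indicator)
  if (!col %in% names(dataset) || all(is.na(dataset[[col]])))
    abort(paste0("indicator column '", col, "' absent from dataset"),
          class = "finprot_config_error")
  u <- as.numeric(dataset[[col]])
  q <- assignment$quintile
  stopifnot(length(q) == nrow(dataset))

  grp_row <- function(label, idx) {
    tibble::tibble(group = label, n = length(idx), users = sum(u[idx]),
                   proportion = mean(u[idx]))
  }
  tab <- dplyr::bind_rows(
    grp_row("all", seq_along(u)),
    dplyr::bind_rows(lapply(1:5, function(k) {
      grp_row(paste0("quintile_", k), which(q == k))
    })))
  if (!is.null(strata) && strata == "urban" && "urban" %in% names(dataset)) {
    tab <- dplyr::bind_rows(tab,
      grp_row("urban", which(dataset$urban == 1)),
      grp_row("rural", which(dataset$urban == 0)))
  }

  degenerate <- length(unique(u)) < 2
  if (degenerate) {
    test <- list(p.value = NA_real_, statistic = NA_real_, parameter = NA_real_)
  } else {
    test <- stats::chisq.test(table(q, u), correct = FALSE)
  }
  list(table = tab, p_value = unname(test$p.value),
       statistic = unname(test$statistic), df = unname(test$parameter),
       degenerate = degenerate)
}

#' Mean OOP health payments by quintile
#'
#' (Weighted) mean OOP per quintile and overall, plus the ratio of the
#' richest to the poorest quintile mean — the gradient summary used to
#' describe how OOP spending rises with living standards.
#'
#' @inheritParams utilization_by_group
#' @param weights_mode `"none"` or `"sampling"`.
#' @return list with `table` (tibble: group, n, mean_oop) and
#'   `q5_q1_ratio`.
#' @export
oop_by_quintile <- function(dataset, assignment,
                            weights_mode = c("none", "sampling")) {
  weights_mode <- match.arg(weights_mode)
  q <- assignment$quintile
  stopifnot(length(q) == nrow(dataset))
  w <- if (weights_mode == "sampling") dataset$weight else rep(1, nrow(dataset))
  t <- dataset$oop_health
  wmean <- function(idx) sum(w[idx] * t[idx]) / sum(w[idx])
  tab <- dplyr::bind_rows(
    tibble::tibble(group = "all", n = length(t), mean_oop = wmean(seq_along(t))),
    dplyr::bind_rows(lapply(1:5, function(k) {
      idx <- which(q == k)
      tibble::tibble(group = paste0("quintile_", k), n = length(idx),
                     mean_oop = wmean(idx))
    })))
  q1 <- tab$mean_oop[tab$group == "quintile_1"]
  q5 <- tab$mean_oop[tab$group == "quintile_5"]
  list(table = tab, q5_q1_ratio = if (q1 > 0) q5 / q1 else NA_real_)
}
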