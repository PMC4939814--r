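#' OOP health payment budget shares
#'
#' The share of out-of-pocket health payments in the chosen living-standard
#' denominator: total household expenditure, or capacity to pay (non-food
#' expenditure). Households with zero capacity to pay and zero OOP get a
#' share of 0. When OOP exceeds capacity to pay (possible when food + OOP
#' together exceed total is ruled out, but food + OOP may still leave
#' OOP > non-food), the share is clamped at 1 with a warning so budget
#' shares stay interpretable as fractions.
#'
#' @param dataset a [survey_dataset()].
#' @param denominator `"total_expenditure"` or `"capacity_to_pay"`
#'   (abbreviations `"total"` / `"capacity"` accepted).
#' @return numeric vector of shares in `[0, 1]`, record order.
#' @export
oop_share <- function(dataset, denominator = c("total_expenditure", "capacity_to_pay")) {
  denominator <- .match_denominator(denominator)
  stopifnot(inherits(dataset, "survey_dataset"))
  t <- dataset$oop_health
  den <- if (denominator == "total_expenditure") {
    dataset$total_expenditure
  } else {
    capacity_to_pay(dataset)
  }
  share <- ifelse(t == 0, 0, t / den)
  # floating-point noise (e.g. a CSV round trip of a household capped at
  # its capacity to pay) can push a share a few ULP above 1; only genuine
  # violations are worth a warning
  tiny <- is.finite(share) & share > 1 & share <= 1 + 1e-9
  share[tiny] <- 1
  over <- is.finite(share) & share > 1
  degenerate <- !is.finite(share)      # t > 0 with zero denominator
  if (any(over | degenerate)) {
    warn(paste0(sum(over | degenerate),
                " household(s) with OOP exceeding ", denominator,
                "; shares clamped at 1"))
    share[over | degenerate] <- 1
  }
  share
}

.match_denominator <- function(denominator) {
  denominator <- denominator[1]
  if (denominator %in% c("total", "total_expenditure")) return("total_expenditure")
  if (denominator %in% c("capacity", "capacity_to_pay", "nonfood")) return("capacity_to_pay")
  abort(paste0("unknown denominator: ", denominator), class = "finprot_config_error")
}

#' Catastrophic payment head count
#'
#' Fraction of households whose OOP budget share strictly exceeds the
#' threshold z: H = (1/N) * sum(E_i) with E_i = 1 if share_i > z. With
#' sampling weights, H = sum(w_i E_i) / sum(w_i). Households exactly at the
#' threshold are not counted (strict inequality).
#'
#' @param shares OOP budget shares, e.g. from [oop_share()].
#' @param z threshold fraction in (0, 1).
#' @param weights optional positive sampling weights (default: all 1).
#' @return head count H in `[0, 1]`.
#' @export
head_count <- function(shares, z, weights = NULL) {
  .check_share_args(shares, z, weights)
  w <- weights %||% rep(1, length(shares))
  sum(w * (shares > z)) / sum(w)
}

#' Catastrophic payment overshoot
#'
#' Per-household overshoot O_i = E_i * (share_i - z), its (weighted) mean O
#' over all households, and the mean positive overshoot MPO = O / H, the
#' average excess among only those exceeding the threshold. MPO is
#' undefined when nobody exceeds the threshold (H = 0); it is then returned
#' as `NA` with `mpo_defined = FALSE`.
#'
#' @inheritParams head_count
#' @return list with `household_overshoot` (vector), `mean_overshoot`,
#'   `mpo`, `mpo_defined`.
#' @export
overshoot <- function(shares, z, weights = NULL) {
  .check_share_args(shares, z, weights)
  w <- weights %||% rep(1, length(shares))
  o_i <- ifelse(shares > z, shares - z, 0)
  o <- sum(w * o_i) / sum(w)
  h <- sum(w * (shares > z)) / sum(w)
  list(household_overshoot = o_i,
       mean_overshoot = o,
       mpo = if (h > 0) o / h else NA_real_,
       mpo_defined = h > 0)
}

.check_share_args <- function(shares, z, weights) {
  if (length(shares) == 0) abort("empty share vector", class = "finprot_input_error")
  if (!(z > 0 && z < 1)) abort("threshold z must lie in (0, 1)",
                               class = "finprot_config_error")
  if (!is.null(weights)) {
    if (length(weights) != length(shares))
      abort("weights and shares differ in length", class = "finprot_input_error")
    if (any(weights <= 0)) abort("weights must be positive",
                                 class = "finprot_input_error")
  }
  invisible(TRUE)
}

#' Weighted fractional ranks
#'
#' Fractional rank of each unit in the (weighted) distribution of a
#' living-standard variable: units are sorted ascending (ties broken by
#' input order) and each receives
#' r_i = (cumulative weight of strictly lower-ranked units + w_i / 2) / W.
#' With equal weights this is the familiar (i - 0.5) / N. Under
#' `tie_rank = "average"` tied values share their midpoint rank instead.
#'
#' @param x variable to rank by (e.g. total household expenditure).
#' @param weights optional positive weights.
#' @param tie_rank `"unit"` (per-unit ranks, input-order tie break, default)
#'   or `"average"` (tied values share the weighted midpoint rank).
#' @return numeric vector of ranks in (0, 1), input order.
#' @export
fractional_rank <- function(x, weights = NULL, tie_rank = c("unit", "average")) {
  tie_rank <- match.arg(tie_rank)
  w <- weights %||% rep(1, length(x))
  ord <- order(x)                       # stable: ties keep input order
  ws <- w[ord]
  r_sorted <- (cumsum(ws) - ws / 2) / sum(ws)
  r <- numeric(length(x))
  r[ord] <- r_sorted
  if (tie_rank == "average") {
    r <- stats::ave(r, x, FUN = mean)
  }
  r
}

#' Concentration index
#'
#' C = 2 * cov_w(outcome, r) / mu, where r is the weighted fractional rank
#' of the living-standard variable and mu the weighted mean of the outcome.
#' Positive values indicate the outcome is concentrated among the
#' better-off; for non-negative outcomes C lies in `[-1, 1]`.
#'
#' @param outcome numeric outcome vector (e.g. catastrophic indicator E_i
#'   or overshoot O_i); its weighted mean must be non-zero.
#' @param rank_variable living-standard variable defining the rank.
#' @param weights optional positive weights.
#' @param tie_rank passed to [fractional_rank()].
#' @return the concentration index, a dimensionless scalar.
#' @export
concentration_index <- function(outcome, rank_variable, weights = NULL,
                                tie_rank = c("unit", "average")) {
  n <- length(outcome)
  if (n < 2) abort("need at least 2 units for a concentration index",
                   class = "finprot_input_error")
  if (length(rank_variable) != n)
    abort("outcome and rank_variable differ in length", class = "finprot_input_error")
  w <- weights %||% rep(1, n)
  mu <- sum(w * outcome) / sum(w)
  if (mu == 0) abort("outcome mean is zero; concentration index undefined",
                     class = "finprot_undefined_error")
  r <- fractional_rank(rank_variable, weights = w, tie_rank = tie_rank)
  rbar <- sum(w * r) / sum(w)
  cov_w <- sum(w * (outcome - mu) * (r - rbar)) / sum(w)
  2 * cov_w / mu
}

#' Rank-weighted head count and overshoot
#'
#' Distribution-sensitive variants that weight the poorest household by 2,
#' declining linearly to 0 for the richest: H_w = H * (1 - C_E) and
#' O_w = O * (1 - C_O). A negative concentration index (burden concentrated
#' among the poor) inflates the weighted measure above its unweighted
#' counterpart.
#'
#' @param H head count (fraction).
#' @param O mean overshoot (fraction); may be `NULL` to compute `H_w` only.
#' @param C_E concentration index of the catastrophic indicator.
#' @param C_O concentration index of the overshoot.
#' @return list with `weighted_head_count` and (if `O` given)
#'   `weighted_overshoot`.
#' @export
rank_weighted_measures <- function(H, O = NULL, C_E, C_O = NULL) {
  stopifnot(H >= 0, abs(C_E) <= 1)
  out <- list(weighted_head_count = H * (1 - C_E))
  if (!is.null(O)) {
    stopifnot(O >= 0, abs(C_O) <= 1)
    out$weighted_overshoot <- O * (1 - C_O)
  }
  out
}

#' All catastrophic-payment measures at one threshold
#'
#' Computes shares, head count H, overshoot O and MPO, concentration
#' indices C_E and C_O (ranked by the same living-standard measure used as
#' denominator, household level, unless overridden), and the rank-weighted
#' H_w and O_w.
#'
#' @param dataset a [survey_dataset()].
#' @param z threshold fraction in (0, 1).
#' @param denominator `"total_expenditure"` or `"capacity_to_pay"`.
#' @param weights_mode `"none"` (every household counts once, default) or
#'   `"sampling"` (use the `weight` column).
#' @param rank_by optional override of the ranking variable for the
#'   concentration indices (numeric vector, household order).
#' @return a `catastrophic_result` list: `threshold`, `denominator`,
#'   `head_count`, `ci_incidence`, `weighted_head_count`, `mean_overshoot`,
#'   `ci_overshoot`, `weighted_overshoot`, `mpo`, `mpo_defined`, plus the
#'   per-household `shares`, `exceed_indicator` and `household_overshoot`.
#' @export
catastrophic_measures <- function(dataset, z,
                                  denominator = c("total_expenditure", "capacity_to_pay"),
                                  weights_mode = c("none", "sampling"),
                                  rank_by = NULL) {
  denominator <- .match_denominator(denominator)
  weights_mode <- match.arg(weights_mode)
  w <- if (weights_mode == "sampling") dataset$weight else NULL

  shares <- oop_share(dataset, denominator)
  e <- as.numeric(shares > z)
  h <- head_count(shares, z, w)
  ov <- overshoot(shares, z, w)
  rank_var <- rank_by %||% if (denominator == "total_expenditure") {
    dataset$total_expenditure
  } else {
    capacity_to_pay(dataset)
  }
  c_e <- if (h > 0) concentration_index(e, rank_var, w) else NA_real_
  c_o <- if (ov$mean_overshoot > 0) {
    concentration_index(ov$household_overshoot, rank_var, w)
  } else {
    NA_real_
  }
  rw <- if (h > 0 && ov$mean_overshoot > 0) {
    rank_weighted_measures(h, ov$mean_overshoot, c_e, c_o)
  } else {
    list(weighted_head_count = if (h > 0) h * (1 - c_e) else 0,
         weighted_overshoot = 0)
  }
  structure(list(
    threshold = z, denominator = denominator,
    head_count = h, ci_incidence = c_e,
    weighted_head_count = rw$weighted_head_count,
    mean_overshoot = ov$mean_overshoot, ci_overshoot = c_o,
    weighted_overshoot = rw$weighted_overshoot,
    mpo = ov$mpo, mpo_defined = ov$mpo_defined,
    shares = shares, exceed_indicator = e,
    household_overshoot = ov$household_overshoot
  ), class = "catastrophic_result")
}

#' @export
print.catastrophic_result <- function(x, ...) {
  cat(sprintf("<catastrophic_result> z = %g%% of %s\n", 100 * x$threshold,
              x$denominator))
  cat(sprintf("  H = %.2f%%  C_E = %s  H_w = %.2f%%\n", 100 * x$head_count,
              .fmt_or_na(x$ci_incidence), 100 * x$weighted_head_count))
  cat(sprintf("  O = %.3f%%  C_O = %s  O_w = %.3f%%  MPO = %s\n",
              100 * x$mean_overshoot, .fmt_or_na(x$ci_overshoot),
              100 * x$weighted_overshoot,
              if (x$mpo_defined) sprintf("%.2f%%", 100 * x$mpo) else "undefined"))
  invisible(x)
}

.fmt_or_na <- function(x) if (is.na(x)) "NA" else sprintf("%.3f", x)

#' The study's default threshold grid
#'
#' Thresholds of 5/10/15/25% of total expenditure and 15/25/40% of capacity
#' to pay, the grid conventional in the catastrophic-payment literature.
#'
#' @return tibble with columns `z` and `denominator`.
#' @export
default_thresholds <- function() {
  tibble::tibble(
    z = c(0.05, 0.10, 0.15, 0.25, 0.15, 0.25, 0.40),
    denominator = c(rep("total_expenditure", 4), rep("capacity_to_pay", 3)))
}

#' Catastrophic measures over a threshold grid
#'
#' One [catastrophic_measures()] result per threshold; the default grid is
#' [default_thresholds()].
#'
#' @inheritParams catastrophic_measures
#' @param thresholds data frame with columns `z` and `denominator`.
#' @return list of `catastrophic_result`, one per row of `thresholds`.
#' @export
catastrophic_table <- function(dataset, thresholds = default_thresholds(),
                               weights_mode = c("none", "sampling")) {
  weights_mode <- match.arg(weights_mode)
  if (NROW(thresholds) == 0) abort("empty threshold list",
                                   class = "finprot_input_error")
  lapply(seq_len(nrow(thresholds)), function(i) {
    catastrophic_measures(dataset, thresholds$z[i], thresholds$denominator[i],
                          weights_mode = weights_mode)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
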