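# Independent oracles, deliberately naive implementations.

# Concentration index by the O(N^2) definitional double sum:
# C = sum_ij w_i w_j (y_i - y_j) sgn(r_i - r_j) / (2 W^2 mu),
# where the sign compares positions in the living-standard ordering
# (ascending, ties broken by input order — same ordering contract as the
# implementation, computed independently here via order()).
oracle_concentration_index <- function(y, x, w = rep(1, length(y))) {
  n <- length(y)
  pos <- integer(n)
  pos[order(x)] <- seq_len(n)
  mu <- sum(w * y) / sum(w)
  s <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      s <- s + w[i] * w[j] * (y[i] - y[j]) * sign(pos[i] - pos[j])
    }
  }
  s / (2 * sum(w)^2 * mu)
}

# Direct rank-weighted mean with weights 2 (poorest) declining to 0
# (richest): sum w_i * 2(1 - r_i) * y_i / sum w_i.
oracle_rank_weighted_mean <- function(y, r, w = rep(1, length(y))) {
  sum(w * 2 * (1 - r) * y) / sum(w)
}

# Person-expansion oracle: replicate each household into size identical
# individuals and compute unweighted individual-level poverty measures.
oracle_poverty_expanded <- function(y, size, pl) {
  yi <- rep(y, times = size)
  poor <- yi < pl
  g <- ifelse(poor, pl - yi, 0)
  list(head_count = mean(poor), gap = mean(g))
}

# tiny valid survey tibble for constructing datasets by hand
toy_survey <- function(total, food = total * 0.4, oop = 0, size = 1,
                       weight = 1, ...) {
  survey_dataset(tibble::tibble(
    total_expenditure = total, food_expenditure = food,
    oop_health = oop, size = size, weight = weight, ...))
}

# random valid survey for property tests
random_survey <- function(n, seed, zero_oop = 0.3) {
  withr::with_seed(seed, {
    total <- exp(rnorm(n, 12, 1))
    food <- runif(n, 0.1, 0.8) * total
    cap <- total - food
    oop <- ifelse(runif(n) < zero_oop, 0, runif(n) * cap)
    size <- 1L + rpois(n, 2.5)
    weight <- runif(n, 0.5, 2)
    survey_dataset(tibble::tibble(
      total_expenditure = total, food_expenditure = food,
      oop_health = oop, size = size, weight = weight))
  })
}
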