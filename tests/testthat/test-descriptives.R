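test_that("quintile assignment partitions equal weights exactly", {
  ds <- toy_survey(total = seq(100, 1000, by = 100), food = 10, size = 1)
  a <- assign_quintiles(ds, "total_expenditure")
  expect_equal(as.vector(table(a$quintile)), rep(2, 5))
  expect_equal(a$quintile, rep(1:5, each = 2))
  expect_equal(a$cutoffs, c(200, 400, 600, 800))
  # identical values: assignment by input order, still exact fifths
  ds2 <- toy_survey(total = rep(100, 10), food = 10, size = 1)
  a2 <- assign_quintiles(ds2, "total_expenditure")
  expect_equal(a2$quintile, rep(1:5, each = 2))
  expect_error(assign_quintiles(toy_survey(total = c(1, 2), size = 1)),
               class = "finprot_input_error")
})

test_that("weighted quintiles place a dominant household by its midpoint", {
  # cumulative-weight midpoints: 0.0625, 0.1875, 0.5, 0.8125, 0.9375 —
  # the dominant middle household spans quintiles 2-4 and lands in Q3
  ds <- toy_survey(total = c(10, 20, 30, 40, 50), food = 1, size = 1,
                   weight = c(0.125, 0.125, 0.5, 0.125, 0.125))
  a <- assign_quintiles(ds, "total_expenditure", weights_mode = "sampling")
  expect_equal(a$quintile, c(1L, 1L, 3L, 5L, 5L))
})

test_that("quintile means of the rank variable are non-decreasing", {
  ds <- random_survey(500, seed = 13)
  a <- assign_quintiles(ds)
  pc <- per_capita_expenditure(ds)
  means <- vapply(1:5, function(k) mean(pc[a$quintile == k]), numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("utilization proportions and chi-square test match closed form", {
  # 2x2: group A 30/100 users, group B 70/100 users -> X^2 = 32, df 1
  u <- c(rep(1, 30), rep(0, 70), rep(1, 70), rep(0, 30))
  grp <- rep(c(1, 2), each = 100)
  p_closed <- pchisq(32, df = 1, lower.tail = FALSE)
  tt <- suppressWarnings(stats::chisq.test(table(grp, u), correct = FALSE))
  expect_equal(unname(tt$statistic), 32)
  expect_equal(unname(tt$p.value), p_closed)

  # through the package surface on a 5-group synthetic survey
  ds <- generate_survey(generator_config(n_households = 2000, seed = 99))
  a <- assign_quintiles(ds)
  res <- utilization_by_group(ds, a, "inpatient", strata = "urban")
  expect_equal(res$table$proportion[res$table$group == "all"],
               mean(ds$used_inpatient))
  expect_equal(sum(res$table$users[grepl("quintile", res$table$group)]),
               sum(ds$used_inpatient))
  expect_true(res$p_value >= 0 && res$p_value <= 1)
  expect_true(all(c("urban", "rural") %in% res$table$group))

  # degenerate indicator: no test, flagged
  ds0 <- ds
  ds0$used_inpatient <- 0
  res0 <- utilization_by_group(ds0, a, "inpatient")
  expect_true(res0$degenerate)
  expect_true(is.na(res0$p_value))
  expect_error(utilization_by_group(toy_survey(total = 1:5 * 10, size = 1),
                                    assign_quintiles(toy_survey(total = 1:5 * 10,
                                                                size = 1)),
                                    "inpatient"),
               class = "finprot_config_error")
})

test_that("mean OOP by quintile reports the rich-to-poor gradient", {
  # constructed: Q5 mean exactly 10x Q1 mean
  ds <- toy_survey(total = seq(100, 1000, by = 100), food = 10,
                   oop = c(2, 2, 4, 4, 6, 6, 8, 8, 20, 20), size = 1)
  a <- assign_quintiles(ds, "total_expenditure")
  res <- oop_by_quintile(ds, a)
  expect_equal(res$q5_q1_ratio, 10)
  expect_equal(res$table$mean_oop[res$table$group == "all"], 8)
  # identical OOP everywhere: ratio 1
  ds2 <- toy_survey(total = seq(100, 1000, by = 100), food = 10, oop = 5,
                    size = 1)
  res2 <- oop_by_quintile(ds2, assign_quintiles(ds2, "total_expenditure"))
  expect_true(all(res2$table$mean_oop == 5))
  expect_equal(res2$q5_q1_ratio, 1)
  # overall mean equals the size-weighted mean of group means
  ds3 <- random_survey(200, seed = 3)
  a3 <- assign_quintiles(ds3)
  res3 <- oop_by_quintile(ds3, a3)
  qrows <- res3$table[grepl("quintile", res3$table$group), ]
  expect_equal(sum(qrows$mean_oop * qrows$n) / sum(qrows$n),
               res3$table$mean_oop[res3$table$group == "all"])
})
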