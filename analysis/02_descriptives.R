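#!/usr/bin/env Rscript
# Step 2 — quintile descriptives: service utilization and OOP gradient.
#
# Reads the simulated survey, forms per-capita expenditure quintiles, and
# tabulates outpatient/inpatient use and mean OOP per quintile — the
# descriptive layer of a financial-protection analysis. Writes
# results/utilization_by_quintile.csv and results/oop_by_quintile.csv.

suppressPackageStartupMessages(library(finprot))
suppressPackageStartupMessages(library(dplyr))

ds <- read_survey("results/synthetic_survey.csv", validation_policy = "strict")
assignment <- assign_quintiles(ds)

util <- lapply(c("outpatient", "inpatient"), function(ind) {
  res <- utilization_by_group(ds, assignment, ind, strata = "urban")
  res$table$indicator <- ind
  res$table$p_value <- res$p_value
  res$table
})
util <- bind_rows(util)
readr::write_csv(util, "results/utilization_by_quintile.csv")

oop <- oop_by_quintile(ds, assignment)
readr::write_csv(oop$table, "results/oop_by_quintile.csv")

cat("utilization (share of households using the service):\n")
print(as.data.frame(util[util$group %in% c("all", paste0("quintile_", 1:5)),
                         c("indicator", "group", "n", "proportion")]),
      row.names = FALSE)
cat(sprintf("\nmean OOP overall: %.0f MNT; richest/poorest quintile ratio: %.1f\n",
            oop$table$mean_oop[oop$table$group == "all"], oop$q5_q1_ratio))
cat("wrote results/utilization_by_quintile.csv, results/oop_by_quintile.csv\n")
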