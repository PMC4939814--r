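#!/usr/bin/env Rscript
# Step 4 — impoverishing effect of OOP health payments.
#
# Poverty head count, gap, normalized gap and normalized mean positive
# gap, measured on expenditure gross and net of OOP health payments, at
# the Mongolian national line (118,668 MNT/person/month) and the World
# Bank $1.90/day line (34,769.6 MNT/month at 2012 prices). The net-minus-
# gross difference is the impoverishment attributable to health payments.
# Writes results/impoverishment_table.csv.

suppressPackageStartupMessages(library(finprot))

ds <- read_survey("results/synthetic_survey.csv", validation_policy = "strict")
lines <- list(poverty_line_preset("mongolia_national_2012"),
              poverty_line_preset("worldbank_190ppp_2012"))
cmps <- lapply(lines, function(l) impoverishment_effect(ds, l))

render_impoverishment(cmps, "csv", "results/impoverishment_table.csv")
writeLines(render_impoverishment(cmps, "text"))

nat <- cmps[[1]]
dh <- nat$net$head_count - nat$gross$head_count
cat(sprintf("\nnational line: head count %.2f%% -> %.2f%% (+%.2f points)\n",
            100 * nat$gross$head_count, 100 * nat$net$head_count, 100 * dh))
cat(sprintf("scaled to a population of 2.8 million: %s people pushed into poverty\n",
            format(impoverished_population(dh, 2.8e6), big.mark = ",")))
cat("wrote results/impoverishment_table.csv\n")
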