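#!/usr/bin/env Rscript
# Step 4: minimum-effort design recommendations.
#
# From the agreement results, selects per indicator and confidence level
# the lowest-effort design (total transect length first, then measurement
# count) that is unbiased and within the acceptable-difference criteria,
# along with the Pareto-minimal alternates.

suppressPackageStartupMessages(library(transectopt))

res <- read_results_table("results/results.csv")
rec <- recommend_designs(res)

if (is.null(rec) || nrow(rec) == 0) {
  message("No design meets the criteria for any indicator")
} else {
  primaries <- rec[rec$rank == 1, ]
  for (i in seq_len(nrow(primaries))) {
    p <- primaries[i, ]
    message(sprintf(
      "%-20s @ %.2f: %d x %g m%s (total %g m, %g measurements)",
      p$indicator, p$level, p$n_transects, p$length_m,
      ifelse(is.na(p$interval_m), "", sprintf(" every %g m", p$interval_m)),
      p$total_length_m, p$n_measurements))
  }
  utils::write.csv(rec, "results/recommendations.csv", row.names = FALSE, na = "")
  message("Wrote results/recommendations.csv")
}
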