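#!/usr/bin/env Rscript
# Time-to-deterioration on trajectories whose deterioration hazards cross:
# the experimental arm deteriorates faster early and slower late, so a
# single Cox hazard ratio misrepresents both phases and the PH diagnostic
# flags it. Also shows the threshold-grid interaction: on the 6-step CF
# grid, thresholds 5 and 16 define identical event sets (no achievable
# change lies in between).

library(qlor)

dir.create("results", showWarnings = FALSE)
trial <- generate_crossing_hazards(crossing_config(seed = 20260930L))

t5 <- ttd_analysis(trial, threshold = 5)
cat("Threshold >= 5 points:\n")
print(t5)

r16 <- derive_td(trial, threshold = 16)
cat("\nEvents at threshold 5 vs 16: ", sum(t5$records$event), " vs ",
    sum(r16$event), " (identical on this grid: no achievable step in (5, 16))\n",
    sep = "")

write.csv(t5$records, "results/ttd_records.csv", row.names = FALSE)
jsonlite::write_json(list(median = as.list(t5$median), hr = t5$hr, ph = t5$ph),
                     "results/ttd_result.json", auto_unbox = TRUE)
cat("\nWrote results/ttd_records.csv and results/ttd_result.json\n")
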