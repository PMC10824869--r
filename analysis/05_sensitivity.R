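#!/usr/bin/env Rscript
# Stage 5: one-at-a-time sensitivity analysis.
#
# Each of the four algorithm parameters is perturbed by +/-20% with the
# others at base case and the whole transect-to-reef pipeline rerun. Two
# outputs are tracked: the mean absolute % change in the count of reefs
# containing problematic transects (thresholds with a zero base count are
# excluded from the mean), and the mean absolute change in rank of the
# base-case top-decile reefs. Parameters are then ranked by sensitivity.

library(reefrubble)

out <- "results/sensitivity"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

profiles <- read_profiles("results/data/region_profiles.csv")
oat <- run_oat(profiles)

detail <- do.call(rbind, lapply(names(oat$runs), function(p) {
  cs <- count_sensitivity(oat, p)
  rs <- ranking_sensitivity(oat, p)
  merge(cbind(parameter = p, cs$detail),
        cbind(parameter = p, rs$by_threshold[, c("threshold",
                                                 "mean_abs_change", "se")]),
        by = c("parameter", "threshold"))
}))
write.csv(detail, file.path(out, "oat_detail.csv"), row.names = FALSE)

rk <- rank_parameters(oat)
write.csv(rk, file.path(out, "parameter_ranking.csv"), row.names = FALSE)

cat("Parameter sensitivity ranking (mean |% change| in reef count):\n")
print(rk, row.names = FALSE)
cat("\nA +/-0% sanity scenario reproduces the base case exactly;\n")
cat("see the test suite for the bit-for-bit identity check.\n")
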