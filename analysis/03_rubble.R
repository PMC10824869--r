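#!/usr/bin/env Rscript
# Stage 3: the rubble accumulation algorithm.
#
# Scans every 10-m point of every profile with the base-case moving-window
# decision tree (50-m half-window, 0.5-m rubble height, 5-m roll limit,
# 0.5-m flat limit): rubble is flagged in depressions deep enough to trap a
# problematic rubble layer and on flat sections, never on local highs or
# where the window's relief says rubble would roll off. Points split into
# shallow (< 10 m) and deep sections for per-section cover.

library(reefrubble)

out <- "results/rubble"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

profiles <- read_profiles("results/data/region_profiles.csv")
params <- rubble_params()
print(params)

ev <- evaluate_profiles(profiles, params)
write.csv(ev$points, file.path(out, "point_flags.csv"), row.names = FALSE)
write.csv(ev$summary, file.path(out, "transect_summary.csv"),
          row.names = FALSE)

summ <- ev$summary
cat(sprintf("\nEvaluated %d transects (%d points)\n",
            nrow(summ), nrow(ev$points)))
cat(sprintf("  potential rubble cover: median %.1f%%, mean %.1f%%, max %.1f%%\n",
            median(summ$cover_pct_total), mean(summ$cover_pct_total),
            max(summ$cover_pct_total)))
cat(sprintf("  transects with zero potential cover: %d (%.1f%%)\n",
            sum(summ$cover_pct_total == 0),
            100 * mean(summ$cover_pct_total == 0)))
cat(sprintf("  mean cover, shallow sections: %.1f%%; deep sections: %.1f%%\n",
            mean(summ$cover_pct_shallow, na.rm = TRUE),
            mean(summ$cover_pct_deep, na.rm = TRUE)))
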