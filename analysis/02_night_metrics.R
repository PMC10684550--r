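#!/usr/bin/env Rscript
# Pair each nocturnal CGM window (00:00-06:00) with the next morning's
# sleep score, apply the >=20-readings night QC rule, compute per-night
# glycemic metrics at both hypoglycemia thresholds, and write the tidy
# night table that every downstream analysis consumes.

library(noctglu)

cgm <- read_cgm_csv("results/cohort/cgm.csv")
sleep <- read_sleep_csv("results/cohort/sleep.csv")
participants <- read_participants_csv("results/cohort/participants.csv")

nights <- night_metrics_table(cgm, sleep, participants, verbose = TRUE)
write.csv(nights, "results/nights.csv", row.names = FALSE)

cat(sprintf("night table: %d rows (%d dropped)\n", nrow(nights),
            nrow(attr(nights, "drops"))))
cat(sprintf("NH<3.9 nights: %d (%.1f%%); level 2: %d (%.1f%%)\n",
            sum(nights$nh39_present), 100 * mean(nights$nh39_present),
            sum(nights$nh30_present), 100 * mean(nights$nh30_present)))
cat(sprintf("median NH duration on NH nights: %.0f min\n",
            median(nights$nh39_duration[nights$nh39_present])))
cat("wrote results/nights.csv\n")
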