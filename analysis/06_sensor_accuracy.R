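#!/usr/bin/env Rscript
# Sensor-accuracy assessment: pair capillary meter downloads with the
# nearest sensor reading within 3 min, compute MARD, and assign every
# pair to Clarke and Parkes (type 1) error-grid zones.

library(noctglu)

cgm <- read_cgm_csv("results/cohort/cgm.csv")
capillary <- read_capillary_csv("results/cohort/capillary.csv")

pairs <- pair_readings(capillary, cgm)
cat(sprintf("%d capillary/sensor pairs within 3 min\n", nrow(pairs)))

clarke <- zone_summary(pairs, grid = "clarke")
parkes <- zone_summary(pairs, grid = "parkes_t1")
print(clarke)
print(parkes)

jsonlite::write_json(noctglu:::strip_classes(
  list(clarke = clarke, parkes = parkes)),
  "results/accuracy.json", auto_unbox = TRUE, digits = NA, pretty = TRUE)
cat("wrote results/accuracy.json\n")
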