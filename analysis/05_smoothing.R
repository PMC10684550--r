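#!/usr/bin/env Rscript
# Smooth the sleep score against nocturnal mean glucose with the
# locally weighted running-line smoother and locate slope-sign
# inflections, the night-level analogue of the published curve analysis.

library(noctglu)

nights <- read.csv("results/nights.csv", stringsAsFactors = FALSE)

curve <- lowess_curve(nights$nocturnal_mean, nights$score, frac = 0.8)
infl <- find_inflections(curve)

write.csv(data.frame(nocturnal_mean = curve$x, fitted_score = curve$fitted),
          "results/lowess.csv", row.names = FALSE)
cat(sprintf("smoothed %d distinct glucose values (frac = %.2f)\n",
            length(curve$x), curve$frac))
cat("inflections (mmol/L):",
    if (length(infl)) paste(sprintf("%.2f", infl), collapse = ", ") else "none",
    "\n")
cat("wrote results/lowess.csv\n")
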