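#!/usr/bin/env Rscript
# Descriptive layer: compare level-1-only vs level-2 NH nights across the
# glycemic metrics (t or Kruskal-Wallis by a Shapiro-Wilk normality gate,
# chi-squared for episode-count proportions), correlate the Gold
# hypoglycemia-awareness score with NH parameters (Spearman), and
# summarise sleep score by NH-duration quartile.

library(noctglu)

nights <- read.csv("results/nights.csv", stringsAsFactors = FALSE)

cmp <- compare_nights(nights[nights$nh39_present, ])
for (v in names(cmp)) {
  r <- cmp[[v]]
  cat(sprintf("%-16s %-14s p = %.4g\n", r$variable, r$test, r$p_value))
}

gold <- correlate_gold(nights)
print(gold, digits = 3)

quart <- quartile_sleep_table(nights)
print(quart, digits = 3)
write.csv(quart, "results/quartile_scores.csv", row.names = FALSE)

jsonlite::write_json(
  list(comparisons = noctglu:::strip_classes(cmp),
       gold = gold, quartiles = quart),
  "results/descriptive.json", auto_unbox = TRUE, digits = NA, pretty = TRUE)
cat("wrote results/quartile_scores.csv and results/descriptive.json\n")
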