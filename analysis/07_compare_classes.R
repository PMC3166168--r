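#!/usr/bin/env Rscript
# Compare the fitted two-timescale parameters (a, b, c, d) between the
# high- and low-risk classes: pooled two-sample t-tests with
# Benjamini-Yekutieli FDR control for 4 dependent comparisons (largest-rank
# adjusted critical value 0.024), plus the day-scale slope e. Reads
# results/model_fits.csv (run 06 first); writes
# results/class_comparison.csv.

source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(),
  value = TRUE)[1])), "00_study_design.R"))

fits <- read.csv(file.path(results_dir(), "model_fits.csv"))
cmp <- compare_classes(fits[, c("a", "b", "c", "d")], fits$class,
                       alpha = 0.05)
print(cmp, digits = 3)
cat(sprintf("largest-rank BY critical value (m = 4): %.3f\n",
            by_critical_values(4, 0.05)[4]))

cmp_day <- compare_classes(fits[, "e_day", drop = FALSE], fits$class)
cat("day-scale slope comparison:\n")
print(cmp_day, digits = 3)

write.csv(rbind(cmp, setNames(cmp_day, names(cmp))),
          file.path(results_dir(), "class_comparison.csv"), row.names = FALSE)
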