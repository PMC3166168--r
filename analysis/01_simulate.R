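#!/usr/bin/env Rscript
# Simulate the twelve synthetic populations and write their raw scan
# samples. Finds: 7 high-risk and 5 low-risk observation sets, 120 scans
# each, written as plain CSV under results/observations/.

source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(),
  value = TRUE)[1])), "00_study_design.R"))

pops <- simulate_study(base_seed = 1)
out <- file.path(results_dir(), "observations")
if (!dir.exists(out)) dir.create(out)

for (p in pops) {
  write_observations(p$obs, file.path(out, paste0(p$name, ".csv")))
  cat(sprintf("%s: %d periods, %d membership rows\n",
              p$name, n_periods(p$obs), nrow(p$obs$records)))
}
cat(sprintf("wrote %d populations to %s\n", length(pops), out))
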