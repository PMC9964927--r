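#!/usr/bin/env Rscript
# Step 1: simulate the full stimulation experiment.
#
# Generates a synthetic twin of the experimental design: for every
# treatment (wound, heat shock, combined, control) and tissue (local,
# systemic), paired one-half-hour electrome recordings before and after
# the stimulus, plus one two-hour turgor series per treatment on the
# systemic leaf.  Series go to scratch/sim (large text files); the
# manifest and a compact per-series summary table go to results/.

library(tdaf)

sim_dir <- "scratch/sim"
dir.create("results", showWarnings = FALSE)
dir.create(sim_dir, recursive = TRUE, showWarnings = FALSE)

# Half-hour series keep the workflow light while still covering the
# 10-minute effect window and the reversion that follows it.
params <- electrome_gen_params(duration_s = 1800, seed = 2024L)
manifest <- generate_experiment(2, sim_dir, params = params,
                                turgor_params = turgor_gen_params(seed = 2024L))

summ <- do.call(rbind, lapply(seq_len(nrow(manifest)), function(i) {
  row <- manifest[i, ]
  if (row$kind == "voltage") {
    s <- read_series(file.path(sim_dir, row$file), treatment = row$treatment,
                     tissue = row$tissue, phase = row$phase)
    data.frame(file = row$file, kind = row$kind, class = row$class,
               n = length(s$samples), sd = sd(s$samples),
               peak_uV = max(abs(s$samples)))
  } else {
    ts <- read_turgor(file.path(sim_dir, row$file))
    data.frame(file = row$file, kind = row$kind, class = NA,
               n = length(ts$samples), sd = sd(ts$samples),
               peak_uV = NA)
  }
}))
write.csv(summ, "results/01_series_summary.csv", row.names = FALSE)

cat(sprintf("wrote %d series (%d voltage, %d turgor) to %s\n",
            nrow(manifest), sum(manifest$kind == "voltage"),
            sum(manifest$kind == "turgor"), sim_dir))
cat("per-series summary in results/01_series_summary.csv\n")
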