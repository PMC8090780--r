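#!/usr/bin/env Rscript
# Stage 3: extreme-deviation scoring.
#
# Thresholds each subject's deviation map at |Z| > 1.96 / 2.6 / 3.1 and
# at FDR q = .05, computes per-subject extreme-negative/-positive
# percentages and the top-1% extreme-value summary, and fits a Gumbel
# distribution per group. Run stages 01-02 first.

suppressPackageStartupMessages(library(normdev))

out_dir <- "results/run"
cohort <- read_cohort(file.path(out_dir, "cohort.tsv"))
vs <- read_mask_nifti(file.path(out_dir, "mask.nii.gz"))
Z <- read_maps_nifti(file.path(out_dir, "zmaps_4d.nii.gz"), vs)
rownames(Z) <- cohort$subject_id

scores <- deviation_scores(Z, thresholds = c(1.96, 2.6, 3.1), fdr_q = 0.05)
scores$group <- cohort$group[match(scores$subject, cohort$subject_id)]
write.table(scores, "results/deviation_scores.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

z26 <- scores[scores$threshold == "z2.60", ]
tab <- do.call(rbind, lapply(split(z26, z26$group), function(d)
  data.frame(group = d$group[1],
             pct_neg = sprintf("%.2f +- %.2f", mean(d$pct_negative), sd(d$pct_negative)),
             pct_pos = sprintf("%.2f +- %.2f", mean(d$pct_positive), sd(d$pct_positive)),
             evs = sprintf("%.2f +- %.2f", mean(d$evs_stat), sd(d$evs_stat)))))
cat("Extreme deviations at |Z| > 2.6 (% of in-mask voxels):\n")
print(tab, row.names = FALSE)

ratio <- prevalence_ratio(mean(z26$pct_negative[z26$group == "SZ"]),
                          mean(z26$pct_negative[z26$group == "HC"]))
cat(sprintf("\nExtreme negative deviations are %.2f times more prevalent in SZ than in HC.\n",
            ratio))

# extreme value distribution of the per-subject top-1% statistic
gum <- do.call(rbind, lapply(split(z26, z26$group), function(d) {
  f <- fit_extreme_value_distribution(d$evs_stat)
  data.frame(group = d$group[1], location = round(f$location, 3),
             scale = round(f$scale, 3), loglik = round(f$loglik, 1))
}))
cat("\nGumbel fits to the per-subject extreme-value statistic:\n")
print(gum, row.names = FALSE)
write.table(gum, "results/evs_gumbel_fits.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
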