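#!/usr/bin/env Rscript
# Full-panel breed composition: SNP-BLUP vs supervised admixture EM on the
# purebred and crossbred validation populations; assignment rates,
# per-breed agreement (the purebred and crossbred agreement tables) and
# Bland-Altman statistics.

suppressPackageStartupMessages(library(breedcomp))
dataset <- readRDS("scratch/sim/dataset.rds")
lab <- dataset$validation_purebred$samples$breed

blup_p <- snp_blup_composition(dataset$training,
                               dataset$validation_purebred, seed = 301)
adm_p <- admixture_composition(dataset$training,
                               dataset$validation_purebred)
cat(sprintf("purebred assignment: SNP-BLUP %.1f%%, admixture %.1f%%\n",
            assignment_rate(blup_p, lab), assignment_rate(adm_p, lab)))

blup_c <- snp_blup_composition(dataset$training,
                               dataset$validation_crossbred, seed = 301)
adm_c <- admixture_composition(dataset$training,
                               dataset$validation_crossbred)

overall_p <- composition_agreement(blup_p, adm_p)
overall_c <- composition_agreement(blup_c, adm_c)
cat(sprintf("purebreds:  mean abs diff %.3f (SD %.3f), RMSE %.3f\n",
            overall_p$mean_abs_diff, overall_p$sd_diff, overall_p$rmse))
cat(sprintf("crossbreds: mean abs diff %.3f (SD %.3f), RMSE %.3f\n",
            overall_c$mean_abs_diff, overall_c$sd_diff, overall_c$rmse))
cat(sprintf("Bland-Altman limits (crossbreds): %.3f to %.3f\n",
            overall_c$ba_lower, overall_c$ba_upper))

per_breed_p <- composition_agreement(blup_p, adm_p, scope = "per_breed")
per_breed_c <- composition_agreement(blup_c, adm_c, scope = "per_breed")
write.table(cbind(population = "purebred", per_breed_p),
            "results/agreement_purebred.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(cbind(population = "crossbred", per_breed_c),
            "results/agreement_crossbred.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

# crossbred realized-truth recovery
tf <- dataset$validation_crossbred$true_fractions
dev_blup <- mean(abs(blup_c$proportions - tf))
dev_adm <- mean(abs(adm_c$proportions - tf))
cat(sprintf("mean abs deviation from realized truth: SNP-BLUP %.3f, admixture %.3f\n",
            dev_blup, dev_adm))

rates <- data.frame(
  predictor = c("snp_blup", "admixture"),
  purebred_assignment = c(assignment_rate(blup_p, lab),
                          assignment_rate(adm_p, lab)),
  crossbred_truth_dev = c(dev_blup, dev_adm)
)
write.table(rates, "results/full_panel_rates.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
saveRDS(list(blup_p = blup_p, adm_p = adm_p, blup_c = blup_c,
             adm_c = adm_c), "scratch/full_panel_predictions.rds")

# Bland-Altman figure (differences vs means of the two predictors)
png("scratch/bland_altman.png", width = 900, height = 600)
d <- as.vector(blup_c$proportions - adm_c$proportions)
m <- as.vector((blup_c$proportions + adm_c$proportions) / 2)
plot(m, d, pch = 16, cex = 0.4, col = "#00000044",
     xlab = "mean of SNP-BLUP and admixture proportion",
     ylab = "difference (SNP-BLUP - admixture)",
     main = "Crossbred validation, full panel")
abline(h = overall_c$mean_diff, col = "blue")
abline(h = c(overall_c$ba_lower, overall_c$ba_upper), col = "red")
dev.off()
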