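#!/usr/bin/env Rscript
# Evaluate every low-density panel against the full-panel SNP-BLUP gold
# standard: purebred assignment rate and crossbred main-breed deviation.
# SNP-BLUP is refitted on every panel; the admixture EM is rerun on the
# Fst-highest panels (the strategy the full-density comparison favours).

suppressPackageStartupMessages(library(breedcomp))
dataset <- readRDS("scratch/sim/dataset.rds")
panels <- readRDS("scratch/panels/panels.rds")
gold <- readRDS("scratch/full_panel_predictions.rds")
lab <- dataset$validation_purebred$samples$breed

runs <- list()
for (nm in names(panels)) {
  p <- panels[[nm]]
  runs[[nm]] <- list(
    strategy = p$strategy, density = p$density, predictor = "snp_blup",
    purebred = snp_blup_composition(dataset$training,
                                    dataset$validation_purebred,
                                    panel = p$snp_ids, seed = 501),
    crossbred = snp_blup_composition(dataset$training,
                                     dataset$validation_crossbred,
                                     panel = p$snp_ids, seed = 501)
  )
}
for (nm in grep("^fst_highest", names(panels), value = TRUE)) {
  p <- panels[[nm]]
  runs[[paste0(nm, "_adm")]] <- list(
    strategy = p$strategy, density = p$density, predictor = "admixture",
    purebred = admixture_composition(dataset$training,
                                     dataset$validation_purebred,
                                     panel = p$snp_ids),
    crossbred = admixture_composition(dataset$training,
                                      dataset$validation_crossbred,
                                      panel = p$snp_ids)
  )
}

out <- gold_standard_comparison(runs, gold_purebred = gold$blup_p,
                                gold_crossbred = gold$blup_c,
                                true_labels = lab)
out <- out[order(out$predictor, out$strategy, out$density), ]
write.table(out, "results/panel_comparison.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cat("SNP-BLUP purebred assignment by strategy and density:\n")
print(reshape(out[out$predictor == "snp_blup",
                  c("strategy", "density", "assignment_rate")],
              idvar = "strategy", timevar = "density",
              direction = "wide"), row.names = FALSE)
cat("\nadmixture (fst_highest panels):\n")
print(out[out$predictor == "admixture", ], row.names = FALSE)
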