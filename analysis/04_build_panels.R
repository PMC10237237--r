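#!/usr/bin/env Rscript
# Score SNPs on the SNP-selection population by the five informativeness
# measures and build low-density panels for the seven selection strategies
# at five densities.

suppressPackageStartupMessages(library(breedcomp))
dataset <- readRDS("scratch/sim/dataset.rds")
sel <- dataset$snp_selection

t0 <- Sys.time()
scores <- snp_score_table(
  sel$map,
  fst = score_snps("fst", sel),
  pca = score_snps("pca_weight", sel),
  snpblup_sd = score_snps("snpblup_sd", sel, seed = 401),
  rf = score_snps("rf_vim", sel, seed = 402),
  plsda = score_snps("plsda_weight", sel)
)
cat("scored", nrow(scores), "SNPs by 5 methods in",
    format(Sys.time() - t0), "\n")
write.table(scores, "scratch/snp_scores.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

# rank agreement between methods at the top of the list
top <- lapply(c("fst", "pca", "snpblup_sd", "rf", "plsda"), function(mth) {
  scores$snp_id[order(-scores[[mth]])][1:500]
})
names(top) <- c("fst", "pca", "snpblup_sd", "rf", "plsda")
ov <- outer(names(top), names(top), Vectorize(function(a, b) {
  length(intersect(top[[a]], top[[b]])) / 500
}))
dimnames(ov) <- list(names(top), names(top))
cat("overlap of top-500 SNPs between scoring methods:\n")
print(round(ov, 2))
write.table(round(ov, 3), "results/score_overlap.tsv", sep = "\t",
            quote = FALSE, col.names = NA)

densities <- c(100, 250, 500, 1000, 2000)
strategies <- c("random", "pam_medoid", "fst_highest", "pca_highest",
                "snpblup_sd_highest", "rf_highest", "plsda_highest")
panels <- build_all_panels(scores, densities = densities,
                           strategies = strategies,
                           chrom_lengths = dataset$config$chromosomes$length_bp,
                           seed = 403)
dir.create("scratch/panels", showWarnings = FALSE)
for (nm in names(panels)) {
  write_panel(panels[[nm]], file.path("scratch/panels",
                                      paste0(nm, ".txt")))
}
saveRDS(panels, "scratch/panels/panels.rds")
cat("built", length(panels), "panels (",
    length(strategies), "strategies x", length(densities), "densities )\n")
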