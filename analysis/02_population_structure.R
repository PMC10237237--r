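#!/usr/bin/env Rscript
# Population structure of the simulated breeds: pairwise Fst, the
# neighbour-joining breed tree, LD pruning and GRM-based PCA, and the
# IBS-clustered training selection.

suppressPackageStartupMessages(library(breedcomp))
dataset <- readRDS("scratch/sim/dataset.rds")

pw <- pairwise_fst(dataset$freqs)
off <- pw[upper.tri(pw)]
cat(sprintf("pairwise Fst: min %.3f, median %.3f, max %.3f\n",
            min(off), median(off), max(off)))
write.table(round(pw, 4), "results/pairwise_fst.tsv", sep = "\t",
            quote = FALSE, col.names = NA)

nwk <- neighbor_joining_tree(pw)
writeLines(nwk, "results/breed_tree.nwk")
cat("NJ tree:", substr(nwk, 1, 70), "...\n")

# per-SNP Fst across the 13 breeds (selection-population frequencies)
sel <- dataset$snp_selection
fst <- score_snps("fst", sel)
write.table(
  data.frame(snp_id = sel$map$snp_id, chrom = sel$map$chrom,
             pos = sel$map$pos, fst = round(fst, 5)),
  "scratch/per_snp_fst.tsv", sep = "\t", quote = FALSE, row.names = FALSE)
write.table(
  data.frame(quantile = names(quantile(fst, 0:10 / 10)),
             fst = round(quantile(fst, 0:10 / 10), 5)),
  "results/per_snp_fst_quantiles.tsv", sep = "\t", quote = FALSE,
  row.names = FALSE)
cat(sprintf("per-SNP Fst: mean %.3f, top percentile %.3f\n",
            mean(fst), quantile(fst, 0.99)))

# LD pruning on the purebred validation set (HWE loci: little to prune)
kept <- ld_prune(dataset$validation_purebred)
cat("LD pruning kept", length(kept), "of",
    ncol(dataset$validation_purebred$geno), "SNPs\n")

# GRM PCA of the purebred validation animals
grm <- compute_grm(dataset$validation_purebred)
pca <- pca_from_grm(grm, n_pcs = 5)
cat(sprintf("PC1-3 variance explained: %.1f%% %.1f%% %.1f%%\n",
            100 * pca$var_explained[1], 100 * pca$var_explained[2],
            100 * pca$var_explained[3]))
write.table(
  data.frame(component = seq_along(pca$var_explained),
             var_explained = round(pca$var_explained, 5)),
  "results/pca_variance.tsv", sep = "\t", quote = FALSE, row.names = FALSE)
outliers <- flag_pca_outliers(pca$scores,
                              dataset$validation_purebred$samples$breed)
cat(sum(outliers), "purebred-validation animals flagged as PC outliers\n")

# IBS-clustered diverse training pick (demonstration at k = 50)
sel50 <- select_training_by_ibs(dataset$snp_selection, k = 50, seed = 99)
cat("IBS clustering picked", length(sel50),
    "animals (50 per breed) for a diversity-maximising training set\n")
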