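# Shared small simulated datasets, built once per test file.
.fixture_cache <- new.env(parent = emptyenv())

cached_fixture <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

# Five breeds, three short chromosomes, strong enough divergence that both
# predictors separate breeds cleanly at 1,500 SNPs.
small_dataset <- function() {
  cached_fixture("small", {
    cfg <- sim_config(
      n_breeds = 5, n_snps = 1500,
      chromosomes = default_cattle_autosomes(3, scale = 0.05),
      drift_F = 0.15,
      pop_sizes = c(training = 60, validation = 30, snp_selection = 80),
      cross_designs = list(
        cross_design("AAxCH", "AA", "CH", 40),
        cross_design("AAx(BAxBB)", "AA", c("BA", "BB"), 40)
      ),
      seed = 7
    )
    assemble_study_dataset(cfg)
  })
}

# Hand-sized genotype matrix from explicit values.
toy_genotypes <- function(geno, chrom = NULL, pos = NULL, breed = NULL) {
  geno <- as.matrix(geno)
  n <- nrow(geno); m <- ncol(geno)
  if (is.null(chrom)) chrom <- rep(1L, m)
  if (is.null(pos)) pos <- seq_len(m) * 100L
  map <- data.frame(snp_id = sprintf("s%02d", seq_len(m)), chrom = chrom,
                    pos = pos, a1 = "A", a2 = "B")
  samples <- data.frame(sample_id = sprintf("a%02d", seq_len(n)),
                        breed = if (is.null(breed)) NA_character_ else breed,
                        population = "toy")
  genotype_matrix(geno, map, samples)
}

# Admixture model with explicit frequencies, bypassing estimation.
toy_admixture_model <- function(freq_matrix, eps = 1e-6) {
  breeds <- rownames(freq_matrix)
  if (is.null(breeds)) breeds <- paste0("P", seq_len(nrow(freq_matrix)))
  dimnames(freq_matrix) <- list(breeds, colnames(freq_matrix))
  structure(list(F = freq_matrix, breeds = breeds, K = nrow(freq_matrix),
                 eps = eps, map = NULL),
            class = "admixture_model")
}
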