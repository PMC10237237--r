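test_that("breed frequencies collapse to the ancestral value in the zero-drift limit", {
  cfg <- sim_config(n_breeds = 2, n_snps = 500,
                    chromosomes = default_cattle_autosomes(2, 0.02),
                    drift_F = 1e-9, seed = 3)
  f <- simulate_breed_frequencies(cfg)
  expect_lt(max(abs(sweep(f$freqs, 2, f$ancestral))), 1e-3)
})

test_that("Balding-Nichols breed frequencies are centred on the ancestral frequency", {
  cfg <- sim_config(n_breeds = 3, n_snps = 20000,
                    chromosomes = default_cattle_autosomes(2),
                    drift_F = 0.15, seed = 5)
  f <- simulate_breed_frequencies(cfg)
  dev <- rowMeans(sweep(f$freqs, 2, f$ancestral))
  expect_lt(max(abs(dev)), 0.01)
})

test_that("realized pairwise Fst matches an independent Monte-Carlo estimate", {
  # two breeds with drift F each; the package's pairwise estimator
  # (population variance) has expectation ~ S/(1-S), S = F/2. Oracle:
  # direct rbeta/ratio simulation outside the package, 10 seeds.
  F <- 0.1
  mc <- vapply(1:10, function(s) {
    set.seed(1000 + s)
    p <- runif(10000, 0.05, 0.95)
    sc <- (1 - F) / F
    fa <- rbeta(10000, p * sc, (1 - p) * sc)
    fb <- rbeta(10000, p * sc, (1 - p) * sc)
    pbar <- (fa + fb) / 2
    s2 <- ((fa - pbar)^2 + (fb - pbar)^2) / 2
    ok <- pbar > 0 & pbar < 1
    mean(ifelse(ok, s2 / (pbar * (1 - pbar)), 0))
  }, numeric(1))
  cfg <- sim_config(n_breeds = 2, n_snps = 10000,
                    chromosomes = default_cattle_autosomes(2),
                    drift_F = F, seed = 11)
  f <- simulate_breed_frequencies(cfg)
  realized <- pairwise_fst(f)[1, 2]
  expect_lt(abs(realized - mean(mc)), 0.03)
})

test_that("purebred genotypes follow Binomial(2, f) at fixed and intermediate frequencies", {
  map <- data.frame(snp_id = c("m1", "m2", "m3"), chrom = 1L,
                    pos = c(100L, 200L, 300L), a1 = "A", a2 = "B")
  f <- allele_freq_table(matrix(c(1, 0, 0.5), nrow = 1), "AA", map)
  g <- simulate_purebreds(f, 500, seed = 9)
  expect_true(all(g$geno[, 1] == 2L))
  expect_true(all(g$geno[, 2] == 0L))
  obs_freq <- mean(g$geno[, 3]) / 2
  het <- mean(g$geno[, 3] == 1L)
  expect_lt(abs(obs_freq - 0.5), 0.05)   # well outside exact binomial bounds
  expect_lt(abs(het - 0.5), 0.05)
})

test_that("cross designs carry exact pedigree-expected fractions", {
  ds <- small_dataset()
  cx <- ds$validation_crossbred
  f1 <- cx$samples$breed == "AAxCH"
  expect_true(all(cx$pedigree_fractions[f1, "AA"] == 0.5))
  expect_true(all(cx$pedigree_fractions[f1, "CH"] == 0.5))
  f3 <- cx$samples$breed == "AAx(BAxBB)"
  expect_true(all(cx$pedigree_fractions[f3, "AA"] == 0.5))
  expect_true(all(cx$pedigree_fractions[f3, "BA"] == 0.25))
  expect_true(all(cx$pedigree_fractions[f3, "BB"] == 0.25))
  expect_error(cross_design("bad", "AA", c("A", "B", "C"), 1),
               "unsupported")
})

test_that("realized crossbred fractions: two-way exact, three-way stochastic around 0.25", {
  ds <- small_dataset()
  cx <- ds$validation_crossbred
  f1 <- cx$samples$breed == "AAxCH"
  # purebred parents transmit whole-breed gametes: realized = expected
  expect_true(all(cx$true_fractions[f1, "AA"] == 0.5))
  f3 <- which(cx$samples$breed == "AAx(BAxBB)")
  ba <- cx$true_fractions[f3, "BA"]
  expect_gt(sd(ba), 0)                      # recombination creates variance
  # oracle: re-simulate the F1 gamete's BA share directly from the
  # Haldane model (Poisson crossovers on the linear map), independently
  # of the package's gamete code
  cfg <- ds$config
  set.seed(42)
  sim_share <- replicate(2000, {
    tot <- 0; ba_len <- 0
    for (ci in seq_len(nrow(cfg$chromosomes))) {
      L <- cfg$chromosomes$length_bp[ci]
      morgans <- L / 1e6 * cfg$recomb_rate / 100
      cuts <- sort(runif(rpois(1, morgans), 0, L))
      bounds <- c(0, cuts, L)
      seg <- diff(bounds)
      start <- sample(0:1, 1)
      lab <- (start + seq_along(seg)) %% 2
      ba_len <- ba_len + sum(seg[lab == 1])
      tot <- tot + L
    }
    ba_len / tot / 2     # one of two haplotypes comes from the F1 parent
  })
  expect_lt(abs(mean(ba) - mean(sim_share)), 0.02)
  expect_lt(abs(mean(ba) - 0.25), 0.02)
})

test_that("study dataset bookkeeping: sizes, disjoint ids, determinism, value range", {
  ds <- small_dataset()
  expect_equal(nrow(ds$training$geno), 5 * 60)
  expect_equal(nrow(ds$validation_purebred$geno), 5 * 30)
  expect_equal(nrow(ds$snp_selection$geno), 5 * 80)
  expect_equal(nrow(ds$validation_crossbred$geno), 80)
  ids <- list(ds$training$samples$sample_id,
              ds$validation_purebred$samples$sample_id,
              ds$snp_selection$samples$sample_id,
              ds$validation_crossbred$samples$sample_id)
  for (i in 1:3) for (j in (i + 1):4) {
    expect_length(intersect(ids[[i]], ids[[j]]), 0)
  }
  expect_true(all(ds$training$geno %in% 0:2))
  ds2 <- assemble_study_dataset(ds$config)
  expect_identical(ds2$training$geno, ds$training$geno)
  expect_identical(ds2$validation_crossbred$geno, ds$validation_crossbred$geno)
  # full-scale defaults mirror the study's per-breed population sizes
  full <- sim_config()
  expect_equal(unname(full$pop_sizes[c("training", "validation",
                                       "snp_selection")]),
               c(500, 250, 1000))
})

test_that("study dataset round-trips through PLINK files and the truth sidecar", {
  ds <- small_dataset()
  dir <- tempfile("study")
  write_study_dataset(ds, dir)
  g2 <- read_plink(file.path(dir, "training"))
  expect_equal(unname(g2$geno), unname(ds$training$geno))
  expect_equal(g2$samples$breed, ds$training$samples$breed)
  side <- read.delim(file.path(dir, "samples.tsv"))
  expect_equal(nrow(side), 5 * 60 + 5 * 30 + 5 * 80 + 80)
  cx <- side[side$population == "crossbred_validation", ]
  expect_equal(unname(rowSums(cx[, grep("^breed_fraction_", names(side))])),
               rep(1, nrow(cx)), tolerance = 1e-12)
})

test_that("yaml round-trip reproduces a simulation config", {
  path <- tempfile(fileext = ".yaml")
  writeLines(c(
    "n_breeds: 3", "n_snps: 200",
    "drift_F: [0.1, 0.1, 0.2]",
    "seed: 4",
    "pop_sizes: {training: 10, validation: 5, snp_selection: 5}",
    "cross_designs:",
    "  - {label: AAxAU, sire: AA, dam: AU, n_animals: 6}"
  ), path)
  cfg <- sim_config_from_yaml(path)
  expect_equal(cfg$n_breeds, 3L)
  expect_equal(cfg$drift_F, c(0.1, 0.1, 0.2))
  expect_equal(cfg$cross_designs[[1]]$n_animals, 6L)
  f <- simulate_breed_frequencies(cfg)
  expect_equal(dim(f$freqs), c(3L, 200L))
})
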