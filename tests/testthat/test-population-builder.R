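test_that("ld_prune removes duplicates, keeps independent SNPs, matches brute force", {
  set.seed(41)
  base <- matrix(sample(0:2, 80 * 6, replace = TRUE), 80, 6)
  base[, 4] <- base[, 3]                       # exact duplicate, r2 = 1
  g <- toy_genotypes(base)
  kept <- ld_prune(g, r2_max = 0.5, window = 6, step = 2)
  expect_true("s03" %in% kept)                 # lower-index member retained
  expect_false("s04" %in% kept)
  # mutually independent SNPs survive intact
  set.seed(42)
  indep <- matrix(rbinom(200 * 8, 2, 0.5), 200, 8)
  r2 <- cor(indep)^2
  expect_lt(max(r2[upper.tri(r2)]), 0.1)       # construction is independent
  expect_length(ld_prune(toy_genotypes(indep)), 8)
  # windowless brute-force oracle on a 6-SNP toy
  brute <- function(x, r2_max = 0.5) {
    keep <- rep(TRUE, ncol(x))
    r2 <- suppressWarnings(cor(x))^2
    r2[is.na(r2)] <- 0
    for (j in 2:ncol(x)) {
      if (any(r2[which(keep[1:(j - 1)]), j] > r2_max)) keep[j] <- FALSE
    }
    keep
  }
  set.seed(43)
  z <- matrix(rbinom(60 * 2, 2, 0.5), 60, 2)
  x <- cbind(z, z[, 1], rbinom(60, 2, 0.5), z[, 2], rbinom(60, 2, 0.5))
  g6 <- toy_genotypes(x)
  kept6 <- ld_prune(g6, window = 6, step = 6)
  expect_equal(kept6, g6$map$snp_id[brute(x)])
  # invariant: no surviving within-window pair above the threshold
  sub <- x[, match(kept6, g6$map$snp_id)]
  r2s <- suppressWarnings(cor(sub))^2
  expect_lt(max(r2s[upper.tri(r2s)], na.rm = TRUE), 0.5)
})

test_that("GRM matches the standardized hand computation and HWE expectation", {
  # identical samples: off-diagonal equals the diagonal entries
  gi <- toy_genotypes(rbind(c(0L, 1L, 2L), c(0L, 1L, 2L), c(2L, 1L, 0L)))
  grm <- compute_grm(gi)
  expect_equal(grm[1, 2], grm[1, 1])
  # 3-sample, 2-SNP toy against explicit Z Z' / m
  x <- rbind(c(0L, 2L), c(1L, 1L), c(2L, 0L))
  g <- toy_genotypes(x)
  p <- colMeans(x) / 2
  z <- sweep(sweep(x, 2, 2 * p), 2, sqrt(2 * p * (1 - p)), "/")
  expect_equal(compute_grm(g), tcrossprod(z) / 2,
               tolerance = 1e-12, ignore_attr = TRUE)
  # HWE data: mean diagonal ~ 1
  set.seed(44)
  fr <- runif(400, 0.1, 0.9)
  hwe <- toy_genotypes(matrix(rbinom(200 * 400, 2, rep(fr, each = 200)), 200))
  expect_lt(abs(mean(diag(compute_grm(hwe))) - 1), 0.05)
  expect_error(compute_grm(toy_genotypes(matrix(2L, 4, 3))), "monomorphic")
})

test_that("GRM PCA returns eigen fractions and separates simulated breeds", {
  n <- 6
  p <- pca_from_grm(diag(n), n_pcs = 3)
  expect_equal(p$var_explained, rep(1 / n, n))
  v <- c(2, 1, 1, 0.5)
  r1 <- tcrossprod(v)
  p1 <- pca_from_grm(r1, n_pcs = 2)
  expect_equal(p1$var_explained[1], 1)
  expect_equal(p1$var_explained[2], 0, tolerance = 1e-12)
  # breed separation on the shared 5-breed simulation
  ds <- small_dataset()
  grm <- compute_grm(ds$validation_purebred)
  pc <- pca_from_grm(grm, n_pcs = 4)
  lab <- ds$validation_purebred$samples$breed
  cent <- apply(pc$scores, 2, tapply, lab, mean)
  within_sd <- mean(apply(pc$scores, 2, function(s) mean(tapply(s, lab, sd))))
  dists <- dist(cent)
  expect_gt(min(dists), within_sd)
  # nearest-centroid purity
  assigned <- rownames(cent)[apply(pc$scores, 1, function(s) {
    which.min(colSums((t(cent) - s)^2))
  })]
  expect_gt(mean(assigned == lab), 0.99)
})

test_that("IBS distance matches hand values and behaves as a metric", {
  d12 <- function(a, b) {
    g <- toy_genotypes(rbind(a, b))
    as.matrix(ibs_dist(g))[1, 2]
  }
  expect_equal(d12(c(0L, 1L, 2L), c(0L, 1L, 2L)), 0)
  expect_equal(d12(c(0L, 0L), c(2L, 2L)), 1)
  expect_equal(d12(c(0L, 1L, 2L), c(0L, 2L, 2L)), 1 / 6)
  set.seed(45)
  x <- matrix(sample(0:2, 10 * 30, replace = TRUE), 10, 30)
  dm <- as.matrix(ibs_dist(toy_genotypes(x)))
  expect_equal(dm, t(dm))
  expect_true(all(diag(dm) == 0))
  for (i in 1:8) for (j in (i + 1):9) for (k in (j + 1):10) {
    expect_lte(dm[i, k], dm[i, j] + dm[j, k] + 1e-12)
  }
})

test_that("IBS training selection spreads picks across clusters", {
  ds <- small_dataset()
  g <- ds$snp_selection
  sel <- select_training_by_ibs(g, k = 20, seed = 17)
  expect_length(sel, 20 * 5)
  expect_equal(as.vector(table(g$samples$breed[match(sel,
                                                     g$samples$sample_id)])),
               rep(20L, 5))
  # k = n returns every animal
  rows <- which(g$samples$breed == "AA")
  gb <- subset_genotypes(g, samples = rows)
  expect_setequal(select_training_by_ibs(gb, k = length(rows), seed = 1),
                  gb$samples$sample_id)
  # deterministic given seed
  expect_identical(sel, select_training_by_ibs(g, k = 20, seed = 17))
})

test_that("validation membership rules follow the purity and band definitions", {
  pr <- rbind(
    c(0.95, 0.05, 0, 0),      # purebred breed 1
    c(0.50, 0.50, 0, 0),      # two-way, 45-55 band
    c(0.75, 0.22, 0.03, 0),   # two-way, 70-80:20-30 band
    c(0.40, 0.35, 0.23, 0.02),# three-way (fourth < 0.025)
    c(0.40, 0.35, 0.22, 0.03),# fourth breed >= 0.025 -> other
    c(0.60, 0.40, 0, 0),      # outside both two-way bands
    c(0.90, 0.10, 0, 0)       # boundary: purity inclusive
  )
  colnames(pr) <- c("AA", "AU", "BA", "BB")
  out <- build_validation_sets(pr)
  expect_equal(out$class,
               c("purebred", "two_way", "two_way", "three_way", "other",
                 "other", "purebred"))
  expect_equal(out$breed[1], "AA")
  expect_equal(out$breed[7], "AA")
})

test_that("PCA outlier flagging marks a far-displaced animal and only it", {
  set.seed(46)
  scores <- matrix(rnorm(60 * 3), 60, 3)
  lab <- rep(c("A", "B"), each = 30)
  scores[7, 1] <- 40
  flags <- flag_pca_outliers(scores, lab, n_pcs = 3, sd_mult = 4)
  expect_true(flags[7])
  expect_lte(sum(flags), 2)
})
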