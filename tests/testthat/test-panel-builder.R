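test_that("largest-remainder allocation is exact, conservative and warns sensibly", {
  expect_equal(allocate_per_chromosome(8, c(100, 50, 50)), c(4L, 2L, 2L))
  expect_equal(allocate_per_chromosome(7, c(100, 50, 50)), c(3L, 2L, 2L))
  set.seed(81)
  for (i in 1:50) {
    lens <- runif(sample(2:20, 1), 1, 100)
    d <- sample(1:500, 1)
    counts <- suppressWarnings(allocate_per_chromosome(d, lens))
    expect_equal(sum(counts), d)
    expect_true(all(counts >= 0))
  }
  expect_error(allocate_per_chromosome(5, c(0, 0)), "zero total")
  expect_warning(allocate_per_chromosome(2, c(10, 10, 10)), "below")
})

test_that("PAM position clusters match exhaustive-search medoids", {
  res <- pam_position_clusters(c(1, 2, 3, 100, 101, 102), 2)
  expect_setequal(res$medoid_idx, c(2L, 5L))
  expect_equal(res$clustering, c(1, 1, 1, 2, 2, 2))
  # k = n: every SNP its own medoid
  expect_equal(pam_position_clusters(c(5, 9, 14), 3)$medoid_idx, 1:3)
  # k = 1: the 1-D geometric median (middle order statistic)
  expect_equal(pam_position_clusters(c(10, 11, 12, 13, 200), 1)$medoid_idx,
               3L)
  # contract: the returned medoid set is single-swap locally optimal
  # (PAM is a local search; see the exhaustive-match check in the
  # acceptance suite for global agreement on small instances)
  pam_cost <- function(pos, med) {
    sum(vapply(pos, function(x) min(abs(x - pos[med])), numeric(1)))
  }
  set.seed(82)
  for (i in 1:8) {
    pos <- sort(sample(1:1000, sample(4:8, 1)))
    k <- sample(1:3, 1)
    res <- pam_position_clusters(pos, k)
    cost <- pam_cost(pos, res$medoid_idx)
    for (out in res$medoid_idx) {
      for (inn in setdiff(seq_along(pos), res$medoid_idx)) {
        swapped <- c(setdiff(res$medoid_idx, out), inn)
        expect_gte(pam_cost(pos, swapped) + 1e-9, cost)
      }
    }
  }
  expect_error(pam_position_clusters(c(1, 2), 3), "sizing")
})

test_that("SNP scores vanish for monomorphic SNPs and spike on fixed differences", {
  ds <- small_dataset()
  sel <- ds$snp_selection
  # append a monomorphic SNP and a fixed-difference SNP
  n <- nrow(sel$geno)
  mono <- rep(2L, n)
  fixed <- ifelse(sel$samples$breed == "AA", 2L, 0L)
  geno <- cbind(sel$geno[, 1:300], mono, fixed)
  map <- rbind(sel$map[1:300, ],
               data.frame(snp_id = c("mono1", "fix1"), chrom = 3L,
                          pos = max(sel$map$pos) + c(1e5, 2e5),
                          a1 = "A", a2 = "B"))
  g <- genotype_matrix(geno, map, sel$samples)
  fst <- score_snps("fst", g)
  expect_equal(fst[301], 0)
  expect_gte(fst[302], quantile(fst, 0.9))    # top decile by construction
  pca <- score_snps("pca_weight", g)
  expect_equal(pca[301], 0)
  sd_ <- score_snps("snpblup_sd", g, seed = 5)
  expect_equal(sd_[301], 0)
  pls <- score_snps("plsda_weight", g, plsda_ncomp = 3)
  expect_equal(pls[301], 0)
  rf1 <- score_snps("rf_vim", g, seed = 9, num_trees = 60)
  rf2 <- score_snps("rf_vim", g, seed = 9, num_trees = 60)
  expect_identical(rf1, rf2)                  # seeded determinism
  expect_true(all(c(fst, pca, sd_, pls, rf1) >= 0))
  expect_error(score_snps("nope", g))
})

test_that("panel selection follows the block / pam / highest / random pickers", {
  map <- data.frame(snp_id = sprintf("s%02d", 1:10), chrom = 1L,
                    pos = (1:10) * 1000L, a1 = "A", a2 = "B")
  sc <- snp_score_table(map, fst = as.numeric(1:10))
  # block: 2 blocks of 5, max of each half
  p <- select_panel("fst_block", 2, sc, chrom_lengths = 1e4)
  expect_equal(p$snp_ids, c("s05", "s10"))
  # highest: top-2 irrespective of position
  ph <- select_panel("fst_highest", 2, sc, chrom_lengths = 1e4)
  expect_equal(ph$snp_ids, c("s10", "s09"))
  # density = total -> all SNPs, any strategy
  pall <- select_panel("pam_medoid", 10, sc, chrom_lengths = 1e4)
  expect_setequal(pall$snp_ids, map$snp_id)
  # random: seeded reproducibility, different seeds differ
  r1 <- select_panel("random", 4, sc, chrom_lengths = 1e4, seed = 1)
  r2 <- select_panel("random", 4, sc, chrom_lengths = 1e4, seed = 1)
  r3 <- select_panel("random", 4, sc, chrom_lengths = 1e4, seed = 2)
  expect_identical(r1$snp_ids, r2$snp_ids)
  expect_false(identical(r1$snp_ids, r3$snp_ids))
  expect_error(select_panel("fst_highest", 2, sc[, -4]), "score column")
})

test_that("build_all_panels produces 7 x 7 unique-SNP panels with conserved counts", {
  set.seed(83)
  m <- 600
  map <- data.frame(snp_id = sprintf("s%03d", 1:m),
                    chrom = rep(1:3, each = 200),
                    pos = rep(seq_len(200) * 500L, 3), a1 = "A", a2 = "B")
  sc <- snp_score_table(map, fst = runif(m), pca = runif(m),
                        snpblup_sd = runif(m), rf = runif(m),
                        plsda = runif(m))
  densities <- c(10, 20, 30, 50, 80, 120, 200)
  panels <- build_all_panels(sc, densities = densities, seed = 3)
  expect_length(panels, 49)
  for (p in panels) {
    expect_equal(sum(p$per_chrom), p$density)
    expect_length(p$snp_ids, p$density)
    expect_false(anyDuplicated(p$snp_ids) > 0)
  }
  # per-chromosome counts identical across strategies at a given density
  for (d in densities) {
    pc <- lapply(panels[grep(paste0("_", d, "$"), names(panels))],
                 `[[`, "per_chrom")
    for (i in seq_along(pc)) expect_equal(pc[[i]], pc[[1]])
  }
})

test_that("score-ranked and random panels share little overlap at low density", {
  ds <- small_dataset()
  sel <- ds$snp_selection
  sc <- snp_score_table(sel$map, fst = score_snps("fst", sel))
  pf <- select_panel("fst_highest", 100, sc)
  pr <- select_panel("random", 100, sc, seed = 4)
  overlap <- length(intersect(pf$snp_ids, pr$snp_ids)) / 100
  expect_lt(overlap, 0.5)
})

test_that("density above a chromosome's SNP count reallocates with a warning", {
  map <- data.frame(snp_id = sprintf("s%02d", 1:12),
                    chrom = rep(c(1L, 2L), c(2, 10)),
                    pos = c(1:2 * 100L, 1:10 * 100L), a1 = "A", a2 = "B")
  sc <- snp_score_table(map, fst = as.numeric(1:12))
  expect_warning(
    p <- select_panel("fst_highest", 8, sc, chrom_lengths = c(1e6, 1e6)),
    "reallocating")
  expect_equal(sum(p$per_chrom), 8)
  expect_lte(p$per_chrom[["1"]], 2)
})
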