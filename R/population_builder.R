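#' Prune markers in strong linkage disequilibrium
#'
#' Sliding-window LD pruning: within each window of `window` SNPs (slid by
#' `step` SNPs, chromosome boundaries respected), one SNP of every pair with
#' squared Pearson correlation of allele counts above `r2_max` is removed
#' greedily, keeping the lower-index SNP of the pair.
#'
#' @param g A [genotype_matrix()] with markers sorted by chromosome and
#'   position.
#' @param r2_max Squared-correlation threshold (default 0.5).
#' @param window Window size in SNPs (default 50).
#' @param step Window slide in SNPs (default 10).
#' @return Character vector of retained marker ids.
#' @export
ld_prune <- function(g, r2_max = 0.5, window = 50L, step = 10L) {
  stopifnot(inherits(g, "genotype_matrix"))
  keep <- rep(TRUE, ncol(g$geno))
  for (ch in unique(g$map$chrom)) {
    idx <- which(g$map$chrom == ch)
    if (is.unsorted(g$map$pos[idx])) {
      stop("markers must be sorted by position within chromosome")
    }
    starts <- seq(1L, max(1L, length(idx) - 1L), by = step)
    for (s in starts) {
      win <- idx[s:min(s + window - 1L, length(idx))]
      act <- win[keep[win]]
      if (length(act) < 2L) next
      r2 <- suppressWarnings(stats::cor(g$geno[, act, drop = FALSE]))^2
      r2[is.na(r2)] <- 0
      for (j in 2:length(act)) {
        prior <- seq_len(j - 1L)
        alive <- keep[act[prior]]
        if (any(r2[prior[alive], j] > r2_max)) keep[act[j]] <- FALSE
      }
    }
  }
  g$map$snp_id[keep]
}

#' Genomic relationship matrix from standardized allele counts
#'
#' `G = Z Z' / m` with `z_ij = (g_ij - 2 p_j) / sqrt(2 p_j (1 - p_j))`,
#' where `p_j` is the observed sample allele frequency; monomorphic SNPs are
#' skipped. This is the standardized (GCTA-style) construction, so the
#' diagonal averages ~1 on Hardy-Weinberg data.
#'
#' @param g A [genotype_matrix()] without missing genotypes.
#' @return A symmetric matrix with sample ids as dimnames, attribute
#'   `m_used` giving the number of polymorphic SNPs.
#' @export
compute_grm <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"), nrow(g$geno) >= 2)
  if (anyNA(g$geno)) stop("compute_grm requires complete genotypes")
  p <- colMeans(g$geno) / 2
  poly <- p > 0 & p < 1
  if (!any(poly)) stop("degenerate input: all SNPs are monomorphic")
  x <- g$geno[, poly, drop = FALSE]
  pp <- p[poly]
  z <- sweep(sweep(x, 2, 2 * pp), 2, sqrt(2 * pp * (1 - pp)), "/")
  grm <- tcrossprod(z) / sum(poly)
  dimnames(grm) <- list(g$samples$sample_id, g$samples$sample_id)
  attr(grm, "m_used") <- sum(poly)
  grm
}

#' Principal components of a genomic relationship matrix
#'
#' Eigendecomposition of the GRM; scores are eigenvectors scaled by the
#' square root of their eigenvalue, and variance-explained fractions are
#' eigenvalues divided by the trace.
#'
#' @param grm Symmetric relationship matrix.
#' @param n_pcs Number of components to return (< number of samples).
#' @return List with `scores` (samples x `n_pcs`), `var_explained`
#'   (fractions, non-increasing) and `values` (all eigenvalues).
#' @export
pca_from_grm <- function(grm, n_pcs = 10L) {
  if (any(!is.finite(grm))) stop("numeric error: non-finite GRM entries")
  stopifnot(n_pcs < nrow(grm))
  eig <- eigen(grm, symmetric = TRUE)
  scores <- eig$vectors[, seq_len(n_pcs), drop = FALSE] %*%
    diag(sqrt(pmax(eig$values[seq_len(n_pcs)], 0)), n_pcs)
  rownames(scores) <- rownames(grm)
  colnames(scores) <- paste0("PC", seq_len(n_pcs))
  list(scores = scores,
       var_explained = eig$values / sum(eig$values),
       values = eig$values)
}

#' Flag animals deviating from their breed cluster in PC space
#'
#' Animals whose score on any of the first `n_pcs` components lies more
#' than `sd_mult` within-breed standard deviations from their breed
#' centroid are flagged as likely mislabeled purebreds.
#'
#' @param scores PC score matrix (samples x components).
#' @param breed_labels Breed label per sample.
#' @param n_pcs Components examined (default 3).
#' @param sd_mult Deviation threshold in SDs (default 4).
#' @return Logical vector, `TRUE` = outlier.
#' @export
flag_pca_outliers <- function(scores, breed_labels, n_pcs = 3L,
                              sd_mult = 4) {
  out <- rep(FALSE, nrow(scores))
  for (b in unique(breed_labels)) {
    rows <- which(breed_labels == b)
    s <- scores[rows, seq_len(n_pcs), drop = FALSE]
    ctr <- colMeans(s)
    sds <- apply(s, 2, stats::sd)
    sds[sds == 0 | is.na(sds)] <- Inf
    dev <- abs(sweep(s, 2, ctr)) / rep(sds, each = length(rows))
    out[rows] <- apply(dev, 1, max) > sd_mult
  }
  out
}

#' Identity-by-state distance between animals
#'
#' `d = 1 - (mean shared alleles per locus) / 2`; two genotypes sharing
#' both alleles everywhere have distance 0, opposite homozygotes everywhere
#' have distance 1. Equivalent to the mean absolute allele-count difference
#' divided by 2, hence a metric on 0/1/2 vectors.
#'
#' @param g A [genotype_matrix()] without missing genotypes.
#' @return A [stats::dist] object.
#' @export
ibs_dist <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  d <- stats::dist(g$geno, method = "manhattan") / (2 * ncol(g$geno))
  attr(d, "Labels") <- g$samples$sample_id
  d
}

#' Select a genomically diverse training population by IBS clustering
#'
#' Within each breed, animals are clustered on identity-by-state distance
#' (average-linkage hierarchical clustering cut at `k` clusters) and one
#' animal per cluster is drawn uniformly at random, spreading the picks
#' across the breed's genomic diversity.
#'
#' @param g A [genotype_matrix()].
#' @param breed_labels Breed label per sample (defaults to the sample
#'   table's `breed` column).
#' @param k Clusters (= animals picked) per breed; lowered to the breed
#'   size with a warning when a breed is smaller.
#' @param n_pick_per_cluster Animals drawn per cluster (default 1).
#' @param seed Integer seed for the within-cluster draw.
#' @return Character vector of selected sample ids.
#' @export
select_training_by_ibs <- function(g, breed_labels = g$samples$breed,
                                   k = 500L, n_pick_per_cluster = 1L,
                                   seed = NULL) {
  stopifnot(inherits(g, "genotype_matrix"))
  with_seed_opt(seed, {
    picks <- character(0)
    for (b in unique(breed_labels)) {
      rows <- which(breed_labels == b)
      if (!length(rows)) stop("sizing error: empty breed ", b)
      kb <- k
      if (length(rows) < k) {
        warning("breed ", b, ": only ", length(rows),
                " animals; lowering k")
        kb <- length(rows)
      }
      gb <- subset_genotypes(g, samples = rows)
      cl <- if (kb == length(rows)) seq_along(rows) else
        stats::cutree(stats::hclust(ibs_dist(gb), method = "average"), k = kb)
      for (ci in unique(cl)) {
        members <- gb$samples$sample_id[cl == ci]
        n_pick <- min(n_pick_per_cluster, length(members))
        picks <- c(picks, members[sample.int(length(members), n_pick)])
      }
    }
    picks
  })
}

#' Classify animals into validation populations from breed compositions
#'
#' Applies the study's membership rules to a table of breed proportions:
#' animals with any breed proportion at or above `purity_min` are
#' purebred-verified; two-way crossbreds have their two largest fractions in
#' one of the bands 45-55%:45-55%, 70-80%:20-30% (either order) with every
#' other breed below 0.05; three-way crossbreds have three breeds each at or
#' above 0.20 and any fourth breed below 0.025.
#'
#' @param proportions Animals x breeds matrix of proportions on the
#'   simplex (or a [breed_composition()]).
#' @param purity_min Purebred threshold (default 0.90).
#' @return Data frame with columns `sample_id` (when available), `class`
#'   (`"purebred"`, `"two_way"`, `"three_way"` or `"other"`) and `breed`
#'   (the verified breed for purebreds, else `NA`).
#' @export
build_validation_sets <- function(proportions, purity_min = 0.90) {
  if (inherits(proportions, "breed_composition")) {
    ids <- proportions$sample_id
    proportions <- proportions$proportions
  } else {
    ids <- rownames(proportions)
    if (is.null(ids)) ids <- as.character(seq_len(nrow(proportions)))
  }
  breeds <- colnames(proportions)
  cls <- character(nrow(proportions))
  breed <- rep(NA_character_, nrow(proportions))
  for (i in seq_len(nrow(proportions))) {
    p <- sort(proportions[i, ], decreasing = TRUE)
    if (p[1] >= purity_min) {
      cls[i] <- "purebred"
      breed[i] <- breeds[which.max(proportions[i, ])]
    } else if (p[1] >= 0.45 && p[1] <= 0.55 && p[2] >= 0.45 && p[2] <= 0.55 &&
                 all(p[-(1:2)] < 0.05)) {
      cls[i] <- "two_way"
    } else if (p[1] >= 0.70 && p[1] <= 0.80 && p[2] >= 0.20 && p[2] <= 0.30 &&
                 all(p[-(1:2)] < 0.05)) {
      cls[i] <- "two_way"
    } else if (length(p) >= 3 && p[3] >= 0.20 &&
                 (length(p) < 4 || p[4] < 0.025)) {
      cls[i] <- "three_way"
    } else {
      cls[i] <- "other"
    }
  }
  data.frame(sample_id = ids, class = cls, breed = breed)
}
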