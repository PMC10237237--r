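#' Allocate a panel density across chromosomes
#'
#' Splits `density` SNPs over chromosomes proportionally to physical
#' length by largest-remainder rounding: each chromosome gets the floor of
#' its quota `density * L_c / sum(L)`, and the leftover SNPs go one each to
#' the largest fractional remainders (ties broken by chromosome order).
#' The counts always sum to `density` exactly.
#'
#' @param density Total number of SNPs to allocate.
#' @param chrom_lengths Positive chromosome lengths (bp).
#' @return Integer vector of per-chromosome counts.
#' @export
allocate_per_chromosome <- function(density, chrom_lengths) {
  if (sum(chrom_lengths) <= 0) stop("parameter error: zero total length")
  stopifnot(all(chrom_lengths >= 0), density >= 0)
  if (density < length(chrom_lengths)) {
    warning("density below the number of chromosomes; some get 0 SNPs")
  }
  quota <- density * chrom_lengths / sum(chrom_lengths)
  counts <- floor(quota)
  left <- density - sum(counts)
  if (left > 0) {
    take <- order(quota - counts, decreasing = TRUE)[seq_len(left)]
    counts[take] <- counts[take] + 1
  }
  as.integer(counts)
}

#' Cluster SNP positions on one chromosome by k-medoids (PAM)
#'
#' Partitioning-around-medoids on 1-D basepair positions (absolute
#' distance; LD is deliberately ignored). The medoid SNP — the one in the
#' middle of each positional cluster — is what position-based panels
#' select. Deterministic: the PAM build phase is deterministic and the
#' swap phase iterates to a local optimum.
#'
#' @param positions Basepair positions of the SNPs on one chromosome.
#' @param k Number of clusters (<= number of SNPs).
#' @return List with `clustering` (cluster index per input SNP) and
#'   `medoid_idx` (index into `positions` of each cluster's medoid).
#' @export
pam_position_clusters <- function(positions, k) {
  n <- length(positions)
  if (k > n) stop("sizing error: k exceeds the number of SNPs")
  if (k == n) {
    return(list(clustering = seq_len(n), medoid_idx = seq_len(n)))
  }
  fit <- cluster::pam(matrix(as.numeric(positions), ncol = 1), k,
                      metric = "euclidean", pamonce = 5)
  list(clustering = fit$clustering, medoid_idx = as.integer(fit$id.med))
}

#' Score SNPs for breed informativeness
#'
#' Computes one informativeness score per SNP on the SNP-selection
#' population (kept separate from training/validation to avoid selection
#' bias):
#' \describe{
#'   \item{`fst`}{per-SNP Wright Fst across all breeds ([fst_per_snp()]).}
#'   \item{`pca_weight`}{eigenvalue-weighted sum of squared SNP loadings
#'     over the leading `n_components` axes of the standardized-genotype
#'     covariance (B - 1 axes by default: what separates B clusters);
#'     larger between-breed frequency contrasts give larger weights.}
#'   \item{`snpblup_sd`}{the SNP-BLUP model of [snp_blup_composition()] is
#'     fitted once per breed on this population and the score is the
#'     standard deviation of the fitted SNP effect across breeds.}
#'   \item{`rf_vim`}{mean-decrease-in-impurity variable importance of a
#'     seeded random forest classifying breed (`num_trees` trees,
#'     `sqrt(m)` candidate features per split).}
#'   \item{`plsda_weight`}{one-vs-rest partial-least-squares regression on
#'     a +1/-1 breed code, run once per breed with `plsda_ncomp` latent
#'     components; the score is the largest absolute regression
#'     coefficient across breeds.}
#' }
#' Monomorphic SNPs score 0 under every method except `rf_vim` (where they
#' are never split on, hence effectively 0).
#'
#' @param method One of `"fst"`, `"pca_weight"`, `"snpblup_sd"`,
#'   `"rf_vim"`, `"plsda_weight"`.
#' @param g SNP-selection [genotype_matrix()] with breed labels.
#' @param breed_labels Breed label per sample.
#' @param seed Integer seed (random forest and the SNP-BLUP 0-set draws).
#' @param n_components PCA axes used (default number of breeds - 1).
#' @param num_trees Random forest size (default 500).
#' @param plsda_ncomp PLS components per one-vs-rest model (default 10).
#' @param h2 Heritability for the `snpblup_sd` fits (default 0.999).
#' @return Non-negative numeric vector, one score per SNP.
#' @export
score_snps <- function(method, g, breed_labels = g$samples$breed,
                       seed = NULL,
                       n_components = length(unique(breed_labels)) - 1L,
                       num_trees = 500L, plsda_ncomp = 10L, h2 = 0.999) {
  stopifnot(inherits(g, "genotype_matrix"))
  method <- match.arg(method, c("fst", "pca_weight", "snpblup_sd",
                                "rf_vim", "plsda_weight"))
  m <- ncol(g$geno)
  breeds <- sort(unique(breed_labels))
  if (method == "fst") {
    f <- t(vapply(breeds, function(b) {
      colMeans(g$geno[breed_labels == b, , drop = FALSE]) / 2
    }, numeric(m)))
    return(unname(fst_per_snp(f)$per_snp))
  }
  if (method == "pca_weight") {
    p <- colMeans(g$geno) / 2
    poly <- p > 0 & p < 1
    score <- numeric(m)
    z <- sweep(sweep(g$geno[, poly, drop = FALSE], 2, 2 * p[poly]), 2,
               sqrt(2 * p[poly] * (1 - p[poly])), "/")
    eig <- eigen(tcrossprod(z), symmetric = TRUE)
    ncomp <- min(n_components, nrow(z) - 1L)
    proj <- crossprod(z, eig$vectors[, seq_len(ncomp), drop = FALSE])
    score[poly] <- rowSums(proj^2)   # = sum_k lambda_k * loading_jk^2
    return(score)
  }
  if (method == "snpblup_sd") {
    eff <- matrix(0, nrow = m, ncol = length(breeds))
    for (bi in seq_along(breeds)) {
      coding <- build_breed_coding(g$samples$sample_id, breed_labels,
                                   breeds[bi],
                                   seed = if (is.null(seed)) NULL else
                                     seed + bi)
      vc <- variance_components(mean(coding$y), m, h2 = h2)
      X <- g$geno[match(coding$sample_id, g$samples$sample_id), ,
                  drop = FALSE]
      eff[, bi] <- fit_snp_blup(X, coding$y, vc$lambda)$g
    }
    return(apply(eff, 1, stats::sd))
  }
  if (method == "rf_vim") {
    fit <- ranger::ranger(x = g$geno, y = factor(breed_labels),
                          num.trees = num_trees,
                          mtry = max(1L, floor(sqrt(m))),
                          importance = "impurity", num.threads = 1L,
                          seed = if (is.null(seed)) 0L else seed)
    return(pmax(unname(fit$variable.importance), 0))
  }
  # plsda_weight
  p <- colMeans(g$geno) / 2
  poly <- p > 0 & p < 1
  X <- g$geno[, poly, drop = FALSE]
  colnames(X) <- g$map$snp_id[poly]
  score <- numeric(m)
  ncomp <- min(plsda_ncomp, nrow(X) - 1L, ncol(X) - 1L)
  for (b in breeds) {
    y <- ifelse(breed_labels == b, 1, -1)
    fit <- mixOmics::pls(X, y, ncomp = ncomp, mode = "regression")
    bh <- stats::predict(fit, X[1, , drop = FALSE])$B.hat
    coef_b <- abs(bh[, 1, ncomp])
    score[poly] <- pmax(score[poly], coef_b)
  }
  score
}

#' Assemble a SNP score table
#'
#' One row per SNP (id, chromosome, position) plus one column per scoring
#' method, ready for [select_panel()].
#'
#' @param map Marker map of the SNP-selection genotypes.
#' @param ... Named numeric score vectors (e.g. `fst = `, `pca = `), each
#'   of length `nrow(map)`.
#' @return Data frame of class `snp_score_table`.
#' @export
snp_score_table <- function(map, ...) {
  scores <- list(...)
  for (nm in names(scores)) {
    stopifnot(length(scores[[nm]]) == nrow(map),
              all(is.finite(scores[[nm]])), all(scores[[nm]] >= 0))
  }
  out <- cbind(map[, c("snp_id", "chrom", "pos")], scores)
  class(out) <- c("snp_score_table", "data.frame")
  out
}

# Cap per-chromosome counts at availability, redistributing the excess to
# chromosomes with spare capacity (largest-remainder on their lengths).
cap_and_redistribute <- function(counts, avail, lengths) {
  repeat {
    over <- counts > avail
    if (!any(over)) return(counts)
    excess <- sum(counts[over] - avail[over])
    counts[over] <- avail[over]
    spare <- which(counts < avail)
    if (!length(spare)) stop("density exceeds the total number of SNPs")
    warning("panel density exceeds SNPs on some chromosome(s); reallocating")
    add <- allocate_per_chromosome(excess, lengths[spare])
    counts[spare] <- counts[spare] + add
  }
}

#' Select a low-density SNP panel
#'
#' Builds one panel of `density` SNPs. The per-chromosome share is fixed
#' by [allocate_per_chromosome()] (so it is identical across strategies at
#' a given density), then SNPs are picked within each chromosome by the
#' strategy:
#' \describe{
#'   \item{`random`}{seeded uniform draw.}
#'   \item{`pam_medoid`}{the medoid SNP of each positional PAM cluster.}
#'   \item{`<score>_block`}{the chromosome is divided into contiguous
#'     equal-count blocks of SNPs in map order (remainder SNPs appended to
#'     the last blocks) and the highest-scoring SNP of each block is
#'     taken.}
#'   \item{`<score>_pam`}{the highest-scoring SNP within each positional
#'     PAM cluster.}
#'   \item{`<score>_highest`}{the top-scoring SNPs on the chromosome
#'     irrespective of location.}
#' }
#' where `<score>` names a column of `scores` (e.g. `fst`, `pca`,
#' `snpblup_sd`, `rf`, `plsda`). Score ties are broken by lower basepair
#' position. No LD threshold or minimum spacing is applied.
#'
#' @param strategy Strategy name, e.g. `"fst_highest"`.
#' @param density Panel size in SNPs.
#' @param scores A [snp_score_table()].
#' @param chrom_lengths Optional chromosome lengths (bp) for the
#'   allocation, named or ordered by `sort(unique(chrom))`; defaults to
#'   the largest mapped position per chromosome.
#' @param seed Integer seed (random strategy).
#' @return An object of class `panel_spec`: list with `strategy`,
#'   `density`, `snp_ids` and `per_chrom` counts.
#' @export
select_panel <- function(strategy, density, scores, chrom_lengths = NULL,
                         seed = NULL) {
  stopifnot(inherits(scores, "snp_score_table"), density >= 1,
            density <= nrow(scores))
  chroms <- sort(unique(scores$chrom))
  if (is.null(chrom_lengths)) {
    chrom_lengths <- vapply(chroms,
                            function(ch) max(scores$pos[scores$chrom == ch]),
                            numeric(1))
  }
  stopifnot(length(chrom_lengths) == length(chroms))
  score_col <- NULL
  picker <- strategy
  if (!strategy %in% c("random", "pam_medoid")) {
    parts <- regmatches(strategy,
                        regexec("^(.+)_(block|pam|highest)$", strategy))[[1]]
    if (!length(parts)) stop("parameter error: unknown strategy ", strategy)
    score_col <- parts[2]
    picker <- parts[3]
    if (!score_col %in% names(scores)) {
      stop("parameter error: no score column '", score_col, "'")
    }
  }
  avail <- vapply(chroms, function(ch) sum(scores$chrom == ch), integer(1))
  counts <- cap_and_redistribute(
    allocate_per_chromosome(density, chrom_lengths), avail, chrom_lengths)
  with_seed_opt(seed, {
    ids <- character(0)
    for (ci in seq_along(chroms)) {
      n_c <- counts[ci]
      if (n_c == 0L) next
      rows <- scores[scores$chrom == chroms[ci], , drop = FALSE]
      rows <- rows[order(rows$pos), , drop = FALSE]
      sel <- switch(
        picker,
        random = sort(sample.int(nrow(rows), n_c)),
        pam_medoid = pam_position_clusters(rows$pos, n_c)$medoid_idx,
        block = {
          base <- nrow(rows) %/% n_c
          rem <- nrow(rows) %% n_c
          sizes <- c(rep(base, n_c - rem), rep(base + 1L, rem))
          ends <- cumsum(sizes)
          starts <- c(1L, utils::head(ends, -1L) + 1L)
          vapply(seq_len(n_c), function(bk) {
            blk <- starts[bk]:ends[bk]
            blk[order(-rows[[score_col]][blk], rows$pos[blk])[1]]
          }, integer(1))
        },
        pam = {
          cl <- pam_position_clusters(rows$pos, n_c)$clustering
          vapply(seq_len(n_c), function(k) {
            members <- which(cl == k)
            members[order(-rows[[score_col]][members],
                          rows$pos[members])[1]]
          }, integer(1))
        },
        highest = utils::head(order(-rows[[score_col]], rows$pos), n_c)
      )
      ids <- c(ids, rows$snp_id[sel])
    }
    structure(list(strategy = strategy, density = as.integer(density),
                   snp_ids = ids,
                   per_chrom = stats::setNames(counts, chroms)),
              class = "panel_spec")
  })
}

#' @export
print.panel_spec <- function(x, ...) {
  cat(sprintf("panel_spec: %s, %d SNPs on %d chromosome(s)\n",
              x$strategy, x$density, length(x$per_chrom)))
  invisible(x)
}

#' Build panels for every strategy and density
#'
#' @param scores A [snp_score_table()] from the SNP-selection population.
#' @param densities Panel sizes (default the seven study densities
#'   100-7500).
#' @param strategies Strategy names (default the seven headline
#'   strategies).
#' @param chrom_lengths,seed Passed to [select_panel()].
#' @return Named list of `panel_spec` objects (`<strategy>_<density>`);
#'   per-chromosome counts are identical across strategies at a given
#'   density.
#' @export
build_all_panels <- function(scores,
                             densities = c(100, 500, 1000, 2000, 3000,
                                           5000, 7500),
                             strategies = c("random", "pam_medoid",
                                            "fst_highest", "pca_highest",
                                            "snpblup_sd_highest",
                                            "rf_highest", "plsda_highest"),
                             chrom_lengths = NULL, seed = NULL) {
  panels <- list()
  for (s in strategies) {
    for (d in densities) {
      panels[[sprintf("%s_%d", s, d)]] <-
        select_panel(s, d, scores, chrom_lengths = chrom_lengths,
                     seed = seed)
    }
  }
  panels
}

#' Write a panel to a SNP-list file
#'
#' One marker id per line (PLINK `--extract` compatible).
#'
#' @param panel A `panel_spec`.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_panel <- function(panel, path) {
  writeLines(panel$snp_ids, path)
  invisible(path)
}
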