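#' Per-SNP and global Fst across breeds
#'
#' Wright's fixation index from breed allele frequencies:
#' `Fst_j = s2_j / (pbar_j (1 - pbar_j))`, where `s2_j` is the
#' among-breed variance of the allele frequency at SNP j (population
#' variance, i.e. divided by the number of breeds, so that a fixed
#' difference between two breeds gives Fst = 1 exactly) and `pbar_j` the
#' unweighted mean frequency. SNPs fixed across all breeds
#' (`pbar` 0 or 1) get Fst = 0. The global value is by default the
#' unweighted mean of per-SNP values (`global = "mean_of_ratios"`); the
#' ratio-of-means alternative is available.
#'
#' @param freqs An [allele_freq_table()] or breeds x SNPs matrix with at
#'   least two rows.
#' @param global `"mean_of_ratios"` (default) or `"ratio_of_means"`.
#' @return An object of class `fst_result`: list with `per_snp`, `global`,
#'   `s2`, `pbar`.
#' @export
fst_per_snp <- function(freqs, global = c("mean_of_ratios",
                                          "ratio_of_means")) {
  global <- match.arg(global)
  f <- if (inherits(freqs, "allele_freq_table")) freqs$freqs else
    as.matrix(freqs)
  if (nrow(f) < 2) stop("parameter error: Fst needs at least two breeds")
  if (any(f < 0 | f > 1)) stop("frequencies must lie in [0, 1]")
  pbar <- colMeans(f)
  s2 <- colMeans(sweep(f, 2, pbar)^2)   # population variance (/ B)
  denom <- pbar * (1 - pbar)
  per_snp <- ifelse(denom > 0, s2 / denom, 0)
  g <- if (global == "mean_of_ratios") mean(per_snp) else
    sum(s2) / sum(denom)
  structure(list(per_snp = per_snp, global = g, s2 = s2, pbar = pbar),
            class = "fst_result")
}

#' Pairwise Fst matrix between breeds
#'
#' Entry (a, b) is the global Fst of [fst_per_snp()] computed from the
#' two-row frequency table of breeds a and b; the matrix is symmetric with
#' a zero diagonal.
#'
#' @inheritParams fst_per_snp
#' @return Symmetric breeds x breeds matrix.
#' @export
pairwise_fst <- function(freqs, global = "mean_of_ratios") {
  f <- if (inherits(freqs, "allele_freq_table")) freqs$freqs else
    as.matrix(freqs)
  if (nrow(f) < 2) stop("parameter error: Fst needs at least two breeds")
  b <- nrow(f)
  labs <- rownames(f)
  out <- matrix(0, b, b, dimnames = list(labs, labs))
  for (i in seq_len(b - 1)) {
    for (j in (i + 1):b) {
      out[i, j] <- out[j, i] <-
        fst_per_snp(f[c(i, j), , drop = FALSE], global = global)$global
    }
  }
  out
}

#' Neighbor-joining tree from a breed distance matrix
#'
#' Saitou-Nei neighbor joining on a symmetric non-negative distance matrix
#' (e.g. pairwise Fst). Negative branch lengths, which NJ can produce on
#' non-additive inputs, are clamped to zero with the deficit moved to the
#' sibling branch so path lengths through the parent are preserved. Two
#' taxa degenerate to a single split of the distance.
#'
#' @param d Symmetric distance matrix with zero diagonal, or [stats::dist].
#' @param labels Taxon labels (default from `d` dimnames).
#' @return Newick string; the `ape::phylo` tree is attached as attribute
#'   `"tree"` (absent in the 2-taxon case).
#' @export
neighbor_joining_tree <- function(d, labels = NULL) {
  d <- as.matrix(d)
  if (is.null(labels)) labels <- rownames(d)
  if (is.null(labels)) labels <- paste0("t", seq_len(nrow(d)))
  stopifnot(nrow(d) == ncol(d), isTRUE(all.equal(d, t(d))),
            all(diag(d) == 0), all(d >= 0))
  dimnames(d) <- list(labels, labels)
  n <- nrow(d)
  if (n < 2) stop("degenerate input: need at least two taxa")
  if (n == 2) {
    return(sprintf("(%s:%g,%s:%g);", labels[1], d[1, 2] / 2,
                   labels[2], d[1, 2] / 2))
  }
  tree <- ape::nj(stats::as.dist(d))
  neg <- which(tree$edge.length < 0)
  for (e in neg) {
    parent <- tree$edge[e, 1]
    sib <- which(tree$edge[, 1] == parent)
    sib <- sib[sib != e]
    if (length(sib)) {
      tree$edge.length[sib] <- tree$edge.length[sib] + tree$edge.length[e]
    }
    tree$edge.length[e] <- 0
  }
  tree$edge.length[tree$edge.length < 0] <- 0
  structure(ape::write.tree(tree), tree = tree)
}
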