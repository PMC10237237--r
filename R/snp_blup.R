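#' Variance components for the 1/0 breed-indicator trait
#'
#' For a balanced purebred/non-purebred coding, the phenotypic variance of
#' the 1/0 dependent variable is the Bernoulli variance `p * q` (p = share
#' of coded animals that are the target breed). With heritability h2 the
#' genetic and residual variances are `h2 * pq` and `(1 - h2) * pq`, and the
#' ridge parameter of the mixed-model equations is
#' `lambda = sigma_e^2 / (sigma_g^2 / m) = m (1 - h2) / h2` when the total
#' genetic variance is split equally over the m SNPs (`lambda_mode =
#' "per_snp"`, the default, which preserves the SNP-BLUP/GBLUP
#' equivalence), or `(1 - h2) / h2` when each SNP carries the full genetic
#' variance (`"total"`).
#'
#' @param p Fraction of coded animals belonging to the target breed.
#' @param m Number of SNPs fitted.
#' @param h2 Heritability of the indicator trait (default 0.999).
#' @param lambda_mode `"per_snp"` or `"total"`.
#' @return List with `sigma_p2`, `sigma_g2`, `sigma_e2`, `h2`, `m`,
#'   `lambda`.
#' @export
variance_components <- function(p, m, h2 = 0.999,
                                lambda_mode = c("per_snp", "total")) {
  lambda_mode <- match.arg(lambda_mode)
  stopifnot(p > 0, p < 1, m >= 1, h2 > 0, h2 < 1)
  q <- 1 - p
  sigma_p2 <- p * q
  lambda <- (1 - h2) / h2
  if (lambda_mode == "per_snp") lambda <- m * lambda
  list(sigma_p2 = sigma_p2, sigma_g2 = h2 * sigma_p2,
       sigma_e2 = (1 - h2) * sigma_p2, h2 = h2, m = as.integer(m),
       lambda = lambda, lambda_mode = lambda_mode)
}

#' Build the balanced 1/0 coding for one target breed
#'
#' All training animals of the target breed are coded 1. An equal number of
#' animals is coded 0, drawn from the other breeds with per-breed counts
#' differing by at most one; the breeds receiving the remainder are chosen
#' uniformly at random (seeded). Animals outside the coding are excluded
#' from the fit.
#'
#' @param sample_id Character vector of training animal ids.
#' @param breed_labels Breed label per training animal.
#' @param target_breed The breed coded 1.
#' @param seed Integer seed for the 0-set draws.
#' @return List with `sample_id`, `y` (1/0), `target_breed` and
#'   `zero_counts` (animals coded 0 per breed).
#' @export
build_breed_coding <- function(sample_id, breed_labels, target_breed,
                               seed = NULL) {
  stopifnot(length(sample_id) == length(breed_labels))
  ones <- which(breed_labels == target_breed)
  if (!length(ones)) stop("sizing error: no training animals for ",
                          target_breed)
  others <- setdiff(unique(breed_labels), target_breed)
  if (!length(others)) stop("at least two breeds are required")
  n_t <- length(ones)
  base <- n_t %/% length(others)
  rem <- n_t %% length(others)
  with_seed_opt(seed, {
    extra <- if (rem > 0) others[sample.int(length(others), rem)] else
      character(0)
    counts <- stats::setNames(rep(base, length(others)), others)
    counts[extra] <- counts[extra] + 1L
    zeros <- integer(0)
    for (b in others) {
      avail <- which(breed_labels == b)
      if (length(avail) < counts[b]) {
        stop("sizing error: breed ", b, " has ", length(avail),
             " training animals but ", counts[b], " are needed in the 0-set")
      }
      zeros <- c(zeros, avail[sample.int(length(avail), counts[b])])
    }
    idx <- c(ones, zeros)
    list(sample_id = sample_id[idx],
         y = c(rep(1, length(ones)), rep(0, length(zeros))),
         target_breed = target_breed, zero_counts = counts)
  })
}

#' Solve the SNP-BLUP ridge system for one breed
#'
#' Solves the mixed-model equations for intercept and SNP effects,
#' `[[n, 1'X], [X'1, X'X + lambda I]] (mu, g)' = (1'y, X'y)'`, with X the
#' raw 0/1/2 allele-count matrix. Equivalently (after centering),
#' `g = (Xc' Xc + lambda I)^{-1} Xc' yc` and `mu = mean(y) - xbar' g`. The
#' primal (m x m) form is used when m <= n and the dual (n x n) form
#' `g = Xc' (Xc Xc' + lambda I)^{-1} yc` otherwise; the two agree to
#' numerical precision. A constant y (no contrast) yields g = 0 and
#' mu = mean(y) rather than an error.
#'
#' @param X Coded-animals x SNPs matrix of raw allele counts (no missing).
#' @param y 1/0 response aligned with the rows of X.
#' @param lambda Ridge parameter (see [variance_components()]).
#' @param method `"auto"` (default), `"primal"` or `"dual"`.
#' @return List with `mu`, `g` (named per-SNP effects), `lambda`,
#'   `method`.
#' @export
fit_snp_blup <- function(X, y, lambda, method = c("auto", "primal", "dual")) {
  method <- match.arg(method)
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(y), ncol(X) >= 1, lambda > 0)
  if (anyNA(X)) stop("fit_snp_blup requires complete genotypes")
  n <- nrow(X); m <- ncol(X)
  if (method == "auto") method <- if (m > n) "dual" else "primal"
  xbar <- colMeans(X)
  ybar <- mean(y)
  xc <- sweep(X, 2, xbar)
  yc <- y - ybar
  if (all(yc == 0)) {
    g <- stats::setNames(rep(0, m), colnames(X))
    return(list(mu = ybar, g = g, lambda = lambda, method = method))
  }
  if (method == "primal") {
    a <- crossprod(xc)
    diag(a) <- diag(a) + lambda
    g <- drop(solve(a, crossprod(xc, yc)))
  } else {
    k <- tcrossprod(xc)
    diag(k) <- diag(k) + lambda
    alpha <- solve(k, yc)
    g <- drop(crossprod(xc, alpha))
  }
  names(g) <- colnames(X)
  list(mu = ybar - sum(xbar * g), g = g, lambda = lambda, method = method)
}

#' Raw per-breed scores from fitted SNP effects
#'
#' The per-breed SNP effects are multiplied by each animal's allele counts:
#' `score_ib = sum_j x_ij g_jb`, optionally plus the fitted intercept
#' (`score_ib = mu_b + sum_j x_ij g_jb`). The default follows the
#' effects-times-allele-counts rule; adding the intercept recentres scores
#' so training purebreds of the target breed average exactly 1, but also
#' shifts every competitor breed's score upward, which inflates the
#' below-threshold leakage that the 0.05 zeroing must remove.
#'
#' @param effects List of per-breed fits from [fit_snp_blup()], named by
#'   breed.
#' @param g A [genotype_matrix()] containing at least the fitted markers.
#' @param include_intercept Add the fitted intercept (default `FALSE`).
#' @return Animals x breeds matrix of raw, unbounded scores.
#' @export
predict_raw_scores <- function(effects, g, include_intercept = FALSE) {
  stopifnot(inherits(g, "genotype_matrix"), length(effects) >= 1)
  ids <- names(effects[[1]]$g)
  mi <- match(ids, g$map$snp_id)
  if (anyNA(mi)) stop("alignment error: fitted markers absent from genotypes")
  X <- g$geno[, mi, drop = FALSE]
  raw <- vapply(effects, function(e) {
    if (!identical(names(e$g), ids)) {
      stop("alignment error: per-breed fits use different marker sets")
    }
    drop(X %*% e$g) + if (include_intercept) e$mu else 0
  }, numeric(nrow(X)))
  raw <- matrix(raw, nrow = nrow(X),
                dimnames = list(g$samples$sample_id, names(effects)))
  raw
}

#' Post-process raw breed scores into proportions
#'
#' In order: (1) negative scores are clamped to 0; (2) values below
#' `threshold` (default 0.05) are set exactly to 0; (3) the remaining
#' values are divided by their sum so each animal's proportions sum to 1.
#' Animals whose scores all vanish after thresholding are flagged
#' unassignable (all-zero row) rather than raising an error.
#'
#' @param raw Numeric vector (one animal) or animals x breeds matrix of
#'   finite raw scores.
#' @param threshold Zeroing threshold (default 0.05).
#' @return List with `proportions` (same shape as `raw`) and
#'   `unassignable` (logical per animal).
#' @export
postprocess_composition <- function(raw, threshold = 0.05) {
  vec_in <- is.null(dim(raw))
  x <- if (vec_in) matrix(raw, nrow = 1) else as.matrix(raw)
  if (any(!is.finite(x))) stop("raw scores must be finite")
  x[x < 0] <- 0
  x[x < threshold] <- 0
  s <- rowSums(x)
  unassignable <- s == 0
  x[!unassignable, ] <- x[!unassignable, , drop = FALSE] /
    s[!unassignable]
  if (vec_in) x <- drop(x)
  list(proportions = x, unassignable = unassignable)
}

#' Assign a breed from processed proportions
#'
#' Returns the largest-proportion breed if and only if that proportion is
#' at or above `threshold` (boundary inclusive), else `NA` (unassigned).
#'
#' @param proportions Numeric vector (one animal) or animals x breeds
#'   matrix of processed proportions.
#' @param threshold Assignment threshold (default 0.90).
#' @return Character vector of assigned breed labels (`NA` = unassigned);
#'   unnamed index when `proportions` has no breed names.
#' @export
assign_breed <- function(proportions, threshold = 0.90) {
  if (is.null(dim(proportions))) {
    x <- matrix(proportions, nrow = 1,
                dimnames = list(NULL, names(proportions)))
  } else {
    x <- as.matrix(proportions)
  }
  labs <- colnames(x)
  if (is.null(labs)) labs <- as.character(seq_len(ncol(x)))
  top <- max.col(x, ties.method = "first")
  hit <- x[cbind(seq_len(nrow(x)), top)] >= threshold
  ifelse(hit, labs[top], NA_character_)
}

#' Full SNP-BLUP breed-composition pipeline
#'
#' Fits one ridge system per breed on the training population (balanced
#' 1/0 coding, heritability `h2`), scores the test animals, post-processes
#' the scores (clamp, zero below 0.05, rescale) and assigns breeds at the
#' 0.90 threshold.
#'
#' @param train Training [genotype_matrix()] with breed labels in its
#'   sample table.
#' @param test Test [genotype_matrix()] on (a superset of) the same
#'   markers.
#' @param panel Optional character vector of marker ids to restrict the
#'   fit and prediction to (a low-density panel); default all markers.
#' @param h2 Heritability of the indicator trait (default 0.999).
#' @param lambda_mode See [variance_components()].
#' @param include_intercept See [predict_raw_scores()].
#' @param zero_threshold,assign_threshold Post-processing thresholds.
#' @param seed Integer seed for the per-breed 0-set draws.
#' @return A [breed_composition()] for the test animals.
#' @export
snp_blup_composition <- function(train, test, panel = NULL, h2 = 0.999,
                                 lambda_mode = "per_snp",
                                 include_intercept = FALSE,
                                 zero_threshold = 0.05,
                                 assign_threshold = 0.90, seed = NULL) {
  stopifnot(inherits(train, "genotype_matrix"),
            inherits(test, "genotype_matrix"))
  if (!is.null(panel)) {
    train <- subset_genotypes(train, markers = panel)
    test <- subset_genotypes(test, markers = panel)
  }
  breeds <- sort(unique(train$samples$breed))
  m <- ncol(train$geno)
  effects <- list()
  for (bi in seq_along(breeds)) {
    coding <- build_breed_coding(train$samples$sample_id,
                                 train$samples$breed, breeds[bi],
                                 seed = if (is.null(seed)) NULL else
                                   seed + bi)
    vc <- variance_components(mean(coding$y), m, h2 = h2,
                              lambda_mode = lambda_mode)
    X <- train$geno[match(coding$sample_id, train$samples$sample_id), ,
                    drop = FALSE]
    effects[[breeds[bi]]] <- fit_snp_blup(X, coding$y, vc$lambda)
  }
  raw <- predict_raw_scores(effects, test,
                            include_intercept = include_intercept)
  post <- postprocess_composition(raw, threshold = zero_threshold)
  breed_composition(raw, post$proportions,
                    assign_breed(post$proportions, assign_threshold),
                    post$unassignable, test$samples$sample_id)
}
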