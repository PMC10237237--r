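#' Fix breed allele frequencies from labelled purebreds
#'
#' The supervised admixture model freezes per-breed reference allele
#' frequencies at their observed values in the labelled purebred training
#' animals: `f_kj = (sum of allele counts in breed k at SNP j) / (2 n_k)`,
#' clamped to `[eps, 1 - eps]` so the binomial log-likelihood stays finite.
#'
#' @param g Training [genotype_matrix()] of labelled purebreds, no missing
#'   genotypes.
#' @param breed_labels Breed label per sample (defaults to the sample
#'   table).
#' @param eps Frequency clamp (default 1e-6).
#' @return An object of class `admixture_model`: list with `F` (breeds x
#'   SNPs), `breeds`, `K`, `eps`, `map`.
#' @export
estimate_breed_frequencies <- function(g, breed_labels = g$samples$breed,
                                       eps = 1e-6) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (anyNA(g$geno)) stop("estimate_breed_frequencies requires complete genotypes")
  breeds <- sort(unique(breed_labels))
  f <- matrix(0, nrow = length(breeds), ncol = ncol(g$geno),
              dimnames = list(breeds, colnames(g$geno)))
  for (b in breeds) {
    rows <- which(breed_labels == b)
    if (!length(rows)) stop("sizing error: empty breed ", b)
    f[b, ] <- colMeans(g$geno[rows, , drop = FALSE]) / 2
  }
  f <- pmin(pmax(f, eps), 1 - eps)
  structure(list(F = f, breeds = breeds, K = length(breeds), eps = eps,
                 map = g$map),
            class = "admixture_model")
}

#' Supervised admixture log-likelihood of one animal
#'
#' Binomial likelihood of the genotype vector given ancestry fractions q on
#' the simplex and fixed breed frequencies:
#' `LL = sum_j [ g_j ln(sum_k q_k f_kj) + (2 - g_j) ln(sum_k q_k (1 - f_kj)) ]`.
#'
#' @param g_i Genotype vector (0/1/2) of one animal.
#' @param q K-vector of ancestry fractions (non-negative, summing to 1).
#' @param model An `admixture_model`.
#' @return Log-likelihood (scalar).
#' @export
admixture_loglik <- function(g_i, q, model) {
  stopifnot(length(q) == model$K, length(g_i) == ncol(model$F))
  if (any(q < -1e-12) || abs(sum(q) - 1) > 1e-8) {
    stop("q must lie on the probability simplex")
  }
  p <- drop(q %*% model$F)
  sum(g_i * log(p) + (2 - g_i) * log(1 - p))
}

# Batch EM dispatcher: G is animals x SNPs. `engine = "batch"` (default)
# runs all animals simultaneously through BLAS matrix products, evaluating
# the log-likelihood every `check_interval` updates (animals keep being
# refined until every one has converged or the iteration cap is hit);
# `engine = "cpp"` runs the compiled per-animal loop (each animal stops at
# its own convergence); `engine = "r"` is a plain-R reference with the
# log-likelihood asserted every iteration. All three implement the same
# update and agree to numerical precision at matched iteration counts.
admixture_em_batch <- function(G, model, tol = 1e-6, max_iter = 2000L,
                               engine = c("batch", "cpp", "r"),
                               check_interval = 8L) {
  engine <- match.arg(engine)
  if (engine == "cpp") {
    res <- em_admixture_cpp(matrix(as.numeric(G), nrow = nrow(G)), model$F,
                            tol, as.integer(max_iter),
                            as.integer(check_interval))
    dimnames(res$Q) <- list(rownames(G), model$breeds)
    return(res)
  }
  if (engine == "r") {
    return(admixture_em_r(G, model, tol = tol, max_iter = max_iter))
  }
  res <- em_admixture_batch_cpp(matrix(as.numeric(G), nrow = nrow(G)),
                                model$F, tol, as.integer(max_iter),
                                as.integer(check_interval))
  dimnames(res$Q) <- list(rownames(G), model$breeds)
  res
}

# Reference EM in plain R: the EM update is
#   q_k <- (1/2M) sum_j [ g_j q_k f_kj / p_j + (2-g_j) q_k (1-f_kj) / (1-p_j) ]
# with p_j = sum_k q_k f_kj; the log-likelihood is non-decreasing and is
# asserted every iteration.
admixture_em_r <- function(G, model, tol = 1e-6, max_iter = 2000L) {
  n <- nrow(G); m <- ncol(G); K <- model$K
  f <- model$F
  Q <- matrix(1 / K, n, K, dimnames = list(rownames(G), model$breeds))
  P <- Q %*% f
  ll <- rowSums(G * log(P) + (2 - G) * log(1 - P))
  iters <- integer(n)
  converged <- rep(FALSE, n)
  G2 <- 2 - G
  for (it in seq_len(max_iter)) {
    A <- (G / P) %*% t(f) + (G2 / (1 - P)) %*% t(1 - f)
    Q <- Q * A / (2 * m)
    Q <- Q / rowSums(Q)             # guard simplex drift
    P <- Q %*% f
    ll_new <- rowSums(G * log(P) + (2 - G) * log(1 - P))
    if (any(ll_new < ll - 1e-8 * (abs(ll) + 1))) {
      stop("EM log-likelihood decreased: numerical failure")
    }
    delta <- ll_new - ll
    ll <- ll_new
    newly <- !converged & delta < tol
    iters[!converged] <- it
    converged <- converged | newly
    if (all(converged)) break
  }
  list(Q = Q, loglik = ll, iterations = iters, converged = converged)
}

#' Estimate ancestry fractions of one animal by EM
#'
#' Maximises the supervised admixture likelihood over the probability
#' simplex by expectation-maximisation from a uniform start. For fixed
#' frequencies the likelihood is concave in q, so the uniform
#' deterministic start reaches the global optimum; the log-likelihood is
#' asserted non-decreasing at every iteration. Convergence is declared
#' when the log-likelihood improves by less than `tol`.
#'
#' @param g_i Genotype vector (0/1/2) of one animal.
#' @param model An `admixture_model` from [estimate_breed_frequencies()].
#' @param tol Log-likelihood convergence tolerance (default 1e-6).
#' @param max_iter Iteration cap (default 2000); hitting it returns the
#'   current estimate with `converged = FALSE`.
#' @param engine `"batch"` (vectorised, default), `"cpp"` (compiled
#'   per-animal loop) or `"r"` (reference implementation with the
#'   monotonicity assertion every iteration).
#' @return List with `q` (named K-vector), `loglik`, `iterations`,
#'   `converged`.
#' @export
fit_admixture_em <- function(g_i, model, tol = 1e-6, max_iter = 2000L,
                             engine = "batch") {
  stopifnot(inherits(model, "admixture_model"),
            length(g_i) == ncol(model$F))
  res <- admixture_em_batch(matrix(as.numeric(g_i), nrow = 1), model,
                            tol = tol, max_iter = max_iter,
                            engine = engine)
  list(q = stats::setNames(drop(res$Q), model$breeds),
       loglik = res$loglik, iterations = res$iterations[1],
       converged = res$converged[1])
}

#' Full supervised-admixture breed-composition pipeline
#'
#' Freezes breed frequencies from the labelled training purebreds,
#' estimates each test animal's ancestry fractions by EM, then applies the
#' same post-processing as the SNP-BLUP pipeline (zero below 0.05,
#' rescale, assign at 0.90).
#'
#' @param train Training [genotype_matrix()] with breed labels.
#' @param test Test [genotype_matrix()].
#' @param panel Optional marker-id subset (low-density panel).
#' @param eps Frequency clamp (default 1e-6).
#' @param tol,max_iter EM convergence controls.
#' @param zero_threshold,assign_threshold Post-processing thresholds.
#' @return A [breed_composition()]; its `raw` slot holds the EM ancestry
#'   fractions before thresholding.
#' @export
admixture_composition <- function(train, test, panel = NULL, eps = 1e-6,
                                  tol = 1e-6, max_iter = 2000L,
                                  zero_threshold = 0.05,
                                  assign_threshold = 0.90) {
  stopifnot(inherits(train, "genotype_matrix"),
            inherits(test, "genotype_matrix"))
  if (!is.null(panel)) {
    train <- subset_genotypes(train, markers = panel)
    test <- subset_genotypes(test, markers = panel)
  }
  model <- estimate_breed_frequencies(train, eps = eps)
  mi <- match(colnames(model$F), test$map$snp_id)
  if (anyNA(mi)) stop("alignment error: model markers absent from test set")
  res <- admixture_em_batch(test$geno[, mi, drop = FALSE], model,
                            tol = tol, max_iter = max_iter)
  post <- postprocess_composition(res$Q, threshold = zero_threshold)
  out <- breed_composition(res$Q, post$proportions,
                           assign_breed(post$proportions, assign_threshold),
                           post$unassignable, test$samples$sample_id)
  out$loglik <- res$loglik
  out$iterations <- res$iterations
  out$converged <- res$converged
  out
}
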