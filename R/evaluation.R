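#' Agreement statistics between two breed-composition tables
#'
#' Element-wise differences `a - b` of processed proportions, summarised as
#' mean signed difference, mean absolute difference, SD of the differences,
#' RMSE and Bland-Altman limits (mean +/- 2 SD). With `scope = "overall"`
#' all breed slots of all animals enter; with `scope = "per_breed"` one row
#' of statistics is returned per breed over the animals in which that breed
#' is present (proportion at or above `presence_min` in either table).
#'
#' @param a,b [breed_composition()] objects (or proportion matrices) over
#'   the same animals and breed order.
#' @param scope `"overall"` or `"per_breed"`.
#' @param presence_min Presence threshold for per-breed scope (default
#'   0.05).
#' @param paired_test Also report a paired two-sided t-test p-value of the
#'   mean difference against zero (default `TRUE`).
#' @return Data frame with columns `breed` (per-breed scope only), `n`,
#'   `mean_diff`, `mean_abs_diff`, `sd_diff`, `rmse`, `ba_lower`,
#'   `ba_upper` and optionally `p_value`.
#' @export
composition_agreement <- function(a, b, scope = c("overall", "per_breed"),
                                  presence_min = 0.05, paired_test = TRUE) {
  scope <- match.arg(scope)
  pa <- if (inherits(a, "breed_composition")) a$proportions else as.matrix(a)
  pb <- if (inherits(b, "breed_composition")) b$proportions else as.matrix(b)
  if (!identical(dim(pa), dim(pb))) {
    stop("alignment error: tables differ in animals or breeds")
  }
  ida <- if (inherits(a, "breed_composition")) a$sample_id else rownames(pa)
  idb <- if (inherits(b, "breed_composition")) b$sample_id else rownames(pb)
  if (!is.null(ida) && !is.null(idb) && !identical(ida, idb)) {
    stop("alignment error: animal ids differ")
  }
  stat_row <- function(d) {
    data.frame(n = length(d), mean_diff = mean(d),
               mean_abs_diff = mean(abs(d)),
               sd_diff = if (length(d) > 1) stats::sd(d) else 0,
               rmse = sqrt(mean(d^2)))
  }
  finish <- function(df, d_list) {
    df$ba_lower <- df$mean_diff - 2 * df$sd_diff
    df$ba_upper <- df$mean_diff + 2 * df$sd_diff
    if (paired_test) {
      df$p_value <- vapply(d_list, function(d) {
        if (length(d) < 2 || stats::sd(d) == 0) NA_real_ else
          stats::t.test(d)$p.value
      }, numeric(1))
    }
    df
  }
  if (scope == "overall") {
    d <- as.vector(pa - pb)
    return(finish(stat_row(d), list(d)))
  }
  breeds <- colnames(pa)
  rows <- list(); d_list <- list()
  for (j in seq_along(breeds)) {
    present <- pa[, j] >= presence_min | pb[, j] >= presence_min
    d <- pa[present, j] - pb[present, j]
    r <- if (length(d)) stat_row(d) else
      data.frame(n = 0L, mean_diff = NA_real_, mean_abs_diff = NA_real_,
                 sd_diff = NA_real_, rmse = NA_real_)
    rows[[j]] <- cbind(data.frame(breed = breeds[j]), r)
    d_list[[j]] <- d
  }
  finish(do.call(rbind, rows), d_list)
}

#' Percentage of purebreds assigned to their true breed
#'
#' Re-applies [assign_breed()] at `threshold` and reports the percentage
#' of animals whose assigned breed equals the true label (unassigned
#' animals count as incorrect).
#'
#' @param composition A [breed_composition()] (or proportion matrix).
#' @param true_labels True breed label per animal.
#' @param threshold Assignment threshold (default 0.90).
#' @return Percentage in `[0, 100]`.
#' @export
assignment_rate <- function(composition, true_labels, threshold = 0.90) {
  p <- if (inherits(composition, "breed_composition"))
    composition$proportions else as.matrix(composition)
  stopifnot(nrow(p) == length(true_labels))
  assigned <- assign_breed(p, threshold)
  100 * mean(!is.na(assigned) & assigned == true_labels)
}

#' Compare low-density panel predictions to the full-panel gold standard
#'
#' For each panel run, reports the purebred assignment rate (at
#' `threshold`) and, for crossbreds, the mean absolute deviation of the
#' main-breed proportion (the breed with the largest gold-standard
#' proportion per animal) from the gold-standard value.
#'
#' @param panel_runs List of runs; each a list with elements `strategy`,
#'   `density`, `predictor`, and [breed_composition()] objects `purebred`
#'   and/or `crossbred`.
#' @param gold_purebred,gold_crossbred Gold-standard
#'   [breed_composition()] objects (full-panel SNP-BLUP) over the same
#'   animals.
#' @param true_labels True breed labels of the purebred validation
#'   animals.
#' @param threshold Assignment threshold (default 0.90).
#' @return Long-format data frame: one row per (strategy, density,
#'   predictor) with `assignment_rate` and `mean_abs_dev_main_breed`.
#' @export
gold_standard_comparison <- function(panel_runs, gold_purebred = NULL,
                                     gold_crossbred = NULL,
                                     true_labels = NULL, threshold = 0.90) {
  main_idx <- NULL
  if (!is.null(gold_crossbred)) {
    main_idx <- max.col(gold_crossbred$proportions, ties.method = "first")
  }
  rows <- lapply(panel_runs, function(run) {
    rate <- NA_real_; dev <- NA_real_
    if (!is.null(run$purebred) && !is.null(true_labels)) {
      rate <- assignment_rate(run$purebred, true_labels, threshold)
    }
    if (!is.null(run$crossbred) && !is.null(gold_crossbred)) {
      i <- seq_len(nrow(gold_crossbred$proportions))
      gold_main <- gold_crossbred$proportions[cbind(i, main_idx)]
      panel_main <- run$crossbred$proportions[cbind(i, main_idx)]
      dev <- mean(abs(panel_main - gold_main))
    }
    data.frame(strategy = run$strategy, density = run$density,
               predictor = run$predictor, assignment_rate = rate,
               mean_abs_dev_main_breed = dev)
  })
  do.call(rbind, c(rows, make.row.names = FALSE))
}

#' Mislabeling robustness experiment
#'
#' Replaces a fraction of one breed's training animals with freshly
#' simulated two-way (F1) crossbreds containing that breed, labels them as
#' purebred, refits both predictors, and reports the target breed's
#' purebred-validation assignment rate at the 0.90 threshold and at a
#' secondary 0.60 threshold. This probes the differential sensitivity of
#' the regression and likelihood approaches to training-label
#' contamination.
#'
#' @param dataset A `study_dataset` (needs `freqs`, `training` and
#'   `validation_purebred`).
#' @param breed Target breed label.
#' @param partner Partner breed of the substituted F1 crossbreds.
#' @param fraction_mislabeled Fraction of the target breed's training
#'   animals replaced (default 0.5); 0 reproduces the clean baseline.
#' @param seed Integer seed (crossbred simulation, replacement draw,
#'   0-set draws).
#' @param h2,tol,max_iter Predictor controls.
#' @param independent_loci Passed to [simulate_crossbreds()].
#' @return List with `rates` (data frame: predictor, rate at 0.90, rate
#'   at 0.60), and the two [breed_composition()] objects.
#' @export
mislabeling_experiment <- function(dataset, breed, partner,
                                   fraction_mislabeled = 0.5, seed = 1L,
                                   h2 = 0.999, tol = 1e-6,
                                   max_iter = 2000L,
                                   independent_loci = FALSE) {
  stopifnot(inherits(dataset, "study_dataset"))
  train <- dataset$training
  target_rows <- which(train$samples$breed == breed)
  n_replace <- round(fraction_mislabeled * length(target_rows))
  if (n_replace > 0) {
    cross <- simulate_crossbreds(
      dataset$freqs,
      list(cross_design(paste0(breed, "x", partner), breed, partner,
                        n_replace)),
      dataset$config, seed = seed, independent_loci = independent_loci)
    replace_rows <- with_seed_opt(seed + 1L,
      target_rows[sample.int(length(target_rows), n_replace)])
    train$geno[replace_rows, ] <- cross$geno
    # the substitutes keep the purebred label: that is the contamination
  }
  val_rows <- which(dataset$validation_purebred$samples$breed == breed)
  val <- subset_genotypes(dataset$validation_purebred, samples = val_rows)
  bc_blup <- snp_blup_composition(train, val, h2 = h2, seed = seed + 2L)
  bc_adm <- admixture_composition(train, val, tol = tol,
                                  max_iter = max_iter)
  truth <- rep(breed, nrow(val$geno))
  rates <- data.frame(
    predictor = c("snp_blup", "admixture"),
    rate_090 = c(assignment_rate(bc_blup, truth, 0.90),
                 assignment_rate(bc_adm, truth, 0.90)),
    rate_060 = c(assignment_rate(bc_blup, truth, 0.60),
                 assignment_rate(bc_adm, truth, 0.60))
  )
  list(rates = rates, snp_blup = bc_blup, admixture = bc_adm)
}
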