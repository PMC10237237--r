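#' Construct a genotype matrix object
#'
#' The universal currency of the pipeline: an animals-by-markers matrix of
#' reference-allele counts (0/1/2, `NA` for missing) together with a marker
#' map and a sample table.
#'
#' @param geno Integer matrix, samples in rows, markers in columns. Values
#'   must be 0, 1, 2 or `NA`.
#' @param map Data frame with one row per marker: columns `snp_id`, `chrom`
#'   (integer; 1-29 for cattle autosomes), `pos` (1-based bp), and allele
#'   codes `a1`, `a2`.
#' @param samples Data frame with one row per animal: column `sample_id`,
#'   optionally `breed` and `population`.
#' @param ... Additional components stored alongside (e.g. realized breed
#'   fractions for simulated crossbreds).
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(geno, map, samples, ...) {
  geno <- as.matrix(geno)
  stopifnot(nrow(geno) == nrow(samples), ncol(geno) == nrow(map))
  bad <- geno[!is.na(geno)]
  if (length(bad) && !all(bad %in% c(0L, 1L, 2L))) {
    stop("genotype values must be 0, 1, 2 or NA")
  }
  if (anyDuplicated(map$snp_id)) stop("marker ids must be unique")
  rownames(geno) <- samples$sample_id
  colnames(geno) <- map$snp_id
  structure(
    list(geno = geno, map = map, samples = samples, ...),
    class = "genotype_matrix"
  )
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf(
    "genotype_matrix: %d samples x %d markers on %d chromosome(s)\n",
    nrow(x$geno), ncol(x$geno), length(unique(x$map$chrom))
  ))
  if (!is.null(x$samples$breed)) {
    cat("breeds:", paste(unique(x$samples$breed), collapse = " "), "\n")
  }
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$geno)

#' Subset a genotype matrix by samples and/or markers
#'
#' @param g A [genotype_matrix()].
#' @param samples Sample ids or row indices to keep (default all).
#' @param markers Marker ids or column indices to keep (default all).
#' @return A `genotype_matrix` restricted to the requested entries.
#' @export
subset_genotypes <- function(g, samples = NULL, markers = NULL) {
  si <- seq_len(nrow(g$geno))
  mi <- seq_len(ncol(g$geno))
  if (!is.null(samples)) {
    si <- if (is.character(samples)) match(samples, g$samples$sample_id) else samples
    if (anyNA(si)) stop("unknown sample id(s)")
  }
  if (!is.null(markers)) {
    mi <- if (is.character(markers)) match(markers, g$map$snp_id) else markers
    if (anyNA(mi)) stop("marker(s) absent from the map: alignment error")
  }
  out <- g
  out$geno <- g$geno[si, mi, drop = FALSE]
  out$map <- g$map[mi, , drop = FALSE]
  out$samples <- g$samples[si, , drop = FALSE]
  for (extra in c("true_fractions", "pedigree_fractions")) {
    if (!is.null(g[[extra]])) out[[extra]] <- g[[extra]][si, , drop = FALSE]
  }
  out
}

#' Construct an allele frequency table
#'
#' Breeds-by-markers reference allele frequencies; drives simulation, Fst and
#' the admixture likelihood.
#'
#' @param freqs Numeric matrix (breeds x markers), entries in `[0, 1]`.
#' @param breeds Character vector of breed labels (row names).
#' @param map Marker map data frame (see [genotype_matrix()]).
#' @return An object of class `allele_freq_table`.
#' @export
allele_freq_table <- function(freqs, breeds, map) {
  freqs <- as.matrix(freqs)
  stopifnot(nrow(freqs) == length(breeds), ncol(freqs) == nrow(map))
  if (any(freqs < 0 | freqs > 1)) stop("allele frequencies must lie in [0, 1]")
  dimnames(freqs) <- list(breeds, map$snp_id)
  structure(list(freqs = freqs, breeds = breeds, map = map),
            class = "allele_freq_table")
}

#' @export
print.allele_freq_table <- function(x, ...) {
  cat(sprintf("allele_freq_table: %d breeds x %d markers\n",
              nrow(x$freqs), ncol(x$freqs)))
  invisible(x)
}

#' Construct a breed composition table
#'
#' Per-animal breed proportion estimates. `proportions` rows lie on the
#' simplex except for animals flagged unassignable (all-zero rows after
#' thresholding).
#'
#' @param raw Numeric matrix of raw (unbounded) per-breed scores.
#' @param proportions Numeric matrix of processed proportions.
#' @param assigned Character vector: assigned breed per animal, `NA` when
#'   unassigned.
#' @param unassignable Logical vector: `TRUE` where thresholding removed all
#'   breeds.
#' @param sample_id Character vector of animal ids.
#' @return An object of class `breed_composition`.
#' @export
breed_composition <- function(raw, proportions, assigned, unassignable,
                              sample_id) {
  structure(
    list(raw = raw, proportions = proportions, assigned = assigned,
         unassignable = unassignable, sample_id = sample_id,
         breeds = colnames(proportions)),
    class = "breed_composition"
  )
}

#' @export
print.breed_composition <- function(x, ...) {
  cat(sprintf(
    "breed_composition: %d animals x %d breeds (%d assigned, %d unassignable)\n",
    nrow(x$proportions), ncol(x$proportions),
    sum(!is.na(x$assigned)), sum(x$unassignable)
  ))
  invisible(x)
}

# Evaluate `code` under a temporary RNG seed; NULL leaves the stream alone.
with_seed_opt <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(seed, code)
}
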