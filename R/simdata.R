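#' Default cattle autosome lengths
#'
#' Approximate lengths (bp) of the 29 cattle autosomes on the ARS-UCD1.2
#' assembly, totalling ~2.5 Gbp. `n` keeps the first `n` autosomes and
#' `scale` shrinks all lengths proportionally, so desk-scale simulations can
#' use a few short chromosomes while preserving relative lengths.
#'
#' @param n Number of autosomes to keep (1-29).
#' @param scale Multiplicative length scaling factor.
#' @return Data frame with columns `chrom` and `length_bp`.
#' @export
default_cattle_autosomes <- function(n = 29, scale = 1) {
  mb <- c(158.5, 136.2, 121.0, 120.8, 120.1, 117.8, 110.7, 113.4, 105.7,
          103.3, 106.9, 87.2, 83.5, 82.4, 85.0, 81.0, 73.2, 65.8, 63.4,
          71.9, 69.9, 60.7, 52.5, 62.7, 42.9, 51.7, 45.6, 45.9, 51.1)
  stopifnot(n >= 1, n <= 29, scale > 0)
  data.frame(chrom = seq_len(n),
             length_bp = round(mb[seq_len(n)] * 1e6 * scale))
}

#' Breed labels used by default
#'
#' Thirteen labels for the cattle breeds the pipeline was designed around
#' (Angus, Aubrac, Blonde d'Aquitaine, Belgian Blue, Charolais, Friesian,
#' Hereford, Holstein, Limousin, Parthenaise, Saler, Shorthorn, Simmental);
#' generic labels otherwise.
#'
#' @param n_breeds Number of breeds.
#' @return Character vector of length `n_breeds`.
#' @export
default_breed_labels <- function(n_breeds) {
  lab13 <- c("AA", "AU", "BA", "BB", "CH", "FR", "HE", "HO", "LM", "PT",
             "SA", "SH", "SI")
  if (n_breeds <= 13) lab13[seq_len(n_breeds)] else
    sprintf("B%02d", seq_len(n_breeds))
}

#' Describe a two- or three-way cross
#'
#' Pedigrees of depth at most two are supported: each parent is either a
#' purebred (one breed) or an F1 (two breeds). A two-way cross is
#' `sire = "AA", dam = "CH"`; a three-way cross `AA x (CH x LM)` is
#' `sire = "AA", dam = c("CH", "LM")`.
#'
#' @param label Text label, e.g. `"AAxCH"`.
#' @param sire,dam Character vector of 1 (purebred parent) or 2 (F1 parent)
#'   breed labels.
#' @param n_animals Number of offspring to simulate.
#' @return An object of class `cross_design`.
#' @export
cross_design <- function(label, sire, dam, n_animals) {
  if (length(sire) > 2 || length(dam) > 2) {
    stop("unsupported cross design: pedigree depth exceeds 2")
  }
  stopifnot(length(sire) >= 1, length(dam) >= 1, n_animals >= 1)
  structure(list(label = label, sire = sire, dam = dam,
                 n_animals = as.integer(n_animals)),
            class = "cross_design")
}

# Pedigree-expected breed fractions of a cross design, named by breed.
expected_cross_fractions <- function(design, breeds) {
  frac <- stats::setNames(numeric(length(breeds)), breeds)
  for (side in list(design$sire, design$dam)) {
    if (!all(side %in% breeds)) stop("cross design names an unknown breed")
    frac[side] <- frac[side] + 0.5 / length(side)
  }
  frac
}

#' Simulation configuration
#'
#' Collects every knob of the synthetic multi-breed genotype generator. The
#' defaults describe the study conditions the pipeline targets: 13 breeds
#' diverged under uniform Balding-Nichols drift F = 0.15 per breed —
#' calibrated so realized pairwise Fst under this package's estimator
#' ([pairwise_fst()], population-variance convention, whose expected
#' pairwise value is S / (1 - S) with S = (F_a + F_b) / 4, i.e. about half
#' the per-breed drift) lands at ~0.065-0.072, the middle of the
#' 0.039-0.146 envelope observed between European cattle breeds — 29
#' autosomes, 1 cM/Mb, and training / purebred-validation / SNP-selection
#' populations of 500 / 250 / 1000 animals per breed.
#'
#' @param n_breeds Number of breeds (>= 2).
#' @param n_snps Total number of biallelic SNPs, allocated to chromosomes
#'   proportionally to length.
#' @param chromosomes Data frame `chrom`, `length_bp`; see
#'   [default_cattle_autosomes()].
#' @param drift_F Per-breed Balding-Nichols drift parameter in (0, 1);
#'   recycled to `n_breeds`.
#' @param ancestral_freq_range Interval the ancestral allele frequency is
#'   drawn uniformly from.
#' @param recomb_rate Recombination rate in cM per Mb (linear genetic map).
#' @param pop_sizes Named list/vector with per-breed counts for `training`,
#'   `validation` and `snp_selection`.
#' @param cross_designs List of [cross_design()] objects for the crossbred
#'   validation population.
#' @param breed_labels Breed labels; defaults to [default_breed_labels()].
#' @param seed Integer seed recorded in, and governing, all outputs.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_breeds = 13,
                       n_snps = 5000,
                       chromosomes = default_cattle_autosomes(),
                       drift_F = 0.15,
                       ancestral_freq_range = c(0.05, 0.95),
                       recomb_rate = 1.0,
                       pop_sizes = c(training = 500, validation = 250,
                                     snp_selection = 1000),
                       cross_designs = list(),
                       breed_labels = default_breed_labels(n_breeds),
                       seed = 1L) {
  if (n_breeds < 2) stop("at least two breeds are required")
  drift_F <- rep_len(drift_F, n_breeds)
  if (any(drift_F <= 0 | drift_F >= 1)) stop("drift_F must lie in (0, 1)")
  stopifnot(all(chromosomes$length_bp > 0), n_snps >= length(chromosomes$chrom))
  stopifnot(length(ancestral_freq_range) == 2,
            ancestral_freq_range[1] > 0, ancestral_freq_range[2] < 1,
            ancestral_freq_range[1] < ancestral_freq_range[2])
  stopifnot(recomb_rate >= 0, length(breed_labels) == n_breeds)
  for (nm in c("training", "validation", "snp_selection")) {
    if (is.null(pop_sizes[[nm]])) stop("pop_sizes must name ", nm)
  }
  structure(
    list(n_breeds = as.integer(n_breeds), n_snps = as.integer(n_snps),
         chromosomes = chromosomes, drift_F = drift_F,
         ancestral_freq_range = ancestral_freq_range,
         recomb_rate = recomb_rate, pop_sizes = pop_sizes,
         cross_designs = cross_designs, breed_labels = breed_labels,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' Read a simulation configuration from YAML
#'
#' @param path Path to a YAML file whose top-level keys are [sim_config()]
#'   arguments; `cross_designs` entries are maps with keys `label`, `sire`,
#'   `dam`, `n_animals`.
#' @return A `sim_config` object.
#' @export
sim_config_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$chromosomes)) {
    y$chromosomes <- do.call(rbind.data.frame, y$chromosomes)
  }
  if (!is.null(y$cross_designs)) {
    y$cross_designs <- lapply(y$cross_designs, function(cd) {
      cross_design(cd$label, unlist(cd$sire), unlist(cd$dam), cd$n_animals)
    })
  }
  do.call(sim_config, y)
}

# Place n_snps markers on the configured chromosomes: counts proportional to
# length (largest-remainder), positions uniform without replacement, sorted.
make_marker_map <- function(config) {
  counts <- allocate_per_chromosome(config$n_snps,
                                    config$chromosomes$length_bp)
  maps <- lapply(seq_along(counts), function(ci) {
    n_c <- counts[ci]
    if (n_c == 0L) return(NULL)
    pos <- sort(sample.int(config$chromosomes$length_bp[ci], n_c))
    data.frame(chrom = config$chromosomes$chrom[ci], pos = pos)
  })
  map <- do.call(rbind, maps)
  map$snp_id <- sprintf("snp%d_%d", map$chrom, map$pos)
  map$a1 <- "A"
  map$a2 <- "B"
  rownames(map) <- NULL
  map[, c("snp_id", "chrom", "pos", "a1", "a2")]
}

#' Simulate diverged breed allele frequencies (Balding-Nichols)
#'
#' Draws a per-SNP ancestral frequency p uniformly on the configured range,
#' then for each breed k a frequency from
#' `Beta(p (1 - F_k) / F_k, (1 - p)(1 - F_k) / F_k)`, whose mean is p and
#' whose dispersion is governed by the drift parameter F_k. Expected
#' pairwise Fst between breeds with drift F is approximately F.
#'
#' @param config A [sim_config()]. All randomness is governed by
#'   `config$seed`; identical configs give bit-identical output.
#' @return An [allele_freq_table()] carrying the generated marker map.
#' @export
simulate_breed_frequencies <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed_opt(config$seed, {
    map <- make_marker_map(config)
    m <- nrow(map)
    p <- stats::runif(m, config$ancestral_freq_range[1],
                      config$ancestral_freq_range[2])
    freqs <- matrix(0, nrow = config$n_breeds, ncol = m)
    for (k in seq_len(config$n_breeds)) {
      f <- config$drift_F[k]
      shape_scale <- (1 - f) / f
      freqs[k, ] <- stats::rbeta(m, p * shape_scale, (1 - p) * shape_scale)
    }
    out <- allele_freq_table(freqs, config$breed_labels, map)
    out$ancestral <- p
    out$seed <- config$seed
    out
  })
}

#' Simulate purebred animals under Hardy-Weinberg equilibrium
#'
#' Genotype at SNP j for a breed-k animal is Binomial(2, f_kj),
#' independently across loci (no within-breed relatedness beyond shared
#' breed frequencies).
#'
#' @param freqs An [allele_freq_table()].
#' @param n_per_breed Integer count per breed (recycled).
#' @param seed Integer seed.
#' @param population Population tag stored in the sample table.
#' @param id_prefix Prefix for generated sample ids.
#' @return A [genotype_matrix()] whose sample table carries the true breed.
#' @export
simulate_purebreds <- function(freqs, n_per_breed, seed = NULL,
                               population = "purebred", id_prefix = "pb") {
  stopifnot(inherits(freqs, "allele_freq_table"))
  b <- nrow(freqs$freqs)
  n_per_breed <- rep_len(as.integer(n_per_breed), b)
  if (any(n_per_breed < 0) || sum(n_per_breed) < 1) {
    stop("n_per_breed must be non-negative with at least one animal")
  }
  m <- ncol(freqs$freqs)
  with_seed_opt(seed, {
    geno <- matrix(0L, nrow = sum(n_per_breed), ncol = m)
    row0 <- 0L
    for (k in seq_len(b)) {
      nk <- n_per_breed[k]
      geno[row0 + seq_len(nk), ] <- matrix(
        stats::rbinom(nk * m, 2L, rep(freqs$freqs[k, ], each = nk)),
        nrow = nk
      )
      row0 <- row0 + nk
    }
    samples <- data.frame(
      sample_id = sprintf("%s_%s_%04d", id_prefix,
                          rep(freqs$breeds, n_per_breed),
                          unlist(lapply(n_per_breed, seq_len))),
      breed = rep(freqs$breeds, n_per_breed),
      population = population
    )
    genotype_matrix(geno, freqs$map, samples)
  })
}

# Origins (breed indices) of one gamete transmitted by a parent. Purebred
# parents transmit their breed everywhere; F1 parents transmit a Haldane
# crossover mosaic of their two breeds along the linear genetic map.
gamete_origins <- function(parent_breeds, map, chromosomes, recomb_rate,
                           independent_loci = FALSE) {
  m <- nrow(map)
  if (length(parent_breeds) == 1L) return(rep(parent_breeds, m))
  if (independent_loci) {
    return(parent_breeds[sample.int(2L, m, replace = TRUE)])
  }
  origin <- integer(m)
  for (ci in seq_len(nrow(chromosomes))) {
    on_c <- which(map$chrom == chromosomes$chrom[ci])
    if (!length(on_c)) next
    len_bp <- chromosomes$length_bp[ci]
    morgans <- len_bp / 1e6 * recomb_rate / 100
    n_x <- stats::rpois(1L, morgans)
    xpos <- sort(stats::runif(n_x, 0, len_bp))
    start <- sample.int(2L, 1L)
    seg <- findInterval(map$pos[on_c], xpos)
    origin[on_c] <- parent_breeds[1L + (start + seg) %% 2L]
  }
  origin
}

#' Simulate crossbred animals with recombination
#'
#' Each offspring receives one gamete per parent. Purebred parents transmit
#' a whole-breed gamete; F1 parents transmit a recombination mosaic of their
#' two breeds formed under the Haldane model (Poisson crossovers on a linear
#' genetic map at `config$recomb_rate` cM/Mb). Every transmitted locus
#' carries a breed-of-origin label and its allele is drawn Bernoulli from
#' that breed's frequency. The realized per-animal breed fraction (share of
#' transmitted loci per origin breed) is recorded alongside the
#' pedigree-expected fraction.
#'
#' @param freqs An [allele_freq_table()].
#' @param designs Non-empty list of [cross_design()] objects.
#' @param config A [sim_config()] (chromosome lengths and recombination
#'   rate are taken from it).
#' @param seed Integer seed.
#' @param independent_loci If `TRUE`, F1 gametes draw the origin of each
#'   locus independently instead of simulating crossovers (cheap mode for
#'   unit tests; no ancestry LD).
#' @return A [genotype_matrix()] with components `true_fractions` and
#'   `pedigree_fractions` (animals x breeds matrices).
#' @export
simulate_crossbreds <- function(freqs, designs, config, seed = NULL,
                                independent_loci = FALSE) {
  stopifnot(inherits(freqs, "allele_freq_table"))
  if (!length(designs)) stop("designs must be non-empty")
  breeds <- freqs$breeds
  m <- ncol(freqs$freqs)
  with_seed_opt(seed, {
    rows <- list(); sample_rows <- list()
    true_fr <- list(); ped_fr <- list()
    for (d in designs) {
      stopifnot(inherits(d, "cross_design"))
      ped <- expected_cross_fractions(d, breeds)
      sire_idx <- match(d$sire, breeds)
      dam_idx <- match(d$dam, breeds)
      geno_d <- matrix(0L, nrow = d$n_animals, ncol = m)
      fr_d <- matrix(0, nrow = d$n_animals, ncol = length(breeds))
      for (a in seq_len(d$n_animals)) {
        h1 <- gamete_origins(sire_idx, freqs$map, config$chromosomes,
                             config$recomb_rate, independent_loci)
        h2 <- gamete_origins(dam_idx, freqs$map, config$chromosomes,
                             config$recomb_rate, independent_loci)
        al1 <- stats::rbinom(m, 1L, freqs$freqs[cbind(h1, seq_len(m))])
        al2 <- stats::rbinom(m, 1L, freqs$freqs[cbind(h2, seq_len(m))])
        geno_d[a, ] <- al1 + al2
        fr_d[a, ] <- tabulate(c(h1, h2), nbins = length(breeds)) / (2 * m)
      }
      rows[[d$label]] <- geno_d
      true_fr[[d$label]] <- fr_d
      ped_fr[[d$label]] <- matrix(ped, nrow = d$n_animals,
                                  ncol = length(breeds), byrow = TRUE)
      sample_rows[[d$label]] <- data.frame(
        sample_id = sprintf("cx_%s_%04d", d$label, seq_len(d$n_animals)),
        breed = d$label, population = "crossbred_validation"
      )
    }
    tf <- do.call(rbind, true_fr); pf <- do.call(rbind, ped_fr)
    colnames(tf) <- colnames(pf) <- breeds
    genotype_matrix(do.call(rbind, rows), freqs$map,
                    do.call(rbind, c(sample_rows, make.row.names = FALSE)),
                    true_fractions = tf, pedigree_fractions = pf)
  })
}

#' Assemble the four study populations
#'
#' Simulates breed frequencies once, then draws disjoint training,
#' purebred-validation, SNP-selection and crossbred-validation populations.
#' All animals are drawn independently (crossbred parents are internal to
#' the gamete simulation and never enter any population), so no
#' parent-offspring pair spans training and validation. Sub-seeds are
#' derived from `config$seed` and recorded.
#'
#' @param config A [sim_config()].
#' @param independent_loci Passed to [simulate_crossbreds()].
#' @return An object of class `study_dataset`: a list with the `config`,
#'   the true `freqs`, and genotype matrices `training`,
#'   `validation_purebred`, `snp_selection` and (when cross designs are
#'   configured) `validation_crossbred`.
#' @export
assemble_study_dataset <- function(config, independent_loci = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  seeds <- config$seed + 0:4
  freqs <- simulate_breed_frequencies(config)
  out <- list(
    config = config, seeds = seeds, freqs = freqs,
    training = simulate_purebreds(freqs, config$pop_sizes[["training"]],
                                  seed = seeds[2], population = "training",
                                  id_prefix = "tr"),
    validation_purebred = simulate_purebreds(
      freqs, config$pop_sizes[["validation"]], seed = seeds[3],
      population = "purebred_validation", id_prefix = "pv"),
    snp_selection = simulate_purebreds(
      freqs, config$pop_sizes[["snp_selection"]], seed = seeds[4],
      population = "snp_selection", id_prefix = "ss")
  )
  if (length(config$cross_designs)) {
    out$validation_crossbred <- simulate_crossbreds(
      freqs, config$cross_designs, config, seed = seeds[5],
      independent_loci = independent_loci)
  }
  structure(out, class = "study_dataset")
}

#' @export
print.study_dataset <- function(x, ...) {
  cat("study_dataset:\n")
  for (nm in c("training", "validation_purebred", "snp_selection",
               "validation_crossbred")) {
    if (!is.null(x[[nm]])) {
      cat(sprintf("  %-21s %5d animals x %d SNPs\n", nm,
                  nrow(x[[nm]]$geno), ncol(x[[nm]]$geno)))
    }
  }
  invisible(x)
}

#' Write a study dataset to PLINK files plus a truth sidecar
#'
#' One PLINK .bed/.bim/.fam triplet per population, and a single TSV with
#' columns `sample_id`, `population`, `breed_label`,
#' `breed_fraction_<breed>` (realized) and `pedigree_fraction_<breed>` for
#' every animal (purebreds have fraction 1 for their own breed).
#'
#' @param dataset A `study_dataset`.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the sidecar path.
#' @export
write_study_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  breeds <- dataset$freqs$breeds
  sidecars <- list()
  for (nm in c("training", "validation_purebred", "snp_selection",
               "validation_crossbred")) {
    g <- dataset[[nm]]
    if (is.null(g)) next
    write_plink(g, file.path(dir, nm))
    tf <- g$true_fractions
    pf <- g$pedigree_fractions
    if (is.null(tf)) {
      tf <- pf <- matrix(0, nrow(g$geno), length(breeds),
                         dimnames = list(NULL, breeds))
      tf[cbind(seq_len(nrow(g$geno)), match(g$samples$breed, breeds))] <- 1
      pf <- tf
    }
    colnames(tf) <- paste0("breed_fraction_", breeds)
    colnames(pf) <- paste0("pedigree_fraction_", breeds)
    sidecars[[nm]] <- cbind(
      data.frame(sample_id = g$samples$sample_id,
                 population = g$samples$population,
                 breed_label = g$samples$breed),
      tf, pf
    )
  }
  sidecar <- do.call(rbind, c(sidecars, make.row.names = FALSE))
  path <- file.path(dir, "samples.tsv")
  utils::write.table(sidecar, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
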