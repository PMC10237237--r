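#' Write a genotype matrix to PLINK 1 binary files
#'
#' Writes the SNP-major PLINK 1 `.bed` (magic bytes `6c 1b`, mode `01`) with
#' allele counts of the `.bim` A1 allele encoded per the PLINK 1.9 two-bit
#' scheme (00 = A1/A1, 10 = het, 11 = A2/A2, 01 = missing; samples packed
#' low bits first, trailing bits zero), a `.bim` with columns chromosome,
#' id, 0 cM, bp, A1, A2, and a `.fam` whose family id is the breed label
#' (or `0`).
#'
#' @param g A [genotype_matrix()].
#' @param prefix Output path prefix (without extension).
#' @return Invisibly, `prefix`.
#' @export
write_plink <- function(g, prefix) {
  stopifnot(inherits(g, "genotype_matrix"))
  n <- nrow(g$geno); m <- ncol(g$geno)
  # two-bit codes for A1 allele count: 2 -> 00, 1 -> 10, 0 -> 11, NA -> 01
  code <- matrix(c(3L, 2L, 0L)[g$geno + 1L], nrow = n)
  code[is.na(code)] <- 1L
  n4 <- 4L * ceiling(n / 4L)
  if (n4 > n) code <- rbind(code, matrix(0L, n4 - n, m))
  bytes <- as.raw(colSums(matrix(as.vector(code), nrow = 4L) *
                            c(1L, 4L, 16L, 64L)))
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  writeBin(bytes, con)

  bim <- data.frame(chrom = g$map$chrom, id = g$map$snp_id, cm = 0,
                    pos = g$map$pos, a1 = g$map$a1, a2 = g$map$a2)
  utils::write.table(bim, paste0(prefix, ".bim"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  fid <- if (is.null(g$samples$breed)) rep("0", n) else g$samples$breed
  fam <- data.frame(fid = fid, iid = g$samples$sample_id,
                    father = 0, mother = 0, sex = 0, pheno = -9)
  utils::write.table(fam, paste0(prefix, ".fam"), sep = " ", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}

#' Read PLINK 1 binary files into a genotype matrix
#'
#' Decodes a SNP-major PLINK 1 `.bed`; allele counts count the A1 allele of
#' the `.bim`, sample order follows the `.fam`, and the missing code decodes
#' to `NA`.
#'
#' @param prefix Path prefix of an existing `.bed`/`.bim`/`.fam` triplet.
#' @return A [genotype_matrix()]; `.fam` family ids other than `0` are
#'   stored as the breed label.
#' @export
read_plink <- function(prefix) {
  for (ext in c(".bed", ".bim", ".fam")) {
    if (!file.exists(paste0(prefix, ext))) {
      stop("missing PLINK file: ", prefix, ext)
    }
  }
  fam <- utils::read.table(paste0(prefix, ".fam"),
                           col.names = c("fid", "iid", "father", "mother",
                                         "sex", "pheno"),
                           colClasses = c("character", "character", "character",
                                          "character", "integer", "numeric"))
  if (nrow(fam) == 0) stop("format error: .fam lists no samples")
  bim <- utils::read.table(paste0(prefix, ".bim"),
                           col.names = c("chrom", "id", "cm", "pos",
                                         "a1", "a2"),
                           colClasses = c("integer", "character", "numeric",
                                          "integer", "character", "character"))
  n <- nrow(fam); m <- nrow(bim)
  bps <- ceiling(n / 4)
  raw <- readBin(paste0(prefix, ".bed"), "raw",
                 n = file.size(paste0(prefix, ".bed")))
  if (length(raw) < 3 || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b)) {
    stop("format error: bad PLINK .bed magic bytes")
  }
  if (raw[3] != as.raw(0x01)) stop("format error: .bed is not SNP-major")
  body <- as.integer(raw[-(1:3)])
  if (length(body) != bps * m) {
    stop("format error: .bed size does not match .bim/.fam dimensions")
  }
  # unpack 4 two-bit codes per byte, low bits first
  codes <- rbind(body %% 4L, (body %/% 4L) %% 4L,
                 (body %/% 16L) %% 4L, body %/% 64L)
  counts <- c(2L, NA, 1L, 0L)[as.vector(codes) + 1L]
  geno <- matrix(counts, nrow = 4L * bps)[seq_len(n), , drop = FALSE]
  samples <- data.frame(sample_id = fam$iid,
                        breed = ifelse(fam$fid == "0", NA, fam$fid),
                        population = NA_character_)
  map <- data.frame(snp_id = bim$id, chrom = bim$chrom, pos = bim$pos,
                    a1 = bim$a1, a2 = bim$a2)
  genotype_matrix(geno, map, samples)
}

#' Quality-control filter for SNPs and samples
#'
#' Drops non-autosomal or unmapped SNPs (chromosome outside 1-29 or missing
#' position), SNPs with call rate below `min_snp_call_rate`, and samples
#' with call rate below `min_sample_call_rate`. No minor allele frequency
#' filter is applied, so markers informative for rare breeds are kept.
#' Remaining sporadic missing genotypes are imputed to the per-SNP mean
#' allele count rounded to the nearest integer (ties round half up), which
#' keeps the 0/1/2 coding; family-based imputation is out of scope.
#'
#' @param g A [genotype_matrix()].
#' @param min_snp_call_rate Minimum per-SNP call rate (default 0.90).
#' @param min_sample_call_rate Minimum per-sample call rate (default 0.90).
#' @param autosomes_only Drop SNPs outside autosomes 1-29 (default `TRUE`).
#' @return A filtered, fully imputed `genotype_matrix`.
#' @export
qc_filter <- function(g, min_snp_call_rate = 0.90,
                      min_sample_call_rate = 0.90, autosomes_only = TRUE) {
  stopifnot(inherits(g, "genotype_matrix"))
  obs <- !is.na(g$geno)
  keep_snp <- colMeans(obs) >= min_snp_call_rate
  if (autosomes_only) {
    keep_snp <- keep_snp & !is.na(g$map$chrom) & g$map$chrom >= 1 &
      g$map$chrom <= 29 & !is.na(g$map$pos)
  }
  if (!any(keep_snp)) stop("empty panel: all SNPs removed by QC")
  keep_sample <- rowMeans(obs[, keep_snp, drop = FALSE]) >=
    min_sample_call_rate
  out <- subset_genotypes(g, samples = which(keep_sample),
                          markers = which(keep_snp))
  miss <- which(is.na(out$geno))
  if (length(miss)) {
    mean_count <- colMeans(out$geno, na.rm = TRUE)
    imputed <- pmin(2L, pmax(0L, as.integer(floor(mean_count + 0.5))))
    out$geno[miss] <- imputed[(miss - 1L) %/% nrow(out$geno) + 1L]
  }
  out
}
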