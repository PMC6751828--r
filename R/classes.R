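#' Marker map
#'
#' A per-SNP table of genomic coordinates and alleles. Positions are 1-based
#' bp (VCF convention) and must be strictly increasing within a chromosome;
#' chromosomes must be grouped contiguously.
#'
#' @param chrom character vector of chromosome ids.
#' @param pos integer vector of 1-based bp positions.
#' @param snp_id character vector of SNP ids; generated if `NULL`.
#' @param ref,alt allele labels (single characters such as "A"/"G").
#'
#' @return A `data.frame` of class `marker_map` with columns
#'   `chrom`, `pos`, `snp_id`, `ref`, `alt`.
#' @export
marker_map <- function(chrom, pos, snp_id = NULL, ref = NULL, alt = NULL) {
  m <- length(pos)
  stopifnot(length(chrom) == m)
  chrom <- as.character(chrom)
  pos <- as.integer(pos)
  if (is.null(snp_id)) snp_id <- paste0("snp_", chrom, "_", pos)
  if (is.null(ref)) ref <- rep("A", m)
  if (is.null(alt)) alt <- rep("G", m)
  map <- data.frame(chrom = chrom, pos = pos, snp_id = as.character(snp_id),
                    ref = as.character(ref), alt = as.character(alt),
                    stringsAsFactors = FALSE)
  validate_marker_map(map)
  class(map) <- c("marker_map", "data.frame")
  map
}

validate_marker_map <- function(map) {
  r <- rle(map$chrom)
  if (anyDuplicated(r$values))
    stop("marker_map: chromosomes must be grouped contiguously")
  for (ch in r$values) {
    p <- map$pos[map$chrom == ch]
    if (is.unsorted(p, strictly = TRUE))
      stop("marker_map: positions must be strictly increasing within chromosome ", ch)
  }
  if (anyDuplicated(map$snp_id)) stop("marker_map: duplicated snp_id")
  invisible(map)
}

#' Phased haplotype panel
#'
#' Binary allele matrix with two rows per individual (haplotypes `2i - 1` and
#' `2i` belong to individual `i`). Phased input is a contract: no missing
#' values are allowed.
#'
#' @param alleles integer matrix (2N x M) over \{0, 1\}.
#' @param sample_ids character vector of N individual ids.
#' @param population character vector of N population labels.
#' @param map a [marker_map()].
#'
#' @return An object of class `haplotype_panel`.
#' @export
haplotype_panel <- function(alleles, sample_ids, population, map) {
  alleles <- as.matrix(alleles)
  storage.mode(alleles) <- "integer"
  n <- length(sample_ids)
  if (nrow(alleles) != 2L * n)
    stop("haplotype_panel: alleles must have 2 rows per individual")
  if (length(population) != n)
    stop("haplotype_panel: one population label per individual required")
  if (ncol(alleles) != nrow(map))
    stop("haplotype_panel: allele columns must match map rows")
  if (anyNA(alleles))
    stop("haplotype_panel: missing alleles not allowed (phased contract)")
  if (!all(alleles %in% c(0L, 1L)))
    stop("haplotype_panel: alleles must be 0/1")
  structure(list(alleles = alleles,
                 sample_ids = as.character(sample_ids),
                 population = as.character(population),
                 map = map),
            class = "haplotype_panel")
}

#' @export
print.haplotype_panel <- function(x, ...) {
  cat("haplotype_panel:", length(x$sample_ids), "individuals (",
      nrow(x$alleles), "haplotypes ) x", ncol(x$alleles), "SNPs;",
      "populations:", paste(sort(unique(x$population)), collapse = ", "), "\n")
  invisible(x)
}

#' Diploid genotype matrix
#'
#' Dosage matrix (count of alt alleles per individual x SNP) over
#' \{0, 1, 2, NA\}; `NA` encodes a missing genotype call.
#'
#' @param dosages integer matrix (N x M).
#' @param sample_ids character vector of N individual ids.
#' @param population character vector of N population labels.
#' @param map a [marker_map()].
#'
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosages, sample_ids, population, map) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "integer"
  n <- length(sample_ids)
  if (nrow(dosages) != n) stop("genotype_matrix: one row per individual")
  if (length(population) != n) stop("genotype_matrix: one population label per individual")
  if (ncol(dosages) != nrow(map)) stop("genotype_matrix: columns must match map rows")
  ok <- dosages %in% c(0L, 1L, 2L) | is.na(dosages)
  if (!all(ok)) stop("genotype_matrix: dosages must be 0/1/2 or NA")
  structure(list(dosages = dosages,
                 sample_ids = as.character(sample_ids),
                 population = as.character(population),
                 map = map),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", length(x$sample_ids), "individuals x",
      ncol(x$dosages), "SNPs;",
      "missing:", sum(is.na(x$dosages)), "calls;",
      "populations:", paste(sort(unique(x$population)), collapse = ", "), "\n")
  invisible(x)
}

#' Subset a haplotype panel by SNPs and/or individuals
#'
#' @param panel a [haplotype_panel()].
#' @param snps integer or logical index into map rows.
#' @param individuals integer or logical index into individuals.
#' @return A `haplotype_panel`.
#' @export
subset_panel <- function(panel, snps = NULL, individuals = NULL) {
  a <- panel$alleles; map <- panel$map
  sid <- panel$sample_ids; pop <- panel$population
  if (!is.null(individuals)) {
    idx <- seq_along(sid)[individuals]
    hap <- as.vector(rbind(2L * idx - 1L, 2L * idx))
    a <- a[hap, , drop = FALSE]; sid <- sid[idx]; pop <- pop[idx]
  }
  if (!is.null(snps)) {
    a <- a[, snps, drop = FALSE]
    map <- map[snps, , drop = FALSE]
    class(map) <- c("marker_map", "data.frame")
  }
  haplotype_panel(a, sid, pop, map)
}

#' Subset a genotype matrix by SNPs and/or individuals
#'
#' @param geno a [genotype_matrix()].
#' @param snps integer or logical index into map rows.
#' @param individuals integer or logical index into individuals.
#' @return A `genotype_matrix`.
#' @export
subset_genotypes <- function(geno, snps = NULL, individuals = NULL) {
  d <- geno$dosages; map <- geno$map
  sid <- geno$sample_ids; pop <- geno$population
  if (!is.null(individuals)) {
    d <- d[individuals, , drop = FALSE]
    sid <- sid[individuals]; pop <- pop[individuals]
  }
  if (!is.null(snps)) {
    d <- d[, snps, drop = FALSE]
    map <- map[snps, , drop = FALSE]
    class(map) <- c("marker_map", "data.frame")
  }
  genotype_matrix(d, sid, pop, map)
}
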