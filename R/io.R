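#' Read a phased VCF into a haplotype panel
#'
#' Biallelic SNP records only: multiallelic or non-SNP records are skipped
#' and counted (a message reports the count). Every GT must be phased
#' (`a|b`); an unphased or missing GT is an error naming the record and
#' sample, since phased input is the panel contract.
#'
#' @param path VCF file (plain text or bgzipped).
#' @param population either a character vector of per-sample population
#'   labels (in VCF sample order) or the path to a two-column TSV
#'   (sample_id, population).
#' @return A [haplotype_panel()].
#' @export
read_phased_vcf <- function(path, population) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  snp_ok <- !is.na(alt) & !grepl(",", alt) & nchar(ref) == 1L & nchar(alt) == 1L
  n_skip <- sum(!snp_ok)
  if (n_skip > 0)
    message("read_phased_vcf: skipped ", n_skip, " multiallelic/non-SNP records")
  if (!any(snp_ok)) stop("no biallelic SNP records in ", path)
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(gt)) stop("VCF has no GT format field: ", path)
  gt <- gt[snp_ok, , drop = FALSE]
  fix <- fix[snp_ok, , drop = FALSE]
  samples <- colnames(gt)
  bad <- which(is.na(gt) | !grepl("^[01]\\|[01]$", gt), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop("unphased or missing GT at ", fix[bad[1, 1], "CHROM"], ":",
         fix[bad[1, 1], "POS"], " sample ", samples[bad[1, 2]],
         " (value '", gt[bad[1, 1], bad[1, 2]], "'); phased input required")
  }
  m <- nrow(gt); n <- length(samples)
  a <- matrix(0L, 2L * n, m)
  a[seq(1L, 2L * n, by = 2L), ] <- t(matrix(as.integer(substr(gt, 1L, 1L)), m, n))
  a[seq(2L, 2L * n, by = 2L), ] <- t(matrix(as.integer(substr(gt, 3L, 3L)), m, n))
  ids <- fix[, "ID"]
  ids[is.na(ids) | ids == "."] <- paste0("snp_", fix[, "CHROM"], "_",
                                         fix[, "POS"])[is.na(ids) | ids == "."]
  map <- marker_map(fix[, "CHROM"], as.integer(fix[, "POS"]), ids, ref[snp_ok],
                    alt[snp_ok])
  pop <- resolve_population(population, samples)
  haplotype_panel(a, samples, pop, map)
}

resolve_population <- function(population, samples) {
  if (length(population) == 1L && file.exists(population)) {
    tab <- read_population_file(population)
    idx <- match(samples, tab$sample_id)
    if (anyNA(idx))
      stop("samples missing from population file: ",
           paste(samples[is.na(idx)], collapse = ", "))
    tab$population[idx]
  } else {
    if (length(population) != length(samples))
      stop("population labels do not match the ", length(samples), " samples")
    as.character(population)
  }
}

#' Read / write a two-column population file (sample_id, population)
#'
#' @param path TSV path; a header line `sample_id<TAB>population` is optional
#'   on read and always written.
#' @return `read_population_file`: a data.frame with columns `sample_id` and
#'   `population`.
#' @export
read_population_file <- function(path) {
  tab <- utils::read.table(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE,
                           col.names = c("sample_id", "population"))
  if (nrow(tab) > 0 && tab$sample_id[1] == "sample_id") tab <- tab[-1, ]
  rownames(tab) <- NULL
  tab
}

#' @param x a [haplotype_panel()], [genotype_matrix()], or a data.frame with
#'   `sample_id` and `population` columns.
#' @rdname read_population_file
#' @export
write_population_file <- function(x, path) {
  tab <- if (is.data.frame(x)) x else
    data.frame(sample_id = x$sample_ids, population = x$population,
               stringsAsFactors = FALSE)
  write_tsv(tab[, c("sample_id", "population")], path)
}

#' Write a haplotype panel as phased VCF 4.2
#'
#' GT fields use the `|` separator; contig header lines carry chromosome
#' lengths (the configured length if given, otherwise the last SNP position).
#'
#' @param panel a [haplotype_panel()].
#' @param path output path (plain text).
#' @param chrom_lengths optional named vector of chromosome lengths in bp.
#' @return The path, invisibly.
#' @export
write_phased_vcf <- function(panel, path, chrom_lengths = NULL) {
  map <- panel$map
  chroms <- unique(map$chrom)
  if (is.null(chrom_lengths))
    chrom_lengths <- vapply(chroms, function(ch) max(map$pos[map$chrom == ch]), 0)
  header <- c("##fileformat=VCFv4.2",
              "##source=popsweep",
              paste0("##contig=<ID=", chroms, ",length=",
                     format(chrom_lengths[chroms], scientific = FALSE, trim = TRUE), ">"),
              '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", panel$sample_ids), collapse = "\t"))
  n <- length(panel$sample_ids)
  h1 <- panel$alleles[seq(1L, 2L * n, by = 2L), , drop = FALSE]
  h2 <- panel$alleles[seq(2L, 2L * n, by = 2L), , drop = FALSE]
  gt <- matrix(paste0(t(h1), "|", t(h2)), ncol = n)  # M x N
  body <- paste(map$chrom, map$pos, map$snp_id, map$ref, map$alt, ".", "PASS",
                ".", "GT", apply(gt, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read PLINK text PED/MAP files into a genotype matrix
#'
#' The PED is whitespace-delimited with six leading columns (family id,
#' individual id, father, mother, sex, phenotype) then two allele columns per
#' SNP; `0 0` encodes a missing genotype. The MAP has columns chromosome,
#' snp id, cM, bp, and optionally declared ref/alt alleles (columns 5-6); if
#' those are absent the major allele (ties broken alphabetically) is taken
#' as ref. The family id column is used as the population label.
#'
#' @param ped_path,map_path file paths.
#' @return A [genotype_matrix()] (dosage = count of alt alleles).
#' @export
read_ped_map <- function(ped_path, map_path) {
  maptab <- utils::read.table(map_path, header = FALSE,
                              stringsAsFactors = FALSE)
  if (!ncol(maptab) %in% c(4L, 6L))
    stop("MAP must have 4 or 6 columns, found ", ncol(maptab))
  m <- nrow(maptab)
  lines <- readLines(ped_path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(trimws(lines), "[ \t]+")
  nf <- vapply(fields, length, 1L)
  bad <- which(nf != 6L + 2L * m)
  if (length(bad))
    stop("PED line ", bad[1], " has ", nf[bad[1]], " fields, expected ",
         6L + 2L * m)
  n <- length(fields)
  pedmat <- matrix(unlist(fields), nrow = n, byrow = TRUE)
  pop <- pedmat[, 1L]
  sample_ids <- pedmat[, 2L]
  a1 <- pedmat[, 6L + 2L * seq_len(m) - 1L, drop = FALSE]
  a2 <- pedmat[, 6L + 2L * seq_len(m), drop = FALSE]
  if (ncol(maptab) == 6L) {
    ref <- as.character(maptab[[5L]]); alt <- as.character(maptab[[6L]])
  } else {
    ref <- character(m); alt <- character(m)
    for (j in seq_len(m)) {
      obs <- c(a1[, j], a2[, j]); obs <- obs[obs != "0"]
      lev <- sort(unique(obs))
      if (length(lev) > 2L)
        stop("SNP ", maptab[[2L]][j], " has >2 alleles in PED")
      if (length(lev) == 0L) lev <- c("A", "G")
      if (length(lev) == 1L) lev <- c(lev, setdiff(c("A", "C", "G", "T"), lev)[1])
      counts <- c(sum(obs == lev[1]), sum(obs == lev[2]))
      ref[j] <- lev[which.max(counts)]; alt[j] <- lev[-which.max(counts)][1]
      if (counts[1] == counts[2]) { ref[j] <- lev[1]; alt[j] <- lev[2] }
    }
  }
  d <- matrix(NA_integer_, n, m)
  for (j in seq_len(m)) {
    ok <- c(ref[j], alt[j], "0")
    badal <- !(a1[, j] %in% ok) | !(a2[, j] %in% ok)
    if (any(badal))
      stop("PED line ", which(badal)[1], " SNP ", maptab[[2L]][j],
           ": allele not in declared {", ref[j], ",", alt[j], ",0}")
    miss <- a1[, j] == "0" | a2[, j] == "0"
    d[, j] <- (a1[, j] == alt[j]) + (a2[, j] == alt[j])
    d[miss, j] <- NA_integer_
  }
  ord <- order(match(maptab[[1L]], unique(maptab[[1L]])), maptab[[4L]])
  map <- marker_map(maptab[[1L]][ord], maptab[[4L]][ord],
                    maptab[[2L]][ord], ref[ord], alt[ord])
  genotype_matrix(d[, ord, drop = FALSE], sample_ids, pop, map)
}

#' Write a genotype matrix as PLINK text PED/MAP
#'
#' @param geno a [genotype_matrix()].
#' @param ped_path,map_path output paths. The MAP is written with 6 columns
#'   (declared ref/alt) so a round trip is exact.
#' @return Invisibly, `c(ped_path, map_path)`.
#' @export
write_ped_map <- function(geno, ped_path, map_path) {
  map <- geno$map
  utils::write.table(
    data.frame(map$chrom, map$snp_id, 0, map$pos, map$ref, map$alt),
    map_path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  d <- geno$dosages
  n <- nrow(d); m <- ncol(d)
  a1 <- matrix(map$ref[col(d)], n, m); a2 <- a1
  i1 <- which(d >= 1L); i2 <- which(d == 2L); im <- which(is.na(d))
  a1[i1] <- map$alt[col(d)][i1]
  a2[i2] <- map$alt[col(d)][i2]
  a1[im] <- "0"; a2[im] <- "0"
  geno_cols <- matrix("", n, 2L * m)
  geno_cols[, seq(1L, 2L * m, 2L)] <- a1
  geno_cols[, seq(2L, 2L * m, 2L)] <- a2
  lines <- paste(geno$population, geno$sample_ids, 0, 0, 0, -9,
                 apply(geno_cols, 1L, paste, collapse = " "))
  writeLines(lines, ped_path)
  invisible(c(ped_path, map_path))
}

#' Collapse a phased panel to diploid dosages
#'
#' @param panel a [haplotype_panel()].
#' @return A [genotype_matrix()] with `dosage(i, j)` the sum of individual
#'   `i`'s two haplotype alleles at SNP `j`; no missing entries.
#' @export
collapse_to_genotypes <- function(panel) {
  n <- length(panel$sample_ids)
  d <- panel$alleles[seq(1L, 2L * n, by = 2L), , drop = FALSE] +
    panel$alleles[seq(2L, 2L * n, by = 2L), , drop = FALSE]
  genotype_matrix(d, panel$sample_ids, panel$population, panel$map)
}

#' Quality-control thresholds
#'
#' Defaults follow common SNP-array practice for breed panels: MAF < 0.01,
#' per-SNP missingness > 0.10, per-individual missingness > 0.10,
#' Hardy-Weinberg exact p < 1e-4, and exclusion of individuals with
#' heterozygosity-based inbreeding coefficient above 0.05.
#'
#' @param maf_min minimum minor allele frequency.
#' @param snp_missing_max maximum per-SNP missing-call proportion.
#' @param ind_missing_max maximum per-individual missing-call proportion.
#' @param hwe_p_min minimum Hardy-Weinberg exact-test p-value.
#' @param f_i_max maximum inbreeding coefficient (used by the pipeline's
#'   pre-QC individual filter, see [inbreeding_coefficients()]).
#' @return A list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(maf_min = 0.01, snp_missing_max = 0.10,
                          ind_missing_max = 0.10, hwe_p_min = 1e-4,
                          f_i_max = 0.05) {
  vals <- c(maf_min, snp_missing_max, ind_missing_max, hwe_p_min)
  stopifnot(all(vals >= 0), all(vals <= 1))
  structure(list(maf_min = maf_min, snp_missing_max = snp_missing_max,
                 ind_missing_max = ind_missing_max, hwe_p_min = hwe_p_min,
                 f_i_max = f_i_max),
            class = "qc_thresholds")
}

#' Genotype quality control
#'
#' Filters in a fixed order, mirroring PLINK 1.9: (1) individuals with
#' missingness above `ind_missing_max`; (2) SNPs with missingness above
#' `snp_missing_max`; (3) SNPs with minor allele frequency below `maf_min`;
#' (4) SNPs with Hardy-Weinberg exact p below `hwe_p_min`. Per-SNP statistics
#' are computed within each population separately (on the individuals
#' surviving step 1), and a SNP failing in any population is removed, so the
#' surviving marker set is shared by both populations.
#'
#' @param geno a [genotype_matrix()].
#' @param thr a [qc_thresholds()].
#' @return A list with `geno` (the filtered [genotype_matrix()]) and
#'   `report` (class `qc_report`): per-step removal counts plus the removed
#'   individual and SNP ids.
#' @export
apply_qc <- function(geno, thr = qc_thresholds()) {
  stopifnot(inherits(geno, "genotype_matrix"), inherits(thr, "qc_thresholds"))
  d <- geno$dosages
  # step 1: individual missingness
  ind_miss <- rowMeans(is.na(d))
  drop_ind <- ind_miss > thr$ind_missing_max
  removed_ind <- geno$sample_ids[drop_ind]
  if (all(drop_ind)) stop("QC step 1 (individual missingness) removed all individuals")
  g <- subset_genotypes(geno, individuals = !drop_ind)
  pops <- unique(g$population)
  per_pop <- function(fun) {
    matrix(vapply(pops, function(p)
      fun(g$dosages[g$population == p, , drop = FALSE]),
      numeric(ncol(g$dosages))), ncol = length(pops))
  }
  # step 2: per-SNP missingness within population
  snp_miss <- per_pop(function(dd) colMeans(is.na(dd)))
  drop_geno <- apply(snp_miss > thr$snp_missing_max, 1L, any)
  removed_geno <- g$map$snp_id[drop_geno]
  if (all(drop_geno)) stop("QC step 2 (SNP missingness) removed all SNPs")
  g <- subset_genotypes(g, snps = !drop_geno)
  # step 3: MAF within population (on the post-step-2 marker set)
  maf <- per_pop(minor_af)
  drop_maf <- apply(maf < thr$maf_min | is.na(maf), 1L, any)
  removed_maf <- g$map$snp_id[drop_maf]
  if (all(drop_maf)) stop("QC step 3 (MAF) removed all SNPs")
  g <- subset_genotypes(g, snps = !drop_maf)
  # step 4: HWE exact test within population
  hwe_p <- vapply(pops, function(p) {
    dd <- g$dosages[g$population == p, , drop = FALSE]
    vapply(seq_len(ncol(dd)), function(j) {
      x <- dd[, j]
      hwe_exact_test(sum(x == 0L, na.rm = TRUE), sum(x == 1L, na.rm = TRUE),
                     sum(x == 2L, na.rm = TRUE))
    }, 1.0)
  }, numeric(ncol(g$dosages)))
  if (is.null(dim(hwe_p))) hwe_p <- matrix(hwe_p, ncol = length(pops))
  drop_hwe <- apply(hwe_p < thr$hwe_p_min, 1L, any)
  removed_hwe <- g$map$snp_id[drop_hwe]
  if (all(drop_hwe)) stop("QC step 4 (HWE) removed all SNPs")
  g <- subset_genotypes(g, snps = !drop_hwe)
  report <- structure(list(
    counts = c(individual_missingness = length(removed_ind),
               snp_missingness = length(removed_geno),
               maf = length(removed_maf),
               hwe = length(removed_hwe)),
    removed_individuals = removed_ind,
    removed_snps = list(snp_missingness = removed_geno, maf = removed_maf,
                        hwe = removed_hwe),
    thresholds = thr,
    n_individuals_kept = length(g$sample_ids),
    n_snps_kept = ncol(g$dosages)), class = "qc_report")
  list(geno = g, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("QC report (filter order: MIND > GENO > MAF > HWE)\n")
  cat(sprintf("  individuals removed (missingness): %d\n", x$counts[1]))
  cat(sprintf("  SNPs removed (missingness): %d\n", x$counts[2]))
  cat(sprintf("  SNPs removed (MAF): %d\n", x$counts[3]))
  cat(sprintf("  SNPs removed (HWE): %d\n", x$counts[4]))
  cat(sprintf("  kept: %d individuals x %d SNPs\n",
              x$n_individuals_kept, x$n_snps_kept))
  invisible(x)
}

#' Write a QC report as TSV
#'
#' One row per removed individual or SNP with the step that removed it.
#'
#' @param report a `qc_report` from [apply_qc()].
#' @param path output TSV path.
#' @return The path, invisibly.
#' @export
write_qc_report <- function(report, path) {
  block <- function(step, kind, id)
    data.frame(step = rep(step, length(id)), kind = rep(kind, length(id)),
               id = id, stringsAsFactors = FALSE)
  rows <- rbind(
    block("individual_missingness", "individual", report$removed_individuals),
    block("snp_missingness", "snp", report$removed_snps$snp_missingness),
    block("maf", "snp", report$removed_snps$maf),
    block("hwe", "snp", report$removed_snps$hwe))
  write_tsv(rows, path)
}
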