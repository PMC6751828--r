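#' Per-individual inbreeding coefficients from loss of heterozygosity
#'
#' Method-of-moments excess-homozygosity estimator (the statistic PLINK's
#' `--het` reports): for individual `i`,
#' `f_i = (O_i - E_i) / (n_i - E_i)` where `O_i` is the observed homozygote
#' count over the individual's non-missing SNPs, `n_i` that SNP count, and
#' `E_i = sum_j (1 - 2 p_j (1 - p_j) * n_j / (n_j - 1))` the expected
#' homozygote count under Hardy-Weinberg with the small-sample correction
#' `n_j / (n_j - 1)` (`p_j` the sample alt-allele frequency and `n_j` the
#' non-missing allele count at SNP `j`).
#'
#' @param geno a [genotype_matrix()]; frequencies are computed over its
#'   samples, so call per population for within-breed estimates.
#' @return A data.frame with columns `sample_id`, `population`,
#'   `observed_hom`, `expected_hom`, `n_nonmissing`, `f_i`.
#' @export
inbreeding_coefficients <- function(geno) {
  stopifnot(inherits(geno, "genotype_matrix"))
  d <- geno$dosages
  p <- alt_freq(d)
  n_alleles <- 2 * colSums(!is.na(d))
  usable <- !is.na(p) & n_alleles >= 2
  if (!any(usable & p > 0 & p < 1))
    stop("inbreeding_coefficients: no polymorphic SNPs (denominator undefined)")
  e_hom_snp <- 1 - 2 * p * (1 - p) * n_alleles / (n_alleles - 1)
  e_hom_snp[!usable] <- NA_real_
  nonmiss <- !is.na(d) & rep(usable, each = nrow(d))
  obs_hom <- rowSums((d == 0L | d == 2L) & nonmiss, na.rm = TRUE)
  e_hom_snp0 <- ifelse(is.na(e_hom_snp), 0, e_hom_snp)
  exp_hom <- as.vector(nonmiss %*% e_hom_snp0)
  n_i <- rowSums(nonmiss)
  denom <- n_i - exp_hom
  if (any(denom <= 0))
    stop("inbreeding_coefficients: degenerate denominator for individual ",
         geno$sample_ids[which(denom <= 0)[1]])
  data.frame(sample_id = geno$sample_ids, population = geno$population,
             observed_hom = obs_hom, expected_hom = exp_hom,
             n_nonmissing = n_i, f_i = (obs_hom - exp_hom) / denom,
             stringsAsFactors = FALSE)
}

#' Exclude individuals whose inbreeding coefficient exceeds a bound
#'
#' f_i is estimated within each population separately, then individuals with
#' `f_i > f_i_max` are removed.
#'
#' @param geno a [genotype_matrix()].
#' @param f_i_max exclusion threshold (default 0.05).
#' @return A list with `geno` (filtered), `f_table` (the per-individual
#'   estimates) and `removed` (excluded sample ids).
#' @export
filter_inbred <- function(geno, f_i_max = 0.05) {
  tabs <- lapply(unique(geno$population), function(p)
    inbreeding_coefficients(subset_genotypes(geno,
                                             individuals = geno$population == p)))
  f_table <- do.call(rbind, tabs)
  f_table <- f_table[match(geno$sample_ids, f_table$sample_id), ]
  rownames(f_table) <- NULL
  keep <- f_table$f_i <= f_i_max
  if (!any(keep)) stop("filter_inbred: all individuals exceed f_i_max")
  list(geno = subset_genotypes(geno, individuals = keep),
       f_table = f_table,
       removed = geno$sample_ids[!keep])
}

#' Hardy-Weinberg exact test
#'
#' Two-sided exact test on one SNP's genotype counts: conditioning on the
#' allele counts, the p-value is the sum over all possible heterozygote
#' counts of the probabilities no larger than that of the observed count
#' (hypergeometric-type null, no mid-p correction).
#'
#' @param n_AA,n_Aa,n_aa genotype counts (non-negative, total >= 1).
#' @return The exact p-value.
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  stopifnot(n_AA >= 0, n_Aa >= 0, n_aa >= 0)
  n <- n_AA + n_Aa + n_aa
  if (n < 1) stop("hwe_exact_test: empty genotype counts")
  n_a <- 2L * n_aa + n_Aa           # alt allele count
  n_A <- 2L * n_AA + n_Aa
  n1 <- min(n_a, n_A)               # rarer allele
  if (n1 == 0L) return(1)
  hets <- seq.int(n1 %% 2L, n1, by = 2L)
  # log P(het = h | n, n1) up to a shared constant
  logp <- -lfactorial((n1 - hets) / 2) - lfactorial(hets) -
    lfactorial(n - (n1 + hets) / 2) + hets * log(2)
  logp <- logp - max(logp)
  prob <- exp(logp) / sum(exp(logp))
  p_obs <- prob[match(n_Aa, hets)]
  sum(prob[prob <= p_obs * (1 + 1e-12)])
}

#' Pairwise linkage disequilibrium r-squared on genotype dosages
#'
#' Squared Pearson correlation of the two dosage vectors over
#' pairwise-complete individuals (composite LD; no phasing needed).
#'
#' @param geno a [genotype_matrix()].
#' @param snp_a,snp_b column indices or SNP ids.
#' @return r-squared, or `NA_real_` when undefined (fewer than two complete
#'   pairs or zero variance at either SNP) - distinct from a true 0.
#' @export
ld_r2 <- function(geno, snp_a, snp_b) {
  j <- resolve_snp(geno$map, snp_a)
  k <- resolve_snp(geno$map, snp_b)
  x <- geno$dosages[, j]; y <- geno$dosages[, k]
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 2L) return(NA_real_)
  x <- x[ok]; y <- y[ok]
  if (stats::var(x) == 0 || stats::var(y) == 0) return(NA_real_)
  stats::cor(x, y)^2
}

resolve_snp <- function(map, snp) {
  if (is.character(snp)) {
    j <- match(snp, map$snp_id)
    if (is.na(j)) stop("unknown SNP id: ", snp)
    j
  } else as.integer(snp)
}

#' LD-pruning parameters
#'
#' @param window_snps window size in SNPs.
#' @param step_snps SNPs the window advances per slide (<= `window_snps`).
#' @param r2_max r-squared ceiling; one member of any kept pair exceeding it
#'   is removed.
#' @return A list of class `ld_prune_params`. Defaults: 50-SNP window,
#'   step 5, r2 > 0.5 pruned.
#' @export
ld_prune_params <- function(window_snps = 50L, step_snps = 5L, r2_max = 0.5) {
  stopifnot(step_snps <= window_snps, r2_max > 0, r2_max <= 1)
  structure(list(window_snps = as.integer(window_snps),
                 step_snps = as.integer(step_snps),
                 r2_max = as.numeric(r2_max)),
            class = "ld_prune_params")
}

#' Greedy windowed LD pruning
#'
#' Within each sliding window (per chromosome) every kept pair with
#' `r^2 > r2_max` loses its lower-MAF member (tie: the later map position is
#' removed); the window then slides by `step_snps`. A SNP removed in one
#' window stays removed. After the pass no kept pair within any window
#' position exceeds the ceiling.
#'
#' @param geno a [genotype_matrix()].
#' @param params an [ld_prune_params()].
#' @return Integer vector of kept SNP column indices (into `geno$map`).
#' @export
ld_prune <- function(geno, params = ld_prune_params()) {
  stopifnot(inherits(geno, "genotype_matrix"),
            inherits(params, "ld_prune_params"))
  d <- geno$dosages
  maf <- minor_af(d)
  maf[is.na(maf)] <- 0
  kept <- rep(TRUE, ncol(d))
  for (ch in unique(geno$map$chrom)) {
    cols <- which(geno$map$chrom == ch)
    m <- length(cols)
    starts <- seq.int(1L, max(1L, m), by = params$step_snps)
    for (s in starts) {
      idx <- cols[s:min(s + params$window_snps - 1L, m)]
      idx <- idx[kept[idx]]
      if (length(idx) < 2L) next
      r2 <- suppressWarnings(
        stats::cor(d[, idx, drop = FALSE],
                   use = "pairwise.complete.obs")^2)
      alive <- rep(TRUE, length(idx))
      for (a in seq_len(length(idx) - 1L)) {
        if (!alive[a]) next
        for (b in seq.int(a + 1L, length(idx))) {
          if (!alive[b]) next
          v <- r2[a, b]
          if (is.na(v) || v <= params$r2_max) next
          # remove lower MAF; tie -> later map position
          drop <- if (maf[idx[a]] < maf[idx[b]]) a
                  else if (maf[idx[b]] < maf[idx[a]]) b
                  else b
          alive[drop] <- FALSE
          if (drop == a) break
        }
      }
      kept[idx[!alive]] <- FALSE
      if (s + params$window_snps - 1L >= m) break
    }
  }
  which(kept)
}
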