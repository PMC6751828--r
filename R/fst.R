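#' Per-SNP Nei fixation index between two populations
#'
#' Nei's G_ST for two demes: with `p1`, `p2` the population alt-allele
#' frequencies and `pbar` their unweighted mean,
#' `H_T = 2 pbar (1 - pbar)`, `H_S = (2 p1 (1 - p1) + 2 p2 (1 - p2)) / 2`
#' and `F_ST = (H_T - H_S) / H_T`. SNPs with `H_T = 0` (both populations
#' fixed for the same allele) or with one population entirely missing are
#' undefined (`NA`) and excluded from window means. No sample-size
#' correction is applied, so values lie in `[0, 1]`; an optional
#' sample-size-weighted mean frequency is available but off by default.
#'
#' @param geno a [genotype_matrix()].
#' @param pops the two population labels (defaults to the two present).
#' @param weighted use sample-size-weighted mean frequency in `H_T`.
#' @return A data.frame `chrom`, `pos`, `snp_id`, `p1`, `p2`, `fst`.
#' @export
per_snp_fst <- function(geno, pops = NULL, weighted = FALSE) {
  stopifnot(inherits(geno, "genotype_matrix"))
  if (is.null(pops)) pops <- unique(geno$population)
  stopifnot(length(pops) == 2L)
  d1 <- geno$dosages[geno$population == pops[1], , drop = FALSE]
  d2 <- geno$dosages[geno$population == pops[2], , drop = FALSE]
  p1 <- alt_freq(d1); p2 <- alt_freq(d2)
  if (weighted) {
    n1 <- colSums(!is.na(d1)); n2 <- colSums(!is.na(d2))
    pbar <- (n1 * p1 + n2 * p2) / (n1 + n2)
  } else {
    pbar <- (p1 + p2) / 2
  }
  ht <- 2 * pbar * (1 - pbar)
  hs <- (2 * p1 * (1 - p1) + 2 * p2 * (1 - p2)) / 2
  fst <- ifelse(is.na(ht) | ht == 0, NA_real_, (ht - hs) / ht)
  data.frame(chrom = geno$map$chrom, pos = geno$map$pos,
             snp_id = geno$map$snp_id, p1 = p1, p2 = p2, fst = fst,
             stringsAsFactors = FALSE)
}

#' Average a per-SNP statistic over non-overlapping genomic windows
#'
#' Windows tile each chromosome as `[k*width + 1, (k+1)*width]` bp, anchored
#' at position 1. Undefined per-SNP values are excluded; windows with no
#' defined value carry `NA` and are excluded from the empirical distribution
#' used by [empirical_cutoff()].
#'
#' @param values numeric per-SNP statistic (length = SNPs in `map`).
#' @param map a [marker_map()].
#' @param width_bp window width in bp (default 500 kb).
#' @return A data.frame `chrom`, `start_bp`, `end_bp`, `n_snps`, `mean_value`
#'   with one row per window containing at least one SNP.
#' @export
window_average <- function(values, map, width_bp = 500000) {
  stopifnot(length(values) == nrow(map))
  wk <- window_key(map, width_bp)
  keys <- unique(wk$key)
  idx <- match(wk$key, keys)
  n_def <- tapply(!is.na(values), idx, sum)
  sums <- tapply(ifelse(is.na(values), 0, values), idx, sum)
  first <- !duplicated(idx)
  data.frame(chrom = wk$chrom[first],
             start_bp = wk$start[first],
             end_bp = wk$end[first],
             n_snps = as.integer(tapply(rep(1L, length(idx)), idx, sum)),
             n_defined = as.integer(n_def),
             mean_value = ifelse(n_def > 0, sums / n_def, NA_real_),
             stringsAsFactors = FALSE)
}

#' Empirical top-fraction cutoff over window means
#'
#' The cutoff is the smallest of the top `ceil(top_fraction * n)` defined
#' window means (an order-statistic quantile); a window is significant iff
#' its mean is `>=` the cutoff, so ties at the cutoff are included. With all
#' means equal every window is flagged (degenerate tie).
#'
#' @param windows output of [window_average()].
#' @param top_fraction upper tail fraction (default 0.01).
#' @return A list with `cutoff` and `windows` (input plus a `significant`
#'   flag; undefined windows are never significant).
#' @export
empirical_cutoff <- function(windows, top_fraction = 0.01) {
  vals <- windows$mean_value[!is.na(windows$mean_value)]
  if (!length(vals)) stop("no window with a defined mean")
  k <- ceiling(top_fraction * length(vals))
  cutoff <- sort(vals, decreasing = TRUE)[k]
  windows$significant <- !is.na(windows$mean_value) &
    windows$mean_value >= cutoff
  list(cutoff = cutoff, windows = windows)
}

#' Windowed F_ST genome scan
#'
#' Convenience wrapper: [per_snp_fst()] then [window_average()] then
#' [empirical_cutoff()].
#'
#' @param geno a [genotype_matrix()].
#' @param pops the two population labels.
#' @param width_bp window width (default 500 kb).
#' @param top_fraction flagged upper tail (default 0.01).
#' @return A list with `per_snp` (data.frame), `windows` (data.frame with
#'   `significant`), and `cutoff`.
#' @export
fst_scan <- function(geno, pops = NULL, width_bp = 500000,
                     top_fraction = 0.01) {
  per_snp <- per_snp_fst(geno, pops)
  win <- window_average(per_snp$fst, geno$map, width_bp)
  cut <- empirical_cutoff(win, top_fraction)
  win <- cut$windows
  names(win)[names(win) == "mean_value"] <- "mean_fst"
  list(per_snp = per_snp, windows = win, cutoff = cut$cutoff)
}
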