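#' Site extended haplotype homozygosity (EHH) curve
#'
#' Computed over all haplotypes of one population at a core SNP: at an
#' offset covering the SNP set S beyond the core,
#' `EHH = sum_h n_h (n_h - 1) / (n (n - 1))` where `n_h` counts haplotypes
#' identical over the core plus S. The curve starts at distance 0 with
#' EHH = 1 (a single unsplit haplotype set) and is extended SNP by SNP
#' outward; computation stops when EHH falls below `ehh_cutoff` (the
#' sub-cutoff value is not recorded) or the chromosome end is reached
#' (`truncated_at_end` set).
#'
#' @param panel a [haplotype_panel()] (phased, no missing).
#' @param population population label.
#' @param core_snp SNP id or map row index.
#' @param direction "left" or "right" along the chromosome.
#' @param ehh_cutoff truncation level (default 0.05).
#' @return A list of class `ehh_curve`: `core_snp`, `direction`, `distances`
#'   (bp offsets, increasing, starting at 0), `ehh` (same length, starting at
#'   1), `truncated_at_end`.
#' @export
site_ehh <- function(panel, population, core_snp, direction = c("right", "left"),
                     ehh_cutoff = 0.05) {
  direction <- match.arg(direction)
  stopifnot(inherits(panel, "haplotype_panel"))
  j0 <- resolve_snp(panel$map, core_snp)
  rows <- hap_rows_of(panel, population)
  n <- length(rows)
  if (n < 2L) stop("site_ehh: need at least 2 haplotypes")
  ch <- panel$map$chrom[j0]
  chrom_cols <- which(panel$map$chrom == ch)
  a <- panel$alleles[rows, , drop = FALSE]
  js <- if (direction == "right") chrom_cols[chrom_cols > j0]
        else rev(chrom_cols[chrom_cols < j0])
  grp <- match(a[, j0], unique(a[, j0]))
  dist <- 0; ehh <- 1
  denom <- n * (n - 1)
  truncated <- FALSE
  if (!length(js)) truncated <- TRUE
  for (j in js) {
    key <- grp * 2L + a[, j]
    grp <- match(key, unique(key))
    tab <- tabulate(grp)
    e <- sum(tab * (tab - 1)) / denom
    if (e < ehh_cutoff) break
    dist <- c(dist, abs(panel$map$pos[j] - panel$map$pos[j0]))
    ehh <- c(ehh, e)
    if (j == js[length(js)]) truncated <- TRUE
  }
  structure(list(core_snp = panel$map$snp_id[j0], direction = direction,
                 distances = dist, ehh = ehh, truncated_at_end = truncated),
            class = "ehh_curve")
}

hap_rows_of <- function(panel, population) {
  ind <- which(panel$population == population)
  if (!length(ind)) stop("population not in panel: ", population)
  as.vector(rbind(2L * ind - 1L, 2L * ind))
}

#' Integrated site EHH (iES)
#'
#' Trapezoidal integral of the two-sided EHH curve over physical distance
#' (bp), left plus right, integrating while EHH stays at or above
#' `ehh_cutoff`. Partial integrals at chromosome ends are kept (see
#' [site_ehh()]).
#'
#' @inheritParams site_ehh
#' @return The integral in bp (a single number).
#' @export
ies <- function(panel, population, core_snp, ehh_cutoff = 0.05) {
  j0 <- resolve_snp(panel$map, core_snp)
  ch <- panel$map$chrom[j0]
  if (sum(panel$map$chrom == ch) < 2L)
    stop("ies: degenerate curve, core SNP is alone on its chromosome")
  left <- site_ehh(panel, population, j0, "left", ehh_cutoff)
  right <- site_ehh(panel, population, j0, "right", ehh_cutoff)
  trap <- function(cv) {
    if (length(cv$distances) < 2L) return(0)
    sum(diff(cv$distances) *
          (utils::head(cv$ehh, -1L) + utils::tail(cv$ehh, -1L)) / 2)
  }
  trap(left) + trap(right)
}

#' Cross-population extended haplotype homozygosity (XP-EHH)
#'
#' For every eligible core SNP (combined minor allele frequency >=
#' `maf_min`), `raw = ln(iES_a / iES_b)`; raw scores are standardized to
#' mean 0 / sd 1 over all eligible cores genome-wide. Positive standardized
#' scores indicate longer haplotypes (a more recent sweep) in `pop_a`.
#' Two-sided normal-tail p-values and Benjamini-Hochberg q-values are
#' attached. Cores where either iES is 0 (EHH fell below the cutoff
#' immediately on both sides) are skipped with a reason.
#'
#' Following the cross-population formulation, both populations' EHH curves
#' are integrated out to a common boundary: the SNP at which the EHH of the
#' combined sample falls below `ehh_cutoff`. Truncating the two integrals at
#' the same physical span compares like with like; truncating each
#' population on its own curve (as the standalone [ies()] does) makes the
#' log-ratio heavy-tailed at cores where one population's EHH collapses a
#' SNP earlier than the other's.
#'
#' If all raw scores are identical (sd 0), standardization is degenerate:
#' standardized scores, p- and q-values are `NA`, the result carries
#' `degenerate = TRUE`, and a warning is emitted.
#'
#' @param panel a [haplotype_panel()] holding both populations.
#' @param pop_a,pop_b population labels; `pop_a` is the numerator.
#' @param ehh_cutoff EHH truncation level (default 0.05).
#' @param maf_min core-SNP minor-allele-frequency floor (default 0.05).
#' @return A data.frame of class `xpehh_result`: `snp_id`, `chrom`, `pos`,
#'   `ies_a`, `ies_b`, `raw`, `standardized`, `p_value`, `q_value`, with
#'   attributes `skipped` (data.frame of snp_id, reason) and `degenerate`.
#' @export
xpehh <- function(panel, pop_a, pop_b, ehh_cutoff = 0.05, maf_min = 0.05) {
  stopifnot(inherits(panel, "haplotype_panel"))
  p_all <- colMeans(panel$alleles)
  maf <- pmin(p_all, 1 - p_all)
  eligible <- which(maf >= maf_min)
  low_maf <- panel$map$snp_id[maf < maf_min]
  skipped <- data.frame(snp_id = low_maf,
                        reason = rep("MAF below floor", length(low_maf)),
                        stringsAsFactors = FALSE)
  rows_a <- hap_rows_of(panel, pop_a)
  rows_b <- hap_rows_of(panel, pop_b)
  ies_a <- numeric(length(eligible)); ies_b <- numeric(length(eligible))
  for (ch in unique(panel$map$chrom)) {
    chrom_cols <- which(panel$map$chrom == ch)
    if (length(chrom_cols) < 2L) next
    sel <- which(panel$map$chrom[eligible] == ch)
    aa <- panel$alleles[rows_a, chrom_cols, drop = FALSE]
    ab <- panel$alleles[rows_b, chrom_cols, drop = FALSE]
    pos <- panel$map$pos[chrom_cols]
    core_local <- match(eligible[sel], chrom_cols)
    both <- ies_block_pair(aa, ab, pos, core_local, ehh_cutoff)
    ies_a[sel] <- both[1, ]
    ies_b[sel] <- both[2, ]
  }
  on_single <- panel$map$chrom[eligible] %in%
    names(which(table(panel$map$chrom) < 2))
  zero <- ies_a == 0 | ies_b == 0 | on_single
  if (any(zero))
    skipped <- rbind(skipped, data.frame(
      snp_id = panel$map$snp_id[eligible[zero]],
      reason = rep("iES zero at core", sum(zero)), stringsAsFactors = FALSE))
  keep <- eligible[!zero]
  raw <- log(ies_a[!zero] / ies_b[!zero])
  s <- stats::sd(raw)
  degenerate <- length(raw) < 2L || s == 0
  if (degenerate) {
    warning("xpehh: raw scores have zero variance; standardization degenerate")
    z <- rep(NA_real_, length(raw)); p <- z; q <- z
  } else {
    z <- (raw - mean(raw)) / s
    p <- 2 * stats::pnorm(-abs(z))
    q <- fdr_adjust(p)
  }
  out <- data.frame(snp_id = panel$map$snp_id[keep],
                    chrom = panel$map$chrom[keep],
                    pos = panel$map$pos[keep],
                    ies_a = ies_a[!zero], ies_b = ies_b[!zero],
                    raw = raw, standardized = z, p_value = p, q_value = q,
                    stringsAsFactors = FALSE)
  attr(out, "skipped") <- skipped
  attr(out, "degenerate") <- degenerate
  class(out) <- c("xpehh_result", "data.frame")
  out
}

# Paired iES for many cores on one chromosome: curves for both populations
# are integrated out to the SNP where the COMBINED-sample EHH drops below
# the cutoff, so both integrals cover the same physical span.
# Returns a 2 x length(cores) matrix (row 1 = pop a, row 2 = pop b).
ies_block_pair <- function(a, b, pos, cores, ehh_cutoff) {
  na <- nrow(a); nb <- nrow(b)
  den_a <- na * (na - 1); den_b <- nb * (nb - 1)
  den_c <- (na + nb) * (na + nb - 1)
  ab <- rbind(a, b)
  ia <- seq_len(na); ib <- na + seq_len(nb)
  m <- ncol(a)
  out <- matrix(0, 2L, length(cores))
  for (ci in seq_along(cores)) {
    j0 <- cores[ci]
    tot_a <- 0; tot_b <- 0
    for (dirstep in c(1L, -1L)) {
      gc <- match(ab[, j0], c(0L, 1L))  # combined-sample grouping
      prev_a <- 1; prev_b <- 1; prev_pos <- pos[j0]
      j <- j0 + dirstep
      while (j >= 1L && j <= m) {
        kc <- gc * 2L + ab[, j]; gc <- match(kc, unique(kc))
        tc <- tabulate(gc)
        e_c <- sum(tc * (tc - 1)) / den_c
        ta <- tabulate(gc[ia]); tb <- tabulate(gc[ib])
        e_a <- sum(ta * (ta - 1)) / den_a
        e_b <- sum(tb * (tb - 1)) / den_b
        if (e_c < ehh_cutoff) break
        step_bp <- abs(pos[j] - prev_pos)
        tot_a <- tot_a + step_bp * (prev_a + e_a) / 2
        tot_b <- tot_b + step_bp * (prev_b + e_b) / 2
        prev_a <- e_a; prev_b <- e_b; prev_pos <- pos[j]
        j <- j + dirstep
      }
    }
    out[1L, ci] <- tot_a
    out[2L, ci] <- tot_b
  }
  out
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up q-values; monotone non-decreasing in the rank order of p.
#'
#' @param p_values vector of p-values in `[0, 1]`.
#' @return q-values of the same length.
#' @export
fdr_adjust <- function(p_values) {
  stopifnot(all(p_values >= 0 & p_values <= 1, na.rm = TRUE))
  stats::p.adjust(p_values, method = "BH")
}

#' Significant XP-EHH windows
#'
#' A SNP is extreme if its absolute standardized score reaches the upper
#' `1 - percentile` tail of the empirical |score| distribution
#' (order-statistic cutoff, ties included) or exceeds the fixed
#' `threshold` (both flags are reported per SNP). Windows tile the genome as
#' in [window_average()] and are retained iff they hold at least `min_snps`
#' extreme SNPs. `mean_xpehh` averages the standardized score over the
#' window's extreme SNPs; `mean_xpehh_all` over all its scored SNPs.
#'
#' @param records an `xpehh_result` from [xpehh()].
#' @param width_bp window width (default 500 kb).
#' @param min_snps minimum extreme SNPs per retained window (default 3).
#' @param percentile empirical percentile defining the extreme tail
#'   (default 0.99).
#' @param threshold fixed |score| threshold (default 4.34).
#' @return A list with `windows` (retained windows), `snp_flags` (per-SNP
#'   `extreme_tail`, `beyond_threshold`), and `tail_cutoff`.
#' @export
significant_windows <- function(records, width_bp = 500000, min_snps = 3,
                                percentile = 0.99, threshold = 4.34) {
  z <- abs(records$standardized)
  if (all(is.na(z))) stop("significant_windows: no standardized scores")
  k <- ceiling((1 - percentile) * sum(!is.na(z)))
  tail_cutoff <- sort(z, decreasing = TRUE)[max(k, 1L)]
  extreme_tail <- !is.na(z) & z >= tail_cutoff
  beyond <- !is.na(z) & z > threshold
  extreme <- extreme_tail | beyond
  wk <- window_key(records[, c("chrom", "pos")], width_bp)
  keys <- unique(wk$key)
  idx <- match(wk$key, keys)
  first <- !duplicated(idx)
  n_ext <- tapply(extreme, idx, sum)
  mean_ext <- tapply(ifelse(extreme, records$standardized, NA_real_), idx,
                     mean, na.rm = TRUE)
  mean_all <- tapply(records$standardized, idx, mean)
  win <- data.frame(chrom = wk$chrom[first], start_bp = wk$start[first],
                    end_bp = wk$end[first],
                    n_snps = as.integer(tapply(rep(1L, length(idx)), idx, sum)),
                    n_significant_snps = as.integer(n_ext),
                    mean_xpehh = as.numeric(mean_ext),
                    mean_xpehh_all = as.numeric(mean_all),
                    stringsAsFactors = FALSE)
  retained <- win[win$n_significant_snps >= min_snps, , drop = FALSE]
  rownames(retained) <- NULL
  list(windows = retained,
       snp_flags = data.frame(snp_id = records$snp_id,
                              extreme_tail = extreme_tail,
                              beyond_threshold = beyond,
                              stringsAsFactors = FALSE),
       tail_cutoff = tail_cutoff)
}

#' Haplotype bifurcation tree around a core SNP
#'
#' The root holds all haplotypes of the population; its children are the
#' core-allele groups; each further level splits nodes by the allele at the
#' next SNP outward in the chosen direction. Node weight is the number of
#' haplotypes sharing the allele prefix, so weights at every depth sum to
#' the haplotype count. Truncates silently at the chromosome end.
#'
#' @inheritParams site_ehh
#' @param max_snps levels beyond the core to expand.
#' @return A nested list (`allele`, `count`, `children`) of class
#'   `bifurcation_tree`; serialize with [write_bifurcation_json()].
#' @export
bifurcation <- function(panel, population, core_snp,
                        direction = c("right", "left"), max_snps = 10L) {
  direction <- match.arg(direction)
  j0 <- resolve_snp(panel$map, core_snp)
  rows <- hap_rows_of(panel, population)
  a <- panel$alleles[rows, , drop = FALSE]
  ch <- panel$map$chrom[j0]
  chrom_cols <- which(panel$map$chrom == ch)
  js <- if (direction == "right") chrom_cols[chrom_cols > j0]
        else rev(chrom_cols[chrom_cols < j0])
  js <- utils::head(js, max_snps)
  snp_seq <- c(j0, js)
  grow <- function(hap_idx, level) {
    node <- list(allele = if (level == 1L) NA_integer_ else
                   a[hap_idx[1], snp_seq[level - 1L]],
                 count = length(hap_idx), children = list())
    if (level > length(snp_seq)) return(node)
    al <- a[hap_idx, snp_seq[level]]
    for (v in sort(unique(al)))
      node$children[[length(node$children) + 1L]] <-
        grow(hap_idx[al == v], level + 1L)
    node
  }
  tree <- grow(seq_len(nrow(a)), 1L)
  structure(list(core_snp = panel$map$snp_id[j0], population = population,
                 direction = direction, n_haplotypes = nrow(a), tree = tree),
            class = "bifurcation_tree")
}

#' Write a bifurcation tree as JSON
#'
#' @param bif a `bifurcation_tree` from [bifurcation()].
#' @param path output file.
#' @return The path, invisibly.
#' @export
write_bifurcation_json <- function(bif, path) {
  jsonlite::write_json(unclass(bif), path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}
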