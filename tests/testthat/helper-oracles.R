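# Independent brute-force oracles used across the suite. These deliberately
# re-derive each quantity with naive loops, not with the package's code path.

# ROH enumerator: literal, loop-based transcription of the class criteria.
oracle_roh <- function(geno, params) {
  out <- list()
  w <- params$window_snps
  for (ch in unique(geno$map$chrom)) {
    cols <- which(geno$map$chrom == ch)
    m <- length(cols)
    if (m < w) next
    pos <- geno$map$pos[cols]
    for (i in seq_along(geno$sample_ids)) {
      g <- geno$dosages[i, cols]
      qual <- logical(m - w + 1L)
      for (s in seq_len(m - w + 1L)) {
        win <- g[s:(s + w - 1L)]
        qual[s] <- sum(win == 1L, na.rm = TRUE) <= params$window_het_max &&
          sum(is.na(win)) <= params$window_missing_max
      }
      elig <- logical(m)
      for (j in seq_len(m)) {
        ws <- max(1L, j - w + 1L):min(j, m - w + 1L)
        elig[j] <- mean(qual[ws]) >= params$window_hit_threshold
      }
      # maximal eligible runs
      j <- 1L
      while (j <= m) {
        if (!elig[j]) { j <- j + 1L; next }
        k <- j
        while (k < m && elig[k + 1L]) k <- k + 1L
        a <- j; b <- k
        # trim to homozygous non-missing endpoints
        is_hom <- function(x) !is.na(x) && x != 1L
        while (a <= b && !is_hom(g[a])) a <- a + 1L
        while (b >= a && !is_hom(g[b])) b <- b - 1L
        if (a <= b) {
          # split at gaps > max_gap
          pieces <- list(); pa <- a
          for (q in a:max(a, b - 1L)) {
            if (q < b && pos[q + 1L] - pos[q] > params$max_gap) {
              pieces[[length(pieces) + 1L]] <- c(pa, q); pa <- q + 1L
            }
          }
          pieces[[length(pieces) + 1L]] <- c(pa, b)
          for (pc in pieces) {
            ns <- pc[2] - pc[1] + 1L
            lk <- (pos[pc[2]] - pos[pc[1]]) / 1000
            if (ns >= params$min_snps &&
                lk >= params$min_length_kb && lk < params$max_length_kb &&
                ns * params$min_density_kb >= lk) {
              out[[length(out) + 1L]] <- data.frame(
                individual = geno$sample_ids[i], chrom = ch,
                start_bp = pos[pc[1]], end_bp = pos[pc[2]], n_snps = ns,
                stringsAsFactors = FALSE)
            }
          }
        }
        j <- k + 1L
      }
    }
  }
  if (!length(out))
    return(data.frame(individual = character(), chrom = character(),
                      start_bp = integer(), end_bp = integer(),
                      n_snps = integer(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

# Canonical string form of a segment set, for set-identity comparison.
segment_key <- function(df) {
  sort(paste(df$individual, df$chrom, df$start_bp, df$end_bp, df$n_snps,
             sep = ":"))
}

# Pairwise-identity EHH oracle: EHH at the k-th flanking SNP equals the
# fraction of ordered haplotype pairs identical over the core..k interval.
oracle_ehh_curve <- function(alleles, pos, core, direction, cutoff) {
  n <- nrow(alleles)
  js <- if (direction == "right") seq_len(ncol(alleles))[-seq_len(core)]
        else rev(seq_len(core - 1L))
  dist <- 0; ehh <- 1
  for (step in seq_along(js)) {
    span <- c(core, js[seq_len(step)])
    same <- 0
    for (h1 in 1:(n - 1)) for (h2 in (h1 + 1):n)
      if (all(alleles[h1, span] == alleles[h2, span])) same <- same + 2
    e <- same / (n * (n - 1))
    if (e < cutoff) break
    dist <- c(dist, abs(pos[js[step]] - pos[core]))
    ehh <- c(ehh, e)
  }
  list(distances = dist, ehh = ehh)
}

oracle_ies <- function(alleles, pos, core, cutoff) {
  trap <- function(cv) {
    if (length(cv$distances) < 2L) return(0)
    sum(diff(cv$distances) * (head(cv$ehh, -1) + tail(cv$ehh, -1)) / 2)
  }
  trap(oracle_ehh_curve(alleles, pos, core, "left", cutoff)) +
    trap(oracle_ehh_curve(alleles, pos, core, "right", cutoff))
}

# HWE exact test by direct multinomial enumeration over genotype counts.
oracle_hwe <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  nA <- 2 * n_AA + n_Aa
  configs <- list(); probs <- numeric()
  for (het in 0:n) {
    aa2 <- (nA - het) / 2
    if (het > nA || aa2 != floor(aa2) || aa2 < 0) next
    bb <- n - het - aa2
    if (bb < 0) next
    lp <- lfactorial(n) - lfactorial(aa2) - lfactorial(het) -
      lfactorial(bb) + het * log(2)
    configs[[length(configs) + 1L]] <- het
    probs <- c(probs, exp(lp))
  }
  probs <- probs / sum(probs)
  p_obs <- probs[which(unlist(configs) == n_Aa)]
  sum(probs[probs <= p_obs * (1 + 1e-12)])
}

# Weighted Nei F_ST over SNPs from the two populations' frequency vectors:
# ratio of summed (H_T - H_S) to summed H_T (frequency-based oracle).
oracle_mean_fst <- function(p1, p2) {
  pbar <- (p1 + p2) / 2
  ht <- 2 * pbar * (1 - pbar)
  hs <- (2 * p1 * (1 - p1) + 2 * p2 * (1 - p2)) / 2
  ok <- ht > 0
  sum(ht[ok] - hs[ok]) / sum(ht[ok])
}

# Build a genotype_matrix with exact alt-allele counts per population.
geno_from_counts <- function(k1, k2, n_per_pop, pos = NULL, chrom = "1") {
  stopifnot(length(k1) == length(k2))
  m <- length(k1)
  if (is.null(pos)) pos <- seq_len(m) * 1000L
  make_col <- function(k, n) {
    d <- integer(n)
    d[seq_len(k %/% 2)] <- 2L
    if (k %% 2 == 1L) d[k %/% 2 + 1L] <- 1L
    d
  }
  d <- rbind(vapply(k1, make_col, integer(n_per_pop), n = n_per_pop),
             vapply(k2, make_col, integer(n_per_pop), n = n_per_pop))
  genotype_matrix(d, sprintf("s%02d", seq_len(2 * n_per_pop)),
                  rep(c("A", "B"), each = n_per_pop),
                  marker_map(rep(chrom, m), pos))
}

# Random dense genotype panel biased toward homozygosity, for ROH property
# tests: regular-ish spacing with occasional large gaps.
random_roh_geno <- function(n_ind, m, p_het = 0.2, p_miss = 0.03,
                            spacing = 3000, big_gap_rate = 0.02) {
  gaps <- ifelse(runif(m) < big_gap_rate,
                 sample(6000:20000, m, replace = TRUE),
                 sample(500:4900, m, replace = TRUE))
  pos <- cumsum(gaps)
  d <- matrix(sample(c(0L, 1L, 2L, NA_integer_), n_ind * m, replace = TRUE,
                     prob = c((1 - p_het - p_miss) / 2, p_het,
                              (1 - p_het - p_miss) / 2, p_miss)),
              n_ind, m)
  genotype_matrix(d, sprintf("i%02d", seq_len(n_ind)),
                  rep("A", n_ind), marker_map(rep("1", m), pos))
}

# Panel fixture: phased haplotypes from given per-haplotype allele rows.
panel_from_rows <- function(rows, pos = NULL, chrom = "1",
                            population = NULL) {
  a <- do.call(rbind, rows)
  n <- nrow(a) / 2
  if (is.null(pos)) pos <- seq_len(ncol(a)) * 1000L
  if (is.null(population)) population <- rep("A", n)
  haplotype_panel(a, sprintf("s%02d", seq_len(n)), population,
                  marker_map(rep(chrom, ncol(a)), pos))
}
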