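#' ROH class parameters
#'
#' Criteria defining one run-of-homozygosity length class plus the scanning
#' window. The stock classes (see [roh_class_defaults()]) are:
#' \describe{
#'   \item{short}{>= 3 SNPs, 1 SNP per 100 kb, max gap 5000 bp, length
#'     50-125 kb, 5-SNP window, 0 heterozygous / 0 missing allowed.}
#'   \item{medium}{>= 10 SNPs, 1/100, 5000 bp, 125-500 kb, 12-SNP window,
#'     0 het / 0 missing.}
#'   \item{long}{>= 30 SNPs, 1/100, 5000 bp, > 500 kb, 50-SNP window,
#'     1 heterozygous and 1 missing call allowed per window.}
#' }
#' Length intervals are `[min, max)` in kb so no segment falls in two
#' classes; the long class has no upper bound.
#'
#' @param name class label.
#' @param min_snps minimum SNPs in a segment.
#' @param min_density_kb density bound expressed as 1 SNP per this many kb.
#' @param max_gap maximum inter-SNP gap in bp.
#' @param min_length_kb,max_length_kb segment length bounds in kb
#'   (`max_length_kb = Inf` leaves the class open above).
#' @param window_snps scanning-window size in SNPs.
#' @param window_het_max heterozygous calls allowed per window.
#' @param window_missing_max missing calls allowed per window.
#' @param window_hit_threshold minimum fraction of the windows containing a
#'   SNP that must qualify for the SNP to be ROH-eligible (default 0.05,
#'   the PLINK `--homozyg-window-threshold` default).
#' @return A list of class `roh_class_params`.
#' @export
roh_class_params <- function(name, min_snps, min_density_kb = 100,
                             max_gap = 5000, min_length_kb,
                             max_length_kb = Inf, window_snps,
                             window_het_max = 0L, window_missing_max = 0L,
                             window_hit_threshold = 0.05) {
  stopifnot(min_snps >= 1, max_gap > 0, min_length_kb < max_length_kb)
  structure(list(name = as.character(name), min_snps = as.integer(min_snps),
                 min_density_kb = as.numeric(min_density_kb),
                 max_gap = as.numeric(max_gap),
                 min_length_kb = as.numeric(min_length_kb),
                 max_length_kb = as.numeric(max_length_kb),
                 window_snps = as.integer(window_snps),
                 window_het_max = as.integer(window_het_max),
                 window_missing_max = as.integer(window_missing_max),
                 window_hit_threshold = as.numeric(window_hit_threshold)),
            class = "roh_class_params")
}

#' @param which one of "short", "medium", "long", or "all" (a named list of
#'   all three).
#' @rdname roh_class_params
#' @export
roh_class_defaults <- function(which = c("short", "medium", "long", "all")) {
  which <- match.arg(which)
  defs <- list(
    short = roh_class_params("short", min_snps = 3, min_length_kb = 50,
                             max_length_kb = 125, window_snps = 5),
    medium = roh_class_params("medium", min_snps = 10, min_length_kb = 125,
                              max_length_kb = 500, window_snps = 12),
    long = roh_class_params("long", min_snps = 30, min_length_kb = 500,
                            window_snps = 50, window_het_max = 1L,
                            window_missing_max = 1L))
  if (which == "all") defs else defs[[which]]
}

#' Sliding-window ROH detection
#'
#' Per individual and chromosome: (1) every contiguous window of
#' `window_snps` SNPs qualifies iff it holds at most `window_het_max`
#' heterozygous and `window_missing_max` missing calls; (2) a SNP is
#' ROH-eligible iff the fraction of windows containing it that qualify is at
#' least `window_hit_threshold`; (3) maximal runs of eligible SNPs are
#' trimmed to start and end at homozygous non-missing calls, then split at
#' any inter-SNP gap above `max_gap`; (4) surviving runs are kept iff they
#' satisfy the class's SNP count, length and density bounds.
#' `length_kb = (end_bp - start_bp) / 1000`.
#'
#' Chromosomes with fewer SNPs than the window yield no calls (warning).
#'
#' @param geno a [genotype_matrix()] (typically LD-pruned).
#' @param params a [roh_class_params()].
#' @return A data.frame of segments: `individual`, `population`, `chrom`,
#'   `start_bp`, `end_bp`, `n_snps`, `length_kb`, `class`.
#' @export
detect_roh <- function(geno, params) {
  stopifnot(inherits(geno, "genotype_matrix"),
            inherits(params, "roh_class_params"))
  out <- list()
  w <- params$window_snps
  for (ch in unique(geno$map$chrom)) {
    cols <- which(geno$map$chrom == ch)
    m <- length(cols)
    if (m < w) {
      warning("chromosome ", ch, " has ", m, " SNPs < window of ", w,
              "; no ROH called there")
      next
    }
    pos <- geno$map$pos[cols]
    gap_after <- c(diff(pos), 0)
    n_win <- m - w + 1L
    for (i in seq_along(geno$sample_ids)) {
      g <- geno$dosages[i, cols]
      het <- as.integer(!is.na(g) & g == 1L)
      mis <- as.integer(is.na(g))
      hc <- c(0L, cumsum(het)); mc <- c(0L, cumsum(mis))
      qual <- (hc[(w + 1):(m + 1)] - hc[1:n_win]) <= params$window_het_max &
        (mc[(w + 1):(m + 1)] - mc[1:n_win]) <= params$window_missing_max
  qc <- c(0L, cumsum(qual))
      j <- seq_len(m)
      lo <- pmax(1L, j - w + 1L); hi <- pmin(j, n_win)
      eligible <- (qc[hi + 1L] - qc[lo]) / (hi - lo + 1L) >=
        params$window_hit_threshold
      segs <- eligible_runs_to_segments(eligible, g, pos, gap_after, params)
      if (length(segs)) {
        segs <- do.call(rbind, segs)
        segs$individual <- geno$sample_ids[i]
        segs$population <- geno$population[i]
        segs$chrom <- ch
        out[[length(out) + 1L]] <- segs
      }
    }
  }
  if (!length(out))
    return(data.frame(individual = character(), population = character(),
                      chrom = character(), start_bp = integer(),
                      end_bp = integer(), n_snps = integer(),
                      length_kb = numeric(), class = character(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[, c("individual", "population", "chrom", "start_bp", "end_bp",
          "n_snps", "length_kb", "class")]
}

# Steps (3)-(4) of the scan on one individual x chromosome.
eligible_runs_to_segments <- function(eligible, g, pos, gap_after, params) {
  segs <- list()
  r <- rle(eligible)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  hom <- !is.na(g) & g != 1L
  for (k in which(r$values)) {
    i1 <- starts[k]; i2 <- ends[k]
    while (i1 <= i2 && !hom[i1]) i1 <- i1 + 1L
    while (i2 >= i1 && !hom[i2]) i2 <- i2 - 1L
    if (i1 > i2) next
    # split at gaps > max_gap
    cuts <- which(gap_after[i1:(i2 - 1L)] > params$max_gap) + i1 - 1L
    sub_start <- c(i1, cuts + 1L)
    sub_end <- c(cuts, i2)
    if (i1 == i2) { sub_start <- i1; sub_end <- i2 }
    for (s in seq_along(sub_start)) {
      a <- sub_start[s]; b <- sub_end[s]
      n_snps <- b - a + 1L
      if (n_snps < params$min_snps) next
      len_kb <- (pos[b] - pos[a]) / 1000
      if (len_kb < params$min_length_kb || len_kb >= params$max_length_kb) next
      if (n_snps * params$min_density_kb < len_kb) next
      segs[[length(segs) + 1L]] <- data.frame(
        start_bp = pos[a], end_bp = pos[b], n_snps = n_snps,
        length_kb = len_kb, class = params$name, stringsAsFactors = FALSE)
    }
  }
  segs
}

#' Scan all three ROH classes
#'
#' Runs [detect_roh()] once per class over the same genotypes (three
#' independent passes) and row-binds the results.
#'
#' @param geno a [genotype_matrix()].
#' @param classes a named list of [roh_class_params()]
#'   (default [roh_class_defaults()]`("all")`).
#' @return A segment data.frame as in [detect_roh()].
#' @export
detect_roh_all <- function(geno, classes = roh_class_defaults("all")) {
  do.call(rbind, lapply(classes, function(p) detect_roh(geno, p)))
}

#' Per-population ROH summary
#'
#' For each population x class: total segment count, mean count per
#' individual (total / population size), mean segment length in kb, and mean
#' per-individual genome coverage (sum of segment lengths) in kb.
#'
#' @param segments a segment data.frame from [detect_roh()].
#' @param n_individuals named integer vector: population size used as the
#'   mean's denominator (individuals scanned, not just those with segments).
#' @return A data.frame with one row per population x class.
#' @export
roh_summary <- function(segments, n_individuals) {
  stopifnot(!is.null(names(n_individuals)))
  pops <- names(n_individuals)
  classes <- c("short", "medium", "long")
  rows <- list()
  for (p in pops) {
    for (cl in classes) {
      s <- segments[segments$population == p & segments$class == cl, ,
                    drop = FALSE]
      tot <- nrow(s)
      cov_by_ind <- if (tot) tapply(s$length_kb, s$individual, sum) else numeric()
      rows[[length(rows) + 1L]] <- data.frame(
        population = p, class = cl, total_n = tot,
        mean_n = tot / n_individuals[[p]],
        mean_length_kb = if (tot) mean(s$length_kb) else 0,
        mean_coverage_kb = sum(s$length_kb) / n_individuals[[p]],
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-SNP ROH incidence
#'
#' Share of individuals having at least one segment (of the given class)
#' covering each SNP position.
#'
#' @param segments a segment data.frame from [detect_roh()].
#' @param geno the [genotype_matrix()] the segments were called on (supplies
#'   the SNP positions and the individual denominator).
#' @param class segment class to count (default "long").
#' @return A data.frame `chrom`, `pos`, `snp_id`, `share`.
#' @export
snp_incidence <- function(segments, geno, class = "long") {
  n <- length(geno$sample_ids)
  share <- numeric(nrow(geno$map))
  segs <- segments[segments$class == class, , drop = FALSE]
  for (ch in unique(geno$map$chrom)) {
    cols <- which(geno$map$chrom == ch)
    pos <- geno$map$pos[cols]
    s <- segs[segs$chrom == ch, , drop = FALSE]
    if (!nrow(s)) next
    covered <- matrix(FALSE, n, length(cols))
    ind_idx <- match(s$individual, geno$sample_ids)
    for (r in seq_len(nrow(s))) {
      hit <- pos >= s$start_bp[r] & pos <= s$end_bp[r]
      covered[ind_idx[r], hit] <- TRUE
    }
    share[cols] <- colSums(covered) / n
  }
  data.frame(chrom = geno$map$chrom, pos = geno$map$pos,
             snp_id = geno$map$snp_id, share = share,
             stringsAsFactors = FALSE)
}

#' Population consensus ROH regions
#'
#' Maximal runs of consecutive SNPs whose incidence ([snp_incidence()])
#' reaches the consensus threshold; the region spans the first to last SNP of
#' the run. Single-SNP runs are reported with `start_bp == end_bp`. The
#' reported `share` is the minimum per-SNP incidence within the region (the
#' fraction of individuals whose ROH set covers every SNP of the region is
#' at most this value, and equals it when segments are long relative to the
#' region).
#'
#' @param incidence output of [snp_incidence()].
#' @param threshold consensus share (default 0.85).
#' @return A data.frame `chrom`, `start_bp`, `end_bp`, `n_snps`, `share`.
#' @export
consensus_regions <- function(incidence, threshold = 0.85) {
  rows <- list()
  for (ch in unique(incidence$chrom)) {
    sub <- incidence[incidence$chrom == ch, , drop = FALSE]
    ok <- sub$share >= threshold
    r <- rle(ok)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = ch, start_bp = sub$pos[starts[k]], end_bp = sub$pos[ends[k]],
        n_snps = ends[k] - starts[k] + 1L,
        share = min(sub$share[starts[k]:ends[k]]),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(chrom = character(), start_bp = integer(),
                      end_bp = integer(), n_snps = integer(),
                      share = numeric(), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
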