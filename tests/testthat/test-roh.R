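# A deterministic genotype with a planted homozygous run on a heterozygous
# background: trimming has nowhere to extend, so recovery must be exact.
planted_run_geno <- function(run_snps, spacing_bp, m = run_snps + 200,
                             n_ind = 1) {
  pos <- seq_len(m) * spacing_bp
  d <- matrix(1L, n_ind, m)  # all heterozygous background
  start <- 101L
  d[, start:(start + run_snps - 1L)] <- 2L
  list(geno = genotype_matrix(d, sprintf("i%02d", seq_len(n_ind)),
                              rep("A", n_ind),
                              marker_map(rep("1", m), pos)),
       run_idx = start:(start + run_snps - 1L), pos = pos)
}

test_that("an all-heterozygous individual yields no segments in any class", {
  d <- matrix(1L, 1, 300)
  g <- genotype_matrix(d, "i1", "A", marker_map(rep("1", 300), 1:300 * 2000L))
  for (p in roh_class_defaults("all"))
    expect_equal(nrow(detect_roh(g, p)), 0L)
})

test_that("a planted 150-SNP run at 4-kb spacing is one long segment", {
  fx <- planted_run_geno(150, 4000L)
  segs <- detect_roh(fx$geno, roh_class_defaults("long"))
  expect_equal(nrow(segs), 1L)
  # scanning-window semantics may shave edge SNPs whose window hit rate
  # falls below the 5% threshold; recovery must stay within one spacing
  expect_lte(abs(segs$start_bp - fx$pos[fx$run_idx[1]]), 4000L)
  expect_lte(abs(segs$end_bp - fx$pos[fx$run_idx[150]]), 4000L)
  expect_gte(segs$n_snps, 148L)
  expect_lte(segs$n_snps, 150L)
  # brute-force enumeration agrees exactly
  oracle <- oracle_roh(fx$geno, roh_class_defaults("long"))
  expect_identical(segment_key(segs), segment_key(oracle))
})

test_that("a 20-SNP 90-kb run is short-class only", {
  # 20 SNPs spanning 90 kb: spacing 90000/19
  pos <- c(1:100 * 1000L,
           as.integer(105000 + round((0:19) * 90000 / 19)),
           as.integer(200000 + 1:100 * 1000L))
  d <- matrix(1L, 1, length(pos))
  d[, 101:120] <- 0L
  g <- genotype_matrix(d, "i1", "A", marker_map(rep("1", length(pos)), pos))
  short <- detect_roh(g, roh_class_defaults("short"))
  expect_equal(nrow(short), 1L)
  expect_equal(short$n_snps, 20L)
  expect_equal(short$length_kb, 90)
  expect_equal(nrow(detect_roh(g, roh_class_defaults("medium"))), 0L)
  expect_equal(nrow(detect_roh(g, roh_class_defaults("long"))), 0L)
})

test_that("a 2-SNP plant is below every class minimum", {
  cfg <- simulation_config(n_individuals_per_pop = 5, seed = 61,
                           snps_per_chromosome = 300,
                           chromosome_length = 9e5)
  panel <- simulate_panel(cfg)
  pos <- panel$map$pos
  plant <- roh_plant("A", 1, "1", pos[100], pos[101])
  g <- collapse_to_genotypes(plant_roh(panel, plant))
  for (p in roh_class_defaults("all")) {
    segs <- suppressWarnings(detect_roh(g, p))
    hits <- segs[segs$start_bp >= pos[100] & segs$end_bp <= pos[101], ]
    expect_equal(nrow(hits), 0L)
  }
})

test_that("detection equals brute-force enumeration on random panels", {
  set.seed(67)
  for (cl in c("short", "medium", "long")) {
    params <- roh_class_defaults(cl)
    for (rep in 1:25) {
      g <- random_roh_geno(n_ind = 5, m = 120, p_het = runif(1, 0.05, 0.3),
                           p_miss = runif(1, 0, 0.08))
      got <- suppressWarnings(detect_roh(g, params))
      want <- oracle_roh(g, params)
      expect_identical(segment_key(got), segment_key(want),
                       info = paste(cl, "rep", rep))
    }
  }
})

test_that("no segment is reported in two classes", {
  set.seed(71)
  g <- random_roh_geno(n_ind = 10, m = 400, p_het = 0.08, p_miss = 0.02,
                       big_gap_rate = 0.01)
  segs <- suppressWarnings(detect_roh_all(g))
  key <- paste(segs$individual, segs$chrom, segs$start_bp, segs$end_bp)
  expect_length(intersect(key[segs$class == "short"],
                          key[segs$class == "medium"]), 0L)
  expect_length(intersect(key[segs$class == "medium"],
                          key[segs$class == "long"]), 0L)
  expect_length(intersect(key[segs$class == "short"],
                          key[segs$class == "long"]), 0L)
  # class length intervals are respected
  expect_true(all(segs$length_kb[segs$class == "short"] < 125))
  expect_true(all(segs$length_kb[segs$class == "medium"] >= 125 &
                    segs$length_kb[segs$class == "medium"] < 500))
  expect_true(all(segs$length_kb[segs$class == "long"] >= 500))
})

test_that("making genotypes more homozygous never shrinks ROH coverage", {
  set.seed(73)
  for (rep in 1:10) {
    g <- random_roh_geno(n_ind = 1, m = 150, p_het = 0.25, p_miss = 0.02)
    cov0 <- sum(suppressWarnings(detect_roh_all(g))$length_kb)
    het_idx <- which(g$dosages[1, ] == 1L)
    flip <- sample(het_idx, min(5, length(het_idx)))
    g$dosages[1, flip] <- 2L
    cov1 <- sum(suppressWarnings(detect_roh_all(g))$length_kb)
    expect_gte(cov1, cov0)
  }
})

test_that("narrow chromosomes warn and yield no calls", {
  d <- matrix(0L, 1, 10)
  g <- genotype_matrix(d, "i1", "A", marker_map(rep("1", 10), 1:10 * 1000L))
  expect_warning(segs <- detect_roh(g, roh_class_defaults("long")), "window")
  expect_equal(nrow(segs), 0L)
})

test_that("roh_summary computes totals, means and coverage per class", {
  segs <- data.frame(
    individual = c("a", "a", "b", "a"),
    population = "P",
    chrom = "1",
    start_bp = c(1e5, 6e5, 1e5, 2e6), end_bp = c(2e5, 7e5, 3e5, 2.7e6),
    n_snps = c(40, 40, 80, 220),
    length_kb = c(100, 100, 200, 700),
    class = c("short", "short", "medium", "long"),
    stringsAsFactors = FALSE)
  s <- roh_summary(segs, c(P = 4L))
  expect_equal(s$total_n[s$class == "short"], 2L)
  expect_equal(s$mean_n[s$class == "short"], 0.5)
  expect_equal(s$mean_length_kb[s$class == "short"], 100)
  expect_equal(s$mean_coverage_kb[s$class == "long"], 700 / 4)
  # empty input gives a zero-filled table
  s0 <- roh_summary(segs[0, ], c(P = 4L))
  expect_true(all(s0$total_n == 0) && all(s0$mean_n == 0))
})

test_that("incidence equals a naive per-individual interval scan", {
  set.seed(79)
  g <- random_roh_geno(n_ind = 12, m = 200, p_het = 0.1, p_miss = 0.03)
  segs <- suppressWarnings(detect_roh(g, roh_class_defaults("short")))
  inc <- snp_incidence(segs, g, class = "short")
  naive <- vapply(seq_len(nrow(g$map)), function(j) {
    covered <- vapply(g$sample_ids, function(id) {
      s <- segs[segs$individual == id, , drop = FALSE]
      any(s$start_bp <= g$map$pos[j] & s$end_bp >= g$map$pos[j])
    }, TRUE)
    mean(covered)
  }, 1.0)
  expect_equal(inc$share, naive, tolerance = 1e-15)
  # no segments -> all zeros
  inc0 <- snp_incidence(segs[0, ], g, class = "long")
  expect_true(all(inc0$share == 0))
})

test_that("consensus regions are maximal runs above the share threshold", {
  map <- marker_map(rep("1", 10), 1:10 * 1000L)
  inc <- data.frame(chrom = map$chrom, pos = map$pos, snp_id = map$snp_id,
                    share = c(0.9, 0.9, 0.5, 0.9, 0.86, 0.9, 0.5, 0.84,
                              0.9, 0.9))
  regions <- consensus_regions(inc, threshold = 0.85)
  expect_equal(nrow(regions), 3L)  # sub-threshold SNPs split runs
  expect_equal(regions$start_bp, c(1000L, 4000L, 9000L))
  expect_equal(regions$end_bp, c(2000L, 6000L, 10000L))
  expect_equal(regions$share, c(0.9, 0.86, 0.9))
  # uniform sub-threshold share gives nothing
  inc$share <- 0.5
  expect_equal(nrow(consensus_regions(inc)), 0L)
  # a single qualifying SNP is reported with start == end
  inc$share <- c(1, rep(0, 9))
  single <- consensus_regions(inc)
  expect_equal(single$start_bp, single$end_bp)
})
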