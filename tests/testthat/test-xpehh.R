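test_that("identical haplotypes keep EHH at 1 out to the chromosome end", {
  hap <- rep(list(c(1L, 0L, 1L, 1L, 0L, 1L)), 8)
  panel <- panel_from_rows(hap, pos = c(1, 3, 6, 10, 15, 21) * 1000L)
  cv <- site_ehh(panel, "A", 3, "right")
  expect_true(all(cv$ehh == 1))
  expect_true(cv$truncated_at_end)
  # iES spans the whole chromosome: rectangle of height 1
  expect_equal(ies(panel, "A", 3), (21 - 1) * 1000)
})

test_that("EHH equals the pair-counting value for a {2,1,1} partition", {
  rows <- list(c(0L, 1L, 1L), c(0L, 1L, 1L), c(0L, 0L, 1L), c(0L, 1L, 0L))
  panel <- panel_from_rows(rows)
  cv <- site_ehh(panel, "A", 1, "right", ehh_cutoff = 0)
  # at the first flank haplotypes partition {3,1}; at the second {2,1,1}
  expect_equal(cv$ehh[2], (3 * 2 + 0) / (4 * 3))
  expect_equal(cv$ehh[3], 2 / 12)
})

test_that("all-distinct haplotypes drop EHH to zero at the first flank", {
  rows <- list(c(0L, 0L, 0L), c(0L, 1L, 0L), c(1L, 0L, 1L), c(1L, 1L, 1L))
  panel <- panel_from_rows(rows)
  cv <- site_ehh(panel, "A", 1, "right", ehh_cutoff = 0)
  expect_equal(cv$ehh[2], 0)
})

test_that("EHH curves are monotone non-increasing within [0,1] from 1", {
  set.seed(103)
  for (rep in 1:20) {
    founders <- matrix(rbinom(4 * 30, 1, 0.5), 4, 30)
    rows <- lapply(1:12, function(i) {
      h <- founders[sample.int(4, 1), ]
      mut <- runif(30) < 0.1
      h[mut] <- 1L - h[mut]
      as.integer(h)
    })
    panel <- panel_from_rows(rows, pos = sort(sample.int(3e5, 30)))
    core <- sample(2:29, 1)
    for (dir in c("left", "right")) {
      cv <- site_ehh(panel, "A", core, dir, ehh_cutoff = 0)
      expect_equal(cv$ehh[1], 1)
      expect_true(all(diff(cv$ehh) <= 1e-12))
      expect_true(all(cv$ehh >= 0 & cv$ehh <= 1))
      expect_true(all(diff(cv$distances) > 0))
    }
  }
})

test_that("site_ehh and ies match the pairwise-identity oracle", {
  set.seed(107)
  for (rep in 1:15) {
    founders <- matrix(rbinom(3 * 25, 1, 0.5), 3, 25)
    rows <- lapply(1:10, function(i) {
      h <- founders[sample.int(3, 1), ]
      mut <- runif(25) < 0.08
      h[mut] <- 1L - h[mut]
      as.integer(h)
    })
    pos <- sort(sample.int(2e5, 25))
    panel <- panel_from_rows(rows, pos = pos)
    a <- panel$alleles
    core <- sample(3:23, 1)
    for (cutoff in c(0.05, 0)) {
      got <- site_ehh(panel, "A", core, "right", ehh_cutoff = cutoff)
      want <- oracle_ehh_curve(a, pos, core, "right", cutoff)
      expect_equal(got$ehh, want$ehh, tolerance = 1e-9)
      expect_equal(got$distances, want$distances)
    }
    expect_equal(ies(panel, "A", core), oracle_ies(a, pos, core, 0.05),
                 tolerance = 1e-9)
  }
})

test_that("identical input panels give symmetric iES and degenerate XP-EHH", {
  cfg <- simulation_config(n_individuals_per_pop = 10,
                           snps_per_chromosome = 120,
                           chromosome_length = 5e5, seed = 109)
  panel <- simulate_panel(cfg)
  # force both populations onto identical haplotypes
  panel$alleles[21:40, ] <- panel$alleles[1:20, ]
  for (core in c(30, 60, 90))
    expect_equal(ies(panel, "A", core), ies(panel, "B", core))
  expect_warning(xp <- xpehh(panel, "A", "B"), "degenerate")
  expect_true(attr(xp, "degenerate"))
  expect_true(all(xp$raw == 0))
  expect_true(all(is.na(xp$standardized)))
  expect_false(any(is.nan(xp$standardized)))
})

test_that("swapping populations negates raw and standardized scores", {
  cfg <- simulation_config(n_individuals_per_pop = 15, seed = 113,
                           snps_per_chromosome = 300,
                           chromosome_length = 1.5e6)
  panel <- simulate_panel(cfg)
  ab <- xpehh(panel, "A", "B")
  ba <- xpehh(panel, "B", "A")
  expect_equal(ab$raw, -ba$raw, tolerance = 1e-12)
  expect_equal(ab$standardized, -ba$standardized, tolerance = 1e-9)
})

test_that("standardized scores have mean 0 and sd 1 by construction", {
  cfg <- simulation_config(n_individuals_per_pop = 20, seed = 127,
                           snps_per_chromosome = 400,
                           chromosome_length = 2e6)
  xp <- xpehh(simulate_panel(cfg), "A", "B")
  expect_lt(abs(mean(xp$standardized)), 1e-9)
  expect_lt(abs(sd(xp$standardized) - 1), 1e-9)
  expect_true(all(xp$q_value >= xp$p_value))
})

test_that("a sweep planted in the denominator population scores negative", {
  cfg <- simulation_config(
    n_individuals_per_pop = 25, snps_per_chromosome = 600,
    chromosome_length = 3e6, seed = 131,
    sweep_specs = list(sweep_spec("B", "1", 1.5e6, 0.9, 4e5)))
  st <- simulate_study(cfg)
  xp <- xpehh(st$panel, "A", "B")
  core <- which.min(abs(xp$pos - 1.5e6))
  expect_lt(xp$raw[core], 0)
  expect_equal(xp$standardized[which.min(xp$raw)], min(xp$standardized))
})

test_that("Benjamini-Hochberg adjustment matches the longhand step-up", {
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(fdr_adjust(rep(1, 5)), rep(1, 5))
  expect_equal(fdr_adjust(0.2), 0.2)
  p <- c(0.001, 0.008, 0.039, 0.041, 0.042, 0.06, 0.074, 0.205)
  m <- length(p)
  longhand <- rev(cummin(rev(p * m / seq_len(m))))
  expect_equal(fdr_adjust(p), longhand)
})

test_that("window retention needs at least three extreme SNPs", {
  records <- data.frame(
    snp_id = sprintf("s%02d", 1:40),
    chrom = rep("1", 40),
    pos = c(1:20 * 10000L, 1000000L + 1:20 * 10000L),
    standardized = c(rep(0.1, 40)))
  records$standardized[c(1, 5, 9)] <- 6       # window 1: three extreme
  records$standardized[c(21, 25)] <- -6       # window 3: two extreme
  out <- significant_windows(records, width_bp = 500000, min_snps = 3,
                             percentile = 0.99, threshold = 4.34)
  expect_equal(nrow(out$windows), 1L)
  expect_equal(out$windows$start_bp, 1L)
  expect_equal(out$windows$mean_xpehh, 6)
  expect_equal(sum(out$snp_flags$beyond_threshold), 5L)
  # scattered mild scores: the 1% tail holds a single SNP, below min_snps
  records$standardized <- seq(0.01, 0.4, length.out = 40)
  out0 <- significant_windows(records, threshold = 4.34, min_snps = 3)
  expect_equal(sum(out0$snp_flags$extreme_tail), 1L)
  expect_equal(nrow(out0$windows), 0L)
})

test_that("bifurcation trees conserve haplotype counts at every depth", {
  # identical haplotypes: a path with full weight at each level
  panel <- panel_from_rows(rep(list(c(1L, 0L, 1L, 0L)), 6))
  bt <- bifurcation(panel, "A", 1, "right", max_snps = 3)
  depth_sums <- function(node) {
    sums <- c()
    level <- list(node)
    while (length(level)) {
      sums <- c(sums, sum(vapply(level, `[[`, 1L, "count")))
      level <- unlist(lapply(level, `[[`, "children"), recursive = FALSE)
    }
    sums
  }
  expect_true(all(depth_sums(bt$tree) == 6))
  # four haplotypes fully distinct by the second flank: four leaves
  rows <- list(c(0L, 0L, 0L), c(0L, 0L, 1L), c(0L, 1L, 0L), c(0L, 1L, 1L),
               c(0L, 0L, 0L), c(0L, 0L, 1L), c(0L, 1L, 0L), c(0L, 1L, 1L))
  p2 <- panel_from_rows(rows)
  bt2 <- bifurcation(p2, "A", 1, "right", max_snps = 2)
  expect_true(all(depth_sums(bt2$tree) == 8))
  leaves <- function(node) if (!length(node$children)) 1L else
    sum(vapply(node$children, leaves, 1L))
  expect_equal(leaves(bt2$tree), 4L)
  # JSON serialization round-trips the counts
  path <- withr::local_tempfile(fileext = ".json")
  write_bifurcation_json(bt2, path)
  parsed <- jsonlite::read_json(path)
  expect_equal(parsed$tree$count, 8L)
})
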