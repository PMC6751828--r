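#' Simulation configuration for a two-population SNP panel
#'
#' Describes a Balding-Nichols style two-population panel: per SNP an
#' ancestral allele frequency is drawn uniformly from `ancestral_maf_range`
#' (randomly polarized so neither allele is systematically minor), each
#' population's frequency is drawn from
#' `Beta(p(1-F)/F, (1-p)(1-F)/F)` with `F` that population's drift
#' parameter (`bn_F`), and haplotype alleles are independent Bernoulli draws
#' from the population frequency. The drift parameter equals the expected
#' fixation index between a population and the ancestral pool.
#'
#' @param n_individuals_per_pop diploid individuals per population (scalar or
#'   length-2).
#' @param n_chromosomes number of autosomes to simulate.
#' @param snps_per_chromosome SNPs per chromosome (>= 2); scalar or one value
#'   per chromosome.
#' @param chromosome_length chromosome length in bp; scalar or one value per
#'   chromosome.
#' @param bn_F length-2 drift parameter in `[0, 1)`, one per population.
#' @param ancestral_maf_range ancestral minor-allele-frequency range, both
#'   ends in `(0, 0.5]`.
#' @param pop_labels two population labels.
#' @param sweep_specs list of [sweep_spec()] to plant after neutral simulation.
#' @param roh_plants list of [roh_plant()] to plant after neutral simulation.
#' @param missing_rate i.i.d. per-genotype missingness applied when collapsing
#'   to genotypes (never inside planted intervals).
#' @param seed master seed; all substreams derive from it deterministically.
#'
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_individuals_per_pop = 50,
                              n_chromosomes = 1,
                              snps_per_chromosome = 1000,
                              chromosome_length = 5e6,
                              bn_F = c(0.1, 0.1),
                              ancestral_maf_range = c(0.05, 0.5),
                              pop_labels = c("A", "B"),
                              sweep_specs = list(),
                              roh_plants = list(),
                              missing_rate = 0,
                              seed = 1L) {
  if (length(n_individuals_per_pop) == 1L)
    n_individuals_per_pop <- rep(n_individuals_per_pop, 2L)
  if (length(bn_F) == 1L) bn_F <- rep(bn_F, 2L)
  snps_per_chromosome <- rep_len(snps_per_chromosome, n_chromosomes)
  chromosome_length <- rep_len(chromosome_length, n_chromosomes)
  stopifnot(length(pop_labels) == 2L,
            length(n_individuals_per_pop) == 2L,
            all(n_individuals_per_pop >= 1),
            all(chromosome_length > 0),
            all(snps_per_chromosome >= 2),
            all(bn_F >= 0), all(bn_F < 1),
            length(ancestral_maf_range) == 2L,
            ancestral_maf_range[1] > 0,
            ancestral_maf_range[1] <= ancestral_maf_range[2],
            ancestral_maf_range[2] <= 0.5,
            missing_rate >= 0, missing_rate < 1)
  structure(list(n_individuals_per_pop = as.integer(n_individuals_per_pop),
                 n_chromosomes = as.integer(n_chromosomes),
                 snps_per_chromosome = as.integer(snps_per_chromosome),
                 chromosome_length = as.numeric(chromosome_length),
                 bn_F = as.numeric(bn_F),
                 ancestral_maf_range = as.numeric(ancestral_maf_range),
                 pop_labels = as.character(pop_labels),
                 sweep_specs = sweep_specs,
                 roh_plants = roh_plants,
                 missing_rate = as.numeric(missing_rate),
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Specification of a planted hard sweep
#'
#' A founder haplotype is copied over the interval
#' `[core_bp - span_bp/2, core_bp + span_bp/2]` onto a `carrier_fraction`
#' share of one population's haplotypes, emulating the homogenized flanking
#' region a recent positive sweep leaves behind.
#'
#' @param population population label carrying the sweep.
#' @param chromosome chromosome id.
#' @param core_bp position of the sweep core.
#' @param carrier_fraction share of haplotypes carrying the founder
#'   haplotype, in `(0, 1]`.
#' @param span_bp length of the homogenized flanking region in bp.
#' @return A list of class `sweep_spec`.
#' @export
sweep_spec <- function(population, chromosome, core_bp, carrier_fraction,
                       span_bp) {
  stopifnot(core_bp >= 1, carrier_fraction > 0, carrier_fraction <= 1,
            span_bp > 0)
  structure(list(population = as.character(population),
                 chromosome = as.character(chromosome),
                 core_bp = as.numeric(core_bp),
                 carrier_fraction = as.numeric(carrier_fraction),
                 span_bp = as.numeric(span_bp)),
            class = "sweep_spec")
}

#' Specification of a planted autozygous segment
#'
#' One individual's second haplotype is overwritten by its first over
#' `[start_bp, end_bp]`, making every genotype there homozygous.
#'
#' @param population population label.
#' @param individual_index 1-based index of the individual within its
#'   population.
#' @param chromosome chromosome id.
#' @param start_bp,end_bp interval bounds in bp (`start_bp < end_bp`).
#' @return A list of class `roh_plant`.
#' @export
roh_plant <- function(population, individual_index, chromosome, start_bp,
                      end_bp) {
  stopifnot(start_bp < end_bp, individual_index >= 1)
  structure(list(population = as.character(population),
                 individual_index = as.integer(individual_index),
                 chromosome = as.character(chromosome),
                 start_bp = as.numeric(start_bp),
                 end_bp = as.numeric(end_bp)),
            class = "roh_plant")
}

# Uniform positions, sorted; collisions resolved by redraw within a budget.
draw_positions <- function(m, length_bp, budget_factor = 100L) {
  if (m > length_bp) stop("more SNPs requested than available positions")
  pos <- unique(ceiling(stats::runif(m) * length_bp))
  budget <- budget_factor * m
  drawn <- m
  while (length(pos) < m) {
    need <- m - length(pos)
    drawn <- drawn + need
    if (drawn > budget)
      stop("could not draw ", m, " distinct positions within the resampling budget")
    pos <- unique(c(pos, ceiling(stats::runif(need) * length_bp)))
  }
  sort(as.integer(pos))
}

#' Simulate a neutral two-population haplotype panel
#'
#' Draws SNP positions uniformly per chromosome (sorted, distinct), then for
#' each SNP an ancestral frequency and two Balding-Nichols population
#' frequencies, then independent Bernoulli haplotype alleles. Sweep/ROH
#' planting and missingness are separate operators ([plant_sweep()],
#' [plant_roh()], [apply_missingness()]); see [simulate_study()] for the
#' orchestrated version.
#'
#' @param config a [simulation_config()].
#' @return A [haplotype_panel()] (its `map` slot holds the marker map).
#' @export
simulate_panel <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  n <- config$n_individuals_per_pop
  n_hap <- 2L * n
  labels <- config$pop_labels
  chroms <- as.character(seq_len(config$n_chromosomes))
  maps <- vector("list", length(chroms))
  blocks <- vector("list", length(chroms))
  freqs <- vector("list", length(chroms))
  for (ci in seq_along(chroms)) {
    set.seed(derive_seed(config$seed, paste0("chrom", ci)))
    m <- config$snps_per_chromosome[ci]
    pos <- draw_positions(m, config$chromosome_length[ci])
    p_anc <- stats::runif(m, config$ancestral_maf_range[1],
                          config$ancestral_maf_range[2])
    flip <- stats::runif(m) < 0.5
    p_anc[flip] <- 1 - p_anc[flip]
    pk <- matrix(NA_real_, 2L, m)
    for (k in 1:2) {
      f <- config$bn_F[k]
      pk[k, ] <- if (f == 0) p_anc else
        stats::rbeta(m, p_anc * (1 - f) / f, (1 - p_anc) * (1 - f) / f)
    }
    a <- matrix(0L, sum(n_hap), m)
    a[seq_len(n_hap[1]), ] <-
      matrix(stats::rbinom(n_hap[1] * m, 1L, rep(pk[1, ], each = n_hap[1])),
             n_hap[1], m)
    a[n_hap[1] + seq_len(n_hap[2]), ] <-
      matrix(stats::rbinom(n_hap[2] * m, 1L, rep(pk[2, ], each = n_hap[2])),
             n_hap[2], m)
    maps[[ci]] <- data.frame(chrom = chroms[ci], pos = pos,
                             stringsAsFactors = FALSE)
    blocks[[ci]] <- a
    freqs[[ci]] <- pk
  }
  mapdf <- do.call(rbind, maps)
  map <- marker_map(mapdf$chrom, mapdf$pos)
  alleles <- do.call(cbind, blocks)
  # haplotype rows are pop-1 individuals then pop-2 individuals
  sample_ids <- c(sprintf("%s_%03d", labels[1], seq_len(n[1])),
                  sprintf("%s_%03d", labels[2], seq_len(n[2])))
  population <- rep(labels, n)
  panel <- haplotype_panel(alleles, sample_ids, population, map)
  # drawn population frequencies, kept for frequency-based validation
  attr(panel, "pop_freqs") <- do.call(cbind, freqs)  # 2 x M, rows = pops
  panel
}

#' Plant a hard sweep into a haplotype panel
#'
#' @param panel a [haplotype_panel()].
#' @param spec a [sweep_spec()].
#' @param seed optional seed for founder/carrier choice; when `NULL` the
#'   current RNG state is used.
#' @return The modified `haplotype_panel`; only the swept interval on the
#'   chosen carrier haplotypes differs from the input.
#' @export
plant_sweep <- function(panel, spec, seed = NULL) {
  stopifnot(inherits(panel, "haplotype_panel"), inherits(spec, "sweep_spec"))
  if (!is.null(seed)) set.seed(seed)
  ind <- which(panel$population == spec$population)
  if (length(ind) == 0L) stop("population not in panel: ", spec$population)
  hap_rows <- as.vector(rbind(2L * ind - 1L, 2L * ind))
  n_carriers <- round(spec$carrier_fraction * length(hap_rows))
  if (n_carriers < 1)
    stop("carrier_fraction too small: no haplotype to modify")
  on_chrom <- panel$map$chrom == spec$chromosome
  if (!any(on_chrom)) stop("chromosome not in map: ", spec$chromosome)
  lo <- spec$core_bp - spec$span_bp / 2
  hi <- spec$core_bp + spec$span_bp / 2
  cols <- which(on_chrom & panel$map$pos >= lo & panel$map$pos <= hi)
  if (length(cols) == 0L) stop("sweep span covers no SNPs")
  founder_row <- hap_rows[sample.int(length(hap_rows), 1L)]
  founder <- panel$alleles[founder_row, cols]
  carriers <- hap_rows[sample.int(length(hap_rows), n_carriers)]
  panel$alleles[carriers, cols] <- rep(founder, each = n_carriers)
  panel
}

#' Plant an autozygous segment into one individual
#'
#' @param panel a [haplotype_panel()].
#' @param plant a [roh_plant()].
#' @return The modified `haplotype_panel`; only the planted interval on the
#'   individual's second haplotype differs from the input.
#' @export
plant_roh <- function(panel, plant) {
  stopifnot(inherits(panel, "haplotype_panel"), inherits(plant, "roh_plant"))
  ind <- which(panel$population == plant$population)
  if (plant$individual_index > length(ind))
    stop("individual_index out of range for population ", plant$population)
  i <- ind[plant$individual_index]
  cols <- which(panel$map$chrom == plant$chromosome &
                  panel$map$pos >= plant$start_bp &
                  panel$map$pos <= plant$end_bp)
  if (length(cols) == 0L) stop("ROH plant interval covers no SNPs")
  panel$alleles[2L * i, cols] <- panel$alleles[2L * i - 1L, cols]
  panel
}

#' Apply i.i.d. genotype missingness outside protected intervals
#'
#' @param geno a [genotype_matrix()].
#' @param rate per-genotype missingness probability.
#' @param protect optional data.frame with columns `chrom`, `start_bp`,
#'   `end_bp` and `individual` (`NA` protects all individuals); genotypes in
#'   protected cells are never set to missing, so planted ground truth is not
#'   eroded.
#' @param seed optional seed.
#' @return The `genotype_matrix` with missing calls added.
#' @export
apply_missingness <- function(geno, rate, protect = NULL, seed = NULL) {
  stopifnot(inherits(geno, "genotype_matrix"), rate >= 0, rate < 1)
  if (rate == 0) return(geno)
  if (!is.null(seed)) set.seed(seed)
  d <- geno$dosages
  miss <- matrix(stats::runif(length(d)) < rate, nrow(d), ncol(d))
  if (!is.null(protect) && nrow(protect) > 0) {
    for (r in seq_len(nrow(protect))) {
      cols <- which(geno$map$chrom == as.character(protect$chrom[r]) &
                      geno$map$pos >= protect$start_bp[r] &
                      geno$map$pos <= protect$end_bp[r])
      rows <- if (is.na(protect$individual[r])) seq_len(nrow(d)) else
        which(geno$sample_ids == as.character(protect$individual[r]))
      miss[rows, cols] <- FALSE
    }
  }
  d[miss] <- NA_integer_
  geno$dosages <- d
  geno
}

#' Simulate a full study: panel, planted truth, genotypes with missingness
#'
#' Orchestrates [simulate_panel()], [plant_sweep()], [plant_roh()],
#' [collapse_to_genotypes()] and [apply_missingness()] under the
#' configuration's master seed. Missingness is applied after planting and
#' never inside planted intervals.
#'
#' @param config a [simulation_config()].
#' @return A list with `panel` (phased, planted), `geno` (dosages with
#'   missingness) and `truth` (data.frame of planted intervals: columns
#'   `type`, `population`, `individual`, `chrom`, `start_bp`, `end_bp`,
#'   `core_bp`).
#' @export
simulate_study <- function(config) {
  panel <- simulate_panel(config)
  truth <- data.frame(type = character(), population = character(),
                      individual = character(), chrom = character(),
                      start_bp = numeric(), end_bp = numeric(),
                      core_bp = numeric(), stringsAsFactors = FALSE)
  for (i in seq_along(config$sweep_specs)) {
    sp <- config$sweep_specs[[i]]
    panel <- plant_sweep(panel, sp, seed = derive_seed(config$seed,
                                                       paste0("sweep", i)))
    truth <- rbind(truth, data.frame(
      type = "sweep", population = sp$population, individual = NA_character_,
      chrom = sp$chromosome, start_bp = sp$core_bp - sp$span_bp / 2,
      end_bp = sp$core_bp + sp$span_bp / 2, core_bp = sp$core_bp,
      stringsAsFactors = FALSE))
  }
  for (i in seq_along(config$roh_plants)) {
    rp <- config$roh_plants[[i]]
    panel <- plant_roh(panel, rp)
    ind <- panel$sample_ids[which(panel$population == rp$population)[rp$individual_index]]
    truth <- rbind(truth, data.frame(
      type = "roh", population = rp$population, individual = ind,
      chrom = rp$chromosome, start_bp = rp$start_bp, end_bp = rp$end_bp,
      core_bp = NA_real_, stringsAsFactors = FALSE))
  }
  geno <- collapse_to_genotypes(panel)
  if (config$missing_rate > 0) {
    protect <- if (nrow(truth) > 0)
      data.frame(chrom = truth$chrom, start_bp = truth$start_bp,
                 end_bp = truth$end_bp, individual = truth$individual,
                 stringsAsFactors = FALSE) else NULL
    geno <- apply_missingness(geno, config$missing_rate, protect,
                              seed = derive_seed(config$seed, "missing"))
  }
  list(panel = panel, geno = geno, truth = truth)
}

#' Read a flat key-value simulation config file
#'
#' One `key = value` (or `key: value`) pair per line; keys mirror the
#' [simulation_config()] arguments; comma-separated values become vectors.
#' Sweep/ROH plants are given as `sweep.<n>.<field>` / `roh.<n>.<field>`.
#'
#' @param path file path.
#' @return A [simulation_config()].
#' @export
read_simulation_config <- function(path) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([^=:]+)[=:](.*)$", lines))
  bad <- which(vapply(kv, length, 1L) != 3L)
  if (length(bad)) stop("malformed config line ", bad[1], ": ", lines[bad[1]])
  keys <- trimws(vapply(kv, `[`, "", 2L))
  vals <- trimws(vapply(kv, `[`, "", 3L))
  parse_val <- function(v) {
    parts <- trimws(strsplit(v, ",")[[1]])
    num <- suppressWarnings(as.numeric(parts))
    if (!anyNA(num)) num else parts
  }
  plain <- !grepl("^(sweep|roh)\\.", keys)
  args <- lapply(vals[plain], parse_val)
  names(args) <- keys[plain]
  collect <- function(prefix, ctor, fields) {
    sel <- grepl(paste0("^", prefix, "\\."), keys)
    if (!any(sel)) return(list())
    parts <- strsplit(keys[sel], ".", fixed = TRUE)
    idx <- vapply(parts, `[`, "", 2L)
    fld <- vapply(parts, `[`, "", 3L)
    out <- list()
    for (id in unique(idx)) {
      a <- lapply(vals[sel][idx == id], parse_val)
      names(a) <- fld[idx == id]
      out[[length(out) + 1L]] <- do.call(ctor, a[fields[fields %in% names(a)]])
    }
    out
  }
  args$sweep_specs <- collect("sweep", sweep_spec,
    c("population", "chromosome", "core_bp", "carrier_fraction", "span_bp"))
  args$roh_plants <- collect("roh", roh_plant,
    c("population", "individual_index", "chromosome", "start_bp", "end_bp"))
  do.call(simulation_config, args)
}

#' Write the planted ground truth as TSV
#'
#' @param truth the `truth` element of [simulate_study()] output.
#' @param path output file.
#' @return The path, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  write_tsv(truth, path)
}
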