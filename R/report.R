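#' Intersect the two differentiation tests
#'
#' Candidate regions are the 500-kb windows flagged by both the windowed
#' F_ST scan and the XP-EHH window filter. Both window sets must lie on the
#' same tiling (equal width, anchored at bp 1).
#'
#' @param fst_windows the `windows` element of [fst_scan()] (with a
#'   `significant` flag).
#' @param xpehh_windows the `windows` element of [significant_windows()]
#'   (already filtered to retained windows).
#' @return A data.frame of candidate regions: `chrom`, `start_bp`, `end_bp`,
#'   `mean_fst`, `mean_xpehh` (over extreme SNPs), `mean_xpehh_all` (over all
#'   scored SNPs in the window), `genes` (empty until
#'   [annotate_regions()]).
#' @export
intersect_tests <- function(fst_windows, xpehh_windows) {
  wf <- unique(fst_windows$end_bp - fst_windows$start_bp)
  wx <- unique(xpehh_windows$end_bp - xpehh_windows$start_bp)
  if (length(wx) && (length(wf) != 1L || length(wx) != 1L || wf != wx))
    stop("intersect_tests: window tilings do not match")
  key_f <- paste0(fst_windows$chrom, ":", fst_windows$start_bp)
  key_x <- paste0(xpehh_windows$chrom, ":", xpehh_windows$start_bp)
  sig_f <- fst_windows[fst_windows$significant, , drop = FALSE]
  hit <- match(paste0(sig_f$chrom, ":", sig_f$start_bp), key_x)
  sel <- !is.na(hit)
  out <- data.frame(chrom = sig_f$chrom[sel],
                    start_bp = sig_f$start_bp[sel],
                    end_bp = sig_f$end_bp[sel],
                    mean_fst = sig_f$mean_fst[sel],
                    mean_xpehh = xpehh_windows$mean_xpehh[hit[sel]],
                    mean_xpehh_all = xpehh_windows$mean_xpehh_all[hit[sel]],
                    genes = rep("", sum(sel)),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Read a gene/QTL annotation interval file
#'
#' BED (0-based half-open; converted to 1-based inclusive on read) or GFF3
#' (1-based inclusive as is). The caller is responsible for supplying an
#' annotation on the same genome assembly as the marker map.
#'
#' @param path `.bed`, `.gff` or `.gff3` file.
#' @return A data.frame `chrom`, `start_bp`, `end_bp`, `name` (1-based
#'   inclusive coordinates).
#' @export
read_annotation <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  fields <- strsplit(lines, "\t")
  if (grepl("\\.gff3?$", path, ignore.case = TRUE)) {
    bad <- which(vapply(fields, length, 1L) < 9L)
    if (length(bad)) stop("malformed GFF line ", lineno[bad[1]])
    chrom <- vapply(fields, `[`, "", 1L)
    start <- suppressWarnings(as.integer(vapply(fields, `[`, "", 4L)))
    end <- suppressWarnings(as.integer(vapply(fields, `[`, "", 5L)))
    attrs <- vapply(fields, `[`, "", 9L)
    name <- sub(".*(?:Name|ID)=([^;]+).*", "\\1", attrs)
  } else {
    bad <- which(vapply(fields, length, 1L) < 3L)
    if (length(bad)) stop("malformed BED line ", lineno[bad[1]])
    chrom <- vapply(fields, `[`, "", 1L)
    start0 <- suppressWarnings(as.integer(vapply(fields, `[`, "", 2L)))
    end <- suppressWarnings(as.integer(vapply(fields, `[`, "", 3L)))
    name <- vapply(fields, function(f) if (length(f) >= 4L) f[4L] else ".", "")
    start <- start0 + 1L
  }
  if (anyNA(start) || anyNA(end))
    stop("malformed annotation line ",
         lineno[which(is.na(start) | is.na(end))[1]], ": non-numeric bounds")
  data.frame(chrom = chrom, start_bp = start, end_bp = end, name = name,
             stringsAsFactors = FALSE)
}

#' Annotate candidate regions with overlapping intervals
#'
#' A gene is listed for a region iff its interval overlaps the region by at
#' least 1 bp (BED half-open input is converted on read, so a feature
#' exactly abutting a region end does not overlap). A feature spanning two
#' regions is listed in both. Region coordinates are never altered.
#'
#' @param regions candidate regions from [intersect_tests()] (or any
#'   data.frame with `chrom`, `start_bp`, `end_bp`).
#' @param annotation a data.frame from [read_annotation()] or a file path.
#' @return `regions` with `genes` (comma-separated names) and `n_genes`.
#' @export
annotate_regions <- function(regions, annotation) {
  if (is.character(annotation)) annotation <- read_annotation(annotation)
  if (nrow(regions) == 0L) {
    regions$genes <- character(0); regions$n_genes <- integer(0)
    return(regions)
  }
  reg <- GenomicRanges::GRanges(regions$chrom,
                                IRanges::IRanges(regions$start_bp,
                                                 regions$end_bp))
  ann <- GenomicRanges::GRanges(annotation$chrom,
                                IRanges::IRanges(annotation$start_bp,
                                                 annotation$end_bp))
  ov <- GenomicRanges::findOverlaps(reg, ann, minoverlap = 1L)
  genes <- vapply(seq_len(nrow(regions)), function(i) {
    hits <- S4Vectors::subjectHits(ov)[S4Vectors::queryHits(ov) == i]
    paste(annotation$name[hits], collapse = ",")
  }, "")
  regions$genes <- genes
  regions$n_genes <- vapply(strsplit(genes, ","), function(g)
    sum(nzchar(g)), 1L)
  regions
}

#' Run the full selection-signature pipeline
#'
#' Executes: input (or simulation) -> per-population inbreeding filter
#' (f_i threshold) -> per-population QC -> branch A: LD pruning, three-class
#' ROH scan, per-SNP incidence and consensus regions per population ->
#' branch B: windowed F_ST scan and XP-EHH windows on the unpruned post-QC
#' set -> intersection -> optional annotation. Every stage writes its
#' TSV/BED artifacts into `out_dir` plus a run log and a MANIFEST marking
#' stage completion; a stage failure aborts with the stage named, retaining
#' the partial MANIFEST.
#'
#' The LD-pruned SNP set feeds only the ROH branch; F_ST and XP-EHH run on
#' the full post-QC marker set.
#'
#' @param input a [simulation_config()] (the panel is simulated), a
#'   [haplotype_panel()], or `list(vcf = path, pop = path)`.
#' @param out_dir output directory (created if needed).
#' @param annotation optional BED/GFF3 path or annotation data.frame.
#' @param pop_a,pop_b population labels (XP-EHH numerator = `pop_a`);
#'   default: first/second label in the data.
#' @param thresholds a [qc_thresholds()].
#' @param prune an [ld_prune_params()].
#' @param classes ROH classes, default [roh_class_defaults()]`("all")`.
#' @param consensus_threshold consensus-ROH share (default 0.85).
#' @param width_bp window width for both tests (default 500 kb).
#' @param fst_top_fraction F_ST flagged tail (default 0.01).
#' @param xpehh_threshold fixed |XP-EHH| threshold (default 4.34).
#' @param xpehh_percentile extreme-tail percentile (default 0.99).
#' @param xpehh_min_snps extreme SNPs required per window (default 3).
#' @param ehh_cutoff,maf_min XP-EHH computation parameters.
#' @return Invisibly, a list with the main result objects (`fi`, `qc`,
#'   `roh`, `summary`, `consensus`, `fst`, `xpehh`, `xpehh_windows`,
#'   `candidates`) and `out_dir`.
#' @export
run_pipeline <- function(input, out_dir, annotation = NULL,
                         pop_a = NULL, pop_b = NULL,
                         thresholds = qc_thresholds(),
                         prune = ld_prune_params(),
                         classes = roh_class_defaults("all"),
                         consensus_threshold = 0.85,
                         width_bp = 500000,
                         fst_top_fraction = 0.01,
                         xpehh_threshold = 4.34,
                         xpehh_percentile = 0.99,
                         xpehh_min_snps = 3,
                         ehh_cutoff = 0.05, maf_min = 0.05) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- data.frame(stage = character(), file = character(),
                         status = character(), stringsAsFactors = FALSE)
  log_lines <- c(paste("popsweep pipeline run:", format(Sys.time(), "%Y-%m-%d")),
                 paste("window width (bp):", width_bp),
                 paste("consensus threshold:", consensus_threshold),
                 paste("fst top fraction:", fst_top_fraction),
                 paste("xpehh threshold:", xpehh_threshold),
                 paste("xpehh percentile:", xpehh_percentile),
                 paste("xpehh min snps/window:", xpehh_min_snps),
                 paste("ehh cutoff:", ehh_cutoff),
                 paste("core maf floor:", maf_min))
  emit <- function(stage, file) {
    manifest <<- rbind(manifest, data.frame(stage = stage, file = file,
                                            status = "complete",
                                            stringsAsFactors = FALSE))
  }
  finish <- function(status) {
    write_tsv(manifest, file.path(out_dir, "MANIFEST.tsv"))
    writeLines(c(log_lines, paste("status:", status)),
               file.path(out_dir, "run_log.txt"))
  }
  stage <- "input"
  res <- tryCatch({
    truth <- NULL
    if (inherits(input, "simulation_config")) {
      log_lines <- c(log_lines, paste("seed:", input$seed))
      study <- simulate_study(input)
      panel <- study$panel; geno <- study$geno; truth <- study$truth
      write_ground_truth(truth, file.path(out_dir, "ground_truth.tsv"))
      emit("input", "ground_truth.tsv")
    } else if (inherits(input, "haplotype_panel")) {
      panel <- input; geno <- collapse_to_genotypes(panel)
    } else {
      panel <- read_phased_vcf(input$vcf, input$pop)
      geno <- collapse_to_genotypes(panel)
    }
    write_population_file(panel, file.path(out_dir, "population.tsv"))
    emit("input", "population.tsv")
    pops <- unique(panel$population)
    if (is.null(pop_a)) pop_a <- pops[1]
    if (is.null(pop_b)) pop_b <- pops[2]

    stage <- "inbreeding_filter"
    fi <- filter_inbred(geno, thresholds$f_i_max)
    write_tsv(fi$f_table, file.path(out_dir, "inbreeding.tsv"))
    emit(stage, "inbreeding.tsv")
    log_lines <- c(log_lines, paste("individuals removed by f_i filter:",
                                    length(fi$removed)))
    geno <- fi$geno

    stage <- "qc"
    qc <- apply_qc(geno, thresholds)
    write_qc_report(qc$report, file.path(out_dir, "qc_report.tsv"))
    emit(stage, "qc_report.tsv")
    log_lines <- c(log_lines,
                   paste("qc removals (mind/geno/maf/hwe):",
                         paste(qc$report$counts, collapse = "/")))
    geno <- qc$geno
    keep_ind <- match(geno$sample_ids, panel$sample_ids)
    keep_snp <- match(geno$map$snp_id, panel$map$snp_id)
    panel <- subset_panel(panel, snps = keep_snp, individuals = keep_ind)

    stage <- "ld_prune"
    kept <- ld_prune(geno, prune)
    writeLines(geno$map$snp_id[kept], file.path(out_dir, "kept_snps.txt"))
    writeLines(setdiff(geno$map$snp_id, geno$map$snp_id[kept]),
               file.path(out_dir, "removed_snps.txt"))
    emit(stage, "kept_snps.txt")
    log_lines <- c(log_lines, paste("snps kept after LD pruning:",
                                    length(kept), "of", ncol(geno$dosages)))
    geno_pruned <- subset_genotypes(geno, snps = kept)

    stage <- "roh"
    segs <- detect_roh_all(geno_pruned, classes)
    write_tsv(segs, file.path(out_dir, "roh_segments.tsv"))
    write_bed(to_bed(segs$chrom, segs$start_bp, segs$end_bp,
                     name = paste(segs$individual, segs$class, sep = "|")),
              file.path(out_dir, "roh_segments.bed"))
    n_by_pop <- table(geno_pruned$population)
    summ <- roh_summary(segs, stats::setNames(as.integer(n_by_pop),
                                              names(n_by_pop)))
    write_tsv(summ, file.path(out_dir, "roh_summary.tsv"))
    emit(stage, "roh_segments.tsv")

    stage <- "consensus"
    consensus <- list()
    for (p in unique(geno_pruned$population)) {
      sub <- subset_genotypes(geno_pruned, individuals =
                                geno_pruned$population == p)
      inc <- snp_incidence(segs[segs$population == p, , drop = FALSE], sub,
                           class = "long")
      bg <- data.frame(chrom = inc$chrom, start = inc$pos - 1L,
                       end = inc$pos, value = inc$share)
      utils::write.table(bg, file.path(out_dir,
                                       paste0("incidence_", p, ".bedgraph")),
                         sep = "\t", quote = FALSE, row.names = FALSE,
                         col.names = FALSE)
      cons <- consensus_regions(inc, consensus_threshold)
      write_tsv(cons, file.path(out_dir, paste0("consensus_", p, ".tsv")))
      if (nrow(cons))
        write_bed(to_bed(cons$chrom, cons$start_bp, cons$end_bp,
                         score = cons$share),
                  file.path(out_dir, paste0("consensus_", p, ".bed")))
      consensus[[p]] <- cons
      emit(stage, paste0("consensus_", p, ".tsv"))
    }

    stage <- "fst"
    fst <- fst_scan(geno, pops = c(pop_a, pop_b), width_bp = width_bp,
                    top_fraction = fst_top_fraction)
    write_tsv(fst$per_snp, file.path(out_dir, "fst_per_snp.tsv"))
    write_tsv(fst$windows, file.path(out_dir, "fst_windows.tsv"))
    sigw <- fst$windows[fst$windows$significant, , drop = FALSE]
    if (nrow(sigw))
      write_bed(to_bed(sigw$chrom, sigw$start_bp, sigw$end_bp,
                       score = sigw$mean_fst),
                file.path(out_dir, "fst_significant.bed"))
    mid <- (fst$windows$start_bp + fst$windows$end_bp) / 2
    write_tsv(data.frame(chrom = fst$windows$chrom, mid_bp = mid,
                         mean_fst = fst$windows$mean_fst),
              file.path(out_dir, "fst_manhattan.tsv"))
    emit(stage, "fst_windows.tsv")
    log_lines <- c(log_lines, paste("fst cutoff:",
                                    format(fst$cutoff, digits = 6)))

    stage <- "xpehh"
    xp <- xpehh(panel, pop_a, pop_b, ehh_cutoff = ehh_cutoff,
                maf_min = maf_min)
    write_tsv(as.data.frame(xp), file.path(out_dir, "xpehh_records.tsv"))
    xw <- significant_windows(xp, width_bp = width_bp,
                              min_snps = xpehh_min_snps,
                              percentile = xpehh_percentile,
                              threshold = xpehh_threshold)
    write_tsv(xw$windows, file.path(out_dir, "xpehh_windows.tsv"))
    if (nrow(xw$windows))
      write_bed(to_bed(xw$windows$chrom, xw$windows$start_bp,
                       xw$windows$end_bp, score = xw$windows$mean_xpehh),
                file.path(out_dir, "xpehh_significant.bed"))
    emit(stage, "xpehh_windows.tsv")

    stage <- "intersection"
    cand <- intersect_tests(fst$windows, xw$windows)
    if (!is.null(annotation)) cand <- annotate_regions(cand, annotation)
    write_tsv(cand, file.path(out_dir, "candidate_regions.tsv"))
    emit(stage, "candidate_regions.tsv")
    log_lines <- c(log_lines, paste("candidate regions:", nrow(cand)))

    finish("complete")
    invisible(list(fi = fi$f_table, qc = qc$report, roh = segs,
                   summary = summ, consensus = consensus, fst = fst,
                   xpehh = xp, xpehh_windows = xw$windows,
                   candidates = cand, truth = truth, out_dir = out_dir))
  }, error = function(e) {
    finish(paste("failed at stage:", stage))
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(res)
}
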