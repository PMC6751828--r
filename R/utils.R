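# Internal helpers shared across modules.

# Deterministic substream seed from a master seed and a tag; kept below 2^31.
derive_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(as.character(tag)) * seq_along(utf8ToInt(as.character(tag))))
  as.integer((as.numeric(seed) * 48271 + h * 131) %% 2147483647)
}

# Allele frequency of the alt allele per SNP from dosages, ignoring missing.
alt_freq <- function(dosages) {
  n2 <- 2 * colSums(!is.na(dosages))
  ifelse(n2 > 0, colSums(dosages, na.rm = TRUE) / n2, NA_real_)
}

minor_af <- function(dosages) {
  p <- alt_freq(dosages)
  pmin(p, 1 - p)
}

# Fixed-width non-overlapping windows anchored at bp 1 per chromosome.
# Returns, per SNP, the window index key "chrom:start".
window_key <- function(map, width_bp) {
  k <- (map$pos - 1L) %/% as.integer(width_bp)
  start <- k * as.integer(width_bp) + 1L
  list(key = paste0(map$chrom, ":", start),
       chrom = map$chrom,
       start = start,
       end = start + as.integer(width_bp) - 1L)
}

# TSV writer with fixed conventions so pipeline outputs are byte-stable.
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, eol = "\n")
  invisible(path)
}

# 1-based inclusive intervals -> BED (0-based half-open) data.frame.
to_bed <- function(chrom, start_bp, end_bp, name = ".", score = 0) {
  data.frame(chrom = chrom, start = start_bp - 1L, end = end_bp,
             name = rep_len(name, length(chrom)),
             score = rep_len(score, length(chrom)), stringsAsFactors = FALSE)
}

write_bed <- function(bed, path) {
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE, eol = "\n")
  invisible(path)
}
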