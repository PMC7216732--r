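# Fixtures and independent brute-force oracles used across the suite.
# All fixtures are generated in code; nothing is read from disk except what
# the tests themselves write to tempfiles.

# a small call set built by hand
make_calls <- function(chrom, pos, meth, unmeth, stage = "oocyte") {
  methrepro:::new_cpg_calls(
    data.frame(chrom = chrom, pos = pos, meth = meth, unmeth = unmeth),
    stage = stage)
}

# random call set over one or more chromosomes
random_calls <- function(n = 500, chroms = c("chr1", "chr2"), stage = "oocyte",
                         max_pos = 100000L) {
  pos_list <- lapply(chroms, function(ch)
    sort(sample.int(max_pos, ceiling(n / length(chroms)))))
  df <- do.call(rbind, Map(function(ch, p)
    data.frame(chrom = ch, pos = p,
               meth = rbinom(length(p), 20, 0.4),
               unmeth = rbinom(length(p), 20, 0.5)), chroms, pos_list))
  df <- df[df$meth + df$unmeth > 0, ]
  methrepro:::new_cpg_calls(df, stage = stage)
}

# brute-force per-position quantitation oracle, independent of the
# overlap-join implementation: plain loops over rows
oracle_quantify <- function(calls, chrom, start, end, min_count = 1,
                            min_obs = 5, unit = "positions") {
  pcts <- c(); n_calls <- 0
  for (i in seq_len(nrow(calls))) {
    if (calls$chrom[i] != chrom) next
    p0 <- calls$pos[i] - 1          # 0-based coordinate of the C
    if (p0 < start || p0 >= end) next
    cov <- calls$meth[i] + calls$unmeth[i]
    if (cov < min_count) next
    pcts <- c(pcts, 100 * calls$meth[i] / cov)
    n_calls <- n_calls + cov
  }
  enough <- if (unit == "positions") length(pcts) >= min_obs
            else n_calls >= min_obs
  if (!enough) NA_real_ else mean(pcts)
}

# brute-force run-grouping domain oracle
oracle_domains <- function(tiles, stage = "oocyte", hyper_min = 75,
                           hypo_max = 25) {
  v <- tiles[[stage]]
  kind <- ifelse(is.na(v), "na",
                 ifelse(v >= hyper_min, "hyper",
                        ifelse(v <= hypo_max, "hypo", "neither")))
  out <- NULL
  i <- 1
  while (i <= nrow(tiles)) {
    if (kind[i] %in% c("hyper", "hypo")) {
      j <- i
      while (j < nrow(tiles) && kind[j + 1] == kind[i] &&
             tiles$chrom[j + 1] == tiles$chrom[i]) j <- j + 1
      out <- rbind(out, data.frame(chrom = tiles$chrom[i],
                                   start = tiles$start[i],
                                   end = tiles$end[j], kind = kind[i],
                                   n_tiles = j - i + 1))
      i <- j + 1
    } else i <- i + 1
  }
  out
}

# quantified tile table built directly (no coverage sampling)
make_tile_table <- function(values_by_stage, chrom = "chr1") {
  n <- length(values_by_stage[[1]])
  df <- data.frame(tile = sprintf("t%03d", seq_len(n)), chrom = chrom,
                   start = (seq_len(n) - 1L) * 1000L,
                   end = seq_len(n) * 1000L, n_cpg = 100L)
  for (s in names(values_by_stage)) df[[s]] <- values_by_stage[[s]]
  df
}

# uniform tile table with all six stages present
make_full_tile_table <- function(n, value = 50, chrom = "chr1") {
  vals <- stats::setNames(rep(list(rep(value, n)), 6), stage_levels())
  make_tile_table(vals, chrom)
}

# base-level Jaccard between two interval sets on the same genome
interval_jaccard <- function(a, b) {
  gra <- GenomicRanges::reduce(GenomicRanges::GRanges(
    a$chrom, IRanges::IRanges(a$start + 1L, a$end)))
  grb <- GenomicRanges::reduce(GenomicRanges::GRanges(
    b$chrom, IRanges::IRanges(b$start + 1L, b$end)))
  inter <- sum(IRanges::width(GenomicRanges::intersect(gra, grb)))
  un <- sum(IRanges::width(GenomicRanges::union(gra, grb)))
  inter / un
}
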