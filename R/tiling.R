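# Tile construction and bisulfite-style feature quantitation.
#
# The unit of unbiased analysis is a non-overlapping window of exactly
# `tile_size` consecutive CpGs (default 100). Quantitation follows the
# per-position semantics of the SeqMonk bisulfite pipeline: each sufficiently
# covered CpG contributes its own percent methylation, and the feature value
# is the unweighted mean of those per-position percentages.

#' Quantitation configuration
#'
#' Thresholds controlling which CpG positions and features are quantified.
#' `min_count` is the minimum reads a position needs to contribute (default
#' 1). `min_obs` is the inclusion threshold for a feature: in `"positions"`
#' units it is the number of covered CpGs required (5 for tiles and repeats,
#' 10 for CpG islands, domains and intergenic regions); in `"calls"` units it
#' is the total number of methylation calls required (10 for curated
#' imprinted-gene features).
#'
#' @param min_count Minimum reads per position (>= 1).
#' @param min_obs Minimum observations per feature (>= 1).
#' @param unit `"positions"` (count covered CpGs) or `"calls"` (count reads).
#' @param aggregate `"mean_of_positions"` (default, SeqMonk-like) or
#'   `"pooled"` (`100 * sum(meth) / sum(meth + unmeth)`), kept for
#'   sensitivity analysis.
#' @return A `quant_config` list.
#' @export
quant_config <- function(min_count = 1L, min_obs = 5L,
                         unit = c("positions", "calls"),
                         aggregate = c("mean_of_positions", "pooled")) {
  unit <- match.arg(unit)
  aggregate <- match.arg(aggregate)
  if (min_count < 1L || min_obs < 1L)
    stop("quantitation thresholds must be >= 1", call. = FALSE)
  structure(list(min_count = as.integer(min_count),
                 min_obs = as.integer(min_obs),
                 unit = unit, aggregate = aggregate),
            class = "quant_config")
}

#' Build non-overlapping tiles of consecutive CpGs
#'
#' Groups each chromosome's sorted CpG positions into consecutive disjoint
#' windows of exactly `tile_size` CpGs; the trailing remainder of fewer than
#' `tile_size` CpGs is dropped. Tiles never span chromosomes. The tile span
#' is 0-based half-open from the first member CpG to (and including) the
#' last.
#'
#' @param cpgs Either a data frame with `chrom` and `pos` (1-based) columns,
#'   a `cpg_calls` object, or a named list of sorted unique position vectors
#'   (one per chromosome).
#' @param tile_size Number of CpGs per tile (default 100).
#' @return A `tile_set` data frame: `tile`, `chrom`, `start`, `end`,
#'   `n_cpg`.
#' @export
build_tiles <- function(cpgs, tile_size = 100L) {
  tile_size <- as.integer(tile_size)
  stopifnot(tile_size >= 1L)
  if (is.data.frame(cpgs)) {
    cpgs <- split(cpgs$pos, cpgs$chrom)
  }
  if (!is.list(cpgs) || is.null(names(cpgs)))
    stop("'cpgs' must be a chrom/pos data frame or a named list of positions",
         call. = FALSE)
  pieces <- lapply(sort(names(cpgs)), function(chrom) {
    pos <- cpgs[[chrom]]
    if (is.unsorted(pos, strictly = TRUE))
      stop("CpG positions must be sorted and unique on ", chrom, call. = FALSE)
    k <- length(pos) %/% tile_size
    if (k == 0L) return(NULL)
    idx1 <- (seq_len(k) - 1L) * tile_size + 1L
    idxN <- seq_len(k) * tile_size
    data.frame(chrom = chrom,
               start = as.integer(pos[idx1] - 1L),
               end = as.integer(pos[idxN]),
               n_cpg = tile_size)
  })
  out <- do.call(rbind, pieces)
  if (is.null(out))
    out <- data.frame(chrom = character(), start = integer(),
                      end = integer(), n_cpg = integer())
  out <- cbind(tile = if (nrow(out))
    sprintf("%s_tile_%06d", out$chrom,
            unlist(lapply(split(seq_len(nrow(out)), out$chrom), seq_along),
                   use.names = FALSE)) else character(), out)
  rownames(out) <- NULL
  structure(out, tile_size = tile_size, class = c("tile_set", "data.frame"))
}

#' Quantify methylation of many features at once
#'
#' For every CpG inside a feature with coverage `>= min_count`, the
#' per-position percent `100 * meth / (meth + unmeth)` is computed; the
#' feature value is the unweighted mean of those percentages (or the pooled
#' ratio under `aggregate = "pooled"`). Features failing the `min_obs`
#' threshold get `NA` — missing is a value, not an error.
#'
#' @param calls A `cpg_calls` object.
#' @param features A data frame of intervals (`chrom`, `start`, `end`;
#'   0-based half-open), e.g. a `tile_set` or `feature_set`.
#' @param cfg A [quant_config()].
#' @return Numeric vector of percentages (0-100) aligned with `features`
#'   rows, `NA` where the feature is not quantifiable.
#' @export
quantify_features <- function(calls, features, cfg = quant_config()) {
  stopifnot(inherits(cfg, "quant_config"))
  n_feat <- nrow(features)
  out <- rep(NA_real_, n_feat)
  if (n_feat == 0L || nrow(calls) == 0L) return(out)
  cov <- calls$meth + calls$unmeth
  keep <- cov >= cfg$min_count
  if (!any(keep)) return(out)
  calls <- calls[keep, , drop = FALSE]
  cov <- cov[keep]
  hits <- findOverlaps(position_gr(calls), interval_gr(features))
  if (length(hits) == 0L) return(out)
  q <- queryHits(hits)
  s <- subjectHits(hits)
  pct <- 100 * calls$meth[q] / cov[q]
  n_pos <- tabulate(s, nbins = n_feat)
  n_calls <- as.numeric(rowsum_by(cov[q], s, n_feat))
  value <- if (cfg$aggregate == "mean_of_positions") {
    rowsum_by(pct, s, n_feat) / ifelse(n_pos > 0, n_pos, NA)
  } else {
    100 * rowsum_by(calls$meth[q], s, n_feat) / n_calls
  }
  qualifies <- if (cfg$unit == "positions") n_pos >= cfg$min_obs
               else n_calls >= cfg$min_obs
  out[qualifies] <- value[qualifies]
  out
}

# sum of x grouped by integer index in 1..n (dense result)
rowsum_by <- function(x, idx, n) {
  out <- numeric(n)
  r <- rowsum(x, idx)
  out[as.integer(rownames(r))] <- r[, 1L]
  out
}

#' Quantify a single interval
#'
#' Scalar convenience wrapper around [quantify_features()].
#'
#' @param calls A `cpg_calls` object.
#' @param chrom,start,end Interval (0-based half-open).
#' @inheritParams quantify_features
#' @return A percentage, or `NA` if the interval fails the inclusion
#'   threshold.
#' @export
quantify_feature <- function(calls, chrom, start, end, cfg = quant_config()) {
  quantify_features(calls, data.frame(chrom = chrom, start = start, end = end),
                    cfg)[1L]
}

#' Quantify tiles (or any features) across all six stages
#'
#' Applies [quantify_features()] per stage and appends one value column per
#' stage to the feature table.
#'
#' @param stacks Named list of `cpg_calls`, one per stage; all six stages in
#'   [stage_levels()] must be present.
#' @param tiles A `tile_set` (or any interval data frame).
#' @param cfg A [quant_config()].
#' @return `tiles` with one numeric column per stage.
#' @export
quantify_all <- function(stacks, tiles, cfg = quant_config()) {
  missing_stages <- setdiff(stage_levels(), names(stacks))
  if (length(missing_stages))
    stop("missing stage(s) in 'stacks': ", paste(missing_stages, collapse = ", "),
         call. = FALSE)
  for (s in stage_levels()) tiles[[s]] <- quantify_features(stacks[[s]], tiles, cfg)
  tiles
}

#' Keep informative tiles
#'
#' A tile is informative when it carries a quantifiable value in all six
#' stages (`"has_data"`, the default). The `"literal_above_zero"` mode
#' additionally requires every value to exceed zero, which discards fully
#' unmethylated tiles; both readings are provided because the source filter
#' wording is ambiguous (see the methods vignette).
#'
#' @param tiles Quantified tiles (output of [quantify_all()]).
#' @param mode `"has_data"` or `"literal_above_zero"`.
#' @return The subset of informative tiles.
#' @export
informative_filter <- function(tiles, mode = c("has_data", "literal_above_zero")) {
  mode <- match.arg(mode)
  vals <- as.matrix(tiles[, stage_levels(), drop = FALSE])
  keep <- rowSums(is.na(vals)) == 0L
  if (mode == "literal_above_zero") keep <- keep & rowSums(vals > 0, na.rm = TRUE) == ncol(vals)
  out <- tiles[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Global methylation level at a stage
#'
#' The unweighted mean of tile values at the given stage, the tile-centric
#' definition of global methylation.
#'
#' @param tiles Informative tiles.
#' @param stage One of [stage_levels()].
#' @return A percentage.
#' @export
global_methylation <- function(tiles, stage) {
  check_stage(stage)
  v <- tiles[[stage]]
  v <- v[!is.na(v)]
  if (!length(v)) stop("no informative tiles to average", call. = FALSE)
  mean(v)
}

#' Pooled per-CpG global methylation
#'
#' The coverage-weighted alternative to [global_methylation()]:
#' `100 * sum(meth) / sum(meth + unmeth)` over all covered CpGs.
#'
#' @param calls A `cpg_calls` object.
#' @param min_count Minimum reads per position.
#' @return A percentage.
#' @export
global_methylation_cpg <- function(calls, min_count = 1L) {
  cov <- calls$meth + calls$unmeth
  keep <- cov >= min_count
  if (!any(keep)) stop("no covered CpGs", call. = FALSE)
  100 * sum(calls$meth[keep]) / sum(cov[keep])
}

#' Histogram of tile methylation values
#'
#' Fractions of informative tiles per methylation bin, `[0,10), [10,20), ...,
#' [90,100]` by default; the last bin is closed so 100% values are counted.
#'
#' @param tiles Informative tiles.
#' @param stage One of [stage_levels()].
#' @param bin_width Bin width in percentage points; must divide 100.
#' @return Data frame with `bin_lo`, `bin_hi`, `n`, `fraction` (percent of
#'   tiles; sums to 100).
#' @export
histogram_bins <- function(tiles, stage, bin_width = 10) {
  check_stage(stage)
  if (100 %% bin_width != 0) stop("bin_width must divide 100", call. = FALSE)
  v <- tiles[[stage]]
  v <- v[!is.na(v)]
  if (!length(v)) stop("no informative tiles to bin", call. = FALSE)
  breaks <- seq(0, 100, by = bin_width)
  idx <- findInterval(v, breaks, rightmost.closed = TRUE)
  n <- tabulate(idx, nbins = length(breaks) - 1L)
  data.frame(bin_lo = breaks[-length(breaks)], bin_hi = breaks[-1L],
             n = n, fraction = 100 * n / length(v))
}
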