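# Oocyte methylome segmentation into hyper- and hypomethylated domains.
#
# A domain is a maximal run of consecutive same-chromosome tiles whose
# oocyte methylation satisfies the kind's threshold (>= hyper_min for
# HyperDomains, <= hypo_max for HypoDomains, both inclusive). Tiles with a
# missing value neither extend nor break a run when at most `max_gap_tiles`
# of them occur consecutively; longer missing stretches, and tiles of
# intermediate methylation, break runs.

#' Call oocyte hyper- and hypomethylation domains
#'
#' @param tiles Informative tiles carrying a value column for `stage`
#'   (rows are assumed to be in genomic order within chromosomes, as
#'   produced by [build_tiles()]).
#' @param stage Stage whose values drive the segmentation (default
#'   `"oocyte"`).
#' @param hyper_min Minimum methylation of a HyperDomain member tile
#'   (inclusive; default 75).
#' @param hypo_max Maximum methylation of a HypoDomain member tile
#'   (inclusive; default 25).
#' @param max_gap_tiles Number of consecutive value-missing tiles tolerated
#'   inside a run (default 0).
#' @return A `domain_set` data frame: `chrom`, `start`, `end` (0-based
#'   half-open, spanning first to last member tile), `kind` (`"hyper"` /
#'   `"hypo"`), `n_tiles`, `mean` (mean member-tile methylation). The
#'   attribute `tile_domain` maps each input tile row to its domain row (NA
#'   if none).
#' @export
call_domains <- function(tiles, stage = "oocyte", hyper_min = 75,
                         hypo_max = 25, max_gap_tiles = 0L) {
  if (hyper_min <= hypo_max)
    stop("hyper_min must exceed hypo_max", call. = FALSE)
  v <- tiles[[stage]]
  if (is.null(v)) stop("tiles carry no '", stage, "' values", call. = FALSE)
  n <- nrow(tiles)
  kind <- rep("neither", n)
  kind[!is.na(v) & v >= hyper_min] <- "hyper"
  kind[!is.na(v) & v <= hypo_max] <- "hypo"
  kind[is.na(v)] <- "na"

  domains <- list()
  tile_domain <- rep(NA_integer_, n)
  cur_kind <- NULL; members <- integer(); gap_run <- 0L
  flush <- function() {
    if (!is.null(cur_kind) && length(members)) {
      domains[[length(domains) + 1L]] <<- list(
        chrom = tiles$chrom[members[1L]],
        start = tiles$start[members[1L]],
        end = tiles$end[members[length(members)]],
        kind = cur_kind, n_tiles = length(members),
        mean = mean(v[members]))
      tile_domain[members] <<- length(domains)
    }
    cur_kind <<- NULL; members <<- integer(); gap_run <<- 0L
  }
  prev_chrom <- NA_character_
  for (i in seq_len(n)) {
    if (!identical(tiles$chrom[i], prev_chrom)) { flush(); prev_chrom <- tiles$chrom[i] }
    k <- kind[i]
    if (k == "na") {
      gap_run <- gap_run + 1L
      if (gap_run > max_gap_tiles) flush()
    } else if (k == "neither") {
      flush()
    } else if (identical(k, cur_kind)) {
      members <- c(members, i); gap_run <- 0L
    } else {
      flush(); cur_kind <- k; members <- i
    }
  }
  flush()
  out <- if (length(domains)) {
    do.call(rbind, lapply(domains, function(d)
      data.frame(chrom = d$chrom, start = d$start, end = d$end, kind = d$kind,
                 n_tiles = d$n_tiles, mean = d$mean)))
  } else {
    data.frame(chrom = character(), start = integer(), end = integer(),
               kind = character(), n_tiles = integer(), mean = numeric())
  }
  rownames(out) <- NULL
  structure(out, tile_domain = tile_domain,
            class = c("domain_set", "data.frame"))
}

#' Domain count, genome coverage and size statistics
#'
#' @param domains A `domain_set` from [call_domains()].
#' @param queried_genome_bp Denominator for coverage: the summed span of
#'   informative tiles (uninformative regions cannot be classified, so the
#'   assembly length is not used).
#' @return Data frame with one row per kind: `kind`, `n`, `coverage_pct`,
#'   `median_bp` (`NA` when no domain of that kind exists).
#' @export
domain_stats <- function(domains, queried_genome_bp) {
  if (queried_genome_bp <= 0)
    stop("queried_genome_bp must be positive", call. = FALSE)
  out <- lapply(c("hyper", "hypo"), function(k) {
    d <- domains[domains$kind == k, , drop = FALSE]
    len <- d$end - d$start
    data.frame(kind = k, n = nrow(d),
               coverage_pct = 100 * sum(len) / queried_genome_bp,
               median_bp = if (nrow(d)) median(len) else NA_real_)
  })
  do.call(rbind, out)
}

#' Follow domain methylation across all stages
#'
#' Quantifies every domain at every stage with [quantify_features()] (10
#' covered CpGs required by default, the domain feature-class threshold) and
#' summarises per-kind medians; the full value table supports violin-style
#' displays.
#'
#' @param domains A `domain_set`.
#' @param stacks Named list of `cpg_calls`, one per stage (all six).
#' @param cfg A [quant_config()]; defaults to the domain threshold class.
#' @return List with `values` (domains plus one value column per stage) and
#'   `medians` (kind x stage matrix of per-stage medians).
#' @export
domain_trajectory <- function(domains, stacks,
                              cfg = quant_config(min_obs = 10L)) {
  values <- quantify_all(stacks, as.data.frame(domains), cfg)
  kinds <- intersect(c("hyper", "hypo"), unique(values$kind))
  med <- matrix(NA_real_, length(kinds), length(stage_levels()),
                dimnames = list(kinds, stage_levels()))
  for (k in kinds) for (s in stage_levels())
    med[k, s] <- median(values[[s]][values$kind == k], na.rm = TRUE)
  list(values = values, medians = med)
}

#' Rank-based test for a methylation shift between two stages
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test comparing the value
#' distributions of a feature set at two stages, with the direction of the
#' median shift.
#'
#' @param values_a,values_b Numeric value vectors at stage A and stage B
#'   (`NA`s dropped).
#' @return List with `statistic` (U), `p.value`, `direction` (sign of
#'   `median(b) - median(a)`), and the two medians.
#' @export
stage_shift_test <- function(values_a, values_b) {
  a <- values_a[!is.na(values_a)]
  b <- values_b[!is.na(values_b)]
  if (!length(a) || !length(b))
    stop("both samples must be non-empty", call. = FALSE)
  wt <- suppressWarnings(wilcox.test(a, b, alternative = "two.sided"))
  list(statistic = unname(wt$statistic), p.value = wt$p.value,
       direction = sign(median(b) - median(a)),
       median_a = median(a), median_b = median(b))
}
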