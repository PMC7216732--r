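# Gametic DMR classification, imprint-candidate screening, stage-to-stage
# methylation change, annotation enrichment, gene mapping and trajectory
# clustering.

#' Classify the gametic methylation state of features
#'
#' Vectorised five-way classification from oocyte and sperm methylation.
#' With `strict = TRUE` (the DMR-calling convention) a gamete passes the
#' hypermethylated side at `> hyper_min` and the hypomethylated side at
#' `< hypo_max`; with `strict = FALSE` (the state-assignment convention)
#' the thresholds are inclusive.
#'
#' @param oocyte_pct,sperm_pct Numeric vectors of percentages.
#' @param hyper_min,hypo_max Thresholds (defaults 75 / 25).
#' @param strict Use strict inequalities (default `TRUE`).
#' @return Character vector in `{"oocyte_dmr", "sperm_dmr", "both_hyper",
#'   "both_hypo", "neither"}`, `NA` where either input is missing.
#' @export
classify_gametic <- function(oocyte_pct, sperm_pct, hyper_min = 75,
                             hypo_max = 25, strict = TRUE) {
  hi <- function(x) if (strict) x > hyper_min else x >= hyper_min
  lo <- function(x) if (strict) x < hypo_max else x <= hypo_max
  o_hi <- hi(oocyte_pct); o_lo <- lo(oocyte_pct)
  s_hi <- hi(sperm_pct); s_lo <- lo(sperm_pct)
  out <- rep("neither", length(oocyte_pct))
  out[o_hi & s_lo] <- "oocyte_dmr"
  out[s_hi & o_lo] <- "sperm_dmr"
  out[o_hi & s_hi] <- "both_hyper"
  out[o_lo & s_lo] <- "both_hypo"
  out[is.na(oocyte_pct) | is.na(sperm_pct)] <- NA_character_
  out
}

#' Screen gametic DMRs for imprint candidates
#'
#' Keeps features (quantified tiles or CpG islands) whose gametic class
#' matches the requested origin (maternal = methylated in the oocyte only,
#' paternal = methylated in sperm only) and that retain intermediate
#' methylation in the embryo: by default the blastocyst value must lie in
#' `[intermediate_lo, intermediate_hi]`; under
#' `scope = "all_embryo_stages"` every embryo-stage value must.
#'
#' @param features Data frame with `oocyte`, `sperm` and `blastocyst`
#'   value columns (plus the other embryo stages for the all-stages scope).
#' @param origin `"both"`, `"maternal"` or `"paternal"`.
#' @param intermediate_lo,intermediate_hi Inclusive range (defaults 30 / 70).
#' @param scope `"blastocyst_only"` (default) or `"all_embryo_stages"`.
#' @param hyper_min,hypo_max,strict Passed to [classify_gametic()].
#' @return The candidate subset of `features` with an added `origin` column.
#' @export
screen_candidates <- function(features, origin = c("both", "maternal", "paternal"),
                              intermediate_lo = 30, intermediate_hi = 70,
                              scope = c("blastocyst_only", "all_embryo_stages"),
                              hyper_min = 75, hypo_max = 25, strict = TRUE) {
  origin <- match.arg(origin)
  scope <- match.arg(scope)
  cls <- classify_gametic(features$oocyte, features$sperm,
                          hyper_min, hypo_max, strict)
  orig <- rep(NA_character_, nrow(features))
  orig[!is.na(cls) & cls == "oocyte_dmr"] <- "maternal"
  orig[!is.na(cls) & cls == "sperm_dmr"] <- "paternal"
  keep <- !is.na(orig)
  if (origin != "both") keep <- keep & orig == origin
  in_range <- function(x) !is.na(x) & x >= intermediate_lo & x <= intermediate_hi
  if (scope == "blastocyst_only") {
    keep <- keep & in_range(features$blastocyst)
  } else {
    for (s in embryo_stages()) keep <- keep & in_range(features[[s]])
  }
  out <- features[keep, , drop = FALSE]
  out$origin <- orig[keep]
  rownames(out) <- NULL
  out
}

#' Flag candidate overlap with CpG islands
#'
#' Sets `cgi_overlap` to `TRUE` where a candidate shares at least one base
#' pair with a CpG island (half-open interval intersection).
#'
#' @param candidates Interval data frame (`chrom`, `start`, `end`).
#' @param cgis A `feature_set` of CpG islands.
#' @return `candidates` with a logical `cgi_overlap` column.
#' @export
overlap_cgis <- function(candidates, cgis) {
  candidates$cgi_overlap <- if (nrow(candidates) == 0L || nrow(cgis) == 0L) {
    rep(FALSE, nrow(candidates))
  } else {
    countOverlaps(interval_gr(candidates), interval_gr(cgis)) > 0L
  }
  candidates
}

#' Count gamete-specifically methylated CpG islands
#'
#' CGI-level application of [classify_gametic()]: how many quantified CpG
#' islands are methylated specifically in the oocyte or specifically in
#' sperm.
#'
#' @param cgi_values Data frame of CGI-level values with `oocyte` and
#'   `sperm` columns (e.g. CpG islands quantified with
#'   `quant_config(min_obs = 10)`).
#' @param hyper_min,hypo_max,strict Passed to [classify_gametic()].
#' @return List with `n_oocyte` and `n_sperm` counts.
#' @export
gametic_cgi_counts <- function(cgi_values, hyper_min = 75, hypo_max = 25,
                               strict = TRUE) {
  cls <- classify_gametic(cgi_values$oocyte, cgi_values$sperm,
                          hyper_min, hypo_max, strict)
  list(n_oocyte = sum(cls == "oocyte_dmr", na.rm = TRUE),
       n_sperm = sum(cls == "sperm_dmr", na.rm = TRUE))
}

#' Tiles gaining or losing methylation between two stages
#'
#' Among tiles with values at both stages, gains are tiles whose change
#' `b - a` exceeds `min_delta` percentage points and losses those whose
#' change falls below `-min_delta` (strict inequalities: a change of exactly
#' `min_delta` is excluded).
#'
#' @param tiles Informative tiles.
#' @param stage_a,stage_b Stage pair (defaults `"c2_4"` to `"c8_16"`).
#' @param min_delta Minimum absolute change in percentage points (default
#'   10).
#' @return List with `gains`, `losses` (tile subsets with a `delta`
#'   column), `n_tested`, and `gain_fraction` / `loss_fraction` (percent of
#'   tested tiles).
#' @export
delta_tiles <- function(tiles, stage_a = "c2_4", stage_b = "c8_16",
                        min_delta = 10) {
  a <- tiles[[stage_a]]; b <- tiles[[stage_b]]
  ok <- !is.na(a) & !is.na(b)
  tested <- tiles[ok, , drop = FALSE]
  delta <- b[ok] - a[ok]
  tested$delta <- delta
  gains <- tested[delta > min_delta, , drop = FALSE]
  losses <- tested[delta < -min_delta, , drop = FALSE]
  rownames(gains) <- rownames(losses) <- NULL
  list(gains = gains, losses = losses, n_tested = nrow(tested),
       gain_fraction = 100 * nrow(gains) / max(1L, nrow(tested)),
       loss_fraction = 100 * nrow(losses) / max(1L, nrow(tested)))
}

#' Annotation enrichment of a tile set over background
#'
#' For every annotation class, tiles are flagged as overlapping (>= 1 bp)
#' or not; the enrichment ratio is the overlap proportion in the selected
#' set divided by the proportion in the full background (so a set equal to
#' its background has ratio exactly 1). The chi-square test (2x2, without
#' continuity correction by default) contrasts the selected tiles against
#' the remaining background tiles; Benjamini-Hochberg adjusted p values are
#' reported alongside the raw ones.
#'
#' @param tile_set Selected tiles (a subset of `background`).
#' @param background All informative tiles.
#' @param annotations Named list of `feature_set`s (one per class).
#' @param correct Apply Yates continuity correction (default `FALSE`).
#' @return Data frame: `class`, `n_set`, `n_bg`, `prop_set`, `prop_bg`,
#'   `ratio`, `statistic`, `p.value`, `padj`.
#' @export
feature_enrichment <- function(tile_set, background, annotations,
                               correct = FALSE) {
  if (nrow(tile_set) == 0L) stop("empty tile set", call. = FALSE)
  set_gr <- interval_gr(tile_set)
  bg_gr <- interval_gr(background)
  key <- function(df) paste(df$chrom, df$start, df$end)
  in_set <- key(background) %in% key(tile_set)
  rows <- lapply(names(annotations), function(cl) {
    ann <- annotations[[cl]]
    ov_set <- countOverlaps(set_gr, interval_gr(ann)) > 0L
    ov_bg <- countOverlaps(bg_gr, interval_gr(ann)) > 0L
    p_set <- mean(ov_set); p_bg <- mean(ov_bg)
    rest <- !in_set
    stat <- p <- NA_real_
    if (any(rest)) {
      tab <- matrix(c(sum(ov_set), sum(!ov_set),
                      sum(ov_bg[rest]), sum(!ov_bg[rest])), nrow = 2L)
      if (all(rowSums(tab) > 0) && all(colSums(tab) > 0)) {
        ct <- suppressWarnings(chisq.test(tab, correct = correct))
        stat <- unname(ct$statistic); p <- ct$p.value
      }
    }
    data.frame(class = cl, n_set = nrow(tile_set), n_bg = nrow(background),
               prop_set = p_set, prop_bg = p_bg,
               ratio = if (p_bg > 0) p_set / p_bg else NA_real_,
               statistic = stat, p.value = p)
  })
  out <- do.call(rbind, rows)
  out$padj <- p.adjust(out$p.value, method = "BH")
  rownames(out) <- NULL
  out
}

#' Map candidates to their nearest gene
#'
#' Signed distance to the nearest gene span: 0 when the candidate overlaps
#' the gene, positive when it lies downstream of the gene end, negative when
#' upstream of the gene start (gap sizes in bp, genomic orientation).
#' Candidates at `max_dist` or farther are flagged unassigned.
#'
#' @param candidates Interval data frame.
#' @param genes A non-empty `feature_set` of gene spans.
#' @param max_dist Assignment limit in bp (default 50000; a candidate is
#'   assigned when `abs(distance) < max_dist`).
#' @return `candidates` with `nearest_gene`, `gene_distance` and `assigned`
#'   columns.
#' @export
map_candidates_to_genes <- function(candidates, genes, max_dist = 50000) {
  if (nrow(genes) == 0L) stop("gene set is empty", call. = FALSE)
  n <- nrow(candidates)
  candidates$nearest_gene <- rep(NA_character_, n)
  candidates$gene_distance <- rep(NA_real_, n)
  candidates$assigned <- rep(FALSE, n)
  if (n == 0L) return(candidates)
  hit <- distanceToNearest(interval_gr(candidates), interval_gr(genes))
  q <- queryHits(hit); s <- subjectHits(hit)
  gs <- genes$start[s]; ge <- genes$end[s]
  cs <- candidates$start[q]; ce <- candidates$end[q]
  d <- numeric(length(q))
  d[cs >= ge] <- (cs - ge)[cs >= ge]          # downstream of gene
  d[ce <= gs] <- (ce - gs)[ce <= gs]          # upstream of gene (negative)
  candidates$nearest_gene[q] <- genes$name[s]
  candidates$gene_distance[q] <- d
  candidates$assigned[q] <- abs(d) < max_dist
  candidates
}

#' Cluster germline DMR methylation trajectories
#'
#' Mean-imputes missing values within each candidate, centres the
#' candidate-by-stage matrix, projects it onto the first two principal
#' components, and partitions the scores by k-means (fixed seed, 10
#' restarts) — deterministic given the seed.
#'
#' @param trajectories Numeric matrix, candidates in rows, stages in
#'   columns.
#' @param n_clusters Number of clusters (default 2).
#' @param seed Integer seed for the k-means restarts.
#' @return List with `cluster` (integer labels), `scores` (first two PC
#'   scores), `centers`, and the `prcomp` fit.
#' @export
cluster_gdmr_dynamics <- function(trajectories, n_clusters = 2L, seed) {
  if (missing(seed)) stop("a seed is required", call. = FALSE)
  x <- as.matrix(trajectories)
  if (nrow(x) < n_clusters)
    stop("fewer candidates than clusters", call. = FALSE)
  for (i in seq_len(nrow(x))) {
    miss <- is.na(x[i, ])
    if (all(miss)) stop("candidate ", i, " has no values", call. = FALSE)
    if (any(miss)) x[i, miss] <- mean(x[i, !miss])
  }
  x <- scale(x, center = TRUE, scale = FALSE)
  pc <- prcomp(x, center = FALSE)
  scores <- pc$x[, seq_len(min(2L, ncol(pc$x))), drop = FALSE]
  set.seed(seed)
  km <- kmeans(scores, centers = n_clusters, nstart = 10L)
  list(cluster = km$cluster, scores = scores, centers = km$centers, pca = pc)
}
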