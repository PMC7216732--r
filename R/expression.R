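# Expression quantitation (log2 FPM), promoter definition, and the
# methylation-expression analyses.

#' Define strand-aware promoter windows
#'
#' Promoters span 1500 bp upstream and 500 bp downstream of the TSS by
#' default. In internal 0-based half-open coordinates with `t` the TSS base:
#' plus strand `[t - upstream, t + downstream)`; minus strand the mirror
#' image `[t - downstream + 1, t + upstream + 1)`. Windows are clipped at
#' chromosome bounds when lengths are supplied.
#'
#' @param genes A `feature_set` of genes carrying `strand` and a 0-based
#'   `tss0` column (as produced by [read_features()] with the `gene_tsv`
#'   dialect). Without `tss0`, the TSS is derived from the span (`start` on
#'   plus, `end - 1` on minus).
#' @param upstream,downstream Window extents in bp (defaults 1500 / 500).
#' @param chrom_lengths Optional named vector of chromosome lengths for
#'   clipping.
#' @param default_strand Strand to assume for `"."` entries; unset, a `"."`
#'   strand is an error.
#' @return A `feature_set` of class `"promoter"`, named after the genes.
#' @export
define_promoters <- function(genes, upstream = 1500L, downstream = 500L,
                             chrom_lengths = NULL, default_strand = NULL) {
  strand <- genes$strand
  if (any(strand == ".")) {
    if (is.null(default_strand))
      stop("genes with strand '.' need a default_strand policy", call. = FALSE)
    strand[strand == "."] <- default_strand
  }
  tss0 <- if (!is.null(genes$tss0)) genes$tss0
          else ifelse(strand == "+", genes$start, genes$end - 1L)
  start <- ifelse(strand == "+", tss0 - upstream, tss0 - downstream + 1L)
  end <- ifelse(strand == "+", tss0 + downstream, tss0 + upstream + 1L)
  start <- pmax(start, 0L)
  if (!is.null(chrom_lengths))
    end <- pmin(end, unname(chrom_lengths[genes$chrom]))
  new_feature_set(data.frame(chrom = genes$chrom, start = start, end = end,
                             name = genes$name, strand = strand),
                  "promoter")
}

#' Expression as log2 fragments per million
#'
#' `log2(1e6 * count / library_size + offset)`; the default offset of 1 FPM
#' keeps zero counts at exactly 0 and avoids minus infinity.
#'
#' @param counts Gene-by-stage matrix of fragment counts (>= 0).
#' @param library_sizes Per-stage library sizes in fragments (> 0), recycled
#'   across the matched columns of `counts`.
#' @param offset Pseudo-FPM added before the log (default 1).
#' @return Matrix of log2 FPM values with the dimnames of `counts`.
#' @export
quantify_log2fpm <- function(counts, library_sizes, offset = 1) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be >= 0", call. = FALSE)
  if (!is.null(names(library_sizes)) && !is.null(colnames(counts)))
    library_sizes <- library_sizes[colnames(counts)]
  if (length(library_sizes) == 1L)
    library_sizes <- rep(library_sizes, ncol(counts))
  if (length(library_sizes) != ncol(counts))
    stop("library_sizes must match the count matrix columns", call. = FALSE)
  if (any(is.na(library_sizes)) || any(library_sizes <= 0))
    stop("library sizes must be positive", call. = FALSE)
  fpm <- sweep(counts, 2L, library_sizes / 1e6, "/")
  log2(fpm + offset)
}

#' Stage-by-stage methylation-expression correlation matrix
#'
#' Pearson correlation of feature methylation against gene expression for
#' every (methylation stage, expression stage) pair, over a common gene
#' list, dropping genes with missing values pairwise. Cells with fewer than
#' three complete pairs, or with a constant margin, are `NA`.
#'
#' @param meth Gene-by-stage matrix of methylation percentages (rows named
#'   by gene).
#' @param expr Gene-by-stage matrix of log2 FPM (rows named by gene).
#' @param genes Optional gene list; defaults to the row-name intersection.
#' @return List with `r` (correlation matrix, methylation stages in rows)
#'   and `n` (complete pairs per cell).
#' @export
meth_expr_correlation <- function(meth, expr, genes = NULL) {
  meth <- as.matrix(meth); expr <- as.matrix(expr)
  if (is.null(genes)) genes <- intersect(rownames(meth), rownames(expr))
  if (!length(genes)) stop("no shared genes between matrices", call. = FALSE)
  meth <- meth[genes, , drop = FALSE]; expr <- expr[genes, , drop = FALSE]
  r <- matrix(NA_real_, ncol(meth), ncol(expr),
              dimnames = list(colnames(meth), colnames(expr)))
  n <- r
  for (i in seq_len(ncol(meth))) for (j in seq_len(ncol(expr))) {
    ok <- !is.na(meth[, i]) & !is.na(expr[, j])
    n[i, j] <- sum(ok)
    if (n[i, j] >= 3 && sd(meth[ok, i]) > 0 && sd(expr[ok, j]) > 0)
      r[i, j] <- cor(meth[ok, i], expr[ok, j])
  }
  list(r = r, n = n)
}

#' Gene-body methylation versus expression
#'
#' Bins genes by gene-body methylation and summarises the expression
#' distribution per bin, with a Spearman rank correlation across genes as
#' the trend statistic.
#'
#' @param genebody_meth Named numeric vector of gene-body methylation
#'   percentages.
#' @param expr Named numeric vector of log2 FPM for the same genes.
#' @param breaks Bin boundaries on the percent scale (default quartile-width
#'   bins `0, 25, 50, 75, 100`).
#' @return List with `bins` (per-bin n, median and mean expression; empty
#'   bins reported with `NA`), `rho` and `p.value` from the rank
#'   correlation.
#' @export
genebody_meth_vs_expr <- function(genebody_meth, expr,
                                  breaks = seq(0, 100, by = 25)) {
  if (!is.null(names(genebody_meth)) && !is.null(names(expr))) {
    genes <- intersect(names(genebody_meth), names(expr))
    genebody_meth <- genebody_meth[genes]; expr <- expr[genes]
  }
  ok <- !is.na(genebody_meth) & !is.na(expr)
  m <- genebody_meth[ok]; e <- expr[ok]
  if (sum(table(cut(m, breaks, include.lowest = TRUE)) > 0) < 2)
    stop("need at least two populated methylation bins", call. = FALSE)
  bin <- cut(m, breaks, include.lowest = TRUE)
  bins <- data.frame(bin = levels(bin),
                     n = as.integer(table(bin)),
                     median_expr = as.numeric(tapply(e, bin, median)[levels(bin)]),
                     mean_expr = as.numeric(tapply(e, bin, mean)[levels(bin)]))
  ct <- suppressWarnings(cor.test(m, e, method = "spearman"))
  list(bins = bins, rho = unname(ct$estimate), p.value = ct$p.value)
}

#' Expression response at promoters demethylated after fertilisation
#'
#' Selects promoters hypermethylated in the chosen gamete (>= `hyper_min`)
#' whose methylation drops by more than `demeth_threshold` percentage
#' points by the cleavage stage, classifies the associated genes as up- or
#' downregulated (> `fold`-fold change in FPM space between the two
#' expression stages) or stable, and contrasts the changed/stable
#' proportions against all other promoters by chi-square.
#'
#' @param promoter_meth Gene-by-stage matrix of promoter methylation
#'   percentages (must contain the gamete column and `cleavage_stage`).
#' @param expr Gene-by-stage matrix of log2 FPM (same row names).
#' @param gamete `"sperm"` or `"oocyte"`.
#' @param hyper_min Gamete hypermethylation threshold (default 75,
#'   inclusive).
#' @param demeth_threshold Required drop in percentage points (default 50,
#'   strict).
#' @param fold Fold-change threshold on the FPM scale (default 2, i.e.
#'   `|delta log2 FPM| > 1`, strict).
#' @param cleavage_stage Stage at which demethylation is assessed (default
#'   `"c2_4"`).
#' @param stage_from,stage_to Expression stage pair (defaults `"c2_4"` to
#'   `"c8_16"`; the source analysis names only "following fertilisation").
#' @return List with `table` (2x2: demethylated-vs-other by changed-vs-
#'   stable), `p.value`, `n_qualifying`, and the per-group up/down/stable
#'   counts.
#' @export
demethylated_promoter_test <- function(promoter_meth, expr,
                                       gamete = c("oocyte", "sperm"),
                                       hyper_min = 75, demeth_threshold = 50,
                                       fold = 2, cleavage_stage = "c2_4",
                                       stage_from = "c2_4", stage_to = "c8_16") {
  gamete <- match.arg(gamete)
  promoter_meth <- as.matrix(promoter_meth); expr <- as.matrix(expr)
  genes <- intersect(rownames(promoter_meth), rownames(expr))
  g <- promoter_meth[genes, gamete]
  cl <- promoter_meth[genes, cleavage_stage]
  de <- expr[genes, stage_to] - expr[genes, stage_from]
  ok <- !is.na(g) & !is.na(cl) & !is.na(de)
  g <- g[ok]; cl <- cl[ok]; de <- de[ok]
  qual <- g >= hyper_min & (g - cl) > demeth_threshold
  if (!any(qual))
    stop("no qualifying demethylated ", gamete, " promoters", call. = FALSE)
  dir <- ifelse(de > log2(fold), "up", ifelse(de < -log2(fold), "down", "stable"))
  changed <- dir != "stable"
  tab <- matrix(c(sum(changed[qual]), sum(!changed[qual]),
                  sum(changed[!qual]), sum(!changed[!qual])),
                nrow = 2L,
                dimnames = list(c("changed", "stable"),
                                c("demethylated", "other")))
  p <- if (all(rowSums(tab) > 0) && all(colSums(tab) > 0))
    suppressWarnings(chisq.test(tab, correct = FALSE))$p.value else NA_real_
  counts <- function(sel) c(up = sum(dir[sel] == "up"),
                            down = sum(dir[sel] == "down"),
                            stable = sum(dir[sel] == "stable"))
  list(table = tab, p.value = p, n_qualifying = sum(qual),
       demethylated = counts(qual), other = counts(!qual))
}
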