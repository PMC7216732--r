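# IO for the external formats the pipeline touches.
#
# Coordinate conventions: CpG positions are 1-based (position of the C on the
# forward strand, as in Bismark coverage files); all interval features are
# held internally as 0-based half-open [start, end). External 1-based
# inclusive dialects are shifted at the read/write boundary and nowhere else.

new_cpg_calls <- function(df, stage, sample = NULL) {
  stage <- check_stage(stage)
  df <- as.data.frame(df)[, c("chrom", "pos", "meth", "unmeth")]
  df$chrom <- as.character(df$chrom)
  df$pos <- as.integer(df$pos)
  df$meth <- as.integer(df$meth)
  df$unmeth <- as.integer(df$unmeth)
  if (nrow(df)) {
    if (any(df$pos < 1L)) stop("CpG positions must be >= 1", call. = FALSE)
    if (any(df$meth < 0L) || any(df$unmeth < 0L))
      stop("methylation counts must be >= 0", call. = FALSE)
    df <- df[order(df$chrom, df$pos), , drop = FALSE]
    if (anyDuplicated(df[, c("chrom", "pos")]))
      stop("duplicate (chrom, pos) entries in call set", call. = FALSE)
    rownames(df) <- NULL
  }
  structure(df, stage = stage, sample = sample,
            class = c("cpg_calls", "data.frame"))
}

#' Read a Bismark-style coverage file
#'
#' Parses the six-column Bismark coverage dialect (chrom, start, end,
#' percent-methylation, count-methylated, count-unmethylated; tab-separated,
#' optionally gzipped). The percent column is ignored and recomputed from the
#' counts downstream; rows with zero total coverage are dropped because they
#' carry no information.
#'
#' @param path Path to a `.cov` or `.cov.gz` file.
#' @param stage One of [stage_levels()].
#' @param sample Optional sample label kept as an attribute.
#' @return A `cpg_calls` data frame with columns `chrom`, `pos` (1-based),
#'   `meth`, `unmeth`, sorted by (chrom, pos), with `stage` and `sample`
#'   attributes.
#' @export
#' @seealso [write_coverage()], [merge_replicates()]
read_coverage <- function(path, stage, sample = NULL) {
  check_stage(stage)
  if (!file.exists(path)) stop("coverage file not found: ", path, call. = FALSE)
  dt <- fread_maybe_gz(path, colClasses = "character")
  if (nrow(dt) == 0L)
    return(new_cpg_calls(data.frame(chrom = character(), pos = integer(),
                                    meth = integer(), unmeth = integer()),
                         stage, sample))
  if (ncol(dt) != 6L) {
    # locate the first offending line for the error message
    bad <- which(apply(is.na(as.matrix(dt)) | as.matrix(dt) == "", 1L, any))
    stop(sprintf("malformed coverage file '%s': expected 6 tab-separated columns (first bad line: %d)",
                 path, if (length(bad)) bad[1L] else 1L), call. = FALSE)
  }
  ok_int <- grepl("^[0-9]+$", dt[[5L]]) & grepl("^[0-9]+$", dt[[6L]])
  if (!all(ok_int))
    stop(sprintf("non-integer count in coverage file '%s' at line %d",
                 path, which(!ok_int)[1L]), call. = FALSE)
  df <- data.frame(chrom = dt[[1L]],
                   pos = as.integer(dt[[2L]]),
                   meth = as.integer(dt[[5L]]),
                   unmeth = as.integer(dt[[6L]]))
  df <- df[df$meth + df$unmeth > 0L, , drop = FALSE]
  new_cpg_calls(df, stage, sample)
}

#' Write a Bismark-style coverage file
#'
#' Emits the bit-exact six-column coverage dialect: the percent column is
#' `100 * meth / (meth + unmeth)` printed with six decimals, rows sorted by
#' (chrom, pos). A `.gz` suffix triggers gzip compression.
#'
#' @param calls A `cpg_calls` object (see [read_coverage()]).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_coverage <- function(calls, path) {
  stopifnot(inherits(calls, "cpg_calls"))
  pct <- sprintf("%.6f", 100 * calls$meth / (calls$meth + calls$unmeth))
  out <- data.table(calls$chrom, calls$pos, calls$pos, pct,
                    calls$meth, calls$unmeth)
  fwrite(out, path, sep = "\t", col.names = FALSE, quote = FALSE,
         compress = if (grepl("\\.gz$", path)) "gzip" else "none")
  invisible(path)
}

#' Merge replicate call sets of one stage
#'
#' Sums methylated and unmethylated counts per (chrom, pos) across replicates,
#' the per-stage merge applied before tile quantitation.
#'
#' @param replicates A list of `cpg_calls` objects sharing one stage label
#'   (a single `cpg_calls` object is also accepted).
#' @return A merged `cpg_calls` object.
#' @export
merge_replicates <- function(replicates) {
  if (inherits(replicates, "cpg_calls")) replicates <- list(replicates)
  stopifnot(length(replicates) >= 1L,
            all(vapply(replicates, inherits, TRUE, "cpg_calls")))
  stages <- vapply(replicates, attr, "", "stage")
  if (length(unique(stages)) != 1L)
    stop("cannot merge replicates with mixed stage labels: ",
         paste(unique(stages), collapse = ", "), call. = FALSE)
  dt <- rbindlist(lapply(replicates, function(x)
    as.data.table(as.data.frame(x))))
  merged <- dt[, list(meth = sum(meth), unmeth = sum(unmeth)),
               by = c("chrom", "pos")]
  new_cpg_calls(as.data.frame(merged), stages[1L])
}

new_feature_set <- function(df, feature_class) {
  df <- as.data.frame(df)
  need <- c("chrom", "start", "end")
  if (!all(need %in% names(df)))
    stop("feature set needs chrom/start/end columns", call. = FALSE)
  if (!"name" %in% names(df))
    df$name <- if (nrow(df)) paste0(feature_class, "_", seq_len(nrow(df))) else character()
  if (!"strand" %in% names(df)) df$strand <- rep(".", nrow(df))
  df$chrom <- as.character(df$chrom)
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  df$strand <- as.character(df$strand)
  if (nrow(df)) {
    if (any(df$start >= df$end))
      stop("feature intervals must satisfy start < end (0-based half-open)",
           call. = FALSE)
    if (!all(df$strand %in% c("+", "-", ".")))
      stop("strand must be one of '+', '-', '.'", call. = FALSE)
    df <- df[order(df$chrom, df$start, df$end), , drop = FALSE]
    rownames(df) <- NULL
  }
  structure(df, feature_class = feature_class,
            class = c("feature_set", "data.frame"))
}

#' Read genomic features (BED or gene-table dialect)
#'
#' Reads annotation intervals into the internal 0-based half-open convention.
#' BED input (`dialect = "bed"`, 3-6 columns) is taken verbatim; the
#' `"gene_tsv"` dialect is a 6-column table `gene_id, chrom, strand, tss,
#' start, end` with 1-based inclusive coordinates, shifted at read time
#' (`start - 1`; `end` unchanged; the TSS is kept as an extra 0-based `tss0`
#' column). `one_based = TRUE` applies the same shift to BED-like input.
#'
#' @param path File path (plain or gzipped TSV).
#' @param feature_class Label such as `"gene"`, `"cgi"`, `"sine"`, `"line"`,
#'   `"promoter"`, `"intergenic"` or `"custom"`.
#' @param dialect `"bed"` (default) or `"gene_tsv"`.
#' @param one_based For `"bed"`, whether coordinates are 1-based inclusive.
#' @return A `feature_set` data frame (`chrom`, `start`, `end`, `name`,
#'   `strand`, and `tss0` for genes) with a `feature_class` attribute.
#' @export
read_features <- function(path, feature_class,
                          dialect = c("bed", "gene_tsv"), one_based = FALSE) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("feature file not found: ", path, call. = FALSE)
  dt <- fread_maybe_gz(path)
  if (nrow(dt) == 0L)
    return(new_feature_set(data.frame(chrom = character(), start = integer(),
                                      end = integer()), feature_class))
  if (dialect == "bed") {
    if (ncol(dt) < 3L) stop("BED input needs at least 3 columns", call. = FALSE)
    df <- data.frame(chrom = as.character(dt[[1L]]),
                     start = as.integer(dt[[2L]]) - if (one_based) 1L else 0L,
                     end = as.integer(dt[[3L]]))
    if (ncol(dt) >= 4L) df$name <- as.character(dt[[4L]])
    if (ncol(dt) >= 6L) df$strand <- as.character(dt[[6L]])
  } else {
    if (ncol(dt) != 6L)
      stop("gene_tsv input needs 6 columns: gene_id, chrom, strand, tss, start, end",
           call. = FALSE)
    df <- data.frame(chrom = as.character(dt[[2L]]),
                     start = as.integer(dt[[5L]]) - 1L,
                     end = as.integer(dt[[6L]]),
                     name = as.character(dt[[1L]]),
                     strand = as.character(dt[[3L]]),
                     tss0 = as.integer(dt[[4L]]) - 1L)
  }
  new_feature_set(df, feature_class)
}

#' Write a feature set as BED
#'
#' BED6 output in the native 0-based half-open convention, so that
#' [read_features()] round-trips coordinates exactly.
#'
#' @param features A `feature_set`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_features <- function(features, path) {
  stopifnot(inherits(features, "feature_set"))
  out <- data.table(features$chrom, features$start, features$end,
                    features$name, 0L, features$strand)
  fwrite(out, path, sep = "\t", col.names = FALSE, quote = FALSE,
         compress = if (grepl("\\.gz$", path)) "gzip" else "none")
  invisible(path)
}

# tab-separated reader with transparent gzip support via a connection
fread_maybe_gz <- function(path, colClasses = NULL) {
  if (grepl("\\.gz$", path)) {
    con <- gzfile(path, "rt")
    on.exit(close(con))
    txt <- readLines(con)
    if (!length(txt))
      return(data.table())
    fread(text = txt, header = FALSE, sep = "\t", colClasses = colClasses,
          fill = TRUE, showProgress = FALSE)
  } else {
    if (file.size(path) == 0L) return(data.table())
    fread(path, header = FALSE, sep = "\t", colClasses = colClasses,
          fill = TRUE, showProgress = FALSE)
  }
}

# GRanges from 0-based half-open intervals (IRanges is 1-based inclusive)
interval_gr <- function(df) {
  GRanges(df$chrom, IRanges(df$start + 1L, df$end))
}

# width-1 GRanges from 1-based CpG positions
position_gr <- function(df) {
  GRanges(df$chrom, IRanges(df$pos, width = 1L))
}
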