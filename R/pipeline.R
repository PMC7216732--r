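# End-to-end orchestration: one config, one call, a result bundle and a
# summary report, with every threshold recorded and deterministic outputs.

#' Pipeline run configuration
#'
#' Bundles input locations (or a simulation block) with every module
#' threshold. Each threshold defaults to the value used throughout the
#' package: 100-CpG tiles, 1 minimum count per position, 5 observed
#' positions for tiles, 10 for CpG islands / domains / intergenic regions,
#' domain thresholds 75/25, intermediate range 30-70, delta > 10 points,
#' promoters -1500/+500 bp of the TSS, gene assignment < 50 kb, > 2-fold
#' expression change, > 50-point promoter demethylation.
#'
#' @param seed Integer seed (mandatory).
#' @param sim Optional [sim_config()] block; when present the study is
#'   simulated instead of read from files.
#' @param coverage Named list of coverage file paths per stage (each entry a
#'   character vector; multiple replicates are merged). Required without
#'   `sim`.
#' @param cpg_track Optional BED of genome CpG positions used to build
#'   tiles; without it, the union of covered positions across stages is
#'   used.
#' @param annotations Named list of annotation file paths (BED) by class,
#'   e.g. `cgi`, `gene` (gene_tsv dialect), `sine`, `line`.
#' @param counts,library_sizes Optional expression inputs: a gene-by-stage
#'   count TSV and a two-column stage/size TSV.
#' @param tile_size,min_count,min_obs_tile,min_obs_feature Quantitation
#'   thresholds.
#' @param informative_mode Passed to [informative_filter()].
#' @param hyper_min,hypo_max,max_gap_tiles Domain thresholds.
#' @param dmr_strict Strict gametic-DMR inequalities (default `TRUE`).
#' @param intermediate_lo,intermediate_hi,screen_scope Imprint screen.
#' @param delta_stage_a,delta_stage_b,min_delta Stage-to-stage change.
#' @param promoter_upstream,promoter_downstream Promoter window.
#' @param max_gene_dist Candidate-to-gene assignment limit (bp).
#' @param demeth_threshold,expr_fold Demethylated-promoter test.
#' @param n_clusters Trajectory clusters (default 2).
#' @param outdir Optional output directory for the result tables.
#' @return A `run_config` list.
#' @export
run_config <- function(seed,
                       sim = NULL,
                       coverage = NULL,
                       cpg_track = NULL,
                       annotations = NULL,
                       counts = NULL,
                       library_sizes = NULL,
                       tile_size = 100L,
                       min_count = 1L,
                       min_obs_tile = 5L,
                       min_obs_feature = 10L,
                       informative_mode = "has_data",
                       hyper_min = 75,
                       hypo_max = 25,
                       max_gap_tiles = 0L,
                       dmr_strict = TRUE,
                       intermediate_lo = 30,
                       intermediate_hi = 70,
                       screen_scope = "blastocyst_only",
                       delta_stage_a = "c2_4",
                       delta_stage_b = "c8_16",
                       min_delta = 10,
                       promoter_upstream = 1500L,
                       promoter_downstream = 500L,
                       max_gene_dist = 50000,
                       demeth_threshold = 50,
                       expr_fold = 2,
                       n_clusters = 2L,
                       outdir = NULL) {
  if (missing(seed)) stop("a seed is mandatory", call. = FALSE)
  if (is.null(sim) && is.null(coverage))
    stop("either a 'sim' block or 'coverage' paths are required", call. = FALSE)
  structure(as.list(environment()), class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' Thin loader: top-level keys map to [run_config()] arguments; a `sim`
#' mapping is passed to [sim_config()] (inheriting the run seed unless it
#' carries its own).
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
run_config_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$sim)) {
    if (is.null(y$sim$seed)) y$sim$seed <- y$seed
    y$sim <- do.call(sim_config, y$sim)
  }
  do.call(run_config, y)
}

#' Run the full pipeline
#'
#' Executes tiling, domain segmentation, imprint screening, stage-change
#' detection and the expression analyses in order, from either simulated or
#' file inputs, and (optionally) writes every result table with a
#' provenance header. Idempotent given fixed inputs and seed.
#'
#' @param cfg A [run_config()].
#' @return A `methrepro_run` bundle: `tiles` (informative, quantified),
#'   `globals`, `histograms`, `domains`, `domain_stats`,
#'   `domain_trajectory`, `hypo_shift_test`, `candidates_tiles`,
#'   `candidates_cgi`, `cgi_counts`, `delta`, `enrichment`, `clusters`,
#'   `expression` components and the `config`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  annotations <- list()
  counts <- NULL; lib_sizes <- NULL
  if (!is.null(cfg$sim)) {
    study <- simulate_methylome_study(cfg$sim)
    stacks <- study$stacks
    cpgs <- study$genome$cpgs
    annotations <- study$genome$features
    expr_sim <- study$expression
    counts <- expr_sim$counts
    lib_sizes <- expr_sim$library_sizes
    genome <- study$genome
  } else {
    # validate every input path before any computation
    paths <- unlist(cfg$coverage)
    missing_files <- paths[!file.exists(paths)]
    if (length(missing_files))
      stop("coverage file(s) not found: ",
           paste(missing_files, collapse = ", "), call. = FALSE)
    missing_stages <- setdiff(stage_levels(), names(cfg$coverage))
    if (length(missing_stages))
      stop("coverage paths missing for stage(s): ",
           paste(missing_stages, collapse = ", "), call. = FALSE)
    stacks <- lapply(stage_levels(), function(s)
      merge_replicates(lapply(cfg$coverage[[s]], read_coverage, stage = s)))
    names(stacks) <- stage_levels()
    cpgs <- if (!is.null(cfg$cpg_track)) {
      tr <- read_features(cfg$cpg_track, "custom")
      split(tr$start + 1L, tr$chrom)
    } else {
      pos <- unique(do.call(rbind, lapply(stacks, function(x)
        as.data.frame(x)[, c("chrom", "pos")])))
      pos <- pos[order(pos$chrom, pos$pos), ]
      split(pos$pos, pos$chrom)
    }
    for (cl in names(cfg$annotations)) {
      annotations[[cl]] <- read_features(
        cfg$annotations[[cl]], cl,
        dialect = if (cl == "gene") "gene_tsv" else "bed")
    }
    if (!is.null(cfg$counts)) {
      cnt <- fread(cfg$counts, showProgress = FALSE)
      counts <- as.matrix(cnt[, -1]); rownames(counts) <- cnt[[1]]
      ls <- fread(cfg$library_sizes, header = FALSE, showProgress = FALSE)
      lib_sizes <- stats::setNames(as.numeric(ls[[2]]), ls[[1]])
    }
    genome <- NULL
  }

  cfg_tile <- quant_config(cfg$min_count, cfg$min_obs_tile)
  cfg_feat <- quant_config(cfg$min_count, cfg$min_obs_feature)

  tiles <- build_tiles(cpgs, cfg$tile_size)
  tiles <- quantify_all(stacks, tiles, cfg_tile)
  informative <- informative_filter(tiles, cfg$informative_mode)

  globals <- vapply(stage_levels(), function(s)
    global_methylation(informative, s), numeric(1))
  histograms <- lapply(stage_levels(), function(s)
    histogram_bins(informative, s))
  names(histograms) <- stage_levels()

  domains <- call_domains(informative, hyper_min = cfg$hyper_min,
                          hypo_max = cfg$hypo_max,
                          max_gap_tiles = cfg$max_gap_tiles)
  queried_bp <- sum(informative$end - informative$start)
  dstats <- domain_stats(domains, queried_bp)
  dtraj <- domain_trajectory(domains, stacks, cfg_feat)
  hypo_vals <- dtraj$values[dtraj$values$kind == "hypo", , drop = FALSE]
  hypo_shift <- if (nrow(hypo_vals) >= 2)
    stage_shift_test(hypo_vals[[cfg$delta_stage_a]],
                     hypo_vals[[cfg$delta_stage_b]]) else NULL

  cand <- screen_candidates(informative, origin = "both",
                            intermediate_lo = cfg$intermediate_lo,
                            intermediate_hi = cfg$intermediate_hi,
                            scope = cfg$screen_scope,
                            hyper_min = cfg$hyper_min, hypo_max = cfg$hypo_max,
                            strict = cfg$dmr_strict)
  cgi_counts <- NULL; cand_cgi <- NULL
  if (!is.null(annotations$cgi) && nrow(annotations$cgi)) {
    cand <- overlap_cgis(cand, annotations$cgi)
    cgi_tbl <- quantify_all(stacks, as.data.frame(annotations$cgi), cfg_feat)
    cgi_counts <- gametic_cgi_counts(cgi_tbl, cfg$hyper_min, cfg$hypo_max,
                                     cfg$dmr_strict)
    cand_cgi <- screen_candidates(cgi_tbl, origin = "both",
                                  intermediate_lo = cfg$intermediate_lo,
                                  intermediate_hi = cfg$intermediate_hi,
                                  scope = cfg$screen_scope,
                                  hyper_min = cfg$hyper_min,
                                  hypo_max = cfg$hypo_max,
                                  strict = cfg$dmr_strict)
  }
  if (!is.null(annotations$gene) && nrow(annotations$gene) && nrow(cand))
    cand <- map_candidates_to_genes(cand, annotations$gene, cfg$max_gene_dist)

  delta <- delta_tiles(informative, cfg$delta_stage_a, cfg$delta_stage_b,
                       cfg$min_delta)
  enr <- if (length(annotations) && nrow(delta$gains))
    feature_enrichment(delta$gains, informative,
                       annotations[setdiff(names(annotations), "promoter")])
  else NULL

  clusters <- NULL
  mat_cand <- cand[cand$origin == "maternal", , drop = FALSE]
  if (nrow(mat_cand) >= cfg$n_clusters) {
    traj <- as.matrix(mat_cand[, embryo_stages(), drop = FALSE])
    rownames(traj) <- mat_cand$tile
    clusters <- cluster_gdmr_dynamics(traj, cfg$n_clusters, seed = cfg$seed)
  }

  expression <- NULL
  if (!is.null(counts) && !is.null(annotations$gene) && nrow(annotations$gene)) {
    expr <- quantify_log2fpm(counts, lib_sizes)
    promoters <- if (!is.null(annotations$promoter)) annotations$promoter
      else define_promoters(annotations$gene,
                            upstream = cfg$promoter_upstream,
                            downstream = cfg$promoter_downstream)
    prom_meth <- sapply(stage_levels(), function(s)
      quantify_features(stacks[[s]], promoters, cfg_feat))
    rownames(prom_meth) <- promoters$name
    gb_meth <- sapply(stage_levels(), function(s)
      quantify_features(stacks[[s]], annotations$gene, cfg_feat))
    rownames(gb_meth) <- annotations$gene$name
    corr <- meth_expr_correlation(prom_meth, expr)
    gb <- tryCatch(genebody_meth_vs_expr(gb_meth[, "oocyte"], expr[, "oocyte"]),
                   error = function(e) NULL)
    demeth <- tryCatch(
      demethylated_promoter_test(prom_meth, expr, gamete = "oocyte",
                                 hyper_min = cfg$hyper_min,
                                 demeth_threshold = cfg$demeth_threshold,
                                 fold = cfg$expr_fold),
      error = function(e) NULL)
    expression <- list(expr = expr, promoter_meth = prom_meth,
                       genebody_meth = gb_meth, correlation = corr,
                       genebody = gb, demeth_test = demeth)
  }

  bundle <- structure(list(
    config = cfg, tiles = informative, n_tiles_total = nrow(tiles),
    globals = globals, histograms = histograms,
    domains = domains, domain_stats = dstats, queried_genome_bp = queried_bp,
    domain_trajectory = dtraj, hypo_shift_test = hypo_shift,
    candidates_tiles = cand, candidates_cgi = cand_cgi,
    cgi_counts = cgi_counts, delta = delta, enrichment = enr,
    clusters = clusters, expression = expression,
    truth = if (!is.null(genome)) genome$truth else NULL),
    class = "methrepro_run")
  if (!is.null(cfg$outdir)) write_bundle(bundle, cfg$outdir)
  bundle
}

# write every result table with a provenance header (no timestamps, so
# repeated runs are byte-identical)
write_bundle <- function(bundle, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  cfg <- bundle$config
  cfg_json <- file.path(outdir, "config.json")
  ser <- cfg[!vapply(cfg, is.null, TRUE)]
  ser$outdir <- NULL        # volatile; keeps repeated runs byte-identical
  ser$sim <- if (!is.null(cfg$sim)) unclass(cfg$sim) else NULL
  jsonlite::write_json(ser, cfg_json, auto_unbox = TRUE, digits = NA,
                       force = TRUE, pretty = TRUE)
  hash <- unname(tools::md5sum(cfg_json))
  header <- sprintf("# methrepro %s seed=%d config_md5=%s",
                    as.character(utils::packageVersion("methrepro")),
                    cfg$seed, hash)
  wt <- function(df, name) {
    path <- file.path(outdir, name)
    writeLines(header, path)
    if (!is.null(df) && nrow(df))
      suppressWarnings(fwrite(as.data.frame(df), path, sep = "\t",
                              append = TRUE, col.names = TRUE, quote = FALSE))
    path
  }
  wt(bundle$tiles, "tiles.tsv")
  wt(bundle$domains, "domains.bed.tsv")
  wt(bundle$domain_stats, "domain_stats.tsv")
  wt(bundle$candidates_tiles, "candidates_tiles.tsv")
  wt(bundle$candidates_cgi, "candidates_cgi.tsv")
  wt(bundle$delta$gains, "delta_gains.tsv")
  wt(bundle$delta$losses, "delta_losses.tsv")
  wt(bundle$enrichment, "enrichment.tsv")
  glob <- data.frame(stage = names(bundle$globals),
                     global_methylation = unname(bundle$globals))
  wt(glob, "global_methylation.tsv")
  if (!is.null(bundle$expression)) {
    r <- bundle$expression$correlation$r
    wt(data.frame(meth_stage = rownames(r), as.data.frame(r)),
       "correlation.tsv")
  }
  writeLines(c(header, format_report(report(bundle))),
             file.path(outdir, "report.txt"))
  invisible(outdir)
}

#' Summarise a pipeline run
#'
#' Collects the figure-level tables of a run: per-stage global methylation,
#' histogram tables, domain statistics, candidate counts by origin and CGI
#' overlap, stage-change counts, and the correlation matrix.
#'
#' @param bundle A `methrepro_run` from [run_pipeline()].
#' @return A `methrepro_report` list with a print method.
#' @export
report <- function(bundle) {
  stopifnot(inherits(bundle, "methrepro_run"))
  cand <- bundle$candidates_tiles
  structure(list(
    n_tiles_total = bundle$n_tiles_total,
    n_tiles_informative = nrow(bundle$tiles),
    globals = bundle$globals,
    histograms = bundle$histograms,
    domain_stats = bundle$domain_stats,
    candidate_counts = c(
      maternal = sum(cand$origin == "maternal"),
      paternal = sum(cand$origin == "paternal"),
      maternal_cgi = if (!is.null(cand$cgi_overlap))
        sum(cand$origin == "maternal" & cand$cgi_overlap) else NA_integer_,
      paternal_cgi = if (!is.null(cand$cgi_overlap))
        sum(cand$origin == "paternal" & cand$cgi_overlap) else NA_integer_),
    cgi_counts = bundle$cgi_counts,
    delta_counts = c(gains = nrow(bundle$delta$gains),
                     losses = nrow(bundle$delta$losses),
                     tested = bundle$delta$n_tested),
    gain_fraction = bundle$delta$gain_fraction,
    correlation = if (!is.null(bundle$expression))
      bundle$expression$correlation$r else NULL),
    class = "methrepro_report")
}

format_report <- function(x) {
  out <- c(
    sprintf("tiles: %d built, %d informative", x$n_tiles_total,
            x$n_tiles_informative),
    "global methylation (%):",
    sprintf("  %-10s %6.2f", names(x$globals), x$globals),
    "domains:",
    sprintf("  %-5s n=%-6d coverage=%5.1f%% median=%s bp",
            x$domain_stats$kind, x$domain_stats$n, x$domain_stats$coverage_pct,
            ifelse(is.na(x$domain_stats$median_bp), "NA",
                   format(x$domain_stats$median_bp, big.mark = ","))),
    sprintf("imprint candidates: %d maternal (%s with CGI), %d paternal (%s with CGI)",
            x$candidate_counts[["maternal"]],
            x$candidate_counts[["maternal_cgi"]],
            x$candidate_counts[["paternal"]],
            x$candidate_counts[["paternal_cgi"]]))
  if (!is.null(x$cgi_counts))
    out <- c(out, sprintf("gamete-specific methylated CGIs: %d oocyte, %d sperm",
                          x$cgi_counts$n_oocyte, x$cgi_counts$n_sperm))
  out <- c(out, sprintf("stage change (%s): %d gains, %d losses of %d tested (gain fraction %.1f%%)",
                        "delta filter", x$delta_counts[["gains"]],
                        x$delta_counts[["losses"]], x$delta_counts[["tested"]],
                        x$gain_fraction))
  if (!is.null(x$correlation))
    out <- c(out, "promoter methylation x expression Pearson r (diagonal):",
             sprintf("  %-10s %6.3f",
                     rownames(x$correlation),
                     diag(x$correlation)))
  out
}

#' @export
print.methrepro_report <- function(x, ...) {
  cat(format_report(x), sep = "\n")
  invisible(x)
}

#' @export
print.methrepro_run <- function(x, ...) {
  cat("<methrepro_run>\n")
  print(report(x))
  invisible(x)
}
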