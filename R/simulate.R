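# Seeded synthetic-methylome generator with planted, machine-readable
# ground truth.
#
# The generator emulates the statistical structure the analysis modules
# assume: a mosaic oocyte methylome of alternating hyper- and hypomethylated
# tracts, a uniformly hypermethylated sperm methylome with unmethylated CpG
# islands, embryo methylomes formed as unphased mixtures of a slowly
# demethylating maternal allele and a rapidly demethylating paternal allele,
# germline DMRs pinned near 50% with dip-and-recovery trajectories,
# transient de novo methylation of oocyte-hypomethylated tracts at the
# 8-16 cell stage, and gene-body-methylation/expression coupling.
#
# Tracts, germline DMRs and transient-gain regions are planted in whole
# 100-CpG tile units so that planted truth and tile-level calls are
# evaluated on the same footing. Random streams are split per phase
# (genome / methylomes / expression) from the one mandatory seed.

#' Simulation configuration
#'
#' All tunable parameters of the synthetic study, with defaults chosen to
#' mimic a pig-like preimplantation series (see the methods vignette for
#' the rationale behind each default). Methylation levels are expressed as
#' probabilities in `[0, 1]`; the analysis modules work in percent.
#'
#' @param seed Mandatory integer seed.
#' @param n_chromosomes,chromosome_length Genome shape (default 3 x 8 Mb).
#' @param cpg_spacing,cgi_spacing Mean inter-CpG distance (bp) outside and
#'   inside CpG islands (defaults 100 / 10).
#' @param cgi_length CpG island length in bp (default 1000).
#' @param n_genes_per_chrom Genes per chromosome (default 60).
#' @param gene_length Min/max gene length in bp.
#' @param cgi_promoter_fraction Fraction of promoters carrying a CGI.
#' @param n_extra_cgis_per_chrom Non-promoter CGIs per chromosome.
#' @param n_sines_per_chrom,sine_length,n_lines_per_chrom,line_length
#'   Interspersed repeat placement.
#' @param tile_size CpGs per tile used for planting (default 100).
#' @param tract_kind_probs Mix of hyper / hypo / mid tracts in the oocyte
#'   mosaic (defaults 0.5 / 0.2 / 0.3).
#' @param min_tract_tiles,mean_extra_tract_tiles Tract length in tiles:
#'   `min + Geometric(mean = mean_extra)`.
#' @param hyper_range,hypo_range,mid_range True oocyte methylation ranges
#'   per tract kind (one level drawn per tract).
#' @param sperm_level,cgi_gamete_level Sperm baseline and the CGI level in
#'   both gametes.
#' @param preset `"pig_like"` (steep morula-to-blastocyst drop) or
#'   `"cow_like"` (shallower drop); sets the per-allele stage demethylation
#'   factors unless given explicitly. Presets are conveniences, not claims
#'   of parameter equality with any real dataset.
#' @param mat_factors,pat_factors Named per-embryo-stage retention factors
#'   for the maternal and paternal allele.
#' @param n_maternal_gdmr,n_paternal_gdmr Planted imprinted germline DMRs.
#' @param n_decoy_maternal,n_decoy_paternal Planted non-imprinted
#'   gamete-specific DMRs (reprogrammed away in the embryo).
#' @param gdmr_level,gdmr_partner_level Methylation of the methylated and
#'   unmethylated gamete at a DMR.
#' @param gdmr_cluster1_traj,gdmr_cluster2_traj Embryo trajectories of the
#'   two imprinted-DMR archetypes: both dip at the 8-16 cell stage and
#'   recover to ~50%, cluster 1 by the morula, cluster 2 only in the
#'   blastocyst.
#' @param gdmr_cluster_fraction Fraction of imprinted maternal DMRs in
#'   cluster 1.
#' @param transient_gain_fraction Fraction of hypo tracts gaining
#'   methylation at the 8-16 cell stage only.
#' @param transient_gain_delta Size of that transient gain (default 0.20).
#' @param depth_mean,depth_dispersion Negative-binomial read depth per CpG
#'   (defaults mean 15, size 5, emulating sparse PBAT coverage).
#' @param conversion_error Probability that a call is read in the wrong
#'   state (default 0.005).
#' @param expr_coupling_r Population correlation between true gene-body
#'   methylation and latent log2 expression (default 0.4).
#' @param expr_baseline,expr_sd Latent log2 FPM mean and standard
#'   deviation.
#' @param library_size RNA library size per stage in fragments.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed,
                       n_chromosomes = 3L,
                       chromosome_length = 8e6,
                       cpg_spacing = 100,
                       cgi_spacing = 10,
                       cgi_length = 1000L,
                       n_genes_per_chrom = 60L,
                       gene_length = c(5000L, 30000L),
                       cgi_promoter_fraction = 0.5,
                       n_extra_cgis_per_chrom = 20L,
                       n_sines_per_chrom = 80L,
                       sine_length = 300L,
                       n_lines_per_chrom = 30L,
                       line_length = 4000L,
                       tile_size = 100L,
                       tract_kind_probs = c(hyper = 0.5, hypo = 0.2, mid = 0.3),
                       min_tract_tiles = 5L,
                       mean_extra_tract_tiles = 5,
                       hyper_range = c(0.85, 0.95),
                       hypo_range = c(0.02, 0.10),
                       mid_range = c(0.30, 0.70),
                       sperm_level = 0.90,
                       cgi_gamete_level = 0.03,
                       preset = c("pig_like", "cow_like"),
                       mat_factors = NULL,
                       pat_factors = NULL,
                       n_maternal_gdmr = 100L,
                       n_paternal_gdmr = 100L,
                       n_decoy_maternal = 100L,
                       n_decoy_paternal = 100L,
                       gdmr_level = 0.90,
                       gdmr_partner_level = 0.03,
                       gdmr_cluster1_traj = c(c2_4 = 0.50, c8_16 = 0.40,
                                              morula = 0.50, blastocyst = 0.50),
                       gdmr_cluster2_traj = c(c2_4 = 0.50, c8_16 = 0.30,
                                              morula = 0.32, blastocyst = 0.50),
                       gdmr_cluster_fraction = 0.5,
                       transient_gain_fraction = 0.3,
                       transient_gain_delta = 0.20,
                       depth_mean = 15,
                       depth_dispersion = 5,
                       conversion_error = 0.005,
                       expr_coupling_r = 0.4,
                       expr_baseline = 4,
                       expr_sd = 1.5,
                       library_size = 2e7) {
  if (missing(seed)) stop("a seed is mandatory", call. = FALSE)
  preset <- match.arg(preset)
  if (is.null(mat_factors))
    mat_factors <- switch(preset,
      pig_like = c(c2_4 = 0.95, c8_16 = 0.90, morula = 0.85, blastocyst = 0.18),
      cow_like = c(c2_4 = 0.95, c8_16 = 0.92, morula = 0.90, blastocyst = 0.55))
  if (is.null(pat_factors))
    pat_factors <- switch(preset,
      pig_like = c(c2_4 = 0.40, c8_16 = 0.35, morula = 0.30, blastocyst = 0.12),
      cow_like = c(c2_4 = 0.45, c8_16 = 0.40, morula = 0.38, blastocyst = 0.35))
  cfg <- list(seed = as.integer(seed), n_chromosomes = as.integer(n_chromosomes),
              chromosome_length = chromosome_length, cpg_spacing = cpg_spacing,
              cgi_spacing = cgi_spacing, cgi_length = as.integer(cgi_length),
              n_genes_per_chrom = as.integer(n_genes_per_chrom),
              gene_length = as.integer(gene_length),
              cgi_promoter_fraction = cgi_promoter_fraction,
              n_extra_cgis_per_chrom = as.integer(n_extra_cgis_per_chrom),
              n_sines_per_chrom = as.integer(n_sines_per_chrom),
              sine_length = as.integer(sine_length),
              n_lines_per_chrom = as.integer(n_lines_per_chrom),
              line_length = as.integer(line_length),
              tile_size = as.integer(tile_size),
              tract_kind_probs = tract_kind_probs,
              min_tract_tiles = as.integer(min_tract_tiles),
              mean_extra_tract_tiles = mean_extra_tract_tiles,
              hyper_range = hyper_range, hypo_range = hypo_range,
              mid_range = mid_range, sperm_level = sperm_level,
              cgi_gamete_level = cgi_gamete_level, preset = preset,
              mat_factors = mat_factors, pat_factors = pat_factors,
              n_maternal_gdmr = as.integer(n_maternal_gdmr),
              n_paternal_gdmr = as.integer(n_paternal_gdmr),
              n_decoy_maternal = as.integer(n_decoy_maternal),
              n_decoy_paternal = as.integer(n_decoy_paternal),
              gdmr_level = gdmr_level, gdmr_partner_level = gdmr_partner_level,
              gdmr_cluster1_traj = gdmr_cluster1_traj,
              gdmr_cluster2_traj = gdmr_cluster2_traj,
              gdmr_cluster_fraction = gdmr_cluster_fraction,
              transient_gain_fraction = transient_gain_fraction,
              transient_gain_delta = transient_gain_delta,
              depth_mean = depth_mean, depth_dispersion = depth_dispersion,
              conversion_error = conversion_error,
              expr_coupling_r = expr_coupling_r, expr_baseline = expr_baseline,
              expr_sd = expr_sd, library_size = library_size)
  probs <- c(conversion_error, cgi_gamete_level, sperm_level, gdmr_level,
             gdmr_partner_level, transient_gain_fraction, gdmr_cluster_fraction,
             cgi_promoter_fraction, tract_kind_probs)
  if (any(probs < 0 | probs > 1))
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  if (abs(sum(tract_kind_probs) - 1) > 1e-8)
    stop("tract_kind_probs must sum to 1", call. = FALSE)
  if (chromosome_length <= 0 || cpg_spacing <= 2)
    stop("invalid genome dimensions", call. = FALSE)
  if (abs(expr_coupling_r) > 1)
    stop("expr_coupling_r must lie in [-1, 1]", call. = FALSE)
  structure(cfg, class = "sim_config")
}

# integer positions with approximately exponential spacing (mean `spacing`),
# strictly increasing, capped at len
sample_positions <- function(len, spacing, from = 1L) {
  n_guess <- ceiling(1.3 * (len - from) / spacing) + 10L
  gaps <- pmax(2, round(rexp(n_guess, 1 / spacing)))
  pos <- from + cumsum(gaps)
  pos[pos <= len - 1]
}

#' Simulate a genome annotation with planted structure
#'
#' Draws CpG positions (background spacing plus dense clusters at CpG
#' islands), places genes, promoter and standalone CGIs, and interspersed
#' repeats, then plants the oocyte tract mosaic, germline DMRs (imprinted
#' and decoy) and transient-gain regions in whole-tile units. Deterministic
#' given the seed.
#'
#' @param cfg A [sim_config()].
#' @return A `sim_genome` list: `cpgs` (named list of sorted positions per
#'   chromosome), `chrom_lengths`, `features` (gene / promoter / cgi /
#'   sine / line / intergenic `feature_set`s), `tiles` (the planted tile
#'   frame), `tracts` (per-tract kind and true oocyte level), and `truth`
#'   (planted `domains`, `gdmrs`, `gain_regions`).
#' @export
simulate_genome <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  chroms <- paste0("chr", seq_len(cfg$n_chromosomes))
  len <- cfg$chromosome_length
  if (len / cfg$cpg_spacing < cfg$tile_size)
    stop("chromosome too short for the requested CpG density", call. = FALSE)

  genes <- list(); cgis <- list(); sines <- list(); lines_ <- list()
  cpgs <- list(); intergenic <- list()
  for (ci in seq_along(chroms)) {
    ch <- chroms[ci]
    ng <- cfg$n_genes_per_chrom
    g_len <- if (ng) round(runif(ng, cfg$gene_length[1], cfg$gene_length[2])) else integer()
    g_start <- if (ng) sort(round(runif(ng, 2000, len - max(c(g_len, 0)) - 2000))) else integer()
    g_strand <- if (ng) sample(c("+", "-"), ng, replace = TRUE) else character()
    gdf <- data.frame(chrom = rep(ch, ng), start = g_start,
                      end = g_start + g_len,
                      name = sprintf("%s_gene_%03d", ch, seq_len(ng)),
                      strand = g_strand)
    gdf$tss0 <- ifelse(gdf$strand == "+", gdf$start, gdf$end - 1L)
    genes[[ci]] <- gdf
    # CGIs at a fraction of promoters, centred on the TSS, plus extras
    has_cgi <- if (ng) runif(ng) < cfg$cgi_promoter_fraction else logical()
    prom_cgi <- data.frame(chrom = rep(ch, sum(has_cgi)),
                           start = gdf$tss0[has_cgi] - cfg$cgi_length %/% 2L,
                           end = gdf$tss0[has_cgi] + cfg$cgi_length %/% 2L)
    nx <- cfg$n_extra_cgis_per_chrom
    x_start <- if (nx) round(runif(nx, 2000, len - cfg$cgi_length - 2000)) else integer()
    extra_cgi <- data.frame(chrom = rep(ch, nx), start = x_start,
                            end = x_start + cfg$cgi_length)
    cgis[[ci]] <- rbind(prom_cgi, extra_cgi)
    ns <- cfg$n_sines_per_chrom
    s_start <- if (ns) round(runif(ns, 1, len - cfg$sine_length - 1)) else integer()
    sines[[ci]] <- data.frame(chrom = rep(ch, ns), start = s_start,
                              end = s_start + cfg$sine_length)
    nl <- cfg$n_lines_per_chrom
    l_start <- if (nl) round(runif(nl, 1, len - cfg$line_length - 1)) else integer()
    lines_[[ci]] <- data.frame(chrom = rep(ch, nl), start = l_start,
                               end = l_start + cfg$line_length)
    # CpG positions: background + CGI clusters
    bg <- sample_positions(len, cfg$cpg_spacing)
    island_pos <- unlist(lapply(seq_len(nrow(cgis[[ci]])), function(k) {
      s <- max(1L, cgis[[ci]]$start[k]) + 1L
      e <- min(len, cgis[[ci]]$end[k])
      p <- sample_positions(e, cfg$cgi_spacing, from = s)
      p[p > s]
    }), use.names = FALSE)
    cpgs[[ch]] <- sort(unique(c(bg, island_pos)))
    # intergenic complement of gene spans
    if (ng) {
      gr <- GenomicRanges::reduce(interval_gr(gdf))
      gaps <- IRanges::gaps(IRanges::ranges(gr), start = 1L, end = len)
      intergenic[[ci]] <- data.frame(chrom = ch,
                                     start = IRanges::start(gaps) - 1L,
                                     end = IRanges::end(gaps))
    } else {
      intergenic[[ci]] <- data.frame(chrom = ch, start = 0L, end = as.integer(len))
    }
  }
  gene_fs <- new_feature_set(do.call(rbind, genes), "gene")
  tiles <- build_tiles(cpgs, cfg$tile_size)

  # tract mosaic over tile indices, per chromosome
  tracts <- list()
  for (ch in sort(names(cpgs))) {
    idx <- which(tiles$chrom == ch)
    nt <- length(idx)
    pos_t <- 1L
    while (pos_t <= nt) {
      kind <- sample(names(cfg$tract_kind_probs), 1L, prob = cfg$tract_kind_probs)
      tlen <- cfg$min_tract_tiles +
        rgeom(1L, 1 / (cfg$mean_extra_tract_tiles + 1))
      tlen <- min(tlen, nt - pos_t + 1L)
      rng <- switch(kind, hyper = cfg$hyper_range, hypo = cfg$hypo_range,
                    mid = cfg$mid_range)
      tracts[[length(tracts) + 1L]] <- data.frame(
        chrom = ch, tile_first = idx[pos_t], tile_last = idx[pos_t + tlen - 1L],
        start = tiles$start[idx[pos_t]], end = tiles$end[idx[pos_t + tlen - 1L]],
        kind = kind, level = runif(1L, rng[1], rng[2]))
      pos_t <- pos_t + tlen
    }
  }
  tracts <- do.call(rbind, tracts)
  rownames(tracts) <- NULL

  # plant germline DMRs (imprinted + decoy) on distinct mid-tract tiles so
  # the hyper/hypo domain truth stays intact
  mid_tiles <- unlist(lapply(which(tracts$kind == "mid"), function(i)
    seq(tracts$tile_first[i], tracts$tile_last[i])), use.names = FALSE)
  n_need <- cfg$n_maternal_gdmr + cfg$n_paternal_gdmr +
    cfg$n_decoy_maternal + cfg$n_decoy_paternal
  if (length(mid_tiles) < n_need)
    stop("genome too small to plant ", n_need, " germline DMRs (",
         length(mid_tiles), " mid-tract tiles available)", call. = FALSE)
  picked <- sample(mid_tiles, n_need)
  split_at <- cumsum(c(cfg$n_maternal_gdmr, cfg$n_paternal_gdmr,
                       cfg$n_decoy_maternal, cfg$n_decoy_paternal))
  grp <- rep(c("maternal_imp", "paternal_imp", "maternal_decoy", "paternal_decoy"),
             c(cfg$n_maternal_gdmr, cfg$n_paternal_gdmr,
               cfg$n_decoy_maternal, cfg$n_decoy_paternal))
  gdmrs <- data.frame(tile_idx = picked,
                      chrom = tiles$chrom[picked],
                      start = tiles$start[picked],
                      end = tiles$end[picked],
                      origin = sub("_.*", "", grp),
                      imprinted = grepl("_imp$", grp))
  gdmrs$cluster <- rep(NA_integer_, nrow(gdmrs))
  imp_mat <- which(gdmrs$imprinted)
  if (length(imp_mat))
    gdmrs$cluster[imp_mat] <- ifelse(
      runif(length(imp_mat)) < cfg$gdmr_cluster_fraction, 1L, 2L)
  gdmrs <- gdmrs[order(gdmrs$chrom, gdmrs$start), , drop = FALSE]
  rownames(gdmrs) <- NULL

  # transient de novo methylation: a fraction of hypo tracts gain at c8_16
  hypo_idx <- which(tracts$kind == "hypo")
  gain_sel <- hypo_idx[runif(length(hypo_idx)) < cfg$transient_gain_fraction]
  gain_regions <- tracts[gain_sel, c("chrom", "tile_first", "tile_last",
                                     "start", "end"), drop = FALSE]
  rownames(gain_regions) <- NULL

  truth <- list(
    tracts = tracts[tracts$kind %in% c("hyper", "hypo"),
                    c("chrom", "start", "end", "kind", "level"), drop = FALSE],
    gdmrs = gdmrs,
    gain_regions = gain_regions)
  rownames(truth$tracts) <- NULL

  obj <- structure(list(
    cpgs = cpgs,
    chrom_lengths = stats::setNames(rep(len, length(chroms)), chroms),
    features = list(
      gene = gene_fs,
      promoter = define_promoters(gene_fs,
                                  chrom_lengths = stats::setNames(rep(len, length(chroms)), chroms)),
      cgi = new_feature_set(do.call(rbind, cgis), "cgi"),
      sine = new_feature_set(do.call(rbind, sines), "sine"),
      line = new_feature_set(do.call(rbind, lines_), "line"),
      intergenic = new_feature_set(do.call(rbind, intergenic), "intergenic")),
    tiles = tiles,
    tracts = tracts,
    truth = truth), class = "sim_genome")

  # the noise-free domain truth: unmethylated CGIs legitimately interrupt
  # hyper tracts, so planted domains are the segmentation of the true
  # (infinite-depth) tile means, not the raw tract intervals
  true_tiles <- obj$tiles
  true_tiles$oocyte <- NA_real_
  for (ch in sort(names(obj$cpgs))) {
    gam <- true_gamete_p(obj, cfg, ch)
    idx <- which(true_tiles$chrom == ch)
    if (!length(idx)) next
    within <- seq_len(length(idx) * cfg$tile_size)
    true_tiles$oocyte[idx] <- 100 * tapply(
      gam$oocyte[within], (seq_along(within) - 1L) %/% cfg$tile_size, mean)
  }
  obj$truth$domains <- as.data.frame(call_domains(true_tiles))
  obj
}

# true per-CpG gamete methylation probabilities for one chromosome;
# deterministic given the genome object (levels were drawn at genome time)
true_gamete_p <- function(genome, cfg, chrom) {
  pos <- genome$cpgs[[chrom]]
  n <- length(pos)
  mid_mean <- mean(cfg$mid_range)
  oocyte <- rep(mid_mean, n)
  sperm <- rep(cfg$sperm_level, n)
  # tile membership of each CpG (trailing remainder has no tile)
  tile_of <- rep(NA_integer_, n)
  idx <- which(genome$tiles$chrom == chrom)
  if (length(idx)) {
    within <- seq_len(length(idx) * cfg$tile_size)
    tile_of[within] <- idx[(within - 1L) %/% cfg$tile_size + 1L]
  }
  tr <- genome$tracts[genome$tracts$chrom == chrom, , drop = FALSE]
  for (i in seq_len(nrow(tr))) {
    sel <- !is.na(tile_of) & tile_of >= tr$tile_first[i] & tile_of <= tr$tile_last[i]
    oocyte[sel] <- tr$level[i]
  }
  # CGIs unmethylated in both gametes
  cg <- genome$features$cgi[genome$features$cgi$chrom == chrom, , drop = FALSE]
  if (nrow(cg)) {
    hit <- findOverlaps(GRanges(chrom, IRanges(pos, width = 1L)), interval_gr(cg))
    sel <- unique(queryHits(hit))
    oocyte[sel] <- cfg$cgi_gamete_level
    sperm[sel] <- cfg$cgi_gamete_level
  }
  # germline DMR overrides (imprinted and decoy alike)
  gd <- genome$truth$gdmrs[genome$truth$gdmrs$chrom == chrom, , drop = FALSE]
  for (i in seq_len(nrow(gd))) {
    sel <- !is.na(tile_of) & tile_of == gd$tile_idx[i]
    if (gd$origin[i] == "maternal") {
      oocyte[sel] <- cfg$gdmr_level; sperm[sel] <- cfg$gdmr_partner_level
    } else {
      sperm[sel] <- cfg$gdmr_level; oocyte[sel] <- cfg$gdmr_partner_level
    }
  }
  list(oocyte = oocyte, sperm = sperm, tile_of = tile_of)
}

# true per-CpG methylation probability at an embryo stage
true_embryo_p <- function(genome, cfg, chrom, stage, gam) {
  p <- (gam$oocyte * cfg$mat_factors[[stage]] +
        gam$sperm * cfg$pat_factors[[stage]]) / 2
  gd <- genome$truth$gdmrs
  gd <- gd[gd$chrom == chrom & gd$imprinted, , drop = FALSE]
  for (i in seq_len(nrow(gd))) {
    traj <- if (gd$cluster[i] == 1L) cfg$gdmr_cluster1_traj else cfg$gdmr_cluster2_traj
    p[!is.na(gam$tile_of) & gam$tile_of == gd$tile_idx[i]] <- traj[[stage]]
  }
  if (stage == "c8_16") {
    gr <- genome$truth$gain_regions
    gr <- gr[gr$chrom == chrom, , drop = FALSE]
    for (i in seq_len(nrow(gr))) {
      sel <- !is.na(gam$tile_of) & gam$tile_of >= gr$tile_first[i] &
        gam$tile_of <= gr$tile_last[i]
      p[sel] <- pmin(1, p[sel] + cfg$transient_gain_delta)
    }
  }
  p
}

#' Simulate the six stage methylomes
#'
#' Computes true per-CpG methylation probabilities for every stage from the
#' planted genome structure, then draws observed counts: read depth is
#' negative binomial, methylated calls are binomial with the bisulfite
#' conversion error folded in symmetrically. Positions drawing zero depth
#' are absent from the call set, as in real coverage files.
#'
#' @param genome A `sim_genome` from [simulate_genome()].
#' @param cfg The same [sim_config()].
#' @return List with `stacks` (named list of `cpg_calls`, one per stage)
#'   and `truth_p` (per-chromosome matrix of true probabilities, one column
#'   per stage), completing the planted ground truth.
#' @export
simulate_stage_methylomes <- function(genome, cfg) {
  stopifnot(inherits(genome, "sim_genome"), inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 1L)
  stacks <- vector("list", length(stage_levels()))
  names(stacks) <- stage_levels()
  truth_p <- list()
  calls_acc <- lapply(stage_levels(), function(s) list())
  names(calls_acc) <- stage_levels()
  for (chrom in sort(names(genome$cpgs))) {
    pos <- genome$cpgs[[chrom]]
    n <- length(pos)
    gam <- true_gamete_p(genome, cfg, chrom)
    p_stage <- matrix(NA_real_, n, length(stage_levels()),
                      dimnames = list(NULL, stage_levels()))
    p_stage[, "oocyte"] <- gam$oocyte
    p_stage[, "sperm"] <- gam$sperm
    for (s in embryo_stages())
      p_stage[, s] <- true_embryo_p(genome, cfg, chrom, s, gam)
    truth_p[[chrom]] <- p_stage
    for (s in stage_levels()) {
      depth <- rnbinom(n, mu = cfg$depth_mean, size = cfg$depth_dispersion)
      e <- cfg$conversion_error
      p_obs <- p_stage[, s] * (1 - e) + (1 - p_stage[, s]) * e
      meth <- rbinom(n, depth, p_obs)
      keep <- depth > 0L
      calls_acc[[s]][[chrom]] <- data.frame(
        chrom = rep(chrom, sum(keep)), pos = pos[keep], meth = meth[keep],
        unmeth = depth[keep] - meth[keep])
    }
  }
  for (s in stage_levels())
    stacks[[s]] <- new_cpg_calls(do.call(rbind, calls_acc[[s]]), s)
  list(stacks = stacks, truth_p = truth_p)
}

#' Simulate a coupled expression study
#'
#' Latent log2 expression of each gene is `baseline + sd * (r * z + sqrt(1 -
#' r^2) * noise)`, where `z` is the standardised true gene-body oocyte
#' methylation, so `r` is the population methylation-expression correlation
#' at every stage. Fragment counts are Poisson around `FPM * library_size /
#' 1e6`.
#'
#' @param genome A `sim_genome`.
#' @param cfg The same [sim_config()].
#' @return List with `counts` (gene x stage), `library_sizes`, `expr`
#'   (log2 FPM via [quantify_log2fpm()]), and `truth` (true gene-body
#'   methylation percent and the planted coupling `r`).
#' @export
simulate_expression <- function(genome, cfg) {
  stopifnot(inherits(genome, "sim_genome"), inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 2L)
  genes <- genome$features$gene
  if (nrow(genes) == 0L)
    return(list(counts = matrix(numeric(), 0, length(stage_levels()),
                                dimnames = list(NULL, stage_levels())),
                library_sizes = stats::setNames(rep(cfg$library_size,
                                                    length(stage_levels())),
                                                stage_levels()),
                expr = matrix(numeric(), 0, length(stage_levels()),
                              dimnames = list(NULL, stage_levels())),
                truth = list(gene_body_meth = numeric(), r = cfg$expr_coupling_r)))
  # true gene-body oocyte methylation from the planted structure
  m <- numeric(nrow(genes))
  for (chrom in unique(genes$chrom)) {
    gam <- true_gamete_p(genome, cfg, chrom)
    pos <- genome$cpgs[[chrom]]
    sel <- which(genes$chrom == chrom)
    hit <- findOverlaps(GRanges(chrom, IRanges(pos, width = 1L)),
                        interval_gr(genes[sel, , drop = FALSE]))
    mm <- tapply(gam$oocyte[queryHits(hit)], subjectHits(hit), mean)
    m[sel] <- mean(gam$oocyte)   # genes without CpGs fall back to the mean
    m[sel[as.integer(names(mm))]] <- mm
  }
  r <- cfg$expr_coupling_r
  z <- if (sd(m) > 0) (m - mean(m)) / sd(m) else rep(0, length(m))
  stages <- stage_levels()
  latent <- sapply(stages, function(s)
    cfg$expr_baseline + cfg$expr_sd *
      (r * z + sqrt(1 - r^2) * rnorm(length(z))))
  fpm <- 2^latent
  lib <- stats::setNames(rep(cfg$library_size, length(stages)), stages)
  counts <- sapply(stages, function(s)
    rpois(nrow(fpm), fpm[, s] * lib[[s]] / 1e6))
  rownames(counts) <- rownames(latent) <- genes$name
  list(counts = counts, library_sizes = lib,
       expr = quantify_log2fpm(counts, lib),
       truth = list(gene_body_meth = stats::setNames(100 * m, genes$name),
                    r = r))
}

#' Simulate a complete methylome study
#'
#' Convenience wrapper running [simulate_genome()],
#' [simulate_stage_methylomes()] and [simulate_expression()] in sequence.
#'
#' @param cfg A [sim_config()].
#' @return List with `genome`, `stacks`, `truth_p`, `expression`.
#' @export
simulate_methylome_study <- function(cfg) {
  genome <- simulate_genome(cfg)
  meth <- simulate_stage_methylomes(genome, cfg)
  expr <- simulate_expression(genome, cfg)
  list(genome = genome, stacks = meth$stacks, truth_p = meth$truth_p,
       expression = expr)
}
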