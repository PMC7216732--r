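test_that("gametic classification covers all states and boundary semantics", {
  expect_equal(classify_gametic(80, 10), "oocyte_dmr")
  expect_equal(classify_gametic(10, 80), "sperm_dmr")
  expect_equal(classify_gametic(90, 90), "both_hyper")
  expect_equal(classify_gametic(5, 5), "both_hypo")
  expect_equal(classify_gametic(50, 50), "neither")
  expect_true(is.na(classify_gametic(NA, 10)))
  # boundary: exactly 75/25 is neither under strict, a DMR when inclusive
  expect_equal(classify_gametic(75, 25, strict = TRUE), "neither")
  expect_equal(classify_gametic(75, 25, strict = FALSE), "oocyte_dmr")
})

test_that("gametic classification is antisymmetric under gamete swap", {
  set.seed(14)
  o <- runif(200, 0, 100); s <- runif(200, 0, 100)
  a <- classify_gametic(o, s); b <- classify_gametic(s, o)
  swap <- c(oocyte_dmr = "sperm_dmr", sperm_dmr = "oocyte_dmr",
            both_hyper = "both_hyper", both_hypo = "both_hypo",
            neither = "neither")
  expect_equal(unname(swap[a]), b)
})

test_that("imprint screen keeps intermediate gametic DMRs and rejects reprogrammed ones", {
  tbl <- make_tile_table(stats::setNames(list(
    sperm = c(5, 5, 90, 50, 5),
    oocyte = c(90, 90, 5, 50, 90),
    c2_4 = c(45, 45, 45, 45, 45),
    c8_16 = c(40, 40, 40, 40, 20),
    morula = c(50, 30, 50, 50, 50),
    blastocyst = c(50, 10, 55, 50, 50))[c("sperm", "oocyte", "c2_4", "c8_16",
                                          "morula", "blastocyst")],
    c("sperm", "oocyte", "c2_4", "c8_16", "morula", "blastocyst")))
  cand <- screen_candidates(tbl)
  # tile 1: textbook maternal; tile 3: paternal; tile 2 reprogrammed away;
  # tile 4 not a DMR; tile 5 dips below range at c8_16 but passes by default
  expect_equal(cand$tile, c("t001", "t003", "t005"))
  expect_equal(cand$origin, c("maternal", "paternal", "maternal"))
  # the all-embryo-stages scope additionally drops tile 5
  strict_scope <- screen_candidates(tbl, scope = "all_embryo_stages")
  expect_equal(strict_scope$tile, c("t001", "t003"))
  # origin filters
  expect_equal(screen_candidates(tbl, origin = "maternal")$tile, c("t001", "t005"))
  expect_equal(screen_candidates(tbl, origin = "paternal")$tile, "t003")
})

test_that("imprint screen is monotone in the intermediate range", {
  set.seed(15)
  tbl <- make_tile_table(stats::setNames(list(
    runif(300, 0, 100), runif(300, 0, 100), runif(300, 0, 100),
    runif(300, 0, 100), runif(300, 0, 100), runif(300, 0, 100)),
    stage_levels()))
  narrow <- screen_candidates(tbl, intermediate_lo = 40, intermediate_hi = 60)
  wide <- screen_candidates(tbl, intermediate_lo = 30, intermediate_hi = 70)
  expect_true(all(narrow$tile %in% wide$tile))
})

test_that("CGI overlap flags match brute-force all-pairs intersection", {
  cgis <- methrepro:::new_feature_set(
    data.frame(chrom = "chr1", start = c(100L, 500L), end = c(200L, 600L)),
    "cgi")
  cand <- data.frame(chrom = "chr1", start = c(100L, 50L, 200L, 550L),
                     end = c(200L, 99L, 300L, 560L))
  got <- overlap_cgis(cand, cgis)
  # exactly coincident -> TRUE; 1 bp short (end 99 vs start 100) -> FALSE;
  # abutting at the half-open boundary (start 200 = cgi end) -> FALSE
  expect_equal(got$cgi_overlap, c(TRUE, FALSE, FALSE, TRUE))
  set.seed(16)
  rc <- data.frame(chrom = sample(c("chr1", "chr2"), 150, TRUE),
                   start = sample.int(5000, 150))
  rc$end <- rc$start + sample(10:200, 150, TRUE)
  rg <- methrepro:::new_feature_set(
    data.frame(chrom = sample(c("chr1", "chr2"), 40, TRUE),
               start = s <- sample.int(5000, 40),
               end = s + sample(10:200, 40, TRUE)), "cgi")
  got2 <- overlap_cgis(rc, rg)
  want <- vapply(seq_len(nrow(rc)), function(i)
    any(rg$chrom == rc$chrom[i] & rg$start < rc$end[i] & rg$end > rc$start[i]),
    logical(1))
  expect_equal(got2$cgi_overlap, want)
})

test_that("delta tiles use strict percentage-point thresholds and nest by delta", {
  tbl <- make_full_tile_table(4)
  tbl$c2_4 <- c(20, 40, 60, 50)
  tbl$c8_16 <- c(45, 48, 30, NA)
  d <- delta_tiles(tbl)
  expect_equal(d$gains$tile, "t001")       # +25
  expect_equal(d$gains$delta, 25)
  expect_equal(d$losses$tile, "t003")      # -30
  expect_equal(d$n_tested, 3L)             # the NA tile is excluded
  expect_equal(d$gain_fraction, 100 / 3)
  # +8 is below the >10 filter; exactly +10 would also be excluded
  tbl$c8_16 <- c(30, 50, 70, 60)
  d2 <- delta_tiles(tbl)
  expect_equal(nrow(d2$gains), 0L)
  # gains/losses are disjoint and a larger min_delta yields a subset
  set.seed(17)
  tbl3 <- make_full_tile_table(400)
  tbl3$c2_4 <- runif(400, 0, 100)
  tbl3$c8_16 <- pmin(100, pmax(0, tbl3$c2_4 + rnorm(400, 0, 15)))
  d10 <- delta_tiles(tbl3, min_delta = 10)
  d20 <- delta_tiles(tbl3, min_delta = 20)
  expect_length(intersect(d10$gains$tile, d10$losses$tile), 0)
  expect_true(all(d20$gains$tile %in% d10$gains$tile))
  expect_true(all(d20$losses$tile %in% d10$losses$tile))
})

test_that("enrichment ratios and chi-square match closed-form computation", {
  # background of 200 tiles, 100 in the selected set; overlap pattern 90/10
  # in the set vs 10/90 in the rest gives the textbook 2x2 (90,10 / 10,90)
  bg <- make_full_tile_table(200)
  set <- bg[1:100, ]
  ann <- methrepro:::new_feature_set(
    data.frame(chrom = "chr1",
               start = bg$start[c(1:90, 101:110)],
               end = bg$start[c(1:90, 101:110)] + 10L), "cgi")
  e <- feature_enrichment(set, bg, list(cgi = ann))
  expect_equal(e$prop_set, 0.9)
  expect_equal(e$prop_bg, 0.5)
  expect_equal(e$ratio, 1.8)
  # chi-square without continuity correction on (90,10 / 10,90): N * (ad-bc)^2
  # / (row and column products) = 200 * (8100 - 100)^2 / 100^4 = 128
  expect_equal(e$statistic, 128)
  expect_equal(e$p.value, stats::pchisq(128, 1, lower.tail = FALSE))
  # a set equal to its background has ratio exactly 1 for every class
  e2 <- feature_enrichment(bg, bg, list(cgi = ann))
  expect_equal(e2$ratio, 1)
  expect_error(feature_enrichment(bg[0, ], bg, list(cgi = ann)), "empty")
})

test_that("set fully inside an annotation covering 10% of background enriches 10-fold", {
  bg <- make_full_tile_table(1000)
  ann <- methrepro:::new_feature_set(
    data.frame(chrom = "chr1", start = bg$start[1:100], end = bg$end[1:100]),
    "cgi")
  set <- bg[1:50, ]
  e <- feature_enrichment(set, bg, list(cgi = ann))
  expect_equal(e$ratio, 10)
})

test_that("nearest-gene mapping matches a brute-force scan and the distance cutoff", {
  genes <- methrepro:::new_feature_set(
    data.frame(chrom = "chr1", start = c(100000L, 400000L),
               end = c(110000L, 420000L), name = c("gA", "gB"),
               strand = c("+", "-")), "gene")
  cand <- data.frame(chrom = "chr1",
                     start = c(105000L, 160001L, 160002L, 50000L),
                     end = c(105500L, 160501L, 160502L, 50100L))
  m <- map_candidates_to_genes(cand, genes, max_dist = 50000)
  expect_equal(m$gene_distance[1], 0)          # inside gA
  expect_true(m$assigned[1])
  expect_equal(m$gene_distance[2], 50001)      # 50,001 bp past gA end
  expect_false(m$assigned[2])
  expect_equal(m$nearest_gene[4], "gA")
  expect_equal(m$gene_distance[4], -49900)     # upstream, within range
  expect_true(m$assigned[4])
  # boundary: gap of exactly 49,999 assigned, 50,000 not
  b <- map_candidates_to_genes(
    data.frame(chrom = "chr1", start = c(159999L, 160000L),
               end = c(160099L, 160100L)), genes, 50000)
  expect_equal(b$gene_distance, c(49999, 50000))
  expect_equal(b$assigned, c(TRUE, FALSE))
  # random candidates vs a brute-force all-pairs scan
  set.seed(18)
  rc <- data.frame(chrom = "chr1", start = sample.int(600000, 100))
  rc$end <- rc$start + 200L
  mr <- map_candidates_to_genes(rc, genes, 50000)
  for (i in seq_len(nrow(rc))) {
    d <- vapply(seq_len(nrow(genes)), function(j) {
      if (rc$start[i] < genes$end[j] && rc$end[i] > genes$start[j]) 0
      else if (rc$start[i] >= genes$end[j]) rc$start[i] - genes$end[j]
      else rc$end[i] - genes$start[j]
    }, numeric(1))
    expect_equal(abs(mr$gene_distance[i]), min(abs(d)))
    expect_equal(mr$assigned[i], min(abs(d)) < 50000)
  }
})

test_that("trajectory clustering separates archetypes and is label-permutation safe", {
  traj <- rbind(matrix(rep(c(50, 40, 50, 50), 2), 2, byrow = TRUE),
                matrix(rep(c(50, 30, 32, 50), 2), 2, byrow = TRUE))
  cl <- cluster_gdmr_dynamics(traj, 2, seed = 1)
  expect_equal(cl$cluster[1], cl$cluster[2])
  expect_equal(cl$cluster[3], cl$cluster[4])
  expect_true(cl$cluster[1] != cl$cluster[3])
  # the partition is what matters, not the label values
  cl2 <- cluster_gdmr_dynamics(traj[c(3, 4, 1, 2), ], 2, seed = 99)
  expect_true(cl2$cluster[1] == cl2$cluster[2] &&
                cl2$cluster[3] == cl2$cluster[4] &&
                cl2$cluster[1] != cl2$cluster[3])
  # determinism given the seed
  expect_identical(cluster_gdmr_dynamics(traj, 2, seed = 5)$cluster,
                   cluster_gdmr_dynamics(traj, 2, seed = 5)$cluster)
  expect_error(cluster_gdmr_dynamics(traj[1, , drop = FALSE], 2, seed = 1),
               "fewer candidates")
  # mean imputation lets rows with missing stages participate
  traj_na <- traj; traj_na[1, 2] <- NA
  expect_silent(cluster_gdmr_dynamics(traj_na, 2, seed = 1))
})
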