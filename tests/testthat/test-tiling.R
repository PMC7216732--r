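test_that("tiles chunk each chromosome and drop the remainder", {
  pos <- list(chr1 = sort(sample.int(1e6, 250)))
  tiles <- build_tiles(pos, 100)
  expect_equal(nrow(tiles), 2L)
  expect_equal(tiles$n_cpg, c(100L, 100L))
  expect_equal(tiles$start[1], pos$chr1[1] - 1L)
  expect_equal(tiles$end[1], pos$chr1[100])
  expect_equal(tiles$start[2], pos$chr1[101] - 1L)
  expect_equal(tiles$end[2], pos$chr1[200])
  expect_error(build_tiles(list(chr1 = c(5L, 3L, 9L)), 2), "sorted")
})

test_that("tile membership matches brute-force chunking on random maps", {
  set.seed(21)
  cpgs <- lapply(stats::setNames(nm = c("chr1", "chr2", "chr3")), function(ch)
    sort(sample.int(5e5, sample(150:450, 1))))
  tiles <- build_tiles(cpgs, 100)
  for (ch in names(cpgs)) {
    pos <- cpgs[[ch]]
    k <- length(pos) %/% 100
    tch <- tiles[tiles$chrom == ch, ]
    expect_equal(nrow(tch), k)
    for (i in seq_len(k)) {
      chunk <- pos[((i - 1) * 100 + 1):(i * 100)]
      # every member CpG lies inside the half-open span, none outside
      expect_true(all(chunk - 1 >= tch$start[i] & chunk - 1 < tch$end[i]))
      if (i > 1) expect_true(tch$start[i] >= tch$end[i - 1])
    }
  }
  # tiles partition the retained CpGs: disjoint within chromosome
  expect_true(all(tapply(seq_len(nrow(tiles)), tiles$chrom, function(ix)
    !is.unsorted(tiles$start[ix], strictly = TRUE))))
})

test_that("quantify_feature follows per-position semantics", {
  # hand-computable oracle: positions (3/1), (0/2), (5/5) -> mean(75, 0, 50)
  calls <- make_calls("chr1", c(10L, 20L, 30L), c(3L, 0L, 5L), c(1L, 2L, 5L))
  v <- quantify_feature(calls, "chr1", 0, 100, quant_config(min_obs = 3))
  expect_equal(v, mean(c(75, 0, 50)))
  # saturation: all covered CpGs fully methylated
  sat <- make_calls("chr1", seq(10L, 100L, 10L), rep(4L, 10), rep(0L, 10))
  expect_equal(quantify_feature(sat, "chr1", 0, 200, quant_config(min_obs = 10)), 100)
  # below the observation threshold -> missing
  expect_true(is.na(quantify_feature(calls, "chr1", 0, 100,
                                     quant_config(min_obs = 5))))
  # call-count mode: 21 calls pass a threshold of 10
  expect_equal(quantify_feature(calls, "chr1", 0, 100,
                                quant_config(min_obs = 10, unit = "calls")),
               mean(c(75, 0, 50)))
  expect_true(is.na(quantify_feature(calls, "chr1", 0, 100,
                                     quant_config(min_obs = 22, unit = "calls"))))
  # min_count excludes thin positions from both value and count
  cfg2 <- quant_config(min_count = 3, min_obs = 1)
  expect_equal(quantify_feature(calls, "chr1", 0, 100, cfg2), mean(c(75, 50)))
})

test_that("quantification agrees with the brute-force oracle on random features", {
  set.seed(33)
  calls <- random_calls(800, chroms = c("chr1", "chr2"), max_pos = 50000L)
  feats <- data.frame(chrom = sample(c("chr1", "chr2", "chr3"), 200, TRUE),
                      start = sample.int(49000, 200))
  feats$end <- feats$start + sample(100:3000, 200, TRUE)
  for (cfg in list(quant_config(), quant_config(min_count = 3, min_obs = 2),
                   quant_config(min_obs = 20, unit = "calls"))) {
    got <- quantify_features(calls, feats, cfg)
    want <- vapply(seq_len(nrow(feats)), function(i)
      oracle_quantify(calls, feats$chrom[i], feats$start[i], feats$end[i],
                      cfg$min_count, cfg$min_obs, cfg$unit), numeric(1))
    expect_equal(got, want)
  }
})

test_that("quantification is invariant to call order and replicate splits", {
  set.seed(44)
  calls <- random_calls(400, chroms = "chr1", max_pos = 20000L)
  feat <- data.frame(chrom = "chr1", start = 0, end = 20000)
  v0 <- quantify_features(calls, feat, quant_config())
  shuf <- calls[sample(nrow(calls)), ]
  v1 <- quantify_features(methrepro:::new_cpg_calls(shuf, "oocyte"), feat,
                          quant_config())
  expect_equal(v1, v0)
  # split counts across two pseudo-replicates, merge, re-quantify
  m1 <- rbinom(nrow(calls), calls$meth, 0.5)
  u1 <- rbinom(nrow(calls), calls$unmeth, 0.5)
  r1 <- data.frame(chrom = calls$chrom, pos = calls$pos, meth = m1, unmeth = u1)
  r2 <- data.frame(chrom = calls$chrom, pos = calls$pos,
                   meth = calls$meth - m1, unmeth = calls$unmeth - u1)
  keep <- function(d) methrepro:::new_cpg_calls(d[d$meth + d$unmeth > 0, ], "oocyte")
  merged <- merge_replicates(list(keep(r1), keep(r2)))
  expect_equal(quantify_features(merged, feat, quant_config()), v0)
})

test_that("tile values are convex combinations of per-position percentages", {
  set.seed(55)
  calls <- random_calls(600, chroms = "chr1", max_pos = 30000L)
  feats <- data.frame(chrom = "chr1", start = seq(0, 29000, 1000))
  feats$end <- feats$start + 1000
  v <- quantify_features(calls, feats, quant_config(min_obs = 1))
  pct <- 100 * calls$meth / (calls$meth + calls$unmeth)
  for (i in which(!is.na(v))) {
    inside <- calls$pos - 1 >= feats$start[i] & calls$pos - 1 < feats$end[i]
    expect_gte(v[i], min(pct[inside]))
    expect_lte(v[i], max(pct[inside]))
  }
})

test_that("quantify_all equals looped quantify_feature and flags missing stages", {
  set.seed(66)
  stacks <- lapply(stats::setNames(nm = stage_levels()), function(s)
    random_calls(300, chroms = "chr1", stage = s, max_pos = 20000L))
  tiles <- build_tiles(list(chr1 = sort(sample.int(20000L, 300))), 100)
  q <- quantify_all(stacks, tiles, quant_config())
  for (s in stage_levels()) {
    want <- vapply(seq_len(nrow(tiles)), function(i)
      quantify_feature(stacks[[s]], tiles$chrom[i], tiles$start[i],
                       tiles$end[i], quant_config()), numeric(1))
    expect_equal(q[[s]], want)
  }
  expect_error(quantify_all(stacks[-2], tiles, quant_config()), "oocyte")
  # stage with an empty call set -> all values missing
  stacks$morula <- make_calls(character(), integer(), integer(), integer(),
                              stage = "morula")
  q2 <- quantify_all(stacks, tiles, quant_config())
  expect_true(all(is.na(q2$morula)))
})

test_that("informative filter distinguishes has_data from literal_above_zero", {
  tiles <- make_tile_table(stats::setNames(list(
    c(50, 50, 50), c(60, 60, 0), c(70, NA, 70), c(80, 80, 80),
    c(90, 90, 90), c(10, 10, 10)), stage_levels()))
  has <- informative_filter(tiles)
  expect_equal(nrow(has), 2L)           # tile 2 lost to the NA at c2_4
  lit <- informative_filter(tiles, "literal_above_zero")
  expect_equal(nrow(lit), 1L)           # tile 3 additionally lost to the 0
  expect_error(informative_filter(tiles, "bogus"))
})

test_that("global methylation and histograms match brute-force summaries", {
  tiles <- make_tile_table(stats::setNames(rep(list(c(20, 80)), 6), stage_levels()))
  expect_equal(global_methylation(tiles, "oocyte"), 50)
  expect_error(global_methylation(tiles[0, ], "oocyte"), "no informative")
  set.seed(77)
  vals <- runif(1000, 0, 100)
  t2 <- make_tile_table(stats::setNames(rep(list(vals), 6), stage_levels()))
  h <- histogram_bins(t2, "sperm")
  expect_equal(sum(h$fraction), 100)
  for (i in seq_len(nrow(h))) {
    inside <- if (i < nrow(h)) vals >= h$bin_lo[i] & vals < h$bin_hi[i]
              else vals >= h$bin_lo[i] & vals <= h$bin_hi[i]
    expect_equal(h$n[i], sum(inside))
  }
  # closed last bin: a value of exactly 100 is counted
  t3 <- make_full_tile_table(4, value = 100)
  h3 <- histogram_bins(t3, "oocyte")
  expect_equal(h3$fraction[10], 100)
})
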