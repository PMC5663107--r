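test_that("tss_distance finds the nearest site, including exact hits and ties", {
  tss <- tss_annotation(rep("chr1", 2), c(1000, 5000))
  v <- variant_catalog(id = c("a", "b", "c", "d"), chrom = "chr1",
                       pos = c(1500, 1000, 3000, 6000))
  expect_equal(tss_distance(v, tss), c(500L, 0L, 2000L, 1000L))
  v2 <- variant_catalog(id = "x", chrom = "chr9", pos = 5)
  expect_error(tss_distance(v2, tss), "no TSS on chromosome")
})

test_that("TSS annotations read from BED (strand-aware) and position tables", {
  bed <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t99\t200\tg1\t0\t+", "chr1\t499\t600\tg2\t0\t-"), bed)
  tss <- read_tss(bed)
  expect_equal(tss$sites$pos, c(100, 600))  # start on +, end on -

  txt <- tempfile()
  writeLines(c("chr1\t100", "chr2\t300"), txt)
  expect_equal(read_tss(txt)$sites$chrom, c("chr1", "chr2"))
})

test_that("tss-matched sampling delivers ratio x positives with matching distance bins", {
  w <- small_world()
  pos <- risk_set(w$risk_catalog, "traitA")
  cand <- benign_candidates(w$benign_catalog, 0.05, w$risk_catalog)
  ms <- match_negatives_tss(pos, cand, w$tss, ratio = 10, seed = 3)
  expect_equal(nrow(ms$negatives), 10 * nrow(ms$positives))
  expect_length(intersect(ms$positives$id, ms$negatives$id), 0)
  # bin report accounts exactly for the delivered set
  expect_equal(sum(ms$report$sampled_in_bin) + sum(ms$report$lent_to_other_bins),
               nrow(ms$negatives))
  expect_equal(ms$report$required, 10 * ms$report$n_positives)
})

test_that("single-positive bins are served from their own bin when possible", {
  tss <- tss_annotation("chr1", 10000)
  pos <- variant_catalog("p1", "chr1", 10050)            # distance 50: bin 1
  cand <- variant_catalog(paste0("c", 1:3), "chr1",
                          c(10030, 60000, 300000))       # bins 1, ~4.7, ~5.5
  ms <- match_negatives_tss(pos, cand, tss, ratio = 1, seed = 1)
  expect_equal(ms$negatives$id, "c1")
})

test_that("bin shortfall is borrowed from adjacent bins, never under-delivered", {
  tss <- tss_annotation("chr1", 100000)
  # both positives in the nearest-distance bin; only one candidate there
  pos <- variant_catalog(c("p1", "p2"), "chr1", c(100010, 100020))
  cand <- variant_catalog(paste0("c", 1:6), "chr1",
                          100000 + c(50, 500, 600, 700, 800, 900))
  ms <- match_negatives_tss(pos, cand, tss, ratio = 2, seed = 1)
  expect_equal(nrow(ms$negatives), 4)
  expect_true("c1" %in% ms$negatives$id)
  expect_equal(sum(ms$report$lent_to_other_bins), 3)
  expect_error(match_negatives_tss(pos, cand, tss, ratio = 4, seed = 1),
               "insufficient candidates")
})

test_that("matched TSS-distance distributions agree (KS on log10 distance)", {
  w <- simulate_world(sim_config(n_risk = 100, n_benign_pool = 10000,
                                 n_features = 10, n_informative = 1,
                                 seed = 23))
  pos <- risk_set(w$risk_catalog, "traitA")
  cand <- benign_candidates(w$benign_catalog, 0, w$risk_catalog)
  ms <- match_negatives_tss(pos, cand, w$tss, ratio = 10, seed = 23)
  d_pos <- log10(1 + tss_distance(ms$positives, w$tss))
  d_neg <- log10(1 + tss_distance(ms$negatives, w$tss))
  ks <- suppressWarnings(stats::ks.test(d_pos, d_neg)$statistic)
  expect_lt(unname(ks), 0.15)
})

test_that("region-matched negatives all lie within max_dist of a positive", {
  pos <- variant_catalog("p1", "chr1", 100000)
  cand <- variant_catalog(c("c1", "c2"), "chr1", c(105000, 150000))
  ms <- match_negatives_region(pos, cand, max_dist = 10000, ratio = 1,
                               seed = 5)
  expect_equal(ms$negatives$id, "c1")
  expect_error(
    match_negatives_region(pos, variant_catalog("far", "chr1", 500000),
                           max_dist = 10000, ratio = 1, seed = 5),
    "no candidate")

  w <- small_world()
  posw <- risk_set(w$risk_catalog, "traitA")
  candw <- benign_candidates(w$benign_catalog, 0.05, w$risk_catalog)
  msw <- suppressWarnings(
    match_negatives_region(posw, candw, max_dist = 10000, ratio = 10,
                           seed = 5))
  dmin <- vapply(seq_len(nrow(msw$negatives)), function(i) {
    same <- posw$chrom == msw$negatives$chrom[i]
    min(abs(posw$pos[same] - msw$negatives$pos[i]))
  }, numeric(1))
  expect_true(all(dmin <= 10000))
  expect_lte(nrow(msw$negatives), 10 * nrow(posw))
})

test_that("matching is deterministic in the seed and insensitive to candidate order", {
  w <- small_world()
  pos <- risk_set(w$risk_catalog, "traitA")
  cand <- benign_candidates(w$benign_catalog, 0.05, w$risk_catalog)
  ms1 <- match_negatives_tss(pos, cand, w$tss, ratio = 5, seed = 42)
  ms2 <- match_negatives_tss(pos, cand, w$tss, ratio = 5, seed = 42)
  expect_identical(ms1$negatives, ms2$negatives)
  shuffled <- cand[rev(seq_len(nrow(cand))), ]
  ms3 <- match_negatives_tss(pos, shuffled, w$tss, ratio = 5, seed = 42)
  expect_identical(sort(ms1$negatives$id), sort(ms3$negatives$id))
  ms4 <- match_negatives_tss(pos, cand, w$tss, ratio = 5, seed = 43)
  expect_false(identical(sort(ms1$negatives$id), sort(ms4$negatives$id)))
})

test_that("matched sets serialize with a provenance header", {
  w <- small_world()
  pos <- risk_set(w$risk_catalog, "traitA")
  cand <- benign_candidates(w$benign_catalog, 0.05, w$risk_catalog)
  ms <- match_negatives_tss(pos, cand, w$tss, ratio = 2, seed = 1)
  paths <- write_matched_sets(ms, file.path(tempdir(), "msets"))
  lines <- readLines(paths[2])
  expect_match(lines[1], "strategy=tss_matched ratio=2 seed=1")
  body <- lines[!startsWith(lines, "#")]
  expect_length(body, nrow(ms$negatives))
})
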