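toy_track <- function(scores_chr1 = c(0.1, 0.2, 0.3, 0.4, 0.5),
                      scores_chr2 = c(0.6, 0.7, 0.85),
                      lengths = c(chr1 = 1000, chr2 = 600)) {
  score_track(toy_build(lengths), 200, "toytrait",
              list(chr1 = scores_chr1, chr2 = scores_chr2))
}

test_that("track archives round-trip bit-exactly and reject damage", {
  tr <- toy_track()
  path <- tempfile(fileext = ".track.gz")
  write_track(tr, path)
  back <- read_track(path)
  expect_identical(back$scores, tr$scores)
  expect_identical(back$build$length, tr$build$length)
  expect_identical(back$disease, "toytrait")

  # truncation: drop the #end terminator
  lines <- readLines(gzfile(path))
  trunc <- tempfile(fileext = ".track.gz")
  con <- gzfile(trunc, "w"); writeLines(lines[-length(lines)], con); close(con)
  expect_error(read_track(trunc), "truncated track file")

  bad <- tempfile(fileext = ".track.gz")
  con <- gzfile(bad, "w"); writeLines("not a track", con); close(con)
  expect_error(read_track(bad), "incompatible track file")
})

test_that("bedGraph export and re-import reproduce the track", {
  tr <- toy_track()
  bg <- tempfile(fileext = ".bedGraph")
  export_track_bedgraph(tr, bg)
  back <- import_track_bedgraph(bg, tr$build, tr$window_size, tr$disease)
  expect_identical(back$scores, tr$scores)
})

test_that("base scores inherit from the host window", {
  tr <- toy_track()
  expect_equal(base_score(tr, "chr1", 1), 0.1)
  expect_equal(base_score(tr, "chr1", 200), 0.1)
  expect_equal(base_score(tr, "chr1", 201), 0.2)
  expect_equal(base_score(tr, "chr2", 600), 0.85)
  expect_error(base_score(tr, "chr1", 1001), "out of bounds")
  expect_error(base_score(tr, "chr1", 0), "out of bounds")
})

test_that("the score distribution counts every base of the genome", {
  tr <- toy_track()
  d <- build_distribution(tr)
  expect_equal(sum(d$counts), 1600)
  expect_equal(d$total, 1600)

  flat <- score_track(toy_build(), 200, "t",
                      list(chr1 = rep(0.5, 5), chr2 = rep(0.5, 3)))
  df <- build_distribution(flat)
  expect_equal(sum(df$counts > 0), 1)
  expect_equal(df$counts[round(0.5 * 1e4) + 1], 1600)
})

test_that("percentiles follow the inclusive convention", {
  # 10 windows of equal width with distinct scores on one chromosome
  tr <- score_track(genome_build("t", c(chr1 = 2000)), 200, "t",
                    list(chr1 = seq(0.05, 0.95, by = 0.1)))
  d <- build_distribution(tr)
  expect_equal(percentile(d, 0.45), 50)      # 5th smallest
  expect_equal(percentile(d, 0.95), 100)     # track maximum
  expect_equal(percentile(d, 0.01), 0)       # below the minimum
  s <- sort(runif(20))
  expect_true(all(diff(percentile(d, s)) >= 0))  # non-decreasing
})

test_that("histogram percentiles equal explicit per-base expansion", {
  fit <- small_fit()
  tr <- fit$track
  per_base <- unlist(lapply(tr$build$chrom, function(ch) {
    len <- tr$build$length[match(ch, tr$build$chrom)]
    rep(tr$scores[[ch]], times = diff(c(
      (seq_along(tr$scores[[ch]]) - 1) * tr$window_size, len))[
        seq_along(tr$scores[[ch]])])
  }), use.names = FALSE)
  # width expansion above: each window repeated by its width
  expect_equal(length(per_base), sum(tr$build$length))
  d <- build_distribution(tr)
  for (q in c(0.1, 0.35, 0.8)) {
    expect_equal(percentile(d, q),
                 100 * mean(per_base <= q + 1e-9), tolerance = 1e-9)
  }
})

test_that("id queries report score, position and percentile in input order", {
  tr <- toy_track()
  d <- build_distribution(tr)
  cat <- variant_catalog(c("rsA", "rsB", "rsC"), c("chr1", "chr1", "chr2"),
                         c(150, 250, 500))
  expect_warning(res <- query_by_id(c("rsB", "rsA", "rsNope"), tr, d, cat),
                 "unmatched")
  expect_equal(res$id, c("rsB", "rsA"))
  expect_equal(res$dscore, c(0.2, 0.1))
  expect_equal(res$pos, c(250, 150))
  expect_equal(res$percentile, round(100 * c(2, 1) * 200 / 1600, 2))
  # two ids in one window share score and percentile
  cat2 <- variant_catalog(c("x", "y"), "chr1", c(10, 190))
  r2 <- query_by_id(c("x", "y"), tr, d, cat2)
  expect_equal(r2$dscore[1], r2$dscore[2])
  expect_equal(r2$percentile[1], r2$percentile[2])
})

test_that("region queries equal a brute-force catalog scan", {
  fit <- small_fit()
  cat <- fit$world$risk_catalog
  tr <- fit$track; d <- fit$dist
  regions <- data.frame(chrom = c("chr1", "chr1", "chr2"),
                        start = c(1, 50001, 100001),
                        end = c(50000, 50002, 190000))
  res <- query_by_region(regions, tr, d, cat)
  brute <- do.call(rbind, lapply(seq_len(nrow(regions)), function(i) {
    hits <- cat[cat$chrom == regions$chrom[i] &
                  cat$pos >= regions$start[i] &
                  cat$pos <= regions$end[i], ]
    hits[order(hits$pos), c("id", "pos")]
  }))
  expect_equal(res$id, brute$id)
  expect_equal(res$pos, brute$pos)
  for (i in seq_len(nrow(res)))
    expect_equal(res$dscore[i], base_score(tr, res$chrom[i], res$pos[i]))
  # a region with no variants contributes zero rows
  none <- query_by_region(data.frame(chrom = "chr1", start = 1, end = 2),
                          tr, d, cat)
  expect_equal(nrow(none), 0)
})

test_that("region averages match explicit per-base expansion", {
  tr <- toy_track()
  d <- build_distribution(tr)
  regions <- data.frame(chrom = c("chr1", "chr1", "chr1"),
                        start = c(250, 101, 101), end = c(280, 300, 900))
  res <- region_average(regions, tr, d)
  for (i in seq_len(nrow(res))) {
    bases <- vapply(regions$start[i]:regions$end[i], function(p)
      base_score(tr, "chr1", p), numeric(1))
    expect_equal(res$mean_dscore[i], mean(bases), tolerance = 1e-12)
    expect_equal(res$sd_dscore[i],
                 sqrt(mean(bases^2) - mean(bases)^2), tolerance = 1e-12)
    expect_equal(res$mean_percentile[i],
                 round(percentile(d, mean(bases)), 2))
  }
  # single-window region: sd exactly 0
  expect_equal(res$sd_dscore[1], 0)
  # 100 bp at score a + 100 bp at score b -> mean (a+b)/2
  r2 <- region_average(data.frame(chrom = "chr1", start = 101, end = 300),
                       tr, d)
  expect_equal(r2$mean_dscore, (0.1 + 0.2) / 2)
  expect_warning(
    r3 <- region_average(data.frame(chrom = "chrX", start = 1, end = 10),
                         tr, d), "skipped")
  expect_equal(nrow(r3), 0)
})

test_that("whole-chromosome region average equals the width-weighted track mean", {
  fit <- small_fit()
  tr <- fit$track
  res <- region_average(data.frame(chrom = "chr1", start = 1,
                                   end = tr$build$length[1]),
                        tr, fit$dist)
  expect_equal(res$mean_dscore, mean(rep(tr$scores$chr1,
                                         each = tr$window_size))[1],
               tolerance = 1e-12)
})

test_that("id and region queries agree on shared variants", {
  fit <- small_fit()
  cat <- fit$world$risk_catalog
  v <- cat[3, ]
  by_id <- query_by_id(v$id, fit$track, fit$dist, cat)
  by_region <- query_by_region(
    data.frame(chrom = v$chrom, start = v$pos - 100, end = v$pos + 100),
    fit$track, fit$dist, cat)
  row <- by_region[by_region$id == v$id, ]
  expect_equal(by_id$dscore, row$dscore)
  expect_equal(by_id$percentile, row$percentile)
})

test_that("query tables serialize in the documented column layouts", {
  tr <- toy_track()
  d <- build_distribution(tr)
  cat <- variant_catalog("rsA", "chr1", 150)
  out <- tempfile()
  write_query_result(query_by_id("rsA", tr, d, cat), out)
  fields <- strsplit(readLines(out), "\t")[[1]]
  expect_length(fields, 5)  # id, dscore, chrom, pos, percentile
  expect_equal(fields[1], "rsA")
  expect_equal(fields[3], "chr1")
  write_query_result(query_by_id("rsA", tr, d, cat), out, header = TRUE)
  expect_match(readLines(out)[1], "^id\tdscore")
})
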