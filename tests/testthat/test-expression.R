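test_that("RPKM follows count * 1e9 / (length * N) on round numbers", {
  # depth summing to 500 over 1000 exonic bp -> count 10 at read length 50
  depth <- c(numeric(100), rep(0.5, 1000), numeric(100))
  tr <- coverage_track("chr1", "+", depth, library_size = 1e6)
  feat <- transcript_tbl("f1", "chr1", "+",
                         list(tibble::tibble(start = 100, end = 1100)))
  rec <- feature_rpkm(feat, tr)
  expect_equal(rec$read_count, 10)
  expect_equal(rec$rpkm, 10.0)
})

test_that("zero depth gives zero RPKM and strand mismatch errors", {
  tr <- coverage_track("chr1", "+", numeric(500), library_size = 1e6)
  feat <- transcript_tbl("f1", "chr1", "+",
                         list(tibble::tibble(start = 0, end = 100)))
  expect_equal(feature_rpkm(feat, tr)$rpkm, 0)
  feat$strand <- "-"
  feat$exons  # keep structure valid
  expect_error(feature_rpkm(feat, tr), "strand")
})

test_that("RPKM agrees with an independent spreadsheet-style recomputation", {
  withr::local_seed(314)
  span <- 20000
  depth <- stats::rpois(span, 3)
  N <- 250000
  tr <- coverage_track("chr9", "-", depth, library_size = N)
  feats <- purrr::map(1:30, function(i) {
    k <- sample(1:3, 1)
    s <- sort(sample(0:(span - 2000), k))
    len <- sample(50:300, k, replace = TRUE)
    s <- cumsum(c(s[1], diff(s) + len[-k]))
    tibble::tibble(start = s, end = pmin(s + len, span))
  })
  models <- transcript_tbl(sprintf("f%02d", 1:30), "chr9", "-", feats)
  rec <- feature_rpkm(models, tr)
  manual <- purrr::map_dbl(feats, function(e) {
    tot <- 0
    for (j in seq_len(nrow(e))) tot <- tot + sum(depth[(e$start[j] + 1):e$end[j]])
    (tot / 50) * 1e9 / (sum(e$end - e$start) * N)
  })
  expect_equal(rec$rpkm, manual, tolerance = 1e-9)
})

test_that("RPKM is linear in depth", {
  depth <- c(rep(2, 300), rep(5, 200))
  tr1 <- coverage_track("c", "+", depth, 1e5)
  tr2 <- coverage_track("c", "+", 2 * depth, 1e5)
  feat <- transcript_tbl("f", "c", "+",
                         list(tibble::tibble(start = 50, end = 450)))
  expect_equal(feature_rpkm(feat, tr2)$rpkm, 2 * feature_rpkm(feat, tr1)$rpkm)
})

test_that("percentiles follow the fraction-at-or-below rule with ties shared", {
  rec <- tibble::tibble(rpkm = c(1, 2, 3, 4))
  expect_equal(assign_percentiles(rec)$percentile, c(25, 50, 75, 100))
  rec <- tibble::tibble(rpkm = rep(7, 5))
  expect_equal(assign_percentiles(rec)$percentile, rep(100, 5))
  rec <- tibble::tibble(rpkm = c(0, 1, 0, 2))
  expect_equal(assign_percentiles(rec)$percentile, c(0, 50, 0, 100))
  expect_error(assign_percentiles(tibble::tibble(rpkm = numeric())), "empty")
  expect_error(assign_percentiles(tibble::tibble(rpkm = c(0, 0))),
               "rpkm > 0")
})

test_that("percentiles match the quadratic counting oracle and are monotone", {
  withr::local_seed(2024)
  rpkm <- c(stats::rexp(170, 1 / 5), numeric(10),
            rep(stats::rexp(4, 1 / 5), each = 5))
  rpkm <- sample(rpkm)  # 200 values with zeros and ties
  rec <- assign_percentiles(tibble::tibble(rpkm = rpkm))
  expect_equal(rec$percentile, oracle_percentiles(rpkm))
  expect_true(all(rec$percentile >= 0 & rec$percentile <= 100))
  o <- order(rpkm)
  expect_true(all(diff(rec$percentile[o]) >= 0))
})

test_that("fragment calling finds thresholded runs with bridged dips", {
  tr <- coverage_track("c", "+", rep(5, 500), 100)
  fr <- call_fragments(tr, min_depth = 2, min_len = 100, max_zero_run = 10)
  expect_equal(nrow(fr), 1)
  expect_equal(fr$start, 0)
  expect_equal(fr$end, 500)

  tr <- coverage_track("c", "+", rep(1, 500), 100)
  expect_equal(nrow(call_fragments(tr, min_depth = 2, min_len = 100,
                                   max_zero_run = 10)), 0)

  # an internal dip within max_zero_run is bridged; a longer one splits
  depth <- c(rep(5, 200), rep(0, 10), rep(5, 200))
  tr <- coverage_track("c", "-", depth, 100)
  expect_equal(nrow(call_fragments(tr, 2, 100, 10)), 1)
  expect_equal(nrow(call_fragments(tr, 2, 100, 9)), 2)
})

test_that("fragment calling matches a brute-force run scanner", {
  withr::local_seed(808)
  for (rep in 1:8) {
    depth <- stats::rpois(2000, 0.8) * stats::rbinom(2000, 1, 0.7)
    tr <- coverage_track("c", "+", depth, 100)
    got <- call_fragments(tr, min_depth = 1, min_len = 20, max_zero_run = 5)
    want <- oracle_fragments(depth, 1, 20, 5)
    expect_equal(nrow(got), nrow(want))
    expect_equal(got$start, want$start)
    expect_equal(got$end, want$end)
  }
})

make_calibration_fixture <- function() {
  pct <- list(
    g1 = c(10, 12, 14, 18, 30),
    g2 = c(50, 50, 51, 50, 80),
    g3 = c(20, 25, 30, 35, 21),
    g4 = c(70, 71, 73, 75, 76),
    g5 = c(40, 44, 48, 44, 90))
  models <- transcript_tbl(
    transcript_id = paste0(names(pct), ".t"),
    chrom = "chrF", strand = "+",
    exons = purrr::map(seq_along(pct), function(g) {
      s <- 100000 * g + 1000 * (0:4)
      tibble::tibble(start = s, end = s + 100)
    }),
    gene_id = names(pct))
  records <- purrr::map_dfr(seq_along(pct), function(g) {
    tibble::tibble(transcript_id = paste0(names(pct)[g], ".t"),
                   exon_index = 1:5, percentile = pct[[g]])
  })
  list(models = models, records = records)
}

test_that("calibration thresholds match a hand-worked 5-gene fixture", {
  fx <- make_calibration_fixture()
  cal <- calibrate_merge(fx$models, fx$records)
  # hand-derived: internal per-gene means {3,1,5,2,4};
  # outer pooled {2,12,0,30,5,14,1,1,4,46}
  expect_setequal(cal$internal_diffs, c(3, 1, 5, 2, 4))
  expect_setequal(cal$outer_diffs, c(2, 12, 0, 30, 5, 14, 1, 1, 4, 46))
  # type-7 quantiles of {1,2,3,4,5} at 0.90/0.95/0.99, worked by hand
  expect_equal(unname(cal$thresholds), c(4.6, 4.8, 4.96))
  expect_equal(unname(cal$outer_fraction_below), c(0.5, 0.5, 0.5))
  expect_true(all(diff(cal$thresholds) >= 0))
})

test_that("3-exon transcripts contribute outer pairs only", {
  fx <- make_calibration_fixture()
  extra <- transcript_tbl("g6.t", "chrF", "+",
                          list(tibble::tibble(start = c(0, 1000, 2000),
                                              end = c(100, 1100, 2100))),
                          gene_id = "g6")
  models <- dplyr::bind_rows(fx$models, extra)
  records <- dplyr::bind_rows(
    fx$records,
    tibble::tibble(transcript_id = "g6.t", exon_index = 1:3,
                   percentile = c(10, 17, 20)))
  cal <- calibrate_merge(models, records)
  expect_length(cal$internal_diffs, 5)          # g6 adds no internal pair
  expect_length(cal$outer_diffs, 12)            # but two outer pairs
  expect_true(all(c(7, 3) %in% cal$outer_diffs))
})

test_that("equal-percentile genes contribute zero internal difference", {
  models <- transcript_tbl("gf.t", "chrF", "-",
                           list(tibble::tibble(start = 1000 * (0:4),
                                               end = 1000 * (0:4) + 100)),
                           gene_id = "gf")
  records <- tibble::tibble(transcript_id = "gf.t", exon_index = 1:5,
                            percentile = rep(62, 5))
  cal <- calibrate_merge(models, records)
  expect_equal(cal$internal_diffs, 0)
})

test_that("calibration without any internal pair is an error", {
  models <- transcript_tbl("a.t", "chrF", "+",
                           list(tibble::tibble(start = c(0, 1000),
                                               end = c(100, 1100))),
                           gene_id = "a")
  records <- tibble::tibble(transcript_id = "a.t", exon_index = 1:2,
                            percentile = c(10, 20))
  expect_error(calibrate_merge(models, records), "internal")
})

test_that("calibration uses the longest isoform of multi-isoform genes", {
  fx <- make_calibration_fixture()
  short <- transcript_tbl("g1.s", "chrF", "+",
                          list(tibble::tibble(start = c(100000, 101000),
                                              end = c(100100, 101100))),
                          gene_id = "g1")
  models <- dplyr::bind_rows(fx$models, short)
  records <- dplyr::bind_rows(
    fx$records,
    tibble::tibble(transcript_id = "g1.s", exon_index = 1:2,
                   percentile = c(0, 99)))
  cal <- calibrate_merge(models, records)
  expect_setequal(cal$internal_diffs, c(3, 1, 5, 2, 4))  # unchanged
})

test_that("tidy and glance summarise a calibration", {
  fx <- make_calibration_fixture()
  cal <- calibrate_merge(fx$models, fx$records)
  td <- generics::tidy(cal)
  expect_setequal(unique(td$pair_type), c("internal", "outer"))
  gl <- generics::glance(cal)
  expect_equal(gl$n_internal, 5)
  expect_equal(gl$median_internal, 3)
  expect_equal(gl$chosen_d, 10)
  expect_equal(gl$max_gap, 11000)
})
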