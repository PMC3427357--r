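# Single-exon fragment chain helper: starts/ends/rpkm vectors -> transcript
# table with percentiles assigned over the whole set.
chain_tbl <- function(starts, ends, rpkm, strand = "+", chrom = "chrM",
                      prefix = "f") {
  tb <- transcript_tbl(sprintf("%s%02d", prefix, seq_along(starts)),
                       chrom, strand,
                       purrr::map2(starts, ends,
                                   ~ tibble::tibble(start = .x, end = .y)))
  tb$rpkm <- rpkm
  assign_percentiles(tb)
}

test_that("merging honours the gap and percentile-difference rule", {
  cal <- list(chosen_d = 5, max_gap = 11000)
  # gap 12000 > 11 kb: never merged even at equal percentiles
  fr <- chain_tbl(c(0, 13000), c(1000, 14000), c(5, 5))
  expect_equal(nrow(merge_fragments(fr, cal)), 2)
  # gap 500 and percentiles 40 vs 44 at chosen_d 5: merged into one
  # two-exon model
  fr <- chain_tbl(c(0, 1500), c(1000, 2500), c(40, 44))
  fr$percentile <- c(40, 44)
  m <- merge_fragments(fr, cal)
  expect_equal(nrow(m), 1)
  expect_equal(nrow(m$exons[[1]]), 2)
  expect_equal(m$start, 0)
  expect_equal(m$end, 2500)
  expect_setequal(m$provenance[[1]], c("f01", "f02"))
  # |dp| beyond d: left apart
  fr <- chain_tbl(c(0, 1500), c(1000, 2500), c(1, 100))
  expect_equal(nrow(merge_fragments(fr, cal)), 2)
})

test_that("merging never crosses strand or chromosome", {
  cal <- list(chosen_d = 100, max_gap = 1e6)
  a <- chain_tbl(0, 1000, 5, strand = "+")
  b <- chain_tbl(2000, 3000, 5, strand = "-", prefix = "g")
  both <- assign_percentiles(dplyr::bind_rows(a, b))
  expect_equal(nrow(merge_fragments(both, cal)), 2)
  c1 <- chain_tbl(0, 1000, 5, chrom = "chr1")
  c2 <- chain_tbl(2000, 3000, 5, chrom = "chr2", prefix = "g")
  both <- assign_percentiles(dplyr::bind_rows(c1, c2))
  expect_equal(nrow(merge_fragments(both, cal)), 2)
})

test_that("merged rpkm is the length-weighted combination, re-ranked", {
  cal <- list(chosen_d = 100, max_gap = 11000)
  fr <- chain_tbl(c(0, 3000, 50000), c(1000, 5000, 51000), c(30, 6, 90))
  m <- merge_fragments(fr, cal)
  expect_equal(nrow(m), 2)
  joined <- m[m$start == 0, ]
  expect_equal(joined$rpkm, (30 * 1000 + 6 * 2000) / 3000)
  # re-looked-up against the pre-merge map {6, 30, 90}: 14 sits above 6 only
  expect_equal(joined$percentile, 100 * 1 / 3)
})

test_that("missing percentiles are rejected", {
  fr <- transcript_tbl("x", "c", "+",
                       list(tibble::tibble(start = 0, end = 10)))
  fr$rpkm <- 1
  expect_error(merge_fragments(fr, list(chosen_d = 5, max_gap = 100)),
               "percentile")
})

test_that("exonic bases are conserved and model count is monotone in d", {
  withr::local_seed(61)
  sim <- simulate_dataset(uniform_cfg())
  fr <- fragments_with_percentiles(sim, "UN")
  exonic_bases <- function(models) {
    sum(purrr::map_dbl(models$exons, ~ sum(.x$end - .x$start)))
  }
  m5 <- merge_fragments(fr, list(chosen_d = 5, max_gap = 11000))
  m10 <- merge_fragments(fr, list(chosen_d = 10, max_gap = 11000))
  expect_equal(exonic_bases(m5), exonic_bases(fr))
  expect_equal(exonic_bases(m10), exonic_bases(fr))
  expect_true(nrow(fr) >= nrow(m5))
  expect_true(nrow(m5) >= nrow(m10))
})

test_that("fragments per gene counts same-strand exonic overlaps", {
  ann <- transcript_tbl(c("gA.t", "gB.t"), "c", "-",
                        list(tibble::tibble(start = 0, end = 2000),
                             tibble::tibble(start = 10000, end = 12000)),
                        gene_id = c("gA", "gB"))
  one <- transcript_tbl("m1", "c", "-",
                        list(tibble::tibble(start = 0, end = 2000)))
  fpg <- fragments_per_gene(one, ann)
  expect_equal(fpg$n_fragments[fpg$gene_id == "gA"], 1L)
  expect_equal(fpg$n_fragments[fpg$gene_id == "gB"], 0L)

  three <- chain_tbl(c(0, 600, 1400), c(500, 1200, 2000), c(5, 5, 5),
                     strand = "-", chrom = "c")
  expect_equal(
    fragments_per_gene(three, ann)$n_fragments[1], 3L)
  merged <- merge_fragments(three, list(chosen_d = 10, max_gap = 11000))
  expect_equal(fragments_per_gene(merged, ann)$n_fragments[1], 1L)
  # opposite strand never counts
  plus <- transcript_tbl("p1", "c", "+",
                         list(tibble::tibble(start = 0, end = 2000)))
  expect_equal(sum(fragments_per_gene(plus, ann)$n_fragments), 0L)
})

test_that("a deliberately bridged gene pair yields exactly one bad join", {
  ann <- transcript_tbl(c("gA.t", "gB.t"), "c", "+",
                        list(tibble::tibble(start = 0, end = 2000),
                             tibble::tibble(start = 7000, end = 9000)),
                        gene_id = c("gA", "gB"))
  fr <- chain_tbl(c(0, 7000), c(2000, 9000), c(12, 12), chrom = "c")
  merged <- merge_fragments(fr, list(chosen_d = 10, max_gap = 11000))
  expect_equal(nrow(merged), 1)
  expect_equal(count_bad_joins(merged, ann), 1L)
  # models confined to single genes are never bad joins
  expect_equal(count_bad_joins(fr, ann), 0L)
  # the same pair over a gap beyond the cap is not merged at all
  far <- chain_tbl(c(0, 13000), c(1000, 14000), c(12, 12), chrom = "c")
  expect_equal(count_bad_joins(
    merge_fragments(far, list(chosen_d = 10, max_gap = 11000)), ann), 0L)
})

test_that("bad joins are monotone non-decreasing in d and max_gap", {
  # gene pairs far enough apart that joins cannot chain across pairs (a
  # chain merge would turn two 2-gene models into one, lowering the
  # model-based count)
  ann <- transcript_tbl(sprintf("g%d.t", 1:4), "c", "+",
                        purrr::map(c(0, 9, 60, 69),
                                   ~ tibble::tibble(start = .x * 1000,
                                                    end = .x * 1000 + 2500)),
                        gene_id = sprintf("g%d", 1:4))
  fr <- chain_tbl(c(0, 9, 60, 69) * 1000, c(0, 9, 60, 69) * 1000 + 2500,
                  c(10, 30, 55, 80), chrom = "c")
  grid_d <- c(0, 10, 30, 60, 100)
  bj_d <- purrr::map_int(grid_d, function(d) {
    count_bad_joins(merge_fragments(fr, list(chosen_d = d, max_gap = 8000)),
                    ann)
  })
  expect_equal(bj_d, c(0L, 0L, 2L, 2L, 2L))
  expect_true(all(diff(bj_d) >= 0))
  grid_g <- c(1000, 5000, 7000, 20000)
  bj_g <- purrr::map_int(grid_g, function(g) {
    count_bad_joins(merge_fragments(fr, list(chosen_d = 30, max_gap = g)),
                    ann)
  })
  expect_true(all(diff(bj_g) >= 0))
})

test_that("left-to-right fixpoint merging matches the all-orders oracle on
           uniform-expression chains", {
  withr::local_seed(1234)
  for (rep in 1:12) {
    # two fragmentized transcripts with within-transcript-constant rpkm,
    # separated by more than the merge gap; some chains carry one outlier
    # fragment whose distinct percentile blocks its joins in every order
    n1 <- sample(3:5, 1)
    n2 <- sample(2:4, 1)
    gaps <- c(sample(500:5000, n1 - 1, replace = TRUE), 20000,
              sample(500:5000, n2 - 1, replace = TRUE))
    lens <- sample(300:2000, n1 + n2, replace = TRUE)
    starts <- cumsum(c(1e5, gaps + lens[-(n1 + n2)]))
    bases <- stats::runif(2, 5, 50)
    rpkm <- rep(bases, c(n1, n2))
    if (rep %% 3 == 0) rpkm[sample(n1, 1)] <- bases[1] * 10
    fr <- chain_tbl(starts, starts + lens, rpkm)
    got <- merge_fragments(fr, list(chosen_d = 10, max_gap = 11000))
    lookup <- enhansr:::percentile_lookup(fr$rpkm)
    rows <- data.frame(start = fr$start, end = fr$end,
                       len = fr$end - fr$start, rpkm = fr$rpkm,
                       pct = fr$percentile)
    rows$prov <- lapply(fr$transcript_id, identity)
    finals <- oracle_merge_all_orders(rows, 10, 11000, lookup)
    expect_length(finals, 1)
    got_sig <- paste(sort(purrr::map_chr(
      got$provenance, ~ paste(sort(.x), collapse = "+"))), collapse = " | ")
    expect_equal(got_sig, finals)
  }
})
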