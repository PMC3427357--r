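ann_one_gene <- function(strand = "-") {
  transcript_tbl("gX.t", "chrS", strand,
                 list(tibble::tibble(start = c(10000, 14000, 18000),
                                     end = c(11000, 15000, 19000))),
                 gene_id = "gX")
}

test_that("novelty is same-strand exonic overlap below the cutoff", {
  ann <- ann_one_gene("-")
  # zero same-strand overlap (antisense configuration): novel
  m <- transcript_tbl("m1", "chrS", "+",
                      list(tibble::tibble(start = 14200, end = 14800)))
  expect_equal(classify_novelty(m, ann)$novelty, "novel")
  # identical to a known transcript: known
  known <- ann
  known$transcript_id <- "m2"
  expect_equal(classify_novelty(known, ann)$novelty, "known")
})

test_that("the novelty cutoff is a strict 10% boundary", {
  ann <- ann_one_gene("+")
  # 1000-bp model overlapping a known exon by 90 vs 110 bp
  m90 <- transcript_tbl("a", "chrS", "+",
                        list(tibble::tibble(start = 10910, end = 11910)))
  m110 <- transcript_tbl("b", "chrS", "+",
                         list(tibble::tibble(start = 10890, end = 11890)))
  expect_equal(classify_novelty(m90, ann)$novelty, "novel")
  expect_equal(classify_novelty(m110, ann)$novelty, "known")
  expect_equal(classify_novelty(m90, ann)$overlap_fraction, 0.09)
  expect_equal(classify_novelty(m110, ann)$overlap_fraction, 0.11)
})

test_that("antisense partner is the opposite-strand gene of maximal overlap", {
  ann <- dplyr::bind_rows(
    transcript_tbl("gA.t", "chrS", "-",
                   list(tibble::tibble(start = 1000, end = 2000)),
                   gene_id = "gA"),
    transcript_tbl("gB.t", "chrS", "-",
                   list(tibble::tibble(start = 2100, end = 4000)),
                   gene_id = "gB"))
  inside <- transcript_tbl("m", "chrS", "+",
                           list(tibble::tibble(start = 1200, end = 1600)))
  expect_equal(find_antisense_partner(inside, ann)$antisense_gene, "gA")
  desert <- transcript_tbl("m", "chrS", "+",
                           list(tibble::tibble(start = 100000, end = 101000)))
  expect_true(is.na(find_antisense_partner(desert, ann)$antisense_gene))
  # overlapping gA by 300 bp and gB by 900 bp -> gB
  both <- transcript_tbl("m", "chrS", "+",
                         list(tibble::tibble(start = 1700, end = 3000)))
  res <- find_antisense_partner(both, ann)
  expect_equal(res$antisense_gene, "gB")
  expect_equal(res$antisense_overlap_bp, 900)
  # same-strand genes are never partners
  same <- transcript_tbl("m", "chrS", "-",
                         list(tibble::tibble(start = 1200, end = 1600)))
  expect_true(is.na(find_antisense_partner(same, ann)$antisense_gene))
})

test_that("enhancer association covers the span and a strand-aware
           upstream window, with exclusive boundaries", {
  m_plus <- transcript_tbl("mp", "chrS", "+",
                           list(tibble::tibble(start = 10000, end = 13000)))
  peaks <- tibble::tibble(chrom = "chrS",
                          start = c(10100, 8500, 7800, 20000),
                          end = c(10400, 8700, 8000, 20200),
                          mark = "P300",
                          condition = "UN")
  got <- associate_enhancer(m_plus, peaks, upstream_window = 2000)
  expect_equal(nrow(got), 2)
  expect_setequal(got$where, c("within", "upstream"))
  expect_setequal(got$peak_start, c(10100, 8500))
  # peak ending exactly at the window edge (1 bp past it) is excluded:
  # upstream interval is [8000, 10000), peak [7800, 8000) misses it
  expect_false(7800 %in% got$peak_start)

  # mirrored geometry: minus-strand model must look above its end
  m_minus <- transcript_tbl("mm", "chrS", "-",
                            list(tibble::tibble(start = 10000, end = 13000)))
  peaks_m <- tibble::tibble(chrom = "chrS",
                            start = c(14300, 8500), end = c(14500, 8700),
                            mark = "P300", condition = "UN")
  got_m <- associate_enhancer(m_minus, peaks_m, upstream_window = 2000)
  expect_equal(got_m$peak_start, 14300)
  expect_equal(got_m$where, "upstream")
})

test_that("the screen requires novelty, an associated peak, and a shared
           expression/enhancer condition", {
  ann <- ann_one_gene("-")
  model <- transcript_tbl("cand", "chrS", "+",
                          list(tibble::tibble(start = 13500, end = 14500)))
  peaks <- tibble::tibble(chrom = "chrS", start = 13400, end = 13700,
                          mark = "P300", condition = "UN")
  expr <- tibble::tibble(transcript_id = "cand",
                         condition = c("UN", "NP"), rpkm = c(25, 0))
  got <- screen_candidates(model, ann, peaks, expr)
  expect_equal(nrow(got), 1)
  expect_equal(got$nearest_gene, "gX")
  expect_equal(got$relationship, "antisense-overlap")
  expect_equal(got$expression[[1]], "UN")
  expect_equal(got$enhancer[[1]], "UN")
  expect_match(got$description, "antisense to gX")

  # criterion 3: no peak, no record
  no_peaks <- peaks[0, ]
  expect_equal(nrow(screen_candidates(model, ann, no_peaks, expr)), 0)

  # criterion 2: peak active only where the model is not expressed
  peaks_np <- dplyr::mutate(peaks, condition = "NP")
  expect_equal(nrow(screen_candidates(model, ann, peaks_np, expr)), 0)

  # criterion 1: a known model is never reported
  known <- ann_one_gene("-")
  known$transcript_id <- "kn"
  expr_kn <- tibble::tibble(transcript_id = "kn", condition = "UN", rpkm = 25)
  peaks_kn <- tibble::tibble(chrom = "chrS", start = 10100, end = 10300,
                             mark = "P300", condition = "UN")
  expect_equal(nrow(screen_candidates(known, ann, peaks_kn, expr_kn)), 0)
})

test_that("screen output expression and enhancer sets always intersect", {
  withr::local_seed(17)
  sim <- simulate_dataset(small_cfg(noise_model = "none"))
  res <- run_pipeline(sim, out_dir = NULL,
                      config = pipeline_config(n_perm = 199))
  expect_gt(nrow(res$candidates), 0)
  for (i in seq_len(nrow(res$candidates))) {
    expect_gt(length(intersect(res$candidates$expression[[i]],
                               res$candidates$enhancer[[i]])), 0)
  }
  # candidates are a subset of novel models
  nov <- classify_novelty(res$models, sim$annotation)
  nov_ids <- nov$transcript_id[nov$novelty == "novel"]
  expect_true(all(res$candidates$transcript_id %in% nov_ids))
})

test_that("the recovered locus set is invariant under a coordinate mirror", {
  withr::local_seed(29)
  sim <- simulate_dataset(small_cfg(noise_model = "none"))
  cfg <- pipeline_config(n_perm = 199)
  res <- run_pipeline(sim, out_dir = NULL, config = cfg)
  msim <- mirror_sim(sim)
  mres <- run_pipeline(msim, out_dir = NULL, config = cfg)
  expect_equal(nrow(mres$candidates), nrow(res$candidates))
  L <- sim$chrom_len
  orig <- res$candidates[order(res$candidates$start), ]
  mirr <- mres$candidates[order(-mres$candidates$end), ]
  expect_equal(L - mirr$end, orig$start)
  expect_equal(L - mirr$start, orig$end)
  expect_equal(flip_strand(mirr$strand), orig$strand)
  ev <- evaluate_screen(res$candidates, sim$truth)
  mev <- evaluate_screen(mres$candidates, msim$truth)
  expect_equal(mev$precision, ev$precision)
  expect_equal(mev$recall, ev$recall)
})
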