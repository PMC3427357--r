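#' RPKM of features from a coverage track
#'
#' Recovers an approximate read count from per-base coverage as
#' `sum(depth over exonic bases) / read_length` and normalises it to RPKM:
#' `count * 1e9 / (exonic_length * library_size)`. If `features` carries a
#' `read_count` column the supplied counts are used directly instead of the
#' coverage-derived ones.
#'
#' @param features Transcript table; all records must match the track strand
#'   (records with strand `"."` are accepted).
#' @param track A [coverage_track()].
#' @param read_length Read-length equivalent used to turn summed depth into a
#'   count (default 50 nt, matching 50 bp single-end reads).
#' @return A tibble with one row per feature: `feature_id`, `read_count`,
#'   `length` (exonic bp), `rpkm`.
#' @export
feature_rpkm <- function(features, track, read_length = 50) {
  bad <- features$strand != track$strand & features$strand != "."
  if (any(bad)) {
    abort_validation("feature '%s' strand does not match track strand (%s)",
                     features$transcript_id[which(bad)[1]], track$strand)
  }
  len <- exonic_length(features)
  depth_sum <- purrr::map_dbl(features$exons, function(e) {
    sum(purrr::map_dbl(seq_len(nrow(e)),
                       ~ sum(track_depth(track, e$start[.x], e$end[.x]))))
  })
  count <- if ("read_count" %in% names(features)) {
    features$read_count
  } else {
    depth_sum / read_length
  }
  tibble::tibble(
    feature_id = features$transcript_id,
    read_count = count,
    length = len,
    rpkm = count * 1e9 / (len * track$library_size)
  )
}

#' Assign transcriptome-wide RPKM percentiles
#'
#' The percentile of a feature is `100 * (# expressed features with
#' rpkm <= this rpkm) / (# expressed features)` — the empirical "fraction at
#' or below" CDF over expressed features only. Features with `rpkm = 0` get
#' percentile 0 and do not enter the denominator; ties share one value.
#'
#' @param records Tibble with an `rpkm` column (e.g. from [feature_rpkm()]).
#' @return `records` with a `percentile` column in `[0, 100]` added
#'   (replaced if present).
#' @export
assign_percentiles <- function(records) {
  if (nrow(records) == 0) abort_validation("assign_percentiles: empty input")
  expressed <- records$rpkm[records$rpkm > 0]
  if (length(expressed) == 0) {
    abort_validation("assign_percentiles: no record with rpkm > 0")
  }
  records$percentile <- percentile_lookup(expressed)(records$rpkm)
  records
}

# Closure mapping rpkm -> percentile against a fixed reference distribution.
# Shared by assign_percentiles() and the merge scan (which re-looks-up merged
# fragments against the unchanged pre-merge map).
percentile_lookup <- function(reference_rpkm) {
  ex <- sort(reference_rpkm[reference_rpkm > 0])
  n <- length(ex)
  function(r) {
    out <- 100 * findInterval(r, ex) / n
    out[r <= 0] <- 0
    out
  }
}

#' Call transcript fragments from a coverage track
#'
#' A naive coverage-threshold caller standing in for an external assembler:
#' fragments are maximal runs of bases with `depth >= min_depth`, where
#' internal sub-threshold runs of at most `max_zero_run` bases are bridged;
#' runs shorter than `min_len` are discarded. Fragments inherit the track's
#' strand and are returned as single-exon transcript models.
#'
#' @param track A [coverage_track()].
#' @param min_depth Minimum per-base depth to call a base covered.
#' @param min_len Minimum fragment length in bp.
#' @param max_zero_run Longest internal sub-threshold run to bridge, in bp.
#' @param id_prefix Prefix for generated fragment ids.
#' @return A transcript table of fragments (possibly 0 rows).
#' @export
call_fragments <- function(track, min_depth = 2, min_len = 200,
                           max_zero_run = 50, id_prefix = NULL) {
  if (min_depth <= 0 || min_len <= 0 || max_zero_run < 0) {
    abort_validation("call_fragments thresholds must be positive")
  }
  ok <- track$depth >= min_depth
  r <- rle(ok)
  n <- length(r$lengths)
  if (n >= 3) {
    internal <- seq_len(n) > 1 & seq_len(n) < n
    bridge <- !r$values & internal & r$lengths <= max_zero_run
    r$values[bridge] <- TRUE
  }
  r2 <- rle(inverse.rle(r))
  ends <- cumsum(r2$lengths)
  starts <- ends - r2$lengths
  keep <- r2$values & r2$lengths >= min_len
  if (!any(keep)) {
    return(transcript_tbl(character(), character(), character(), list()))
  }
  starts <- track$offset + starts[keep]
  ends <- track$offset + ends[keep]
  if (is.null(id_prefix)) {
    id_prefix <- paste0("frag", if (!is.na(track$condition)) {
      paste0("_", track$condition)
    } else "", if (track$strand == "+") "_p" else "_m")
  }
  ids <- sprintf("%s_%03d", id_prefix, seq_along(starts))
  transcript_tbl(
    transcript_id = ids,
    chrom = track$chrom,
    strand = track$strand,
    exons = purrr::map2(starts, ends, ~ tibble::tibble(start = .x, end = .y))
  )
}

#' Calibrate fragment-merge thresholds from annotated adjacent exons
#'
#' Within genuinely single transcripts, the RPKM percentiles of adjacent
#' exons should be close; the spread of their differences sets how large a
#' percentile gap a merge rule may bridge. For each gene (longest isoform),
#' internal pairs are consecutive exon pairs in which both exons are
#' non-terminal; the gene contributes the mean absolute percentile difference
#' of its internal pairs to `internal_diffs`. Outer pairs — (first, second)
#' and (last-1, last) — are pooled unaveraged into `outer_diffs`. Thresholds
#' are the empirical 90/95/99th percentiles of `internal_diffs`, and
#' `outer_fraction_below` reports the fraction of outer pairs at or below
#' each threshold.
#'
#' @param annotation Transcript table with `gene_id` set; genes need >= 4
#'   exons to contribute internal pairs and >= 2 for outer pairs.
#' @param exon_records Exon-level expression with percentiles: columns
#'   `transcript_id`, `exon_index`, `percentile` (see [exon_expression()]).
#' @param chosen_d Percentile-difference cap used by [merge_fragments()]
#'   (default 10; 5 is the conservative preset).
#' @param max_gap Largest bridged gap ("intron length") in bp, default 11000.
#' @return An object of class `merge_calibration` with fields
#'   `internal_diffs`, `outer_diffs`, `thresholds` (q90/q95/q99),
#'   `outer_fraction_below`, `chosen_d`, `max_gap`.
#' @export
calibrate_merge <- function(annotation, exon_records, chosen_d = 10,
                            max_gap = 11000) {
  if (chosen_d < 0 || chosen_d > 100) {
    abort_validation("chosen_d must lie in [0, 100]")
  }
  if (max_gap <= 0) abort_validation("max_gap must be positive")
  longest <- annotation %>%
    dplyr::mutate(.len = exonic_length(annotation)) %>%
    dplyr::group_by(.data$gene_id) %>%
    dplyr::slice_max(.data$.len, n = 1, with_ties = FALSE) %>%
    dplyr::ungroup()
  ex <- exon_tbl(longest) %>%
    dplyr::inner_join(
      exon_records[, c("transcript_id", "exon_index", "percentile")],
      by = c("transcript_id", "exon_index"))
  per_gene <- ex %>%
    dplyr::arrange(.data$transcript_id, .data$exon_index) %>%
    dplyr::group_by(.data$gene_id, .data$transcript_id) %>%
    dplyr::summarise(
      n_exons = dplyr::n(),
      diffs = list(abs(diff(.data$percentile))),
      .groups = "drop")
  internal_diffs <- per_gene %>%
    dplyr::filter(.data$n_exons >= 4) %>%
    dplyr::mutate(mean_internal = purrr::map2_dbl(
      .data$diffs, .data$n_exons, ~ mean(.x[2:(.y - 2)]))) %>%
    dplyr::pull(.data$mean_internal)
  outer_diffs <- per_gene %>%
    dplyr::filter(.data$n_exons >= 2) %>%
    dplyr::mutate(outer = purrr::map(.data$diffs,
                                     ~ .x[unique(c(1, length(.x)))])) %>%
    dplyr::pull(.data$outer) %>%
    unlist()
  if (length(internal_diffs) == 0) {
    abort_validation(
      "no gene contributes an internal exon pair; calibration needs genes with >= 4 exons")
  }
  thresholds <- stats::quantile(internal_diffs, c(0.9, 0.95, 0.99),
                                names = FALSE)
  structure(
    list(
      internal_diffs = internal_diffs,
      outer_diffs = outer_diffs,
      thresholds = stats::setNames(thresholds, c("q90", "q95", "q99")),
      outer_fraction_below = stats::setNames(
        vapply(thresholds, function(t) mean(outer_diffs <= t), numeric(1)),
        c("q90", "q95", "q99")),
      chosen_d = chosen_d,
      max_gap = max_gap
    ),
    class = "merge_calibration"
  )
}

#' Exon-level expression records for annotated transcripts
#'
#' Convenience wrapper computing [feature_rpkm()] for every exon of every
#' model on a track (features whose strand does not match are skipped), then
#' assigning percentiles across all exons with [assign_percentiles()].
#'
#' @inheritParams feature_rpkm
#' @return Tibble with `transcript_id`, `exon_index`, `read_count`, `length`,
#'   `rpkm`, `percentile`.
#' @export
exon_expression <- function(features, track, read_length = 50) {
  features <- features[features$strand %in% c(track$strand, "."), ]
  ex <- exon_tbl(features)
  if (nrow(ex) == 0) abort_validation("no features on track strand")
  as_models <- transcript_tbl(
    transcript_id = sprintf("%s|%d", ex$transcript_id, ex$exon_index),
    chrom = ex$chrom, strand = ex$strand,
    exons = purrr::map2(ex$start, ex$end,
                        ~ tibble::tibble(start = .x, end = .y)))
  rec <- feature_rpkm(as_models, track, read_length)
  rec <- assign_percentiles(rec)
  tibble::tibble(
    transcript_id = ex$transcript_id,
    exon_index = ex$exon_index,
    read_count = rec$read_count,
    length = rec$length,
    rpkm = rec$rpkm,
    percentile = rec$percentile
  )
}

#' @export
print.merge_calibration <- function(x, ...) {
  cat("<merge_calibration>\n")
  cat(sprintf("  genes with internal pairs: %d; outer pairs: %d\n",
              length(x$internal_diffs), length(x$outer_diffs)))
  cat(sprintf("  |dp| thresholds: q90=%.2f q95=%.2f q99=%.2f\n",
              x$thresholds[["q90"]], x$thresholds[["q95"]],
              x$thresholds[["q99"]]))
  cat(sprintf("  outer fraction below: %.3f %.3f %.3f\n",
              x$outer_fraction_below[["q90"]],
              x$outer_fraction_below[["q95"]],
              x$outer_fraction_below[["q99"]]))
  cat(sprintf("  chosen_d=%g max_gap=%g\n", x$chosen_d, x$max_gap))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a merge calibration into its paired-difference observations
#'
#' @param x A `merge_calibration`.
#' @param ... Unused.
#' @return Tibble with `pair_type` (`"internal"`/`"outer"`) and
#'   `abs_percentile_diff`.
#' @export
tidy.merge_calibration <- function(x, ...) {
  dplyr::bind_rows(
    tibble::tibble(pair_type = "internal",
                   abs_percentile_diff = x$internal_diffs),
    tibble::tibble(pair_type = "outer",
                   abs_percentile_diff = x$outer_diffs)
  )
}

#' One-row summary of a merge calibration
#'
#' @inheritParams tidy.merge_calibration
#' @return One-row tibble with counts, thresholds, outer fractions and the
#'   chosen merge parameters.
#' @export
glance.merge_calibration <- function(x, ...) {
  tibble::tibble(
    n_internal = length(x$internal_diffs),
    n_outer = length(x$outer_diffs),
    median_internal = stats::median(x$internal_diffs),
    median_outer = stats::median(x$outer_diffs),
    q90 = x$thresholds[["q90"]],
    q95 = x$thresholds[["q95"]],
    q99 = x$thresholds[["q99"]],
    outer_frac_q90 = x$outer_fraction_below[["q90"]],
    outer_frac_q95 = x$outer_fraction_below[["q95"]],
    outer_frac_q99 = x$outer_fraction_below[["q99"]],
    chosen_d = x$chosen_d,
    max_gap = x$max_gap
  )
}
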