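#' Merge fragmented transcript calls under the percentile-difference/gap rule
#'
#' Two adjacent fragments on the same chromosome and strand are joined iff
#' their gap (`next.start - prev.end`) is at most `max_gap` AND the absolute
#' difference of their RPKM percentiles is at most `chosen_d`. Joining
#' concatenates the exon lists (the gap becomes an intron), unions the
#' provenance, and recomputes the joined fragment's RPKM as the
#' length-weighted combination of the two parts; its percentile is then
#' re-looked-up against the *unchanged* pre-merge percentile map. The scan is
#' left-to-right per chromosome/strand and repeats until no join fires.
#'
#' @param fragments Transcript table carrying `rpkm` and `percentile` columns
#'   (e.g. [call_fragments()] output joined with [feature_rpkm()] +
#'   [assign_percentiles()]).
#' @param calibration A [calibrate_merge()] object, or any list with
#'   `chosen_d` and `max_gap` elements.
#' @return A transcript table of merged models with updated `rpkm`,
#'   `percentile` and `provenance`.
#' @export
merge_fragments <- function(fragments, calibration) {
  if (!all(c("rpkm", "percentile") %in% names(fragments)) ||
      anyNA(fragments$percentile)) {
    abort_validation("fragments must carry non-missing rpkm and percentile")
  }
  d <- calibration$chosen_d
  gap_max <- calibration$max_gap
  if (is.null(d) || is.null(gap_max)) {
    abort_validation("calibration must provide chosen_d and max_gap")
  }
  if (nrow(fragments) == 0) return(fragments)
  lookup <- percentile_lookup(fragments$rpkm)

  merged <- fragments %>%
    dplyr::arrange(.data$chrom, .data$strand, .data$start) %>%
    dplyr::group_by(.data$chrom, .data$strand) %>%
    dplyr::group_map(~ merge_chain(dplyr::bind_cols(
      .x, tibble::tibble(chrom = .y$chrom, strand = .y$strand)),
      d, gap_max, lookup)) %>%
    dplyr::bind_rows()
  merged <- merged[, names(fragments)] %>%
    dplyr::arrange(.data$chrom, .data$start, .data$strand)
  validate_transcripts(merged)
  merged
}

# Left-to-right fixpoint scan over one chromosome/strand chain (rows sorted
# by start). Percentiles of merged rows come from `lookup` (pre-merge map).
merge_chain <- function(rows, d, gap_max, lookup) {
  repeat {
    changed <- FALSE
    i <- 1
    while (i < nrow(rows)) {
      gap <- rows$start[i + 1] - rows$end[i]
      dp <- abs(rows$percentile[i] - rows$percentile[i + 1])
      if (gap <= gap_max && dp <= d) {
        rows <- join_rows(rows, i, lookup)
        changed <- TRUE
        i <- max(i - 1, 1)   # the new row may now pair with its left neighbour
      } else {
        i <- i + 1
      }
    }
    if (!changed) break
  }
  rows
}

join_rows <- function(rows, i, lookup) {
  a <- rows[i, ]
  b <- rows[i + 1, ]
  ex <- dplyr::bind_rows(a$exons[[1]], b$exons[[1]]) %>%
    dplyr::arrange(.data$start)
  # Union any overlapping/adjacent book-keeping overlaps; introns are kept.
  ir <- IRanges::reduce(IRanges::IRanges(start = ex$start + 1, end = ex$end))
  ex <- tibble::tibble(start = BiocGenerics::start(ir) - 1,
                       end = BiocGenerics::end(ir))
  la <- sum(a$exons[[1]]$end - a$exons[[1]]$start)
  lb <- sum(b$exons[[1]]$end - b$exons[[1]]$start)
  new <- a
  new$exons[[1]] <- ex
  new$start <- min(a$start, b$start)
  new$end <- max(a$end, b$end)
  new$rpkm <- (a$rpkm * la + b$rpkm * lb) / (la + lb)
  new$percentile <- lookup(new$rpkm)
  new$provenance[[1]] <- c(a$provenance[[1]], b$provenance[[1]])
  if ("read_count" %in% names(rows)) new$read_count <- a$read_count + b$read_count
  dplyr::bind_rows(
    if (i > 1) rows[seq_len(i - 1), ],
    new,
    if (i + 1 < nrow(rows)) rows[seq.int(i + 2, nrow(rows)), ]
  )
}

#' Count transcript models per annotated gene
#'
#' A model is assigned to every annotated gene it overlaps on the same strand
#' by at least one exonic base. Genes with no overlapping model get 0.
#'
#' @param models Transcript table (fragments or merged models).
#' @param annotation Transcript table with `gene_id`.
#' @return Tibble with `gene_id` and `n_fragments`, one row per annotated
#'   gene.
#' @export
fragments_per_gene <- function(models, annotation) {
  genes <- unique(annotation$gene_id)
  pairs <- model_gene_exonic_pairs(models, annotation)
  counts <- pairs %>%
    dplyr::distinct(.data$gene_id, .data$transcript_id) %>%
    dplyr::count(.data$gene_id, name = "n_fragments")
  tibble::tibble(gene_id = genes) %>%
    dplyr::left_join(counts, by = "gene_id") %>%
    dplyr::mutate(n_fragments = dplyr::coalesce(.data$n_fragments, 0L))
}

# Distinct (model, gene) pairs with same-strand exonic overlap >= 1 bp.
model_gene_exonic_pairs <- function(models, annotation) {
  empty <- tibble::tibble(transcript_id = character(), gene_id = character())
  if (nrow(models) == 0 || nrow(annotation) == 0) return(empty)
  mg <- models_to_gr(models, "exon")
  ag <- models_to_gr(annotation, "exon")
  hits <- GenomicRanges::findOverlaps(mg, ag, ignore.strand = FALSE)
  if (length(hits) == 0) return(empty)
  tibble::tibble(
    transcript_id = mg$transcript_id[S4Vectors::queryHits(hits)],
    gene_id = ag$gene_id[S4Vectors::subjectHits(hits)]
  ) %>% dplyr::distinct()
}

#' Count bad joins against an annotation
#'
#' A bad join is a (merged) model whose exons overlap, on the same strand,
#' exonic bases of two or more distinct annotated genes — i.e. separate genes
#' fused into a single transcript model.
#'
#' @inheritParams fragments_per_gene
#' @return Integer count of models spanning >= 2 genes.
#' @export
count_bad_joins <- function(models, annotation) {
  pairs <- model_gene_exonic_pairs(models, annotation)
  if (nrow(pairs) == 0) return(0L)
  sum(table(pairs$transcript_id) >= 2)
}
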