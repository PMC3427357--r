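#' Classify models as novel or known against an annotation
#'
#' A model is novel iff its same-strand exonic overlap with any known
#' transcript is below `max_overlap` of the model's own exonic length.
#' Opposite-strand overlap (the antisense configuration) does not count
#' against novelty.
#'
#' @param models Transcript table to classify.
#' @param annotation Known transcript table.
#' @param max_overlap Largest same-strand exonic overlap fraction still
#'   considered novel (default 0.1).
#' @return `models` with `overlap_fraction` and `novelty`
#'   (`"novel"`/`"known"`) columns added.
#' @export
classify_novelty <- function(models, annotation, max_overlap = 0.1) {
  ov <- same_strand_exonic_overlap(models, annotation)
  models$overlap_fraction <- ov / exonic_length(models)
  models$novelty <- ifelse(models$overlap_fraction < max_overlap,
                           "novel", "known")
  models
}

#' Find the antisense sense-gene partner of each model
#'
#' Returns, per model, the opposite-strand annotated gene with maximal
#' genomic (span) overlap of at least 1 bp, or `NA` when no opposite-strand
#' gene overlaps.
#'
#' @inheritParams classify_novelty
#' @return `models` with `antisense_gene` and `antisense_overlap_bp` columns
#'   added.
#' @export
find_antisense_partner <- function(models, annotation) {
  models$antisense_gene <- NA_character_
  models$antisense_overlap_bp <- 0
  if (nrow(models) == 0 || nrow(annotation) == 0) return(models)
  flipped <- models
  flipped$strand <- ifelse(models$strand == "+", "-",
                           ifelse(models$strand == "-", "+", "."))
  mg <- models_to_gr(flipped, "span")
  ag <- models_to_gr(annotation, "span")
  hits <- GenomicRanges::findOverlaps(mg, ag, ignore.strand = FALSE)
  if (length(hits) == 0) return(models)
  ov <- GenomicRanges::pintersect(mg[S4Vectors::queryHits(hits)],
                                  ag[S4Vectors::subjectHits(hits)])
  best <- tibble::tibble(
    row = S4Vectors::queryHits(hits),
    gene_id = ag$gene_id[S4Vectors::subjectHits(hits)],
    width = BiocGenerics::width(ov)
  ) %>%
    dplyr::group_by(.data$row, .data$gene_id) %>%
    dplyr::summarise(width = sum(.data$width), .groups = "drop") %>%
    dplyr::group_by(.data$row) %>%
    dplyr::arrange(dplyr::desc(.data$width), .data$gene_id) %>%
    dplyr::slice(1) %>%
    dplyr::ungroup()
  models$antisense_gene[best$row] <- best$gene_id
  models$antisense_overlap_bp[best$row] <- best$width
  models
}

#' Associate enhancer peaks with models
#'
#' A peak is associated with a model when it overlaps the model span, or lies
#' within `upstream_window` bp 5' of the model's transcription start
#' (strand-aware: below the start for a plus-strand model, above the end for
#' a minus-strand model). Peaks are strandless.
#'
#' @param models Transcript table.
#' @param peaks Tibble of enhancer peaks with columns `chrom`, `start`,
#'   `end`, `condition` and optionally `mark`.
#' @param upstream_window Size of the 5' upstream window in bp (default
#'   2000).
#' @return Tibble with one row per (model, associated peak): `transcript_id`,
#'   peak coordinates, `mark`, `condition`, and `where`
#'   (`"within"`/`"upstream"`).
#' @export
associate_enhancer <- function(models, peaks, upstream_window = 2000) {
  if (upstream_window < 0) {
    abort_validation("upstream_window must be >= 0")
  }
  empty <- tibble::tibble(transcript_id = character(), chrom = character(),
                          peak_start = numeric(), peak_end = numeric(),
                          mark = character(), condition = character(),
                          where = character())
  if (nrow(models) == 0 || nrow(peaks) == 0) return(empty)
  if (!"mark" %in% names(peaks)) peaks$mark <- NA_character_
  purrr::map_dfr(seq_len(nrow(models)), function(i) {
    m <- models[i, ]
    if (m$strand == "+") {
      up_start <- m$start - upstream_window
      up_end <- m$start
    } else {
      up_start <- m$end
      up_end <- m$end + upstream_window
    }
    hit_within <- peaks$chrom == m$chrom &
      peaks$end > m$start & peaks$start < m$end
    hit_up <- peaks$chrom == m$chrom &
      peaks$end > up_start & peaks$start < up_end
    sel <- which(hit_within | hit_up)
    if (length(sel) == 0) return(empty)
    tibble::tibble(
      transcript_id = m$transcript_id,
      chrom = peaks$chrom[sel],
      peak_start = peaks$start[sel],
      peak_end = peaks$end[sel],
      mark = peaks$mark[sel],
      condition = peaks$condition[sel],
      where = ifelse(hit_within[sel], "within", "upstream")
    )
  })
}

#' Screen merged models for novel enhancer-associated antisense RNAs
#'
#' Applies the three screening criteria and emits one candidate record per
#' passing model:
#' 1. the model is novel (same-strand exonic overlap with known transcripts
#'    below `novelty_max_overlap`);
#' 2. there is a condition in which the model is expressed
#'    (`rpkm >= expression_threshold`) AND an associated peak is active;
#' 3. an enhancer peak overlaps the model or lies just upstream of its 5'
#'    end.
#'
#' @param models Transcript table of (merged) models to screen.
#' @param annotation Known transcript table.
#' @param peaks Enhancer peak tibble (see [associate_enhancer()]).
#' @param expression Tibble with per-condition expression of the models:
#'   columns `transcript_id`, `condition`, `rpkm`.
#' @param expression_threshold Minimum RPKM to call a model expressed in a
#'   condition (default 1).
#' @param novelty_max_overlap Passed to [classify_novelty()].
#' @param upstream_window Passed to [associate_enhancer()].
#' @return A candidate tibble with columns `transcript_id`, `chrom`, `start`,
#'   `end`, `strand`, `nearest_gene`, `relationship`, `description`,
#'   `expression` (list of conditions expressed), `enhancer` (list of
#'   conditions with an associated active peak).
#' @export
screen_candidates <- function(models, annotation, peaks, expression,
                              expression_threshold = 1,
                              novelty_max_overlap = 0.1,
                              upstream_window = 2000) {
  empty <- tibble::tibble(
    transcript_id = character(), chrom = character(), start = numeric(),
    end = numeric(), strand = character(), nearest_gene = character(),
    relationship = character(), description = character(),
    expression = list(), enhancer = list())
  if (nrow(models) == 0) return(empty)
  models <- classify_novelty(models, annotation, novelty_max_overlap)
  novel <- models[models$novelty == "novel", ]
  if (nrow(novel) == 0) return(empty)
  novel <- find_antisense_partner(novel, annotation)
  assoc <- associate_enhancer(novel, peaks, upstream_window)
  expr_sets <- expression %>%
    dplyr::filter(.data$rpkm >= expression_threshold) %>%
    dplyr::group_by(.data$transcript_id) %>%
    dplyr::summarise(expr = list(sort(unique(.data$condition))))
  enh_sets <- assoc %>%
    dplyr::group_by(.data$transcript_id) %>%
    dplyr::summarise(enh = list(sort(unique(.data$condition))))
  out <- purrr::map_dfr(seq_len(nrow(novel)), function(i) {
    m <- novel[i, ]
    expr <- expr_sets$expr[match(m$transcript_id, expr_sets$transcript_id)][[1]]
    enh <- enh_sets$enh[match(m$transcript_id, enh_sets$transcript_id)][[1]]
    if (is.null(expr) || is.null(enh)) return(empty)
    both <- intersect(expr, enh)
    if (length(both) == 0) return(empty)
    near <- nearest_gene_info(m, annotation)
    desc <- if (!is.na(m$antisense_gene)) {
      sprintf("novel transcript antisense to %s", m$antisense_gene)
    } else {
      "novel transcript"
    }
    tibble::tibble(
      transcript_id = m$transcript_id, chrom = m$chrom, start = m$start,
      end = m$end, strand = m$strand,
      nearest_gene = near$gene, relationship = near$relationship,
      description = desc,
      expression = list(expr), enhancer = list(enh))
  })
  if (nrow(out) == 0) empty else out
}

# Nearest gene and its relationship to a single candidate model.
nearest_gene_info <- function(m, annotation) {
  if (!is.na(m$antisense_gene)) {
    return(list(gene = m$antisense_gene, relationship = "antisense-overlap"))
  }
  if (nrow(annotation) == 0) {
    return(list(gene = NA_character_, relationship = NA_character_))
  }
  ann <- annotation[annotation$chrom == m$chrom, ]
  if (nrow(ann) == 0) {
    return(list(gene = NA_character_, relationship = NA_character_))
  }
  dist <- pmax(ann$start - m$end, m$start - ann$end, 0)
  j <- which.min(dist)
  centre_gene <- (ann$start[j] + ann$end[j]) / 2
  centre_model <- (m$start + m$end) / 2
  # Relationship expressed relative to the candidate's own direction.
  gene_is_after <- centre_gene > centre_model
  rel <- if (m$strand == "-") {
    if (gene_is_after) "upstream" else "downstream"
  } else {
    if (gene_is_after) "downstream" else "upstream"
  }
  list(gene = ann$gene_id[j], relationship = rel)
}

#' Precision and recall of a screen against planted truth
#'
#' @param candidates Candidate tibble from [screen_candidates()].
#' @param truth Truth tibble from [simulate_dataset()] (needs `chrom`,
#'   `as_start`, `as_end`, `as_strand`).
#' @return One-row tibble with `n_candidates`, `n_truth`, `tp`, `fp`, `fn`,
#'   `precision`, `recall`.
#' @export
evaluate_screen <- function(candidates, truth) {
  hit <- function(cand, tr) {
    cand$chrom == tr$chrom & cand$strand == tr$as_strand &
      cand$end > tr$as_start & cand$start < tr$as_end
  }
  truth_hit <- purrr::map_lgl(seq_len(nrow(truth)), function(j) {
    any(hit(candidates, truth[j, ]))
  })
  cand_hit <- purrr::map_lgl(seq_len(nrow(candidates)), function(i) {
    any(purrr::map_lgl(seq_len(nrow(truth)),
                       ~ hit(candidates[i, ], truth[.x, ])))
  })
  tp <- sum(truth_hit)
  tibble::tibble(
    n_candidates = nrow(candidates),
    n_truth = nrow(truth),
    tp = tp,
    fp = sum(!cand_hit),
    fn = sum(!truth_hit),
    precision = if (nrow(candidates)) mean(cand_hit) else NA_real_,
    recall = if (nrow(truth)) mean(truth_hit) else NA_real_
  )
}
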