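#' @importFrom rlang .data
#' @importFrom dplyr %>%
NULL

# All coordinates in this package are 0-based half-open (BED-native).
# Conversions to/from 1-based formats happen only in readers/writers.

STRANDS <- c("+", "-", ".")

abort_validation <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("enhansr_validation_error", "error", "condition")))
}

#' Build a transcript table
#'
#' Transcript models are plain tibbles with one row per transcript and the exon
#' structure in a list-column, so they compose with dplyr verbs. Coordinates
#' are 0-based half-open throughout.
#'
#' @param transcript_id Character vector of unique transcript identifiers.
#' @param chrom Chromosome name per transcript.
#' @param strand One of `"+"`, `"-"`, `"."` per transcript.
#' @param exons List of data frames with `start`/`end` columns (0-based
#'   half-open), one per transcript. Exons must be sorted and pairwise
#'   disjoint.
#' @param gene_id Optional gene identifier per transcript.
#' @param provenance Optional list of character vectors naming the source
#'   fragments each model was built from. Defaults to the transcript's own id.
#'
#' @return A tibble with columns `transcript_id`, `gene_id`, `chrom`, `start`,
#'   `end`, `strand`, `exons` (list-column) and `provenance` (list-column).
#'   The span is derived from the exons: `start` is the first exon start and
#'   `end` the last exon end.
#' @export
#' @examples
#' transcript_tbl("tx1", "chr1", "+", list(data.frame(start = 0, end = 100)))
transcript_tbl <- function(transcript_id, chrom, strand, exons,
                           gene_id = NA_character_, provenance = NULL) {
  n <- length(transcript_id)
  if (anyDuplicated(transcript_id)) {
    abort_validation("duplicated transcript_id values")
  }
  exons <- purrr::map(exons, function(e) {
    e <- tibble::as_tibble(e)[, c("start", "end")]
    e$start <- as.numeric(e$start)
    e$end <- as.numeric(e$end)
    e
  })
  if (is.null(provenance)) provenance <- as.list(transcript_id)
  out <- tibble::tibble(
    transcript_id = as.character(transcript_id),
    gene_id = rep_len(as.character(gene_id), n),
    chrom = rep_len(as.character(chrom), n),
    start = purrr::map_dbl(exons, ~ min(.x$start)),
    end = purrr::map_dbl(exons, ~ max(.x$end)),
    strand = rep_len(as.character(strand), n),
    exons = exons,
    provenance = provenance
  )
  validate_transcripts(out)
  out
}

# Invariant checks shared by readers, simulator and merger.
validate_transcripts <- function(x) {
  stopifnot(is.data.frame(x))
  need <- c("transcript_id", "chrom", "start", "end", "strand", "exons")
  missing <- setdiff(need, names(x))
  if (length(missing)) {
    abort_validation("transcript table lacks column(s): %s",
                     paste(missing, collapse = ", "))
  }
  if (!all(x$strand %in% STRANDS)) {
    abort_validation("strand values must be one of +, -, .")
  }
  for (i in seq_len(nrow(x))) {
    e <- x$exons[[i]]
    id <- x$transcript_id[i]
    if (nrow(e) == 0) abort_validation("record '%s' has no exons", id)
    if (any(e$start >= e$end) || any(e$start < 0)) {
      abort_validation("record '%s' has an invalid exon interval", id)
    }
    if (is.unsorted(e$start, strictly = TRUE) && nrow(e) > 1) {
      abort_validation("record '%s' exons are not sorted", id)
    }
    if (nrow(e) > 1 && any(e$start[-1] < e$end[-nrow(e)])) {
      abort_validation("record '%s' exons overlap", id)
    }
    if (e$start[1] != x$start[i] || e$end[nrow(e)] != x$end[i]) {
      abort_validation("record '%s': span does not match exon extremes", id)
    }
  }
  invisible(x)
}

#' Flatten transcript models to one row per exon
#'
#' @param models A transcript table (see [transcript_tbl()]).
#' @return A tibble with columns `transcript_id`, `gene_id`, `chrom`, `strand`,
#'   `exon_index` (1-based, in genomic order), `start`, `end`.
#' @export
exon_tbl <- function(models) {
  models %>%
    dplyr::mutate(exon = purrr::map(.data$exons, function(e) {
      e$exon_index <- seq_len(nrow(e))
      e
    })) %>%
    dplyr::select("transcript_id", "gene_id", "chrom", "strand", "exon") %>%
    tidyr::unnest("exon") %>%
    dplyr::select("transcript_id", "gene_id", "chrom", "strand",
                  "exon_index", "start", "end")
}

#' Exonic length of each transcript model
#'
#' @inheritParams exon_tbl
#' @return Numeric vector of summed exon widths, one per model.
#' @export
exonic_length <- function(models) {
  purrr::map_dbl(models$exons, ~ sum(.x$end - .x$start))
}

# GRanges conversion helpers. GRanges are 1-based closed, so start + 1.
models_to_gr <- function(models, level = c("span", "exon")) {
  level <- match.arg(level)
  if (level == "span") {
    df <- models
    GenomicRanges::GRanges(
      seqnames = df$chrom,
      ranges = IRanges::IRanges(start = df$start + 1, end = df$end),
      strand = ifelse(df$strand == ".", "*", df$strand),
      transcript_id = df$transcript_id,
      gene_id = df$gene_id %||% NA_character_
    )
  } else {
    ex <- exon_tbl(models)
    GenomicRanges::GRanges(
      seqnames = ex$chrom,
      ranges = IRanges::IRanges(start = ex$start + 1, end = ex$end),
      strand = ifelse(ex$strand == ".", "*", ex$strand),
      transcript_id = ex$transcript_id,
      gene_id = ex$gene_id
    )
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Same-strand exonic overlap in bp between each model and a set of annotation
# models, returned as a numeric vector aligned with `models`.
same_strand_exonic_overlap <- function(models, annotation) {
  out <- numeric(nrow(models))
  if (nrow(models) == 0 || nrow(annotation) == 0) return(out)
  mg <- models_to_gr(models, "exon")
  ag <- models_to_gr(annotation, "exon")
  hits <- GenomicRanges::findOverlaps(mg, ag, ignore.strand = FALSE)
  if (length(hits) == 0) return(out)
  ov <- GenomicRanges::pintersect(mg[S4Vectors::queryHits(hits)],
                                  ag[S4Vectors::subjectHits(hits)])
  per_exon <- tibble::tibble(
    transcript_id = mg$transcript_id[S4Vectors::queryHits(hits)],
    ann_gene = ag$gene_id[S4Vectors::subjectHits(hits)],
    ann_exon = S4Vectors::subjectHits(hits),
    q_exon = S4Vectors::queryHits(hits),
    width = BiocGenerics::width(ov)
  )
  # A model exon can overlap several isoforms of the same gene; count each
  # model base once by unioning per model.
  agg <- per_exon %>%
    dplyr::group_by(.data$transcript_id) %>%
    dplyr::group_map(function(d, key) {
      r <- IRanges::reduce(IRanges::IRanges(
        start = pmax(BiocGenerics::start(mg)[d$q_exon],
                     BiocGenerics::start(ag)[d$ann_exon]),
        end = pmin(BiocGenerics::end(mg)[d$q_exon],
                   BiocGenerics::end(ag)[d$ann_exon])
      ))
      tibble::tibble(transcript_id = key$transcript_id,
                     overlap_bp = sum(BiocGenerics::width(r)))
    }) %>%
    dplyr::bind_rows()
  idx <- match(models$transcript_id, agg$transcript_id)
  out[!is.na(idx)] <- agg$overlap_bp[idx[!is.na(idx)]]
  out
}
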