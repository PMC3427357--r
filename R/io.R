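#' Read transcript features from BED6, BED12 or GTF
#'
#' BED coordinates are kept 0-based half-open; GTF coordinates (1-based
#' inclusive) are converted at this boundary so that everything downstream
#' works in a single convention. BED12 blocks become exons ordered by genomic
#' coordinate; a BED6 record becomes a single-exon model. Columns beyond the
#' 6th/12th BED column are preserved opaquely in an `extra` list-column and
#' dropped again on write.
#'
#' @param path Input file.
#' @param format One of `"auto"`, `"bed6"`, `"bed12"`, `"gtf"`. `"auto"`
#'   guesses from the file extension and column count.
#' @return A transcript table (see [transcript_tbl()]).
#' @export
read_features <- function(path, format = c("auto", "bed6", "bed12", "gtf")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort_validation("file not found: %s", path)
  if (format == "auto") {
    format <- if (grepl("\\.gtf(\\.gz)?$", path, ignore.case = TRUE)) {
      "gtf"
    } else {
      first <- readr::read_lines(path, n_max = 50)
      first <- first[!grepl("^(track|browser|#)", first) & nzchar(first)]
      nf <- if (length(first)) length(strsplit(first[1], "\t")[[1]]) else 6
      if (nf >= 12) "bed12" else "bed6"
    }
  }
  switch(format,
         bed6 = read_bed(path, blocks = FALSE),
         bed12 = read_bed(path, blocks = TRUE),
         gtf = read_gtf(path))
}

read_bed <- function(path, blocks) {
  lines <- readr::read_lines(path)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(trimws(lines))
  line_no <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0) {
    return(transcript_tbl(character(), character(), character(), list()))
  }
  fields <- strsplit(lines, "\t")
  min_cols <- if (blocks) 12 else 6
  recs <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    f <- fields[[i]]
    if (length(f) < min_cols) {
      abort_validation("malformed BED line %d: expected >= %d columns, got %d",
                       line_no[i], min_cols, length(f))
    }
    start <- suppressWarnings(as.numeric(f[2]))
    end <- suppressWarnings(as.numeric(f[3]))
    if (is.na(start) || is.na(end) || start < 0 || start >= end) {
      abort_validation("malformed BED line %d: bad coordinates", line_no[i])
    }
    strand <- f[6]
    if (!strand %in% STRANDS) {
      abort_validation("malformed BED line %d: bad strand '%s'",
                       line_no[i], strand)
    }
    if (blocks) {
      n_blk <- suppressWarnings(as.integer(f[10]))
      sizes <- suppressWarnings(as.numeric(strsplit(f[11], ",")[[1]]))
      starts <- suppressWarnings(as.numeric(strsplit(f[12], ",")[[1]]))
      if (is.na(n_blk) || length(sizes) != n_blk || length(starts) != n_blk ||
          anyNA(sizes) || anyNA(starts)) {
        abort_validation("malformed BED line %d: inconsistent blocks",
                         line_no[i])
      }
      ex_start <- start + starts
      ex <- tibble::tibble(start = ex_start, end = ex_start + sizes)
      if (any(ex$end > end) || any(ex$start < start)) {
        abort_validation("exon outside parent span in record '%s'", f[4])
      }
    } else {
      ex <- tibble::tibble(start = start, end = end)
    }
    recs[[i]] <- list(id = f[4], chrom = f[1], strand = strand, exons = ex,
                      score = suppressWarnings(as.numeric(f[5])),
                      extra = if (length(f) > min_cols) {
                        f[(min_cols + 1):length(f)]
                      } else {
                        character()
                      })
  }
  out <- transcript_tbl(
    transcript_id = purrr::map_chr(recs, "id"),
    chrom = purrr::map_chr(recs, "chrom"),
    strand = purrr::map_chr(recs, "strand"),
    exons = purrr::map(recs, "exons")
  )
  out$score <- purrr::map_dbl(recs, "score")
  out$extra <- purrr::map(recs, "extra")
  out
}

read_gtf <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type == "exon"]
  if (length(gr) == 0) {
    return(transcript_tbl(character(), character(), character(), list()))
  }
  df <- tibble::tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = BiocGenerics::start(gr) - 1,   # 1-based inclusive -> 0-based half-open
    end = BiocGenerics::end(gr),
    strand = as.character(BiocGenerics::strand(gr)),
    transcript_id = as.character(gr$transcript_id),
    gene_id = if ("gene_id" %in% names(S4Vectors::mcols(gr))) {
      as.character(gr$gene_id)
    } else {
      NA_character_
    }
  )
  df$strand[df$strand == "*"] <- "."
  nested <- df %>%
    dplyr::arrange(.data$transcript_id, .data$start) %>%
    tidyr::nest(exons = c("start", "end"))
  transcript_tbl(nested$transcript_id, nested$chrom, nested$strand,
                 nested$exons, gene_id = nested$gene_id)
}

#' Write transcript models as BED12 (or BED6)
#'
#' @param models A transcript table.
#' @param path Output file.
#' @param format `"bed12"` (exon blocks preserved) or `"bed6"` (span only).
#' @return `path`, invisibly.
#' @export
write_features <- function(models, path, format = c("bed12", "bed6")) {
  format <- match.arg(format)
  fmt_int <- function(x) format(x, scientific = FALSE, trim = TRUE)
  lines <- purrr::map_chr(seq_len(nrow(models)), function(i) {
    m <- models[i, ]
    score <- if ("score" %in% names(models) && !is.na(m$score)) m$score else 0
    base6 <- c(m$chrom, fmt_int(m$start), fmt_int(m$end), m$transcript_id,
               fmt_int(score), m$strand)
    if (format == "bed6") return(paste(base6, collapse = "\t"))
    e <- m$exons[[1]]
    paste(c(base6, fmt_int(m$start), fmt_int(m$end), "0", length(e$start),
            paste0(paste(fmt_int(e$end - e$start), collapse = ","), ","),
            paste0(paste(fmt_int(e$start - m$start), collapse = ","), ",")),
          collapse = "\t")
  })
  readr::write_lines(lines, path)
  invisible(path)
}

#' Write a candidate table
#'
#' Writes screened antisense-enhancer candidates as a tab-separated table with
#' columns `Region`, `Strand`, `Nearest Gene`, `Description`, `Expression`,
#' `Enhancer` (plus a header row). Regions are printed as
#' `chrom:start-end` in the package's 0-based half-open convention.
#'
#' @param candidates Candidate tibble from [screen_candidates()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_candidate_table <- function(candidates, path) {
  df <- tibble::tibble(
    Region = sprintf("%s:%s-%s", candidates$chrom,
                     format(candidates$start, scientific = FALSE, trim = TRUE),
                     format(candidates$end, scientific = FALSE, trim = TRUE)),
    Strand = candidates$strand,
    `Nearest Gene` = ifelse(
      is.na(candidates$nearest_gene), ".",
      sprintf("%s (%s)", candidates$nearest_gene, candidates$relationship)),
    Description = candidates$description,
    Expression = purrr::map_chr(candidates$expression,
                                ~ paste(sort(.x), collapse = ",")),
    Enhancer = purrr::map_chr(candidates$enhancer,
                              ~ paste(sort(.x), collapse = ","))
  )
  readr::write_tsv(df, path)
  invisible(path)
}

#' Read a candidate table written by [write_candidate_table()]
#'
#' @param path Input file.
#' @return A tibble with the same semantic columns as [screen_candidates()]
#'   output: `chrom`, `start`, `end`, `strand`, `nearest_gene`,
#'   `relationship`, `description`, `expression`, `enhancer`.
#' @export
read_candidate_table <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(.default = "c"))
  m <- stringr::str_match(df$Region, "^(.*):([0-9]+)-([0-9]+)$")
  if (anyNA(m[, 1])) {
    abort_validation("malformed Region at candidate row %d",
                     which(is.na(m[, 1]))[1])
  }
  ng <- stringr::str_match(df$`Nearest Gene`, "^(.*) \\((.*)\\)$")
  tibble::tibble(
    chrom = m[, 2],
    start = as.numeric(m[, 3]),
    end = as.numeric(m[, 4]),
    strand = df$Strand,
    nearest_gene = ifelse(df$`Nearest Gene` == ".", NA_character_, ng[, 2]),
    relationship = ifelse(df$`Nearest Gene` == ".", NA_character_, ng[, 3]),
    description = df$Description,
    expression = purrr::map(df$Expression,
                            ~ if (is.na(.x) || !nzchar(.x)) character()
                              else strsplit(.x, ",")[[1]]),
    enhancer = purrr::map(df$Enhancer,
                          ~ if (is.na(.x) || !nzchar(.x)) character()
                            else strsplit(.x, ",")[[1]])
  )
}

#' Read transcript sequences from FASTA
#'
#' @param path FASTA file.
#' @return A named character vector of uppercase sequences.
#' @export
read_transcript_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(seqs))
  names(out) <- sub("\\s.*$", "", names(seqs))
  out
}

#' Write transcript sequences to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_transcript_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path, width = 70)
  invisible(path)
}
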