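#' Per-base stranded coverage track
#'
#' A coverage track is the substrate for all expression computations: dense
#' per-base read depth over one strand of one chromosome, together with the
#' total mapped read count of the library it came from (the `N` in RPKM).
#'
#' @param chrom Chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param depth Numeric vector of non-negative per-base depths. Position `i`
#'   of the vector is genomic base `offset + i - 1` (0-based).
#' @param library_size Total mapped reads of the library, `> 0`.
#' @param condition Condition label (e.g. `"UN"`, `"NP"`).
#' @param offset 0-based genomic position of the first element of `depth`.
#'
#' @return An object of class `coverage_track`.
#' @export
coverage_track <- function(chrom, strand, depth, library_size,
                           condition = NA_character_, offset = 0) {
  if (!strand %in% c("+", "-")) {
    abort_validation("coverage track strand must be '+' or '-'")
  }
  depth <- as.numeric(depth)
  if (any(depth < 0)) abort_validation("negative depth in coverage track")
  if (!is.numeric(library_size) || length(library_size) != 1 ||
      is.na(library_size) || library_size <= 0) {
    abort_validation("library_size must be a single positive number")
  }
  structure(
    list(chrom = chrom, strand = strand, condition = condition,
         offset = as.numeric(offset), depth = depth,
         library_size = as.numeric(library_size)),
    class = "coverage_track"
  )
}

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf(
    "<coverage_track> %s(%s) condition=%s span=[%d,%d) library_size=%.0f\n",
    x$chrom, x$strand, x$condition, as.integer(x$offset),
    as.integer(x$offset + length(x$depth)), x$library_size))
  invisible(x)
}

#' Depth over a genomic window
#'
#' @param track A [coverage_track()].
#' @param start,end 0-based half-open window.
#' @return Numeric vector of length `end - start`; bases outside the track
#'   span have depth 0.
#' @export
track_depth <- function(track, start, end) {
  if (end <= start) abort_validation("track_depth: end must exceed start")
  pos <- seq.int(start, end - 1)
  idx <- pos - track$offset + 1
  out <- numeric(length(idx))
  ok <- idx >= 1 & idx <= length(track$depth)
  out[ok] <- track$depth[idx[ok]]
  out
}

# Depth at individual 0-based positions (vectorised).
track_depth_at <- function(track, pos) {
  idx <- pos - track$offset + 1
  out <- numeric(length(idx))
  ok <- idx >= 1 & idx <= length(track$depth)
  out[ok] <- track$depth[idx[ok]]
  out
}

#' Read a BedGraph pair into stranded coverage tracks
#'
#' BedGraph carries no strand column, so a stranded library is interchanged as
#' one file per strand. Intervals within a file must be non-overlapping;
#' uncovered bases get depth 0 over the union span (from base 0 to the last
#' covered base of either file).
#'
#' @param path_plus,path_minus BedGraph files for the plus and minus strand.
#' @param library_size Total mapped reads of the library.
#' @param condition Condition label attached to both tracks.
#' @param chrom Restrict to one chromosome; default takes the single
#'   chromosome present (an error if the files mix chromosomes).
#' @return A named list with elements `plus` and `minus`, each a
#'   [coverage_track()].
#' @export
read_stranded_coverage <- function(path_plus, path_minus, library_size,
                                   condition = NA_character_, chrom = NULL) {
  plus <- read_bedgraph_df(path_plus)
  minus <- read_bedgraph_df(path_minus)
  chroms <- unique(c(plus$chrom, minus$chrom))
  if (is.null(chrom)) {
    if (length(chroms) > 1) {
      abort_validation(
        "coverage files contain multiple chromosomes (%s); pass `chrom`",
        paste(chroms, collapse = ", "))
    }
    chrom <- if (length(chroms)) chroms else "chr"
  }
  plus <- plus[plus$chrom == chrom, , drop = FALSE]
  minus <- minus[minus$chrom == chrom, , drop = FALSE]
  span <- max(1, plus$end, minus$end)
  list(
    plus = coverage_track(chrom, "+", fill_depth(plus, span), library_size,
                          condition),
    minus = coverage_track(chrom, "-", fill_depth(minus, span), library_size,
                           condition)
  )
}

read_bedgraph_df <- function(path) {
  if (!file.exists(path)) abort_validation("file not found: %s", path)
  lines <- readr::read_lines(path)
  lines <- lines[!grepl("^(track|#)", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0) {
    return(tibble::tibble(chrom = character(), start = numeric(),
                          end = numeric(), depth = numeric()))
  }
  fields <- strsplit(lines, "[ \t]+")
  bad <- which(lengths(fields) < 4)
  if (length(bad)) {
    abort_validation("malformed BedGraph line %d in %s", bad[1], path)
  }
  df <- tibble::tibble(
    chrom = vapply(fields, `[[`, "", 1),
    start = suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2))),
    end = suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3))),
    depth = suppressWarnings(as.numeric(vapply(fields, `[[`, "", 4)))
  )
  bad <- which(is.na(df$start) | is.na(df$end) | is.na(df$depth) |
                 df$start < 0 | df$start >= df$end)
  if (length(bad)) {
    abort_validation("malformed BedGraph line %d in %s", bad[1], path)
  }
  if (any(df$depth < 0)) {
    abort_validation("negative depth at BedGraph line %d in %s",
                     which(df$depth < 0)[1], path)
  }
  # Overlap check per chromosome.
  for (ch in unique(df$chrom)) {
    d <- df[df$chrom == ch, ]
    d <- d[order(d$start), ]
    if (nrow(d) > 1 && any(d$start[-1] < d$end[-nrow(d)])) {
      abort_validation("overlapping BedGraph intervals on %s in %s", ch, path)
    }
  }
  df
}

fill_depth <- function(df, span) {
  depth <- numeric(span)
  for (i in seq_len(nrow(df))) {
    depth[(df$start[i] + 1):df$end[i]] <- df$depth[i]
  }
  depth
}

#' Write a coverage track as BedGraph
#'
#' Zero-depth runs are omitted, matching the sparse BedGraph convention.
#'
#' @param track A [coverage_track()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  r <- rle(track$depth)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values != 0
  df <- tibble::tibble(
    chrom = track$chrom,
    start = format(track$offset + starts[keep], scientific = FALSE,
                   trim = TRUE),
    end = format(track$offset + ends[keep], scientific = FALSE, trim = TRUE),
    depth = format(r$values[keep], scientific = FALSE, trim = TRUE)
  )
  readr::write_tsv(df, path, col_names = FALSE)
  invisible(path)
}
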