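ORF_STOPS <- c("TAA", "TAG", "TGA")

#' Longest open reading frame of a transcript sequence
#'
#' Scans the three frames of the given strand only (transcripts are assumed
#' already stranded) for the longest `ATG ... stop` stretch, with the stop
#' codon (`TAA`/`TAG`/`TGA`) included in the reported length. Ties are broken
#' by smallest start offset. Codons containing `N` never match `ATG` or a
#' stop. ORFs without an in-frame stop inside the sequence are not reported.
#'
#' @param sequence A single character string (or `DNAString`) over
#'   `A,C,G,T,N`; case-insensitive.
#' @return A one-row tibble with `start` (0-based offset), `length_nt`
#'   (stop-inclusive, a multiple of 3, >= 6), `protein_len_aa`
#'   (`length_nt / 3 - 1`), `frame` (0/1/2) and `coverage_fraction`
#'   (`length_nt / nchar(sequence)`); a zero-row tibble when no ORF exists.
#' @export
#' @examples
#' longest_orf("ATGAAATGA")   # length 9, protein 2 aa
longest_orf <- function(sequence) {
  s <- toupper(as.character(sequence))
  if (length(s) != 1) abort_validation("longest_orf takes a single sequence")
  if (grepl("[^ACGTN]", s)) {
    abort_validation("sequence contains characters outside {A,C,G,T,N}")
  }
  n <- nchar(s)
  none <- tibble::tibble(start = integer(), length_nt = integer(),
                         protein_len_aa = integer(), frame = integer(),
                         coverage_fraction = numeric())
  best <- NULL
  for (f in 0:2) {
    ncod <- (n - f) %/% 3
    if (ncod < 2) next
    at <- f + 1 + 3 * (0:(ncod - 1))
    cod <- substring(s, at, at + 2)
    starts <- which(cod == "ATG")
    stops <- which(cod %in% ORF_STOPS)
    if (length(starts) == 0 || length(stops) == 0) next
    # First stop at or beyond each start codon (a start is never a stop).
    k <- findInterval(starts - 0.5, stops) + 1
    ok <- k <= length(stops)
    if (!any(ok)) next
    starts <- starts[ok]
    len_nt <- 3 * (stops[k[ok]] - starts + 1)
    i <- which.max(len_nt)
    cand <- list(start = (starts[i] - 1) * 3 + f,
                 length_nt = len_nt[i], frame = f)
    if (is.null(best) || cand$length_nt > best$length_nt ||
        (cand$length_nt == best$length_nt && cand$start < best$start)) {
      best <- cand
    }
  }
  if (is.null(best)) return(none)
  tibble::tibble(
    start = as.integer(best$start),
    length_nt = as.integer(best$length_nt),
    protein_len_aa = protein_length(best$length_nt),
    frame = as.integer(best$frame),
    coverage_fraction = best$length_nt / n
  )
}

#' Protein length implied by a stop-inclusive ORF length
#'
#' @param orf_length_nt ORF length in nucleotides, stop codon included; must
#'   be a multiple of 3 and at least 6.
#' @return Amino-acid count `orf_length_nt / 3 - 1` (the stop codon encodes
#'   no residue).
#' @export
#' @examples
#' protein_length(243)  # 80
#' protein_length(108)  # 35
protein_length <- function(orf_length_nt) {
  if (any(orf_length_nt %% 3 != 0)) {
    abort_validation("ORF length must be divisible by 3")
  }
  if (any(orf_length_nt < 6)) {
    abort_validation("ORF length must be at least 6 nt (start + stop)")
  }
  as.integer(orf_length_nt / 3 - 1)
}

#' Coding-potential flag from ORF coverage and protein length
#'
#' A deliberately simple heuristic (no Kozak-context scoring, no homology):
#' a transcript is noncoding-like iff its longest ORF covers less than
#' `max_fraction` of the transcript AND encodes fewer than `max_protein_len`
#' amino acids; transcripts without any ORF are noncoding-like.
#'
#' @param orf A [longest_orf()] result (possibly zero rows).
#' @param transcript_length Transcript length in nt.
#' @param max_fraction ORF coverage fraction below which a transcript can be
#'   called noncoding-like (default 0.5).
#' @param max_protein_len Protein length (aa) below which a transcript can be
#'   called noncoding-like (default 100).
#' @return `"coding-like"` or `"noncoding-like"`.
#' @export
coding_flag <- function(orf, transcript_length, max_fraction = 0.5,
                        max_protein_len = 100) {
  if (is.null(orf) || nrow(orf) == 0) return("noncoding-like")
  frac <- orf$length_nt / transcript_length
  if (frac < max_fraction && orf$protein_len_aa < max_protein_len) {
    "noncoding-like"
  } else {
    "coding-like"
  }
}

#' ORF table for a set of transcript sequences
#'
#' @param seqs Named character vector (or `DNAStringSet`) of transcript
#'   sequences.
#' @inheritParams coding_flag
#' @return Tibble with one row per sequence: `seq_id`, `transcript_length`,
#'   the [longest_orf()] fields (`NA` when no ORF) and `flag`.
#' @export
orf_table <- function(seqs, max_fraction = 0.5, max_protein_len = 100) {
  ids <- names(seqs) %||% as.character(seq_along(seqs))
  seqs_chr <- toupper(as.character(seqs))
  purrr::map_dfr(seq_along(seqs_chr), function(i) {
    orf <- longest_orf(seqs_chr[[i]])
    len <- nchar(seqs_chr[[i]])
    flag <- coding_flag(orf, len, max_fraction, max_protein_len)
    if (nrow(orf) == 0) {
      orf <- tibble::tibble(start = NA_integer_, length_nt = NA_integer_,
                            protein_len_aa = NA_integer_, frame = NA_integer_,
                            coverage_fraction = NA_real_)
    }
    dplyr::bind_cols(tibble::tibble(seq_id = ids[i], transcript_length = len),
                     orf, tibble::tibble(flag = flag))
  })
}
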