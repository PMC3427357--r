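# Shared engine: exonic sense-strand depth of a gene laid out in sense
# (5'->3') order, plus prefix sums for O(1) flank-window means.
shift_engine <- function(gene, tracks, flank) {
  stopifnot(nrow(gene) == 1)
  e <- gene$exons[[1]]
  pos <- unlist(purrr::map2(e$start, e$end, ~ seq.int(.x, .y - 1)))
  pos <- sort(pos)
  sense_pos <- if (gene$strand == "-") rev(pos) else pos
  depth <- purrr::map(tracks, function(tr) {
    if (tr$strand != gene$strand) {
      abort_validation("shift: track strand does not match gene strand")
    }
    track_depth_at(tr, sense_pos)
  })
  cums <- purrr::map(depth, cumsum)
  n <- length(pos)
  list(gene = gene, pos = pos, sense_pos = sense_pos, cums = cums, n = n,
       flank = flank)
}

# Index of the boundary in sense-ordered exonic space: number of exonic
# bases strictly 5' (sense-upstream) of `boundary`, plus one.
boundary_index <- function(eng, boundary) {
  g <- eng$gene
  if (boundary <= g$start || boundary >= g$end) {
    abort_validation("boundary %s lies outside gene '%s'",
                     format(boundary), g$transcript_id)
  }
  if (g$strand == "-") {
    sum(eng$pos >= boundary) + 1
  } else {
    sum(eng$pos < boundary) + 1
  }
}

# Window means around sense index j; upstream = [j-flank, j-1],
# downstream = [j, j+flank-1] in sense order. Vectorised over j.
window_means <- function(cums, j, flank, n) {
  bad_up <- j - flank < 1
  bad_down <- j + flank - 1 > n
  jm1 <- pmax(j - 1, 1)
  low <- pmax(j - flank - 1, 1)
  up <- (cums[jm1] - ifelse(j - flank - 1 >= 1, cums[low], 0)) / flank
  down <- (cums[pmin(j + flank - 1, n)] - cums[jm1]) / flank
  list(up = up, down = down, bad_up = bad_up, bad_down = bad_down)
}

#' Sense isoform-shift score at a boundary
#'
#' Quantifies whether the sense gene prefers a short isoform ending near the
#' overlapping antisense transcript's 3' end when the antisense RNA is
#' expressed. For each condition `c`, `r_c` is the ratio of mean sense-strand
#' exonic coverage in the flank window downstream (in the sense direction) of
#' the boundary to the mean in the upstream flank, each with a pseudocount:
#' `r_c = (mean_down + pseudocount) / (mean_up + pseudocount)`. The score is
#' `log2(r_off) - log2(r_on)`; a positive score means the long isoform is
#' relatively favoured when the antisense RNA is off.
#'
#' @param gene One-row transcript table (use the gene's longest isoform so
#'   means are taken over exonic bases only).
#' @param tracks Named list of sense-strand [coverage_track()]s, one per
#'   condition.
#' @param boundary 0-based position strictly inside the gene span (typically
#'   the antisense model's 3' end).
#' @param on,off Names in `tracks` of the antisense-ON and antisense-OFF
#'   conditions.
#' @param flank Flank window size in exonic bases (default 1000).
#' @param pseudocount Added to both window means (default 1 depth unit).
#' @return One-row tibble: `gene_id`, `transcript_id`, `boundary`, `r_on`,
#'   `r_off`, `score`.
#' @export
shift_score <- function(gene, tracks, boundary, on, off, flank = 1000,
                        pseudocount = 1) {
  eng <- shift_engine(gene, tracks[c(on, off)], flank)
  j <- boundary_index(eng, boundary)
  ratios <- purrr::map_dbl(c(on = on, off = off), function(cond) {
    w <- window_means(eng$cums[[cond]], j, flank, eng$n)
    if (w$bad_up) {
      abort_validation("upstream flank window does not fit inside gene '%s'",
                       gene$transcript_id)
    }
    if (w$bad_down) {
      abort_validation("downstream flank window does not fit inside gene '%s'",
                       gene$transcript_id)
    }
    (w$down + pseudocount) / (w$up + pseudocount)
  })
  tibble::tibble(
    gene_id = gene$gene_id,
    transcript_id = gene$transcript_id,
    boundary = boundary,
    r_on = ratios[["on"]],
    r_off = ratios[["off"]],
    score = log2(ratios[["off"]]) - log2(ratios[["on"]])
  )
}

#' Permutation p-value for an isoform-shift score
#'
#' Builds a null by recomputing the score at `n_perm` boundary positions
#' drawn uniformly from the gene's interior exonic positions, excluding a
#' margin of `flank` exonic bases at each end, and returns the add-one
#' estimator `p = (1 + #{|score_perm| >= |score_obs|}) / (n_perm + 1)`.
#'
#' @inheritParams shift_score
#' @param n_perm Number of permutation draws (>= 100).
#' @param seed Integer seed; the draw is deterministic given the seed.
#' @return One-row tibble: the [shift_score()] columns plus `pvalue` and
#'   `n_perm`.
#' @export
shift_pvalue <- function(gene, tracks, boundary, on, off, flank = 1000,
                         pseudocount = 1, n_perm = 999, seed = 1) {
  if (n_perm < 100) abort_validation("n_perm must be >= 100")
  eng <- shift_engine(gene, tracks[c(on, off)], flank)
  n <- eng$n
  eligible <- seq.int(flank + 1, n - flank + 1)
  if (length(eligible) < 2) {
    abort_validation("gene '%s' too short to place permutation boundaries",
                     gene$transcript_id)
  }
  score_at <- function(j) {
    r <- purrr::map(c(on = on, off = off), function(cond) {
      w <- window_means(eng$cums[[cond]], j, flank, n)
      (w$down + pseudocount) / (w$up + pseudocount)
    })
    log2(r$off) - log2(r$on)
  }
  j_obs <- boundary_index(eng, boundary)
  obs <- shift_score(gene, tracks, boundary, on, off, flank, pseudocount)
  perm_j <- withr::with_seed(seed,
                             sample(eligible, n_perm, replace = TRUE))
  perm_scores <- score_at(perm_j)
  p <- (1 + sum(abs(perm_scores) >= abs(obs$score))) / (n_perm + 1)
  obs$pvalue <- p
  obs$n_perm <- n_perm
  obs
}
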