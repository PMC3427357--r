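#' Pipeline configuration
#'
#' Central home of every tunable default. Unknown parameter names are
#' rejected; every value is range-checked before any compute runs.
#'
#' @param chosen_d Percentile-difference cap for merging, in `[0, 100]`
#'   (default 10; 5 is the conservative preset).
#' @param max_gap Largest bridged "intron length" in bp (default 11000).
#' @param novelty_max_overlap Same-strand exonic overlap fraction above which
#'   a model is "known" (default 0.1).
#' @param upstream_window Enhancer association window 5' of the transcription
#'   start, bp (default 2000).
#' @param expression_threshold RPKM at or above which a model counts as
#'   expressed (default 1).
#' @param flank Isoform-shift flank window, exonic bp (default 1000).
#' @param pseudocount Isoform-shift pseudocount in depth units (default 1).
#' @param n_perm Permutation draws for the shift p-value (default 999).
#' @param min_depth,min_len,max_zero_run Fragment-caller thresholds (see
#'   [call_fragments()]).
#' @param read_length Read-length equivalent for coverage-derived counts.
#' @param seed Integer seed for the pipeline's stochastic stages.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(chosen_d = 10, max_gap = 11000,
                            novelty_max_overlap = 0.1, upstream_window = 2000,
                            expression_threshold = 1, flank = 1000,
                            pseudocount = 1, n_perm = 999, min_depth = 2,
                            min_len = 200, max_zero_run = 50,
                            read_length = 50, seed = 1L) {
  cfg <- list(chosen_d = chosen_d, max_gap = max_gap,
              novelty_max_overlap = novelty_max_overlap,
              upstream_window = upstream_window,
              expression_threshold = expression_threshold, flank = flank,
              pseudocount = pseudocount, n_perm = n_perm,
              min_depth = min_depth, min_len = min_len,
              max_zero_run = max_zero_run, read_length = read_length,
              seed = as.integer(seed))
  validate_pipeline_config(cfg)
  structure(cfg, class = "pipeline_config")
}

validate_pipeline_config <- function(cfg) {
  known <- c("chosen_d", "max_gap", "novelty_max_overlap", "upstream_window",
             "expression_threshold", "flank", "pseudocount", "n_perm",
             "min_depth", "min_len", "max_zero_run", "read_length", "seed")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown)) {
    abort_validation("unknown pipeline parameter(s): %s",
                     paste(unknown, collapse = ", "))
  }
  in_range <- function(nm, lo, hi = Inf) {
    v <- cfg[[nm]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < lo || v > hi) {
      abort_validation("pipeline parameter %s out of range [%s, %s]: %s",
                       nm, format(lo), format(hi), format(cfg[[nm]]))
    }
  }
  in_range("chosen_d", 0, 100)
  in_range("max_gap", 1)
  in_range("novelty_max_overlap", 0, 1)
  in_range("upstream_window", 0)
  in_range("expression_threshold", 0)
  in_range("flank", 1)
  in_range("pseudocount", 0)
  in_range("n_perm", 100)
  in_range("min_depth", 1e-9)
  in_range("min_len", 1)
  in_range("max_zero_run", 0)
  in_range("read_length", 1)
  invisible(cfg)
}

#' Run the full screen on a dataset
#'
#' Orchestrates expression/calibration, fragment calling, merging, the
#' antisense screen, the isoform-shift statistic and ORF scanning, writing
#' every intermediate to `out_dir`. Deterministic given `config$seed`.
#'
#' @param sim An `enhansr_sim` dataset from [simulate_dataset()], or an
#'   equivalently shaped list built from files (see the CLI).
#' @param out_dir Output directory, created if needed. `NULL` skips writing.
#' @param config A [pipeline_config()].
#' @return A list with `calibration`, `merged` (per condition), `models`
#'   (deduplicated candidates input), `expression`, `candidates`, `shift`,
#'   `orf`, and `paths` of the written files.
#' @export
run_pipeline <- function(sim, out_dir = NULL, config = pipeline_config()) {
  validate_pipeline_config(config)
  conds <- names(sim$coverage)
  if (length(conds) < 2) {
    abort_validation("run_pipeline needs at least two conditions")
  }

  # --- calibration from annotated exons (sense strand of each condition)
  calib <- tryCatch({
    exr <- purrr::map_dfr(intersect(c("+", "-"),
                                    unique(sim$annotation$strand)),
                          function(st) {
      tr <- sim$coverage[[conds[1]]][[if (st == "+") "plus" else "minus"]]
      exon_expression(sim$annotation[sim$annotation$strand == st, ], tr,
                      config$read_length)
    })
    calibrate_merge(sim$annotation, exr, chosen_d = config$chosen_d,
                    max_gap = config$max_gap)
  }, enhansr_validation_error = function(e) {
    stop(errorCondition(paste("stage calibrate:", conditionMessage(e)),
                        class = class(e)))
  })

  # --- fragment calling + merge, per condition and strand
  merged <- list()
  for (cd in conds) {
    per_strand <- list()
    for (st in c("plus", "minus")) {
      tr <- sim$coverage[[cd]][[st]]
      fr <- call_fragments(tr, config$min_depth, config$min_len,
                           config$max_zero_run,
                           id_prefix = sprintf("%s_%s", cd, st))
      if (nrow(fr) == 0) next
      rec <- feature_rpkm(fr, tr, config$read_length)
      fr$read_count <- rec$read_count
      fr$rpkm <- rec$rpkm
      fr <- assign_percentiles(fr)
      per_strand[[st]] <- merge_fragments(fr, calib)
    }
    merged[[cd]] <- dplyr::bind_rows(per_strand)
  }

  # --- candidate models: union over conditions, deduplicated by same-strand
  # overlap (keep the longest representative per cluster)
  all_models <- dplyr::bind_rows(merged)
  models <- dedupe_models(all_models)

  # --- per-condition expression of every model
  expression <- purrr::map_dfr(conds, function(cd) {
    purrr::map_dfr(c("plus", "minus"), function(st) {
      tr <- sim$coverage[[cd]][[st]]
      sub <- models[models$strand == tr$strand, ]
      if (nrow(sub) == 0) return(NULL)
      sub$read_count <- NULL   # force coverage-derived counts per condition
      rec <- feature_rpkm(sub, tr, config$read_length)
      tibble::tibble(transcript_id = rec$feature_id, condition = cd,
                     rpkm = rec$rpkm)
    })
  })

  candidates <- screen_candidates(
    models, sim$annotation, sim$peaks, expression,
    expression_threshold = config$expression_threshold,
    novelty_max_overlap = config$novelty_max_overlap,
    upstream_window = config$upstream_window)

  # --- isoform shift at each candidate with an antisense partner
  shift <- purrr::map_dfr(seq_len(nrow(candidates)), function(i) {
    cand <- candidates[i, ]
    if (is.na(cand$nearest_gene) ||
        cand$relationship != "antisense-overlap") {
      return(NULL)
    }
    gene <- sim$genes[sim$genes$gene_id == cand$nearest_gene, ]
    if (nrow(gene) != 1) return(NULL)
    boundary <- if (cand$strand == "+") cand$end else cand$start
    on <- cand$expression[[1]][1]
    off <- setdiff(conds, cand$expression[[1]])[1]
    if (is.na(off)) return(NULL)
    tracks <- purrr::map(stats::setNames(conds, conds), function(cd) {
      sim$coverage[[cd]][[if (gene$strand == "+") "plus" else "minus"]]
    })
    res <- tryCatch(
      shift_pvalue(gene, tracks, boundary, on = on, off = off,
                   flank = config$flank, pseudocount = config$pseudocount,
                   n_perm = config$n_perm,
                   seed = locus_seed(config$seed, i, salt = 300L)),
      enhansr_validation_error = function(e) NULL)
    if (is.null(res)) return(NULL)
    res$candidate_id <- cand$transcript_id
    res$on <- on
    res$off <- off
    res
  })

  # --- ORF scan of provided transcript sequences
  orf <- if (length(sim$sequences)) orf_table(sim$sequences) else
    tibble::tibble()

  paths <- character()
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    p <- function(f) file.path(out_dir, f)
    readr::write_tsv(tidy(calib), p("calibration_pairs.tsv"))
    jsonlite::write_json(as.list(glance(calib)), p("calibration_summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    for (cd in conds) {
      write_features(merged[[cd]], p(sprintf("merged_%s.bed", cd)))
    }
    write_candidate_table(candidates, p("candidates.tsv"))
    readr::write_tsv(shift, p("shift.tsv"))
    readr::write_tsv(orf, p("orf.tsv"))
    paths <- c("calibration_pairs.tsv", "calibration_summary.json",
               sprintf("merged_%s.bed", conds), "candidates.tsv",
               "shift.tsv", "orf.tsv")
    log_lines <- c(
      "# enhansr run log",
      sprintf("parameter\t%s\t%s", names(config),
              purrr::map_chr(config, ~ format(.x, scientific = FALSE,
                                              trim = TRUE))),
      sprintf("output_md5\t%s\t%s", paths,
              unname(tools::md5sum(file.path(out_dir, paths)))))
    readr::write_lines(log_lines, p("run_log.txt"))
    paths <- file.path(out_dir, c(paths, "run_log.txt"))
  }

  list(calibration = calib, merged = merged, models = models,
       expression = expression, candidates = candidates, shift = shift,
       orf = orf, paths = paths)
}

# Collapse same-strand overlapping models from different conditions into one
# representative (the longest; ties by id).
dedupe_models <- function(models) {
  if (nrow(models) <= 1) return(models)
  gr <- models_to_gr(models, "span")
  cl <- GenomicRanges::reduce(gr, ignore.strand = FALSE, with.revmap = TRUE)
  keep <- purrr::map_int(as.list(cl$revmap), function(idx) {
    len <- models$end[idx] - models$start[idx]
    idx[order(-len, models$transcript_id[idx])[1]]
  })
  models[sort(keep), ]
}
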