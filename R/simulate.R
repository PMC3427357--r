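#' Configuration for the synthetic dataset generator
#'
#' The generator emulates a two-condition stranded RNA-seq experiment over a
#' toy chromosome: multi-exon sense genes on the minus strand, a subset of
#' loci carrying a condition-specific antisense transcript on the plus strand
#' whose 5' end sits under an enhancer peak active in the same condition, and
#' a correlated sense isoform shift — the fraction of sense signal stopping
#' at the antisense 3' boundary differs between conditions.
#'
#' @param n_genes Number of sense genes.
#' @param n_antisense_loci Number of genes carrying a planted antisense locus
#'   (`<= n_genes`).
#' @param exon_count_range,exon_len_range,intron_len_range Integer ranges for
#'   sense-gene geometry (bp).
#' @param base_expression_range Range of per-gene mean exonic depth.
#' @param antisense_depth Mean per-base depth of planted antisense
#'   transcripts in their active condition.
#' @param antisense_len_range Range of antisense transcript lengths (bp;
#'   unspliced).
#' @param noise_model `"poisson"` (per-base Poisson depth around the planted
#'   mean) or `"none"` (deterministic depth).
#' @param short_isoform_fraction_on,short_isoform_fraction_off Proportion of
#'   sense signal stopping at the antisense 3' boundary in the antisense-ON
#'   and antisense-OFF conditions.
#' @param terminal_attenuation_range Range of the multiplicative factor
#'   applied to the first and last exon's mean depth, emulating the
#'   systematically deviating coverage of terminal exons (UTRs, alternative
#'   ends, assembly edge effects) seen in real libraries. `c(1, 1)` disables
#'   it (fully within-gene-uniform expression).
#' @param n_breaks_per_transcript,gap_len_range Fragmentation of the true
#'   transcripts into assembly-like fragment calls.
#' @param library_size_per_condition Total mapped reads per condition.
#'   `NULL` (default) derives it from the planted coverage as
#'   `sum(depth) / read_length`; a fixed value rescales the planted mean
#'   depths so the realised read count matches it.
#' @param read_length Read-length equivalent in bp.
#' @param conditions Named character vector `c(on = ..., off = ...)` labelling
#'   the antisense-ON and antisense-OFF conditions.
#' @param gene_spacing Minimum spacing between genes (bp); the default keeps
#'   neighbouring genes far beyond the largest merge gap.
#' @param chrom Chromosome name.
#' @param seed Master integer seed. Each locus derives a child seed from its
#'   index, so adding loci does not perturb earlier loci.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 20,
                       n_antisense_loci = 6,
                       exon_count_range = c(10, 14),
                       exon_len_range = c(250, 500),
                       intron_len_range = c(800, 2500),
                       base_expression_range = c(5, 50),
                       antisense_depth = 10,
                       antisense_len_range = c(800, 1800),
                       noise_model = c("poisson", "none"),
                       short_isoform_fraction_on = 0.9,
                       short_isoform_fraction_off = 0.1,
                       terminal_attenuation_range = c(0.4, 1),
                       n_breaks_per_transcript = 2,
                       gap_len_range = c(50, 200),
                       library_size_per_condition = NULL,
                       read_length = 50,
                       conditions = c(on = "UN", off = "NP"),
                       gene_spacing = 20000,
                       chrom = "chrS",
                       seed = 1L) {
  cfg <- list(
    n_genes = n_genes, n_antisense_loci = n_antisense_loci,
    exon_count_range = exon_count_range, exon_len_range = exon_len_range,
    intron_len_range = intron_len_range,
    base_expression_range = base_expression_range,
    antisense_depth = antisense_depth,
    antisense_len_range = antisense_len_range,
    noise_model = match.arg(noise_model),
    short_isoform_fraction_on = short_isoform_fraction_on,
    short_isoform_fraction_off = short_isoform_fraction_off,
    terminal_attenuation_range = terminal_attenuation_range,
    n_breaks_per_transcript = n_breaks_per_transcript,
    gap_len_range = gap_len_range,
    library_size_per_condition = library_size_per_condition,
    read_length = read_length, conditions = conditions,
    gene_spacing = gene_spacing, chrom = chrom, seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  chk_range <- function(r, nm) {
    if (length(r) != 2 || anyNA(r) || r[1] > r[2] || r[1] < 0) {
      abort_validation("sim_config: %s must be an ordered non-negative pair",
                       nm)
    }
  }
  if (cfg$n_genes < 0 || cfg$n_antisense_loci < 0) {
    abort_validation("sim_config: counts must be >= 0")
  }
  if (cfg$n_antisense_loci > cfg$n_genes) {
    abort_validation("sim_config: n_antisense_loci must be <= n_genes")
  }
  for (nm in c("exon_count_range", "exon_len_range", "intron_len_range",
               "base_expression_range", "antisense_len_range",
               "gap_len_range", "terminal_attenuation_range")) {
    chk_range(cfg[[nm]], nm)
  }
  for (nm in c("short_isoform_fraction_on", "short_isoform_fraction_off")) {
    f <- cfg[[nm]]
    if (!is.numeric(f) || f < 0 || f > 1) {
      abort_validation("sim_config: %s must lie in [0, 1]", nm)
    }
  }
  if (cfg$n_breaks_per_transcript < 0) {
    abort_validation("sim_config: n_breaks_per_transcript must be >= 0")
  }
  if (is.null(names(cfg$conditions)) ||
      !all(c("on", "off") %in% names(cfg$conditions))) {
    abort_validation("sim_config: conditions must be named c(on=, off=)")
  }
  invisible(cfg)
}

# sample() treats a length-1 numeric x as 1:x; this keeps ranges literal.
sample_range <- function(lo, hi, n) {
  if (lo == hi) return(rep(lo, n))
  sample(seq(lo, hi), n, replace = TRUE)
}

locus_seed <- function(master, i, salt = 0L) {
  as.integer((as.numeric(master) + i * 1000003 + salt * 7919) %% 2147483647)
}

#' Generate a synthetic stranded RNA-seq dataset with planted ground truth
#'
#' See [sim_config()] for the model. Deterministic given the config seed.
#'
#' @param config A [sim_config()].
#' @return A list of class `enhansr_sim` with elements:
#'   * `annotation`: transcript table of known sense transcripts (long
#'     isoform everywhere; an additional short isoform at antisense loci);
#'   * `genes`: the long isoforms only (one per gene);
#'   * `coverage`: `coverage[[condition]]$plus` / `$minus` tracks;
#'   * `fragments`: per-condition transcript tables of fragmentized true
#'     transcripts;
#'   * `peaks`: enhancer peak tibble (`chrom,start,end,mark,condition`);
#'   * `sequences`: named character vector of antisense transcript sequences;
#'   * `truth`: per-locus tibble of planted antisense loci;
#'   * `config`, `chrom_len`.
#' @export
simulate_dataset <- function(config = sim_config()) {
  cfg <- config
  validate_sim_config(cfg)
  conds <- cfg$conditions
  pad <- 10000
  cursor <- pad
  loci <- vector("list", cfg$n_genes)
  for (i in seq_len(cfg$n_genes)) {
    loci[[i]] <- withr::with_seed(
      locus_seed(cfg$seed, i),
      make_locus(cfg, i, cursor, antisense = i <= cfg$n_antisense_loci))
    cursor <- loci[[i]]$gene_end + cfg$gene_spacing
  }
  chrom_len <- cursor + pad

  # Planted mean depth per condition x strand.
  mean_depth <- list()
  for (cd in conds) {
    mean_depth[[cd]] <- list(plus = numeric(chrom_len),
                             minus = numeric(chrom_len))
  }
  for (loc in loci) {
    for (nm in names(conds)) {
      cd <- conds[[nm]]
      frac <- if (loc$has_antisense) {
        if (nm == "on") cfg$short_isoform_fraction_on
        else cfg$short_isoform_fraction_off
      } else {
        0
      }
      e <- loc$long$exons[[1]]
      for (k in seq_len(nrow(e))) {
        idx <- (e$start[k] + 1):e$end[k]
        dep <- rep(loc$base * loc$edge_factor[k], length(idx))
        if (loc$has_antisense) {
          below <- (e$start[k] + 1):e$end[k] <= loc$boundary
          dep[below] <- dep[below] * (1 - frac)
        }
        mean_depth[[cd]]$minus[idx] <- mean_depth[[cd]]$minus[idx] + dep
      }
      if (loc$has_antisense && nm == "on") {
        idx <- (loc$as_start + 1):loc$as_end
        mean_depth[[cd]]$plus[idx] <- mean_depth[[cd]]$plus[idx] +
          cfg$antisense_depth
      }
    }
  }

  # Optional rescale to a requested library size, then noise, then N.
  tracks <- list()
  for (ci in seq_along(conds)) {
    cd <- conds[[ci]]
    tot <- sum(mean_depth[[cd]]$plus) + sum(mean_depth[[cd]]$minus)
    scale <- 1
    if (!is.null(cfg$library_size_per_condition)) {
      scale <- cfg$library_size_per_condition * cfg$read_length / tot
    }
    dp <- mean_depth[[cd]]$plus * scale
    dm <- mean_depth[[cd]]$minus * scale
    if (cfg$noise_model == "poisson") {
      dp <- withr::with_seed(locus_seed(cfg$seed, 0L, salt = ci * 2L),
                             as.numeric(stats::rpois(length(dp), dp)))
      dm <- withr::with_seed(locus_seed(cfg$seed, 0L, salt = ci * 2L + 1L),
                             as.numeric(stats::rpois(length(dm), dm)))
    }
    lib <- if (!is.null(cfg$library_size_per_condition)) {
      cfg$library_size_per_condition
    } else {
      max(1, round((sum(dp) + sum(dm)) / cfg$read_length))
    }
    tracks[[cd]] <- list(
      plus = coverage_track(cfg$chrom, "+", dp, lib, condition = cd),
      minus = coverage_track(cfg$chrom, "-", dm, lib, condition = cd))
  }

  annotation <- dplyr::bind_rows(purrr::map(loci, "models"))
  genes <- annotation[grepl("\\.L$", annotation$transcript_id), ]
  truth <- dplyr::bind_rows(purrr::map(loci, "truth_row"))
  peaks <- if (nrow(truth)) {
    tibble::tibble(chrom = cfg$chrom, start = truth$enhancer_start,
                   end = truth$enhancer_end, mark = "P300",
                   condition = truth$active_condition)
  } else {
    tibble::tibble(chrom = character(), start = numeric(), end = numeric(),
                   mark = character(), condition = character())
  }

  fragments <- list()
  for (nm in names(conds)) {
    cd <- conds[[nm]]
    frs <- list()
    for (i in seq_along(loci)) {
      loc <- loci[[i]]
      frs[[length(frs) + 1]] <- fragmentize(
        loc$long, cfg$n_breaks_per_transcript, cfg$gap_len_range,
        seed = locus_seed(cfg$seed, i, salt = 100L + which(names(conds) == nm)))
      if (loc$has_antisense && nm == "on") {
        frs[[length(frs) + 1]] <- fragmentize(
          loc$antisense,
          feasible_breaks(loc$antisense, cfg$n_breaks_per_transcript,
                          cfg$gap_len_range),
          cfg$gap_len_range,
          seed = locus_seed(cfg$seed, i, salt = 200L))
      }
    }
    fragments[[cd]] <- dplyr::bind_rows(frs)
  }

  sequences <- stats::setNames(
    purrr::map_chr(loci[purrr::map_lgl(loci, "has_antisense")], "sequence"),
    purrr::map_chr(loci[purrr::map_lgl(loci, "has_antisense")],
                   ~ .x$antisense$transcript_id))

  structure(
    list(annotation = annotation, genes = genes, coverage = tracks,
         fragments = fragments, peaks = peaks, sequences = sequences,
         truth = truth, config = cfg, chrom_len = chrom_len),
    class = "enhansr_sim")
}

# One locus: a minus-strand sense gene, optionally with a plus-strand
# antisense transcript whose 3' end defines the isoform boundary.
make_locus <- function(cfg, i, start, antisense) {
  n_ex <- sample_range(cfg$exon_count_range[1], cfg$exon_count_range[2], 1)
  ex_len <- sample_range(cfg$exon_len_range[1], cfg$exon_len_range[2], n_ex)
  in_len <- if (n_ex > 1) {
    sample_range(cfg$intron_len_range[1], cfg$intron_len_range[2], n_ex - 1)
  } else {
    integer()
  }
  starts <- start + cumsum(c(0, ex_len[-n_ex] + in_len))
  exons <- tibble::tibble(start = starts, end = starts + ex_len)
  gene_id <- sprintf("gene%02d", i)
  long <- transcript_tbl(paste0(gene_id, ".L"), cfg$chrom, "-", list(exons),
                         gene_id = gene_id)
  base <- stats::runif(1, cfg$base_expression_range[1],
                       cfg$base_expression_range[2])
  edge_factor <- rep(1, n_ex)
  edge_factor[c(1, n_ex)] <- stats::runif(2, cfg$terminal_attenuation_range[1],
                                          cfg$terminal_attenuation_range[2])
  out <- list(gene_id = gene_id, long = long, base = base,
              edge_factor = edge_factor, gene_end = max(exons$end),
              has_antisense = antisense, models = long)
  if (!antisense) {
    out$truth_row <- NULL
    return(out)
  }
  epos <- sort(unlist(purrr::map2(exons$start, exons$end,
                                  ~ seq.int(.x, .y - 1))))
  boundary <- epos[ceiling(length(epos) / 2)]
  as_len <- sample_range(cfg$antisense_len_range[1],
                         cfg$antisense_len_range[2], 1)
  as_end <- boundary
  as_start <- max(as_end - as_len, min(exons$start) + 1)
  if (as_start >= as_end) {
    abort_validation(
      "locus %d: antisense does not fit inside the gene; enlarge the gene geometry", i)
  }
  antis <- transcript_tbl(paste0(gene_id, ".AS"), cfg$chrom, "+",
                          list(tibble::tibble(start = as_start, end = as_end)),
                          gene_id = paste0(gene_id, "as"))
  short_ex <- exons %>%
    dplyr::filter(.data$end > boundary) %>%
    dplyr::mutate(start = pmax(.data$start, boundary))
  short <- transcript_tbl(paste0(gene_id, ".S"), cfg$chrom, "-",
                          list(short_ex), gene_id = gene_id)
  seq_chr <- paste(sample(c("A", "C", "G", "T"), as_end - as_start,
                          replace = TRUE), collapse = "")
  out$antisense <- antis
  out$boundary <- boundary
  out$as_start <- as_start
  out$as_end <- as_end
  out$sequence <- seq_chr
  out$models <- dplyr::bind_rows(long, short)
  out$truth_row <- tibble::tibble(
    locus = i, gene_id = gene_id,
    sense_long_id = long$transcript_id,
    sense_short_id = short$transcript_id,
    antisense_id = antis$transcript_id,
    chrom = cfg$chrom,
    as_start = as_start, as_end = as_end, as_strand = "+",
    enhancer_start = as_start - 150, enhancer_end = as_start + 150,
    active_condition = cfg$conditions[["on"]],
    boundary = boundary,
    short_isoform_fraction_on = cfg$short_isoform_fraction_on,
    short_isoform_fraction_off = cfg$short_isoform_fraction_off)
  out
}

# Largest break count (capped at `requested`) the transcript can absorb
# while keeping every fragment non-empty; short unspliced transcripts may
# support none.
feasible_breaks <- function(transcript, requested, gap_len_range) {
  margin <- gap_len_range[2] + 200
  n_epos <- sum(transcript$exons[[1]]$end - transcript$exons[[1]]$start)
  max(0, min(requested, floor((n_epos - 2 * margin) / (margin + 1))))
}

#' Split a transcript into assembly-like fragments
#'
#' Emulates a fragmented assembler output: the transcript is split at
#' `n_breaks` random internal points (chosen among exonic positions), each
#' break removing a coverage-free gap of length drawn from `gap_len_range`.
#' The resulting `n_breaks + 1` fragments are disjoint, ordered, on the
#' transcript's strand, and their union is contained in the transcript span;
#' every fragment retains at least one exonic base.
#'
#' @param transcript One-row transcript table.
#' @param n_breaks Number of internal break points.
#' @param gap_len_range Range of gap lengths (bp).
#' @param seed Optional integer seed for a deterministic split.
#' @return Transcript table of fragments with provenance pointing at the
#'   source transcript.
#' @export
fragmentize <- function(transcript, n_breaks, gap_len_range, seed = NULL) {
  stopifnot(nrow(transcript) == 1)
  if (n_breaks == 0) return(transcript)
  run <- function() {
    e <- transcript$exons[[1]]
    epos <- sort(unlist(purrr::map2(e$start, e$end, ~ seq.int(.x, .y - 1))))
    margin <- gap_len_range[2] + 200
    if (length(epos) - margin < margin + 1) {
      abort_validation("n_breaks too large for transcript '%s'",
                       transcript$transcript_id)
    }
    cand_idx <- seq.int(margin + 1, length(epos) - margin)
    if (length(cand_idx) < n_breaks) {
      abort_validation("n_breaks too large for transcript '%s'",
                       transcript$transcript_id)
    }
    # Greedy pick of break indices separated (in exonic space) by > margin,
    # so no fragment loses all its exonic bases to a gap.
    picked <- integer()
    for (j in sample(cand_idx)) {
      if (all(abs(j - picked) > margin)) picked <- c(picked, j)
      if (length(picked) == n_breaks) break
    }
    if (length(picked) < n_breaks) {
      abort_validation("n_breaks too large for transcript '%s'",
                       transcript$transcript_id)
    }
    breaks <- epos[sort(picked)]
    gaps <- sample_range(gap_len_range[1], gap_len_range[2], n_breaks)
    piece_start <- c(transcript$start, breaks + gaps)
    piece_end <- c(breaks, transcript$end)
    frs <- purrr::map(seq_len(n_breaks + 1), function(k) {
      pe <- e %>%
        dplyr::filter(.data$end > piece_start[k],
                      .data$start < piece_end[k]) %>%
        dplyr::mutate(start = pmax(.data$start, piece_start[k]),
                      end = pmin(.data$end, piece_end[k]))
      pe
    })
    transcript_tbl(
      transcript_id = sprintf("%s.f%d", transcript$transcript_id,
                              seq_len(n_breaks + 1)),
      chrom = transcript$chrom, strand = transcript$strand,
      exons = frs, gene_id = transcript$gene_id,
      provenance = rep(list(transcript$transcript_id), n_breaks + 1))
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Write a simulated dataset to a directory
#'
#' Writes the standard interchange files: BED12 annotation and per-condition
#' fragment calls, per-condition/strand BedGraph coverage, a peak table, the
#' antisense transcript FASTA, the truth table, and a flat key=value config
#' file.
#'
#' @param sim An `enhansr_sim` from [simulate_dataset()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(dir, ...)
  write_features(sim$annotation, p("annotation.bed"))
  for (cd in names(sim$coverage)) {
    write_bedgraph(sim$coverage[[cd]]$plus,
                   p(sprintf("coverage_%s_plus.bedgraph", cd)))
    write_bedgraph(sim$coverage[[cd]]$minus,
                   p(sprintf("coverage_%s_minus.bedgraph", cd)))
    write_features(sim$fragments[[cd]], p(sprintf("fragments_%s.bed", cd)))
  }
  readr::write_tsv(sim$peaks, p("peaks.tsv"))
  readr::write_tsv(sim$truth, p("truth.tsv"))
  if (length(sim$sequences)) {
    write_transcript_fasta(sim$sequences, p("transcripts.fa"))
  }
  cfg <- sim$config
  scalar <- purrr::map_chr(cfg, ~ paste(format(.x, scientific = FALSE,
                                               trim = TRUE), collapse = ","))
  readr::write_lines(sprintf("%s=%s", names(scalar), scalar), p("config.txt"))
  lib <- purrr::map_dbl(sim$coverage, ~ .x$plus$library_size)
  readr::write_lines(sprintf("library_size_%s=%s", names(lib),
                             format(lib, scientific = FALSE, trim = TRUE)),
                     p("library_sizes.txt"))
  invisible(dir)
}

#' Read a dataset directory back into pipeline form
#'
#' Inverse of [write_dataset()]: rebuilds the annotation, per-condition
#' stranded coverage, fragment calls, peaks, sequences and (when present)
#' truth from their interchange files. BED carries no gene column, so gene
#' ids are recovered from the `gene.isoform` naming convention of the
#' transcript ids (everything before the last dot).
#'
#' @param dir Directory written by [write_dataset()] (or assembled by hand
#'   with the same file names).
#' @return A list shaped like [simulate_dataset()] output.
#' @export
read_dataset <- function(dir) {
  p <- function(...) file.path(dir, ...)
  libs_raw <- readr::read_lines(p("library_sizes.txt"))
  libs <- stats::setNames(
    as.numeric(sub("^.*=", "", libs_raw)),
    sub("^library_size_", "", sub("=.*$", "", libs_raw)))
  annotation <- read_features(p("annotation.bed"))
  annotation$gene_id <- sub("\\.[^.]*$", "", annotation$transcript_id)
  coverage <- purrr::map(stats::setNames(names(libs), names(libs)),
                         function(cd) {
    tr <- read_stranded_coverage(p(sprintf("coverage_%s_plus.bedgraph", cd)),
                                 p(sprintf("coverage_%s_minus.bedgraph", cd)),
                                 library_size = libs[[cd]], condition = cd)
    tr
  })
  fragments <- purrr::map(stats::setNames(names(libs), names(libs)),
                          function(cd) {
    f <- p(sprintf("fragments_%s.bed", cd))
    if (file.exists(f)) read_features(f) else NULL
  })
  peaks <- if (file.exists(p("peaks.tsv"))) {
    readr::read_tsv(p("peaks.tsv"), show_col_types = FALSE)
  } else {
    tibble::tibble(chrom = character(), start = numeric(), end = numeric(),
                   mark = character(), condition = character())
  }
  truth <- if (file.exists(p("truth.tsv"))) {
    readr::read_tsv(p("truth.tsv"), show_col_types = FALSE)
  } else {
    NULL
  }
  sequences <- if (file.exists(p("transcripts.fa"))) {
    read_transcript_fasta(p("transcripts.fa"))
  } else {
    character()
  }
  genes <- annotation %>%
    dplyr::mutate(.len = exonic_length(annotation)) %>%
    dplyr::group_by(.data$gene_id) %>%
    dplyr::slice_max(.data$.len, n = 1, with_ties = FALSE) %>%
    dplyr::ungroup() %>%
    dplyr::select(-".len")
  chrom_len <- max(purrr::map_dbl(coverage,
                                  ~ .x$plus$offset + length(.x$plus$depth)))
  list(annotation = annotation, genes = genes, coverage = coverage,
       fragments = fragments, peaks = peaks, sequences = sequences,
       truth = truth, chrom_len = chrom_len)
}

#' @export
print.enhansr_sim <- function(x, ...) {
  cat(sprintf(
    "<enhansr_sim> %d genes, %d antisense loci on %s (%d bp), conditions %s\n",
    nrow(x$genes), nrow(x$truth), x$config$chrom, as.integer(x$chrom_len),
    paste(x$config$conditions, collapse = "/")))
  invisible(x)
}
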