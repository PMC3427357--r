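#' Plot internal vs outer adjacent-exon percentile differences
#'
#' Boxplots of the absolute RPKM-percentile differences used to calibrate the
#' merge rule, with the chosen thresholds overlaid.
#'
#' @param object A [calibrate_merge()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.merge_calibration <- function(object, ...) {
  df <- tidy(object)
  thr <- tibble::tibble(name = names(object$thresholds),
                        value = unname(object$thresholds))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pair_type,
                                   y = .data$abs_percentile_diff)) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::geom_hline(data = thr,
                        ggplot2::aes(yintercept = .data$value,
                                     linetype = .data$name),
                        colour = "grey40") +
    ggplot2::labs(x = "adjacent exon pair type",
                  y = "|RPKM percentile difference|",
                  linetype = "internal-pair\nquantile") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Coverage around one locus, stranded and per condition
#'
#' @param sim An `enhansr_sim` dataset.
#' @param locus Truth-table locus number to display.
#' @param pad Extra bp shown either side of the gene span.
#' @return A ggplot object with one facet per condition; positive depth is
#'   the plus strand, negated depth the minus strand.
#' @export
plot_locus <- function(sim, locus = 1, pad = 2000) {
  tr <- sim$truth[sim$truth$locus == locus, ]
  if (nrow(tr) != 1) abort_validation("no such locus in the truth table")
  gene <- sim$genes[sim$genes$gene_id == tr$gene_id, ]
  win <- c(max(0, gene$start - pad), min(sim$chrom_len, gene$end + pad))
  pos <- seq.int(win[1], win[2] - 1)
  df <- purrr::map_dfr(names(sim$coverage), function(cd) {
    dplyr::bind_rows(
      tibble::tibble(condition = cd, strand = "+", pos = pos,
                     depth = track_depth(sim$coverage[[cd]]$plus,
                                         win[1], win[2])),
      tibble::tibble(condition = cd, strand = "-", pos = pos,
                     depth = -track_depth(sim$coverage[[cd]]$minus,
                                          win[1], win[2])))
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pos, y = .data$depth,
                                   fill = .data$strand)) +
    ggplot2::geom_col(width = 1) +
    ggplot2::geom_vline(xintercept = tr$boundary, linetype = "dashed") +
    ggplot2::annotate("rect", xmin = tr$enhancer_start,
                      xmax = tr$enhancer_end, ymin = -Inf, ymax = Inf,
                      alpha = 0.15, fill = "darkgreen") +
    ggplot2::facet_wrap(~condition, ncol = 1) +
    ggplot2::scale_fill_manual(values = c(`+` = "#2166ac", `-` = "#d6604d")) +
    ggplot2::labs(x = sprintf("%s position (bp)", gene$chrom),
                  y = "read depth (+ strand up, - strand down)",
                  title = sprintf("locus %d: %s / %s", locus, tr$gene_id,
                                  tr$antisense_id)) +
    ggplot2::theme_minimal()
}

#' Isoform-shift scores with permutation significance
#'
#' @param shift Shift tibble from [run_pipeline()] (or rows of
#'   [shift_pvalue()] results).
#' @param alpha Significance level used for the fill (default 0.05).
#' @return A ggplot object.
#' @export
plot_shift_scores <- function(shift, alpha = 0.05) {
  df <- shift %>%
    dplyr::mutate(sig = ifelse(.data$pvalue <= alpha,
                               sprintf("p <= %g", alpha),
                               sprintf("p > %g", alpha)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$gene_id, y = .data$score,
                                   fill = .data$sig)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 0) +
    ggplot2::labs(x = NULL, fill = NULL,
                  y = "isoform-shift score  log2(r_off) - log2(r_on)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
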