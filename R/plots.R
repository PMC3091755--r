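#' Xist QC scatter plot
#'
#' Scatter of the two Xist probe signals per array, coloured by recorded
#' sex, with flagged (sex-discordant) arrays highlighted and the decision
#' thresholds drawn. With a near-binary Xist signal the sexes occupy
#' opposite quadrants and mislabeled arrays land in the wrong one.
#'
#' @param qc A `qc_report` from [xist_sex_check()].
#' @return A ggplot object.
#' @export
plot_xist_qc <- function(qc) {
  stopifnot(inherits(qc, "qc_report"))
  ids <- qc$thresholds$probe_id
  d <- tidy(qc)
  if (length(ids) < 2) {
    p <- ggplot2::ggplot(d, ggplot2::aes(
      x = .data$sex, y = .data[[ids[1]]], colour = .data$sex,
      shape = .data$flagged)) +
      ggplot2::geom_jitter(width = 0.15, height = 0) +
      ggplot2::geom_hline(yintercept = qc$thresholds$threshold[1],
                          linetype = 2) +
      ggplot2::labs(y = paste0("log2 intensity (", ids[1], ")"))
  } else {
    p <- ggplot2::ggplot(d, ggplot2::aes(
      x = .data[[ids[1]]], y = .data[[ids[2]]], colour = .data$sex,
      shape = .data$flagged)) +
      ggplot2::geom_point(size = 2) +
      ggplot2::geom_vline(xintercept = qc$thresholds$threshold[1],
                          linetype = 2) +
      ggplot2::geom_hline(yintercept = qc$thresholds$threshold[2],
                          linetype = 2) +
      ggplot2::labs(x = paste0("log2 intensity (", ids[1], ")"),
                    y = paste0("log2 intensity (", ids[2], ")"))
  }
  p + ggplot2::scale_shape_manual(values = c(`FALSE` = 16, `TRUE` = 4)) +
    ggplot2::labs(colour = "recorded sex", shape = "flagged") +
    ggplot2::theme_minimal()
}

#' Heatmap of significant probes
#'
#' Tile plot of the mean-centered expression of significant probes across
#' the balanced arrays, samples ordered females first; yellow-blue encodes
#' deviation from each probe's overall mean.
#'
#' @param es The balanced [expr_set].
#' @param hits A `sexbias_result`.
#' @return A ggplot object.
#' @export
plot_sexbias_heatmap <- function(es, hits) {
  m <- heatmap_matrix(es, hits)
  ord <- order(es$samples$sex, es$samples$sample_id)
  d <- tibble::tibble(
    probe_id = rep(rownames(m), times = ncol(m)),
    sample_id = rep(colnames(m), each = nrow(m)),
    value = as.vector(m))
  d$sample_id <- factor(d$sample_id,
                        levels = es$samples$sample_id[ord])
  d$probe_id <- factor(d$probe_id, levels = rev(rownames(m)))
  ggplot2::ggplot(d, ggplot2::aes(.data$sample_id, .data$probe_id,
                                  fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "blue3", mid = "black",
                                  high = "yellow") +
    ggplot2::labs(x = NULL, y = NULL, fill = "centered\nlog2") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' qPCR female/male ratio bar chart
#'
#' Mean female expression relative to mean male expression per gene, with
#' standard-error bars and significance stars.
#'
#' @param object A `qpcr_result` from [qpcr_analysis()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.qpcr_result <- function(object, ...) {
  d <- dplyr::mutate(object,
                     rel_f = .data$mean_f / .data$mean_m,
                     rel_sem = .data$sem_f / .data$mean_m)
  ggplot2::ggplot(d, ggplot2::aes(.data$gene, .data$rel_f)) +
    ggplot2::geom_col(fill = "gold2") +
    ggplot2::geom_hline(yintercept = 1, linetype = 2, colour = "steelblue") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$rel_f - .data$rel_sem,
                                        ymax = .data$rel_f + .data$rel_sem),
                           width = 0.3) +
    ggplot2::geom_text(ggplot2::aes(label = .data$stars,
                                    y = .data$rel_f + .data$rel_sem),
                       vjust = -0.5) +
    ggplot2::scale_y_log10() +
    ggplot2::facet_wrap(ggplot2::vars(.data$tissue)) +
    ggplot2::labs(x = NULL, y = "female / male expression") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Domain peak-coverage bar chart
#'
#' Inside vs flanking coverage per region, visualising repressive-mark
#' depletion over escapee domains against an X-inactivated control.
#'
#' @param coverage Output of [domain_peak_coverage()] with a `region`
#'   column.
#' @return A ggplot object.
#' @export
plot_domain_coverage <- function(coverage) {
  d <- tidyr::pivot_longer(coverage, c("inside", "flank_mean"),
                           names_to = "where", values_to = "coverage")
  ggplot2::ggplot(d, ggplot2::aes(.data$region, .data$coverage,
                                  fill = .data$where)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "peak coverage fraction", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
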