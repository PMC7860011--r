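#' Heatmap of top differentially methylated probes
#'
#' Tile heatmap of beta values with samples and probes in centroid-linkage
#' cluster order (see [cluster_heatmap_order()]); sample labels are
#' colored by group.
#'
#' @param beta Samples x probes beta matrix.
#' @param order_result Output of [cluster_heatmap_order()].
#' @param groups Optional per-sample labels for the annotation strip.
#' @return A ggplot object.
#' @export
plot_dmp_heatmap <- function(beta, order_result, groups = NULL) {
  x <- beta[order_result$sample_order, order_result$probe_order,
            drop = FALSE]
  d <- tibble::as_tibble(as.data.frame.table(x, responseName = "beta"))
  names(d)[1:2] <- c("sample_id", "probe_id")
  d$sample_id <- factor(d$sample_id, levels = order_result$sample_order)
  d$probe_id <- factor(d$probe_id, levels = order_result$probe_order)
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$sample_id,
                                       y = .data$probe_id,
                                       fill = .data$beta)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "#f7f7f7",
                                  high = "#b2182b", midpoint = 0.5,
                                  limits = c(0, 1), name = "beta") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank(),
                   axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
  p
}

#' Linear-discriminant classification strip plot
#'
#' LD1 values per sample with the decision threshold and shaded
#' high/low-confidence regions (class probability >= 0.95 dark,
#' > 0.5 bright), the standard display for a two-class CpG-panel
#' classifier.
#'
#' @param predictions Tibble from [lda_predict()].
#' @param model The `panel_model` that produced them.
#' @return A ggplot object.
#' @export
plot_ld1 <- function(predictions, model) {
  m <- sort(model$proj_means)
  # probability-0.95 boundaries on the LD1 scale (equal priors geometry)
  off <- log(0.95 / 0.05) / (m[2] - m[1])
  thr <- model$threshold
  d <- dplyr::arrange(predictions, .data$ld1)
  d$rank <- seq_len(nrow(d))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$ld1, y = .data$rank)) +
    ggplot2::annotate("rect", xmin = -Inf, xmax = thr - off, ymin = -Inf,
                      ymax = Inf, fill = "#c6dbef", alpha = 0.8) +
    ggplot2::annotate("rect", xmin = thr + off, xmax = Inf, ymin = -Inf,
                      ymax = Inf, fill = "#fcbba1", alpha = 0.8) +
    ggplot2::geom_vline(xintercept = thr, linetype = 2) +
    ggplot2::geom_point(ggplot2::aes(color = .data$class), size = 2) +
    ggplot2::geom_text(ggplot2::aes(label = .data$sample_id), hjust = -0.3,
                       size = 2.5) +
    ggplot2::labs(x = "LD1", y = NULL, color = "predicted") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}

#' Genome-wide copy-number profile plot
#'
#' Per-probe log2 copy ratios with segment means overlaid, faceted by
#' chromosome, with the gain/loss call threshold marked.
#'
#' @param profile Output of [cna_profile()].
#' @param threshold Call threshold drawn as guide lines (default 0.5).
#' @return A ggplot object.
#' @export
plot_cna_profile <- function(profile, threshold = 0.5) {
  r <- profile$ratios
  r$chr <- factor(r$chr, levels = unique(r$chr))
  s <- profile$segments
  s$chr <- factor(s$chr, levels = levels(r$chr))
  ggplot2::ggplot(r, ggplot2::aes(x = .data$pos / 1e6,
                                  y = .data$log2_ratio)) +
    ggplot2::geom_point(size = 0.3, alpha = 0.4, color = "grey40") +
    ggplot2::geom_segment(data = s,
                          ggplot2::aes(x = .data$start / 1e6,
                                       xend = .data$end / 1e6,
                                       y = .data$seg_log2,
                                       yend = .data$seg_log2),
                          color = "#b2182b", linewidth = 0.9) +
    ggplot2::geom_hline(yintercept = c(-threshold, threshold),
                        linetype = 3) +
    ggplot2::facet_grid(. ~ chr, scales = "free_x", space = "free_x") +
    ggplot2::labs(x = "position (Mb)", y = "log2 copy ratio") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   panel.spacing.x = ggplot2::unit(0, "pt"))
}

#' Epigenetic vs chronological age plot
#'
#' One line per patient from chronological to epigenetic age, faceted by
#' group; rising lines mark samples with accelerated epigenetic aging.
#'
#' @param results Age tibble from [compute_epigenetic_age()].
#' @param groups Per-sample group labels.
#' @return A ggplot object.
#' @export
plot_age_results <- function(results, groups) {
  d <- tidyr::pivot_longer(dplyr::mutate(results, group = groups),
                           c("ca", "ea"), names_to = "kind",
                           values_to = "years")
  d$kind <- factor(d$kind, levels = c("ca", "ea"),
                   labels = c("chronological", "epigenetic"))
  d$accelerated <- rep(results$delta > 0, each = 2)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$kind, y = .data$years,
                                  group = .data$sample_id,
                                  color = .data$accelerated)) +
    ggplot2::geom_line(alpha = 0.6) +
    ggplot2::geom_point(size = 1.5) +
    ggplot2::facet_wrap(~group) +
    ggplot2::labs(x = NULL, y = "age (years)") +
    ggplot2::theme_minimal()
}
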