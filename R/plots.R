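#' Plot a UMAP embedding colored by cluster
#'
#' @param embedding tibble from [embed_cells()].
#' @param clusters optional `mpt_clusters` or assignment tibble to color
#'   points by cluster and shape by role.
#' @return A ggplot object.
#' @export
plot_embedding <- function(embedding, clusters = NULL) {
  df <- embedding
  if (!is.null(clusters)) {
    df <- left_join(df, cluster_assignment(clusters), by = "cell_id")
    df$cluster <- factor(df$cluster)
    p <- ggplot2::ggplot(df, ggplot2::aes(.data$UMAP1, .data$UMAP2,
                                          colour = .data$cluster,
                                          shape = .data$role))
  } else {
    p <- ggplot2::ggplot(df, ggplot2::aes(.data$UMAP1, .data$UMAP2))
  }
  p + ggplot2::geom_point(size = 0.6, alpha = 0.7) +
    ggplot2::theme_minimal() +
    ggplot2::labs(title = "UMAP embedding of single-cell genotypes")
}

#' Heatmap of cluster consensus genotypes
#'
#' @param profiles an `mpt_profiles` tibble.
#' @return A ggplot object (clusters x variants, fill = genotype code).
#' @export
plot_clone_heatmap <- function(profiles) {
  df <- profiles
  df$consensus_ngt <- factor(df$consensus_ngt, levels = 0:2,
                             labels = c("ref", "het", "hom"))
  ggplot2::ggplot(df, ggplot2::aes(.data$variant_id,
                                   factor(.data$cluster),
                                   fill = .data$consensus_ngt)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_manual(
      values = c(ref = "grey90", het = "#7bafd4", hom = "#1f4e79"),
      na.value = "white", name = "genotype"
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       size = 6)) +
    ggplot2::labs(x = "variant", y = "cluster",
                  title = "Cluster consensus genotypes")
}

#' Cluster copy-number profile plot
#'
#' @param cluster_cn an `mpt_cluster_cn` tibble from
#'   [summarize_cluster_cn()].
#' @return A ggplot object of per-amplicon log2 median ratios by cluster.
#' @export
plot_cluster_cn <- function(cluster_cn) {
  ggplot2::ggplot(cluster_cn,
                  ggplot2::aes(.data$amplicon_id, .data$log2_ratio,
                               colour = .data$call)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::facet_wrap(~cluster, ncol = 1) +
    ggplot2::scale_colour_manual(
      values = c(gain = "#c0392b", neutral = "grey60", loss = "#2e86c1")
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank()) +
    ggplot2::labs(x = "amplicon", y = "log2 median copy ratio")
}

#' Downsampling sensitivity plot
#'
#' @param x an `mpt_downsample` tibble.
#' @return A ggplot of detected cluster count against level.
#' @export
plot_downsample <- function(x) {
  med <- glance(x)
  ggplot2::ggplot(x, ggplot2::aes(factor(.data$level), .data$k_detected)) +
    ggplot2::geom_jitter(width = 0.15, height = 0.05, alpha = 0.5) +
    ggplot2::geom_line(data = med,
                       ggplot2::aes(factor(.data$level), .data$median_k,
                                    group = 1), colour = "#c0392b") +
    ggplot2::scale_x_discrete(limits = rev(levels(factor(x$level)))) +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = "downsampling level", y = "clusters detected")
}
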