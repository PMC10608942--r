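#' Stacked-bar plot of a MAG abundance profile
#'
#' One stacked bar per condition; MAGs below `min_pct` in every condition are
#' lumped into an "other" slice to keep the legend readable, and the unbinned
#' fraction is always shown as its own slice.
#'
#' @param object A `mag_abundance` profile.
#' @param min_pct Lumping threshold in percent.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mag_abundance
#' @export
autoplot.mag_abundance <- function(object, min_pct = 1, ...) {
  df <- as_tibble(object)
  keep <- df %>% group_by(.data$mag_id) %>%
    summarise(mx = max(.data$abundance_pct), .groups = "drop") %>%
    filter(.data$mx >= min_pct | .data$mag_id == UNBINNED) %>%
    pull(.data$mag_id)
  df <- df %>%
    mutate(slice = ifelse(.data$mag_id %in% keep, .data$mag_id,
                          "other (< threshold)")) %>%
    group_by(.data$condition_id, .data$slice) %>%
    summarise(abundance_pct = sum(.data$abundance_pct), .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$condition_id,
                                   y = .data$abundance_pct,
                                   fill = .data$slice)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "condition", y = "relative abundance [%]",
                  fill = NULL,
                  title = paste0(attr(object, "layer") %||% "",
                                 " MAG abundance")) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Heatmap of an enzyme-level summary
#'
#' Tile plot of log10-scaled spectral counts per enzyme and condition,
#' faceted by anaerobic-digestion category, with the AGCN printed in each
#' tile.
#'
#' @param enzyme_table Output of [enzyme_level_summary()].
#' @return A ggplot object.
#' @export
plot_enzyme_summary <- function(enzyme_table) {
  ggplot2::ggplot(enzyme_table,
                  ggplot2::aes(x = .data$condition_id,
                               y = .data$enzyme_label,
                               fill = log10(.data$spectral_count + 1))) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.1f", .data$agcn)),
                       size = 2.6) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$ad_category),
                        scales = "free_y", space = "free_y") +
    ggplot2::scale_fill_viridis_c(name = "log10(spectra + 1)") +
    ggplot2::labs(x = "condition", y = NULL) +
    ggplot2::theme_minimal()
}

#' Clustered heatmap of taxon-parameter correlations
#'
#' Tile plot of the Pearson correlation matrix from
#' [metadata_correlations()], with rows and columns ordered by
#' average-linkage hierarchical clustering on Euclidean distance (a purely
#' cosmetic ordering; `NA` correlations are treated as 0 for clustering
#' only).
#'
#' @param correlations Output of [metadata_correlations()].
#' @return A ggplot object.
#' @export
plot_metadata_correlations <- function(correlations) {
  wide <- tidyr::pivot_wider(correlations, names_from = "parameter",
                             values_from = "r")
  m <- as.matrix(wide[, -1])
  rownames(m) <- wide$taxon_id
  m0 <- m
  m0[is.na(m0)] <- 0
  row_ord <- if (nrow(m0) > 2) {
    stats::hclust(stats::dist(m0), method = "average")$order
  } else seq_len(nrow(m0))
  col_ord <- if (ncol(m0) > 2) {
    stats::hclust(stats::dist(t(m0)), method = "average")$order
  } else seq_len(ncol(m0))
  df <- correlations %>%
    mutate(taxon_id = factor(.data$taxon_id, levels = rownames(m)[row_ord]),
           parameter = factor(.data$parameter, levels = colnames(m)[col_ord]))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$parameter, y = .data$taxon_id,
                                   fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "Pearson r") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
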