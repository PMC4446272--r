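#' Volcano plot of a differential-expression result
#'
#' @param object A `trilayer_de` object.
#' @param fdr_cutoff Highlighting threshold (default 0.05).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.trilayer_de <- function(object, fdr_cutoff = 0.05, ...) {
  df <- as_tibble(object) |>
    mutate(status = dplyr::case_when(
      .data$fdr < fdr_cutoff & .data$logfc > 0 ~ "up",
      .data$fdr < fdr_cutoff & .data$logfc < 0 ~ "down",
      TRUE ~ "ns"))
  ggplot2::ggplot(df, ggplot2::aes(.data$logfc, -log10(.data$p),
                                   colour = .data$status)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::scale_colour_manual(
      values = c(up = "#b2182b", down = "#2166ac", ns = "grey70")) +
    ggplot2::labs(x = "log2 fold change (HFD - LFD)",
                  y = expression(-log[10] ~ p), colour = NULL) +
    ggplot2::theme_minimal()
}

#' Bar plot of top enriched gene sets
#'
#' Shows the signed node score (-log10 p, negative for downregulated sets)
#' of the most significant sets.
#'
#' @param object A `trilayer_gsea` object (classified records preferred).
#' @param n_top Number of sets to show (default 20).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.trilayer_gsea <- function(object, n_top = 20, ...) {
  df <- as_tibble(object)
  if (!"node_score" %in% names(df)) {
    df$node_score <- -log10(df$p) * sign(df$es)
    df$direction <- ifelse(df$es >= 0, "up", "down")
  }
  df <- df |> arrange(.data$p) |> head(n_top)
  ggplot2::ggplot(df, ggplot2::aes(.data$node_score,
                                   stats::reorder(.data$set,
                                                  abs(.data$node_score)),
                                   fill = .data$direction)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(up = "#b2182b", down = "#2166ac",
                                          both = "#1b7837", none = "grey70")) +
    ggplot2::labs(x = expression(signed ~ -log[10] ~ p), y = NULL,
                  fill = "direction") +
    ggplot2::theme_minimal()
}

#' Layered layout plot of a three-layer network
#'
#' Physiology, regulator and process layers are drawn as columns; edge width
#' follows the similarity coefficient and node colour the direction call.
#'
#' @param object A `trilayer_network` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.trilayer_network <- function(object, ...) {
  nodes <- object$nodes
  if (!nrow(nodes)) {
    return(ggplot2::ggplot() + ggplot2::theme_void() +
             ggplot2::labs(title = "empty network"))
  }
  layer_x <- c(physiology = 0, regulator = 1, process = 2)
  nodes <- nodes |>
    group_by(.data$layer) |>
    mutate(x = layer_x[[unique(.data$layer)]],
           y = (row_number() - 1) / max(1L, n() - 1L)) |>
    ungroup()
  edges <- object$edges |>
    left_join(select(nodes, "id", x0 = "x", y0 = "y"),
              by = c(from = "id")) |>
    left_join(select(nodes, "id", x1 = "x", y1 = "y"),
              by = c(to = "id"))
  p <- ggplot2::ggplot()
  if (nrow(edges)) {
    p <- p + ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(x = .data$x0, y = .data$y0, xend = .data$x1,
                   yend = .data$y1, linewidth = .data$coefficient),
      colour = "grey75", alpha = 0.7) +
      ggplot2::scale_linewidth(range = c(0.2, 1.2), guide = "none")
  }
  p +
    ggplot2::geom_point(
      data = nodes,
      ggplot2::aes(.data$x, .data$y, colour = .data$direction,
                   size = .data$set_size)) +
    ggplot2::scale_colour_manual(
      values = c(up = "#b2182b", down = "#2166ac", both = "#1b7837",
                 none = "grey50")) +
    ggplot2::scale_x_continuous(breaks = unname(layer_x),
                                labels = names(layer_x),
                                limits = c(-0.3, 2.3)) +
    ggplot2::labs(x = NULL, y = NULL, colour = "direction",
                  size = "gene-set size") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank(),
                   panel.grid = ggplot2::element_blank())
}

#' Running-sum plot for one gene set
#'
#' @param ranked Output of [rank_genes()].
#' @param genes Gene set to trace.
#' @param weight_exponent See [enrichment_score()].
#' @return A ggplot object showing the running sum with hit positions marked.
#' @export
plot_running_sum <- function(ranked, genes, weight_exponent = 1) {
  es <- enrichment_score(ranked, genes, weight_exponent)
  df <- tibble(rank = seq_along(es$running_sum), running_sum = es$running_sum)
  hits <- tibble(rank = which(ranked$gene %in% genes))
  ggplot2::ggplot(df, ggplot2::aes(.data$rank, .data$running_sum)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey70") +
    ggplot2::geom_line(colour = "#1b7837") +
    ggplot2::geom_rug(data = hits, ggplot2::aes(x = .data$rank),
                      inherit.aes = FALSE, sides = "b", length = ggplot2::unit(0.03, "npc")) +
    ggplot2::labs(x = "rank", y = "running enrichment sum",
                  subtitle = sprintf("ES = %.3f", es$es)) +
    ggplot2::theme_minimal()
}
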