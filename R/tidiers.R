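#' Tidy a differential-expression result
#'
#' @param x A `trilayer_de` object.
#' @param ... Unused.
#' @return A tibble with broom-style columns `gene`, `estimate` (log2 fold
#'   change), `statistic`, `p.value`, `q.value`.
#' @export
tidy.trilayer_de <- function(x, ...) {
  tibble(gene = x$gene, estimate = x$logfc, statistic = x$t,
         p.value = x$p, q.value = x$fdr)
}

#' @rdname tidy.trilayer_de
#' @export
glance.trilayer_de <- function(x, ...) {
  tibble(n_genes = nrow(x),
         n_de = sum(x$fdr < 0.05, na.rm = TRUE),
         prior_df = attr(x, "prior_df"),
         prior_var = attr(x, "prior_var"),
         n_hfd = attr(x, "n_hfd"),
         n_lfd = attr(x, "n_lfd"),
         timepoint = attr(x, "timepoint"))
}

#' Tidy an enrichment result
#'
#' @param x A `trilayer_gsea` object.
#' @param ... Unused.
#' @return The records without the list-column, with broom-style `p.value`
#'   and `q.value` names.
#' @export
tidy.trilayer_gsea <- function(x, ...) {
  out <- as_tibble(x) |> select(-"leading_edge")
  rename(out, p.value = "p", q.value = "q")
}

#' @rdname tidy.trilayer_gsea
#' @export
glance.trilayer_gsea <- function(x, ...) {
  tibble(n_sets = nrow(x),
         n_significant = sum(x$p < 0.05),
         n_perm = attr(x, "n_perm"))
}

#' Tidy a regulon-enrichment result
#'
#' @param x A `trilayer_regulons` object.
#' @param ... Unused.
#' @return The records without the list-column.
#' @export
tidy.trilayer_regulons <- function(x, ...) {
  as_tibble(x) |> select(-dplyr::any_of(c("de_targets", "targets")))
}

#' @rdname tidy.trilayer_regulons
#' @export
glance.trilayer_regulons <- function(x, ...) {
  tibble(n_tfs = nrow(x),
         n_significant = sum(x$significant),
         n_clusters = if ("cluster" %in% names(x) && nrow(x))
           max(x$cluster) else NA_integer_,
         n_universe = attr(x, "n_universe"),
         n_de_genes = attr(x, "n_de_genes"))
}

#' Tidy a physiology-correlation result
#'
#' @param x A `trilayer_physio` object.
#' @param ... Unused.
#' @return One row per (parameter, gene) pair with `rho` and `p.value`.
#' @export
tidy.trilayer_physio <- function(x, ...) {
  out <- as_tibble(x) |>
    select("parameter", "genes") |>
    tidyr::unnest("genes")
  if (!nrow(out)) {
    return(tibble(parameter = character(), gene = character(),
                  rho = double(), p.value = double()))
  }
  rename(out, p.value = "p")
}

#' @rdname tidy.trilayer_physio
#' @export
glance.trilayer_physio <- function(x, ...) {
  tibble(n_parameters = nrow(x),
         n_significant = sum(x$significant),
         rho_cutoff = attr(x, "rho_cutoff"),
         alpha = attr(x, "alpha"))
}

#' Tidy a three-layer network
#'
#' @param x A `trilayer_network` object.
#' @param ... Unused.
#' @return The edge tibble (`from`, `to`, `relationship`, `overlap`,
#'   `coefficient`).
#' @export
tidy.trilayer_network <- function(x, ...) {
  x$edges
}

#' @rdname tidy.trilayer_network
#' @export
glance.trilayer_network <- function(x, ...) {
  topology_stats(x)$network
}
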