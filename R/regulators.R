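#' Regulon enrichment among differentially expressed genes
#'
#' For every transcription factor, tests whether its target genes are
#' over-represented among the differentially expressed genes (FDR below
#' `fdr_cutoff`) with a one-sided hypergeometric test over the tested-gene
#' universe, and scores the direction of regulation with the activation
#' z-score
#' \deqn{z = (n_{up} - n_{down}) / \sqrt{n_{up} + n_{down}},}
#' where \eqn{n_{up}}/\eqn{n_{down}} count differentially expressed targets
#' with positive/negative log fold change. The activation score is
#' \eqn{-\log_{10}(p) \cdot \mathrm{sign}(z)}. A regulon with no
#' differentially expressed target has `z = 0` (flagged via `z_defined`).
#'
#' @param de A `trilayer_de` result; its genes define the universe.
#' @param regulons Named list of target-gene vectors (e.g. from
#'   [read_gmt()]).
#' @param fdr_cutoff FDR threshold defining the differentially expressed gene
#'   list (default 0.05).
#' @param p_cutoff Significance threshold for the `significant` flag
#'   (default 0.05, nominal).
#' @return A `trilayer_regulons` tibble sorted by `p`: `tf`, `n_targets`
#'   (targets in universe), `n_de`, `n_up`, `n_down`, `p`, `z`, `z_defined`,
#'   `activation_score`, `significant`, `de_targets` (list-column).
#' @export
regulon_enrichment <- function(de, regulons, fdr_cutoff = 0.05,
                               p_cutoff = 0.05) {
  stopifnot(is.data.frame(de), all(c("gene", "logfc", "fdr") %in% names(de)))
  if (!length(regulons)) abort("`regulons` is empty.")
  if (is.null(names(regulons)) || anyDuplicated(names(regulons))) {
    abort("`regulons` must have unique TF names.")
  }
  universe <- de$gene
  if (!length(universe)) abort("empty gene universe.")
  de_genes <- de$gene[!is.na(de$fdr) & de$fdr < fdr_cutoff]
  sign_up <- de$gene[de$gene %in% de_genes & de$logfc > 0]
  N <- length(universe)
  m <- length(de_genes)

  rows <- imap(regulons, function(targets, tf) {
    targ <- unique(targets[targets %in% universe])
    k <- length(targ)
    det <- targ[targ %in% de_genes]
    ov <- length(det)
    p <- if (k == 0L) 1 else phyper(ov - 1L, m, N - m, k, lower.tail = FALSE)
    n_up <- sum(det %in% sign_up)
    n_down <- ov - n_up
    z <- if (ov > 0L) (n_up - n_down) / sqrt(ov) else 0
    tibble(tf = tf, n_targets = k, n_de = ov, n_up = n_up, n_down = n_down,
           p = p, z = z, z_defined = ov > 0L,
           activation_score = -log10(p) * sign(z),
           de_targets = list(sort(det)))
  })
  empty_tfs <- names(regulons)[map_int(rows, "n_targets") == 0L]
  if (length(empty_tfs)) {
    warn(paste0(length(empty_tfs),
                " regulon(s) with no targets in the universe (p set to 1): ",
                paste(head(empty_tfs, 5L), collapse = ", "),
                if (length(empty_tfs) > 5L) ", ..." else ""))
  }
  out <- bind_rows(rows) |>
    mutate(significant = .data$p < p_cutoff) |>
    arrange(.data$p, .data$tf)
  attr(out, "fdr_cutoff") <- fdr_cutoff
  attr(out, "n_universe") <- N
  attr(out, "n_de_genes") <- m
  class(out) <- c("trilayer_regulons", class(out))
  out
}

#' Cluster regulators with identical target sets
#'
#' Transcription factors whose target sets coincide exactly are merged into
#' one cluster; the member with the smallest enrichment p-value (ties broken
#' lexically by TF name) becomes the cluster representative. By default the
#' comparison uses the differentially expressed target sets (`de_targets`);
#' set `key = "all_targets"` to compare full target lists instead (requires a
#' `targets` list-column or the original regulon list via `regulons`).
#' Clustering is idempotent: applying it twice yields the same result.
#'
#' @param records A `trilayer_regulons` tibble.
#' @param key `"de_targets"` (default) or `"all_targets"`.
#' @param regulons Full regulon list, only needed for `key = "all_targets"`.
#' @return `records` with `cluster` (integer id, ordered by the
#'   representative's significance) and `is_representative` columns.
#' @export
cluster_regulators <- function(records, key = c("de_targets", "all_targets"),
                               regulons = NULL) {
  key <- match.arg(key)
  stopifnot(is.data.frame(records), all(c("tf", "p") %in% names(records)))
  sets <- if (key == "de_targets") {
    records$de_targets
  } else {
    if (!is.null(regulons)) {
      lapply(records$tf, function(tf) regulons[[tf]])
    } else if ("targets" %in% names(records)) {
      records$targets
    } else {
      abort("`key = \"all_targets\"` needs `regulons` or a `targets` column.")
    }
  }
  keys <- map_chr(sets, function(s) paste(sort(unique(s)), collapse = "\r"))
  # representative-first order: smallest p, then lexical tf
  ord <- order(records$p, records$tf)
  first_seen <- !duplicated(keys[ord])
  unique_keys <- keys[ord][first_seen] # in representative order
  records$cluster <- match(keys, unique_keys)
  records$is_representative <- seq_len(nrow(records)) %in% ord[first_seen]
  records
}
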