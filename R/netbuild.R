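#' Gene-set similarity
#'
#' Overlap size and a similarity coefficient between two gene sets:
#' `"overlap"` is the overlap coefficient \eqn{|A \cap B| / \min(|A|, |B|)}
#' (the edge measure used throughout the network build), `"jaccard"` is
#' \eqn{|A \cap B| / |A \cup B|}, and `"combined"` is the enrichment-map
#' blend \eqn{k \cdot overlap + (1 - k) \cdot jaccard}.
#'
#' @param a,b Character vectors (nonempty gene sets).
#' @param method `"overlap"` (default), `"jaccard"` or `"combined"`.
#' @param k Mixing weight for `"combined"`, in `[0, 1]`.
#' @return A list with `overlap` (count) and `coefficient` (in `[0, 1]`).
#' @export
#' @examples
#' set_similarity(c("a", "b", "c"), c("b", "c", "d", "e"))
set_similarity <- function(a, b, method = c("overlap", "jaccard", "combined"),
                           k = 0.5) {
  method <- match.arg(method)
  a <- unique(a); b <- unique(b)
  if (!length(a) || !length(b)) abort("gene sets must be nonempty.")
  ov <- length(intersect(a, b))
  oc <- ov / min(length(a), length(b))
  jc <- ov / length(union(a, b))
  coef <- switch(method,
                 overlap = oc,
                 jaccard = jc,
                 combined = k * oc + (1 - k) * jc)
  list(overlap = ov, coefficient = coef)
}

default_relationships <- c("process-process", "regulator-process",
                           "regulator-physiology", "physiology-process")

relationship_of <- function(l1, l2) {
  canon <- c(process = 3L, regulator = 2L, physiology = 1L)
  pair <- c(l1, l2)[order(canon[c(l1, l2)], decreasing = TRUE)]
  # canonical naming: physiology last, regulator before process partners
  if (setequal(pair, c("regulator", "process"))) return("regulator-process")
  if (setequal(pair, c("regulator", "physiology"))) return("regulator-physiology")
  if (setequal(pair, c("physiology", "process"))) return("physiology-process")
  paste(pair, collapse = "-")
}

#' Assemble the three-layered gene-set overlap network
#'
#' Nodes are gene-set-backed records from the three upstream stages:
#' enriched biological processes (kept when their enrichment p is below
#' `node_p_cutoff`), representative transcription regulators (p below the
#' cutoff, nonempty differentially-expressed target set) and physiological
#' parameters (every parameter with a nonempty correlated gene set). Edges
#' connect allowed layer pairs whose backing sets share at least one gene and
#' whose similarity coefficient reaches the layer-pair cutoff:
#' `physio_coef_cutoff` (default 0.3) for physiology-process pairs and
#' `coef_cutoff` (default 0.5) for every other pair, both boundary-inclusive.
#' Process-process edges within the process layer are included by default
#' (an enrichment map); other intra-layer edges are not.
#'
#' @param enrichments Classified enrichment records ([classify_direction()]).
#' @param regulators A clustered `trilayer_regulons` table
#'   ([cluster_regulators()]); only representatives become nodes.
#' @param physio A `trilayer_physio` table ([correlate_parameters()]).
#' @param process_sets Named list backing the process layer (full memberships,
#'   e.g. from [read_gmt()]); each is intersected with `universe`.
#' @param universe Character vector of tested genes.
#' @param node_p_cutoff Node significance threshold (default 0.05).
#' @param coef_cutoff General similarity cutoff (default 0.5).
#' @param physio_coef_cutoff Physiology-process similarity cutoff (default
#'   0.3).
#' @param method,k Similarity method, see [set_similarity()].
#' @param relationships Allowed relationship types (defaults to
#'   process-process, regulator-process, regulator-physiology and
#'   physiology-process).
#' @param leading_edge If `TRUE`, back process nodes by their leading-edge
#'   genes instead of full memberships.
#' @return A `trilayer_network` with `nodes` (id, layer, score, direction,
#'   set_size, genes list-column), `edges` (from, to, relationship, overlap,
#'   coefficient) and `graph` (igraph, attribute-carrying). Node and edge
#'   ordering is deterministic.
#' @export
build_network <- function(enrichments, regulators, physio, process_sets,
                          universe, node_p_cutoff = 0.05, coef_cutoff = 0.5,
                          physio_coef_cutoff = 0.3,
                          method = c("overlap", "jaccard", "combined"),
                          k = 0.5, relationships = default_relationships,
                          leading_edge = FALSE) {
  method <- match.arg(method)
  stopifnot(coef_cutoff >= 0, coef_cutoff <= 1,
            physio_coef_cutoff >= 0, physio_coef_cutoff <= 1)

  nodes <- list()
  if (!is.null(enrichments) && nrow(enrichments)) {
    sig <- filter(enrichments, .data$p < node_p_cutoff)
    backing <- lapply(seq_len(nrow(sig)), function(i) {
      g <- if (leading_edge) sig$leading_edge[[i]]
      else intersect(process_sets[[sig$set[i]]], universe)
      sort(unique(g))
    })
    keep <- lengths(backing) > 0L
    if (any(keep)) {
      nodes$process <- tibble(
        id = sig$set[keep], layer = "process",
        score = if ("node_score" %in% names(sig)) sig$node_score[keep]
        else -log10(sig$p[keep]) * sign(sig$es[keep]),
        direction = if ("direction" %in% names(sig)) sig$direction[keep]
        else ifelse(sig$es[keep] >= 0, "up", "down"),
        genes = backing[keep])
    }
  }
  if (!is.null(regulators) && nrow(regulators)) {
    if (!"is_representative" %in% names(regulators)) {
      regulators <- cluster_regulators(regulators)
    }
    sig <- filter(regulators, .data$is_representative,
                  .data$p < node_p_cutoff, lengths(.data$de_targets) > 0L)
    if (nrow(sig)) {
      nodes$regulator <- tibble(
        id = sig$tf, layer = "regulator", score = sig$activation_score,
        direction = ifelse(sig$z > 0, "up", ifelse(sig$z < 0, "down", "none")),
        genes = lapply(sig$de_targets, function(g) sort(unique(g))))
    }
  }
  if (!is.null(physio) && nrow(physio)) {
    sig <- filter(physio, .data$n_genes > 0L)
    if (nrow(sig)) {
      nodes$physiology <- tibble(
        id = sig$parameter, layer = "physiology", score = NA_real_,
        direction = "none",
        genes = lapply(sig$genes, function(gt) sort(unique(gt$gene))))
    }
  }
  nodes <- bind_rows(nodes)
  if (nrow(nodes)) {
    if (anyDuplicated(nodes$id)) {
      abort("duplicate node ids across layers; rename inputs.")
    }
    nodes <- nodes |>
      mutate(set_size = lengths(.data$genes)) |>
      arrange(factor(.data$layer,
                     levels = c("process", "regulator", "physiology")),
              .data$id) |>
      select("id", "layer", "score", "direction", "set_size", "genes")
  } else {
    warn("network has no nodes.")
    nodes <- tibble(id = character(), layer = character(), score = double(),
                    direction = character(), set_size = integer(),
                    genes = list())
  }

  edges <- tibble(from = character(), to = character(),
                  relationship = character(), overlap = integer(),
                  coefficient = double())
  if (nrow(nodes) > 1L) {
    idx <- utils::combn(nrow(nodes), 2L)
    rows <- lapply(seq_len(ncol(idx)), function(jj) {
      i <- idx[1L, jj]; j <- idx[2L, jj]
      rel <- relationship_of(nodes$layer[i], nodes$layer[j])
      if (!rel %in% relationships) return(NULL)
      sim <- set_similarity(nodes$genes[[i]], nodes$genes[[j]],
                            method = method, k = k)
      cut <- if (rel == "physiology-process") physio_coef_cutoff else coef_cutoff
      if (sim$overlap < 1L || sim$coefficient < cut) return(NULL)
      tibble(from = nodes$id[i], to = nodes$id[j], relationship = rel,
             overlap = as.integer(sim$overlap), coefficient = sim$coefficient)
    })
    rows <- rows[!vapply(rows, is.null, logical(1))]
    if (length(rows)) {
      edges <- bind_rows(rows) |> arrange(.data$from, .data$to)
    }
  }

  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  if (nrow(nodes)) {
    g <- igraph::add_vertices(g, nrow(nodes), name = nodes$id,
                              layer = nodes$layer, score = nodes$score,
                              direction = nodes$direction,
                              set_size = nodes$set_size)
    if (nrow(edges)) {
      g <- igraph::add_edges(g, rbind(match(edges$from, nodes$id),
                                      match(edges$to, nodes$id)),
                             relationship = edges$relationship,
                             overlap = edges$overlap,
                             coefficient = edges$coefficient)
    }
  }
  structure(list(nodes = nodes, edges = edges, graph = g,
                 config = list(node_p_cutoff = node_p_cutoff,
                               coef_cutoff = coef_cutoff,
                               physio_coef_cutoff = physio_coef_cutoff,
                               method = method, k = k,
                               relationships = relationships)),
            class = "trilayer_network")
}

#' @export
print.trilayer_network <- function(x, ...) {
  cat("<trilayer_network>", nrow(x$nodes), "nodes,", nrow(x$edges), "edges\n")
  if (nrow(x$nodes)) {
    print(table(layer = x$nodes$layer))
  }
  invisible(x)
}

#' Network topology statistics
#'
#' Per-node degree, shortest-path betweenness centrality (unweighted,
#' unnormalised) and local clustering coefficient, plus whole-network node and
#' edge counts and density. Nodes with degree below 2 have an undefined
#' clustering coefficient, reported as `NA`.
#'
#' @param net A `trilayer_network`.
#' @return A list with `nodes` (tibble sorted by decreasing betweenness) and
#'   `network` (one-row tibble: n_nodes, n_edges, density).
#' @export
topology_stats <- function(net) {
  stopifnot(inherits(net, "trilayer_network"))
  g <- net$graph
  n <- igraph::vcount(g)
  if (n == 0L) {
    return(list(nodes = tibble(id = character(), layer = character(),
                               degree = integer(), betweenness = double(),
                               clustering = double()),
                network = tibble(n_nodes = 0L, n_edges = 0L,
                                 density = NA_real_)))
  }
  deg <- igraph::degree(g)
  btw <- igraph::betweenness(g, directed = FALSE, normalized = FALSE)
  cc <- igraph::transitivity(g, type = "local", isolates = "NaN")
  cc[is.nan(cc)] <- NA_real_
  nodes <- tibble(id = igraph::V(g)$name, layer = igraph::V(g)$layer,
                  degree = as.integer(deg), betweenness = as.numeric(btw),
                  clustering = as.numeric(cc)) |>
    arrange(desc(.data$betweenness), .data$id)
  dens <- if (n > 1L) nrow(net$edges) / (n * (n - 1L) / 2) else NA_real_
  list(nodes = nodes,
       network = tibble(n_nodes = n, n_edges = nrow(net$edges),
                        density = dens))
}
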