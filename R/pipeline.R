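#' Configure a pipeline run
#'
#' Bundles input paths and every stage parameter for [run_pipeline()]. All
#' paths are validated up front so a misconfigured run fails before any
#' computation.
#'
#' @param expression,samples,process_gmt,regulon_gmt,physiology Input file
#'   paths (expression TSV, sample TSV, two GMT collections, physiology TSV).
#' @param out_dir Output directory, created if missing.
#' @param timepoints Optional character vector restricting which timepoints
#'   are analysed (default: all in the sample table).
#' @param prior_df,prior_var Moderated t-test parameters.
#' @param de_fdr_cutoff FDR threshold defining the differentially expressed
#'   gene list for regulon enrichment.
#' @param min_size,max_size,weight_exponent,n_perm Enrichment parameters.
#' @param alpha Significance level for direction calls and node inclusion.
#' @param rho_cutoff Absolute Spearman threshold for the physiology layer.
#' @param coef_cutoff,physio_coef_cutoff,similarity_method,similarity_k
#'   Network edge parameters.
#' @param cluster_key Regulator clustering key, see [cluster_regulators()].
#' @param seed Integer seed driving every stochastic stage.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(expression, samples, process_gmt, regulon_gmt,
                            physiology, out_dir,
                            timepoints = NULL,
                            prior_df = 4, prior_var = NULL,
                            de_fdr_cutoff = 0.05,
                            min_size = 15L, max_size = 500L,
                            weight_exponent = 1, n_perm = 1000L,
                            alpha = 0.05, rho_cutoff = 0.8,
                            coef_cutoff = 0.5, physio_coef_cutoff = 0.3,
                            similarity_method = "overlap", similarity_k = 0.5,
                            cluster_key = "de_targets", seed = 1L) {
  paths <- c(expression = expression, samples = samples,
             process_gmt = process_gmt, regulon_gmt = regulon_gmt,
             physiology = physiology)
  missing <- paths[!file.exists(paths)]
  if (length(missing)) {
    abort(paste0("input file(s) not found: ",
                 paste(paste0(names(missing), " (", missing, ")"),
                       collapse = ", ")))
  }
  stopifnot(prior_df >= 0, min_size >= 1L, min_size <= max_size,
            n_perm >= 100L, alpha > 0, alpha < 1,
            rho_cutoff >= 0, rho_cutoff <= 1,
            coef_cutoff >= 0, coef_cutoff <= 1,
            physio_coef_cutoff >= 0, physio_coef_cutoff <= 1)
  structure(list(paths = as.list(paths), out_dir = out_dir,
                 timepoints = timepoints, prior_df = prior_df,
                 prior_var = prior_var, de_fdr_cutoff = de_fdr_cutoff,
                 min_size = as.integer(min_size),
                 max_size = as.integer(max_size),
                 weight_exponent = weight_exponent,
                 n_perm = as.integer(n_perm), alpha = alpha,
                 rho_cutoff = rho_cutoff, coef_cutoff = coef_cutoff,
                 physio_coef_cutoff = physio_coef_cutoff,
                 similarity_method = similarity_method,
                 similarity_k = similarity_k, cluster_key = cluster_key,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

log_stage <- function(verbose, ...) {
  if (verbose) inform(paste0(...))
}

#' Run the full three-layer pipeline
#'
#' Per timepoint: differential expression, forward and reversed preranked
#' enrichment with direction classification, regulon enrichment and
#' clustering, physiology correlation, and network assembly. Every stage
#' table is written as TSV, the network as GraphML, SIF and an edge TSV, and
#' a JSON run manifest records parameters, the seed, record counts and md5
#' checksums of every output so a run can be verified bit for bit. Outputs
#' contain no timestamps: rerunning with the same config and seed reproduces
#' every file byte-identically.
#'
#' @param cfg A [pipeline_config()].
#' @param verbose Log stage progress and record counts (default `TRUE`).
#' @return Invisibly, a named list per timepoint (each with `de`, `gsea`,
#'   `regulators`, `physio`, `network`, `topology`) plus `manifest`.
#' @export
run_pipeline <- function(cfg, verbose = TRUE) {
  stopifnot(inherits(cfg, "pipeline_config"))
  if (!dir.exists(cfg$out_dir)) dir.create(cfg$out_dir, recursive = TRUE)

  expr <- read_tsv_quiet(cfg$paths$expression)
  samples <- read_tsv_quiet(cfg$paths$samples)
  physio <- read_tsv_quiet(cfg$paths$physiology)
  processes <- read_gmt(cfg$paths$process_gmt)
  regulons <- read_gmt(cfg$paths$regulon_gmt)
  tps <- cfg$timepoints %||% unique(samples$timepoint)
  log_stage(verbose, "inputs: ", nrow(expr), " genes, ", nrow(samples),
            " samples, ", length(processes), " processes, ",
            length(regulons), " regulons, ", length(tps), " timepoint(s)")

  results <- list()
  files <- character(0)
  counts <- list()
  for (tp in tps) {
    tag <- function(name) file.path(cfg$out_dir, paste0(tp, "_", name))
    de <- moderated_ttest(expr, samples, timepoint = tp,
                          prior_df = cfg$prior_df, prior_var = cfg$prior_var)
    n_de <- sum(de$fdr < cfg$de_fdr_cutoff, na.rm = TRUE)
    log_stage(verbose, "[", tp, "] differential expression: ", nrow(de),
              " genes tested, ", n_de, " at FDR < ", cfg$de_fdr_cutoff)
    write_tsv_full(as_tibble(de), tag("de.tsv"))

    ranked <- rank_genes(de)
    rev_ranked <- tibble(gene = base::rev(ranked$gene),
                         score = base::rev(-ranked$score))
    fwd <- gsea_preranked(ranked, processes, min_size = cfg$min_size,
                          max_size = cfg$max_size,
                          weight_exponent = cfg$weight_exponent,
                          n_perm = cfg$n_perm, seed = cfg$seed)
    bwd <- gsea_preranked(rev_ranked, processes, min_size = cfg$min_size,
                          max_size = cfg$max_size,
                          weight_exponent = cfg$weight_exponent,
                          n_perm = cfg$n_perm, seed = cfg$seed + 1L)
    enr <- classify_direction(fwd, bwd, alpha = cfg$alpha)
    log_stage(verbose, "[", tp, "] enrichment: ", nrow(enr),
              " sets after size filter, ",
              sum(enr$p < cfg$alpha), " at p < ", cfg$alpha)
    write_tsv_full(flatten_gsea(enr), tag("enrichment.tsv"))

    regs <- regulon_enrichment(de, regulons, fdr_cutoff = cfg$de_fdr_cutoff,
                               p_cutoff = cfg$alpha) |>
      cluster_regulators(key = cfg$cluster_key, regulons = regulons)
    log_stage(verbose, "[", tp, "] regulators: ", nrow(regs), " TFs, ",
              sum(regs$significant), " significant, ",
              max(regs$cluster), " clusters")
    write_tsv_full(flatten_regulons(regs), tag("regulators.tsv"))

    phys <- correlate_parameters(expr, physio, timepoint = tp,
                                 rho_cutoff = cfg$rho_cutoff,
                                 alpha = cfg$alpha)
    log_stage(verbose, "[", tp, "] physiology: ",
              sum(phys$significant), " of ", nrow(phys),
              " parameters with correlated genes")
    write_tsv_full(flatten_physio(phys), tag("physiology.tsv"))

    net <- build_network(enr, regs, phys, processes, universe = de$gene,
                         node_p_cutoff = cfg$alpha,
                         coef_cutoff = cfg$coef_cutoff,
                         physio_coef_cutoff = cfg$physio_coef_cutoff,
                         method = cfg$similarity_method, k = cfg$similarity_k)
    topo <- topology_stats(net)
    log_stage(verbose, "[", tp, "] network: ", nrow(net$nodes), " nodes, ",
              nrow(net$edges), " edges")
    export_network(net, "graphml", tag("network.graphml"))
    export_network(net, "sif", tag("network.sif"))
    export_network(net, "tsv", tag("edges.tsv"))
    write_tsv_full(select(net$nodes, -"genes"), tag("nodes.tsv"))
    write_tsv_full(topo$nodes, tag("topology.tsv"))

    files <- c(files, tag("de.tsv"), tag("enrichment.tsv"),
               tag("regulators.tsv"), tag("physiology.tsv"),
               tag("network.graphml"), tag("network.sif"), tag("edges.tsv"),
               tag("nodes.tsv"), tag("topology.tsv"))
    counts[[tp]] <- list(genes_tested = nrow(de), de_genes = n_de,
                         sets_tested = nrow(enr),
                         sets_significant = sum(enr$p < cfg$alpha),
                         tfs = nrow(regs),
                         tfs_significant = sum(regs$significant),
                         tf_clusters = max(regs$cluster),
                         physio_significant = sum(phys$significant),
                         network_nodes = nrow(net$nodes),
                         network_edges = nrow(net$edges))
    results[[tp]] <- list(de = de, gsea = enr, regulators = regs,
                          physio = phys, network = net, topology = topo)
  }

  manifest <- list(
    package = "trilayer",
    version = as.character(utils::packageVersion("trilayer")),
    seed = cfg$seed,
    parameters = unclass(cfg)[setdiff(names(cfg), c("paths", "out_dir"))],
    inputs = lapply(cfg$paths, function(p)
      list(path = p, md5 = unname(tools::md5sum(p)))),
    counts = counts,
    outputs = lapply(setNames(files, basename(files)), function(p)
      unname(tools::md5sum(p)))
  )
  manifest_path <- file.path(cfg$out_dir, "run_manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  results$manifest <- manifest
  invisible(results)
}

flatten_gsea <- function(enr) {
  enr |>
    as_tibble() |>
    mutate(leading_edge = map_chr(.data$leading_edge, paste,
                                  collapse = ";")) |>
    select("set", "size", "es", "nes", "p", "q", "p_rev", "p_pos", "p_neg",
           "direction", "node_score", "leading_edge")
}

flatten_regulons <- function(regs) {
  regs |>
    as_tibble() |>
    mutate(de_targets = map_chr(.data$de_targets, paste, collapse = ";")) |>
    select("tf", "n_targets", "n_de", "n_up", "n_down", "p", "z",
           "activation_score", "significant", "cluster",
           "is_representative", "de_targets")
}

flatten_physio <- function(phys) {
  out <- phys |>
    as_tibble() |>
    select("parameter", "genes") |>
    tidyr::unnest("genes")
  if (!nrow(out)) {
    out <- tibble(parameter = character(), gene = character(),
                  rho = double(), p = double())
  }
  out
}
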