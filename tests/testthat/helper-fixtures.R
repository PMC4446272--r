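# small seeded fixtures shared across test files

small_config <- function(seed = 1L, ...) {
  args <- list(
    n_genes = 500L, n_processes = 30L, process_size_range = c(15L, 60L),
    n_regulons = 15L, regulon_size_range = c(10L, 30L),
    n_planted_regulons = 3L, effect_size = 1.5, noise_sd = 0.5,
    n_physio_params = 6L, n_linked_params = 2L, link_module_size = 25L,
    link_rho_target = 0.9, seed = seed)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(synth_config, args)
}

small_study <- function(seed = 1L, ...) {
  generate_study(small_config(seed = seed, ...))
}

# ranked list with iid normal scores over a synthetic universe
random_ranked <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rank_genes(tibble::tibble(gene = sprintf("g%04d", seq_len(n)),
                            t = rnorm(n)))
}

# a regulon record table with controllable target sets, for clustering tests
fake_regulon_records <- function(tfs, de_sets, p) {
  tibble::tibble(
    tf = tfs,
    n_targets = lengths(de_sets) + 2L,
    n_de = lengths(de_sets),
    n_up = lengths(de_sets),
    n_down = 0L,
    p = p,
    z = ifelse(lengths(de_sets) > 0, sqrt(lengths(de_sets)), 0),
    z_defined = lengths(de_sets) > 0,
    activation_score = -log10(p),
    significant = p < 0.05,
    de_targets = lapply(de_sets, as.character))
}

# minimal upstream record tables for driving build_network directly
fake_enrichments <- function(ids, p = rep(0.001, length(ids)),
                             es = rep(0.8, length(ids))) {
  tibble::tibble(
    set = ids, size = 10L, es = es, nes = es * 2, p = p, q = p,
    p_pos = p, p_neg = 1 - p, pos_dev = abs(es), neg_dev = -0.01,
    leading_edge = replicate(length(ids), character(), simplify = FALSE),
    direction = ifelse(es >= 0, "up", "down"),
    node_score = -log10(p) * sign(es))
}

fake_physio_records <- function(params, gene_sets) {
  tibble::tibble(
    parameter = params,
    n_animals = 20L,
    n_genes = lengths(gene_sets),
    significant = lengths(gene_sets) > 0,
    genes = lapply(gene_sets, function(g) {
      tibble::tibble(gene = as.character(g),
                     rho = rep(0.9, length(g)),
                     p = rep(0.001, length(g)))
    }))
}

# assemble a network straight from (id, layer, set) triples
fake_network <- function(ids, layers, sets, ...) {
  proc <- layers == "process"
  reg <- layers == "regulator"
  phy <- layers == "physiology"
  enr <- if (any(proc)) fake_enrichments(ids[proc]) else NULL
  process_sets <- if (any(proc)) setNames(sets[proc], ids[proc]) else list()
  regs <- if (any(reg)) {
    cluster_regulators(fake_regulon_records(
      ids[reg], sets[reg], p = rep(0.001, sum(reg))))
  } else {
    NULL
  }
  phys <- if (any(phy)) fake_physio_records(ids[phy], sets[phy]) else NULL
  build_network(enr, regs, phys, process_sets,
                universe = unique(unlist(sets)), ...)
}
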