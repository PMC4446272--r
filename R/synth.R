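#' Configure a synthetic two-diet, two-timepoint study
#'
#' Parameterises the synthetic-study generator: a high-fat vs low-fat diet
#' contrast profiled at an early ("5d") and a late ("12w") timepoint, with
#' planted differentially expressed regulons, planted enriched processes and
#' gene modules tied to latent physiological parameters. The generated study
#' carries a truth manifest so every downstream stage can be validated against
#' known ground truth.
#'
#' @param n_genes Number of genes in the universe.
#' @param n_per_group Named integer vector, animals per diet group at each
#'   timepoint. Defaults to 10 at "5d" and 12 at "12w".
#' @param n_processes Number of gene sets in the biological-process collection.
#' @param process_size_range Length-2 integer vector, inclusive bounds for
#'   process sizes (default 15-500, the enrichment size filter's own bounds).
#' @param n_regulons Number of transcription-factor regulons.
#' @param regulon_size_range Length-2 integer vector of regulon target counts.
#' @param n_planted_regulons How many regulons receive a planted expression
#'   shift in the high-fat group.
#' @param planted_directions Optional vector of +1/-1 per planted regulon;
#'   defaults to alternating +1, -1, ...
#' @param effect_size log2 expression shift applied to planted targets in HFD
#'   samples.
#' @param noise_sd Residual standard deviation of log2 expression.
#' @param n_physio_params Number of physiological parameters measured per
#'   animal.
#' @param n_linked_params How many parameters are tied to a latent factor
#'   shared with a gene module.
#' @param link_module_size Genes per linked module.
#' @param link_rho_target Target Spearman correlation magnitude between module
#'   genes and their parameter, in `[0, 1]`.
#' @param seed Integer RNG seed; the same config always generates the same
#'   study.
#'
#' @return A `synth_config` list, validated.
#' @export
synth_config <- function(n_genes = 2000L,
                         n_per_group = c("5d" = 10L, "12w" = 12L),
                         n_processes = 100L,
                         process_size_range = c(15L, 500L),
                         n_regulons = 50L,
                         regulon_size_range = c(20L, 100L),
                         n_planted_regulons = 5L,
                         planted_directions = NULL,
                         effect_size = 1.5,
                         noise_sd = 0.5,
                         n_physio_params = 11L,
                         n_linked_params = 2L,
                         link_module_size = 50L,
                         link_rho_target = 0.9,
                         seed = 1L) {
  cfg <- list(
    n_genes = as.integer(n_genes),
    n_per_group = setNames(as.integer(n_per_group), names(n_per_group)),
    n_processes = as.integer(n_processes),
    process_size_range = as.integer(process_size_range),
    n_regulons = as.integer(n_regulons),
    regulon_size_range = as.integer(regulon_size_range),
    n_planted_regulons = as.integer(n_planted_regulons),
    planted_directions = planted_directions,
    effect_size = as.numeric(effect_size),
    noise_sd = as.numeric(noise_sd),
    n_physio_params = as.integer(n_physio_params),
    n_linked_params = as.integer(n_linked_params),
    link_module_size = as.integer(link_module_size),
    link_rho_target = as.numeric(link_rho_target),
    seed = as.integer(seed)
  )
  if (is.null(names(cfg$n_per_group)) || any(!nzchar(names(cfg$n_per_group)))) {
    abort("`n_per_group` must be a named vector (names are timepoint labels).")
  }
  counts <- c(cfg$n_genes, cfg$n_per_group, cfg$n_processes, cfg$n_regulons,
              cfg$n_physio_params)
  if (any(counts <= 0L)) abort("all counts must be positive.")
  if (cfg$n_planted_regulons < 0L || cfg$n_linked_params < 0L ||
      cfg$link_module_size <= 0L) {
    abort("planted counts must be nonnegative and module size positive.")
  }
  rng_ok <- function(r, lo, hi) length(r) == 2L && r[1] <= r[2] &&
    r[1] >= lo && r[2] <= hi
  if (!rng_ok(cfg$process_size_range, 1L, cfg$n_genes)) {
    abort("`process_size_range` must lie within [1, n_genes].")
  }
  if (!rng_ok(cfg$regulon_size_range, 1L, cfg$n_genes)) {
    abort("`regulon_size_range` must lie within [1, n_genes].")
  }
  if (cfg$link_rho_target < 0 || cfg$link_rho_target > 1) {
    abort("`link_rho_target` must be in [0, 1].")
  }
  if (cfg$n_planted_regulons > cfg$n_regulons) {
    abort("`n_planted_regulons` cannot exceed `n_regulons`.")
  }
  if (is.null(cfg$planted_directions)) {
    cfg$planted_directions <-
      rep_len(c(1L, -1L), cfg$n_planted_regulons)
  } else {
    if (length(cfg$planted_directions) != cfg$n_planted_regulons ||
        !all(cfg$planted_directions %in% c(-1L, 1L))) {
      abort("`planted_directions` must be +1/-1, one per planted regulon.")
    }
    cfg$planted_directions <- as.integer(cfg$planted_directions)
  }
  # feasibility: planted regulon targets are disjoint, and linked modules are
  # drawn from genes left over after planting
  max_planted <- cfg$n_planted_regulons * cfg$regulon_size_range[2]
  need <- max_planted + cfg$n_linked_params * cfg$link_module_size
  if (need > cfg$n_genes) {
    abort(paste0("infeasible configuration: up to ", need,
                 " planted/linked genes requested but only ", cfg$n_genes,
                 " genes exist."))
  }
  structure(cfg, class = "synth_config")
}

# uniform integer draw that is safe when lo == hi (unlike sample(lo:hi, ...))
rint <- function(n, lo, hi) lo + sample.int(hi - lo + 1L, n, replace = TRUE) - 1L

# Spearman target -> Pearson scale for a bivariate normal, then the regression
# slope that achieves it against residual sd `sd_e`:
#   rho_S = (6/pi) asin(rho_P / 2)  =>  rho_P = 2 sin(pi rho_S / 6)
link_slope <- function(rho_s, sd_e) {
  if (rho_s <= 0) return(0)
  rho_p <- 2 * sin(pi * rho_s / 6)
  rho_p <- min(rho_p, 1 - 1e-12)
  sd_e * rho_p / sqrt(1 - rho_p^2)
}

#' Generate a synthetic study
#'
#' Draws a complete study from a [synth_config()]: a log2 expression matrix per
#' timepoint (Gaussian noise around gene baselines), a sample table, a process
#' gene-set collection, a regulon collection, an animal-by-parameter physiology
#' table, and a truth manifest recording every planted effect.
#'
#' Planted regulons have pairwise-disjoint target sets; their targets are
#' shifted by `direction * effect_size` (log2) in HFD samples only. Each
#' planted regulon also seeds a "planted process" built from its targets plus
#' random fill, and a fraction of the remaining processes borrow members from
#' random regulons so that cross-layer gene-set overlap exists by construction.
#' Linked physiological parameters are latent standard-normal animal factors;
#' their module genes gain `slope * latent` with the slope calibrated so the
#' population Spearman correlation magnitude matches `link_rho_target`.
#' Timepoints are generated as independent cohorts sharing the gene universe
#' and planted structure.
#'
#' @param config A [synth_config()].
#' @return A `synthetic_study` list with elements `expression` (tibble, `gene`
#'   column plus one column per sample, all timepoints side by side), `samples`
#'   (tibble: sample, diet, timepoint), `processes` and `regulons` (named lists
#'   of gene-id vectors), `physiology` (tibble: animal, timepoint, one column
#'   per parameter), `truth` (manifest list) and `config`.
#' @export
generate_study <- function(config) {
  if (!inherits(config, "synth_config")) config <- do.call(synth_config, config)
  with_seed(config$seed, generate_study_impl(config))
}

generate_study_impl <- function(cfg) {
  genes <- sprintf("g%05d", seq_len(cfg$n_genes))
  baseline <- rnorm(cfg$n_genes, mean = 8, sd = 1.5)
  names(baseline) <- genes

  # --- regulons: planted targets disjoint, null regulons uniform ------------
  reg_sizes <- rint(cfg$n_regulons, cfg$regulon_size_range[1],
                    cfg$regulon_size_range[2])
  reg_names <- sprintf("TF%03d", seq_len(cfg$n_regulons))
  planted_idx <- seq_len(cfg$n_planted_regulons)
  pool <- sample(genes) # shuffled universe for disjoint planting
  regulons <- vector("list", cfg$n_regulons)
  names(regulons) <- reg_names
  used <- 0L
  for (i in seq_len(cfg$n_regulons)) {
    if (i %in% planted_idx && cfg$effect_size != 0) {
      regulons[[i]] <- sort(pool[(used + 1L):(used + reg_sizes[i])])
      used <- used + reg_sizes[i]
    } else {
      regulons[[i]] <- sort(sample(genes, reg_sizes[i]))
    }
  }
  plant_active <- cfg$effect_size != 0 && cfg$n_planted_regulons > 0L
  planted_regulons <- if (plant_active) {
    tibble(regulon = reg_names[planted_idx],
           direction = cfg$planted_directions)
  } else {
    tibble(regulon = character(), direction = integer())
  }
  de_truth <- if (plant_active) {
    bind_rows(lapply(planted_idx, function(i) {
      tibble(gene = regulons[[i]], direction = cfg$planted_directions[i])
    }))
  } else {
    tibble(gene = character(), direction = integer())
  }

  # --- linked physiology modules from genes untouched by planting -----------
  free <- setdiff(genes, de_truth$gene)
  linked_params <- character(0)
  modules <- list()
  if (cfg$n_linked_params > 0L && cfg$link_rho_target > 0) {
    free_shuffled <- sample(free)
    for (j in seq_len(cfg$n_linked_params)) {
      take <- free_shuffled[((j - 1L) * cfg$link_module_size + 1L):
                              (j * cfg$link_module_size)]
      modules[[sprintf("param%02d", j)]] <- sort(take)
    }
    linked_params <- names(modules)
  }
  param_names <- sprintf("param%02d", seq_len(cfg$n_physio_params))

  # --- processes: planted ones wrap planted regulon targets; a third of the
  # rest borrow half their members from a random regulon ---------------------
  proc_names <- sprintf("process%03d", seq_len(cfg$n_processes))
  lo <- cfg$process_size_range[1]; hi <- cfg$process_size_range[2]
  processes <- vector("list", cfg$n_processes)
  names(processes) <- proc_names
  n_plant_proc <- if (plant_active) min(cfg$n_planted_regulons,
                                        cfg$n_processes) else 0L
  for (i in seq_len(cfg$n_processes)) {
    if (i <= n_plant_proc) {
      targ <- regulons[[i]]
      size <- max(lo, min(hi, length(targ) + ceiling(length(targ) / 2)))
      extra <- sample(setdiff(genes, targ), max(0L, size - length(targ)))
      processes[[i]] <- sort(c(targ, extra))
    } else {
      size <- rint(1L, lo, hi)
      if (runif(1) < 1 / 3) {
        donor <- regulons[[sample.int(cfg$n_regulons, 1L)]]
        half <- sample(donor, min(length(donor), size %/% 2L))
        rest <- sample(setdiff(genes, half), size - length(half))
        processes[[i]] <- sort(c(half, rest))
      } else {
        processes[[i]] <- sort(sample(genes, size))
      }
    }
  }
  planted_processes <- proc_names[seq_len(n_plant_proc)]

  # --- expression + physiology per timepoint --------------------------------
  slope <- link_slope(cfg$link_rho_target, cfg$noise_sd)
  expr_blocks <- list()
  sample_tabs <- list()
  physio_tabs <- list()
  for (tp in names(cfg$n_per_group)) {
    n <- cfg$n_per_group[[tp]]
    ids <- c(sprintf("%s_LFD_%02d", tp, seq_len(n)),
             sprintf("%s_HFD_%02d", tp, seq_len(n)))
    diet <- rep(c("LFD", "HFD"), each = n)
    E <- matrix(rnorm(cfg$n_genes * 2L * n, 0, cfg$noise_sd),
                nrow = cfg$n_genes, dimnames = list(genes, ids))
    E <- E + baseline
    if (plant_active) {
      hfd <- diet == "HFD"
      for (i in planted_idx) {
        E[regulons[[i]], hfd] <- E[regulons[[i]], hfd] +
          cfg$planted_directions[i] * cfg$effect_size
      }
    }
    P <- matrix(rnorm(2L * n * cfg$n_physio_params), nrow = 2L * n,
                dimnames = list(ids, param_names))
    for (pm in linked_params) {
      latent <- P[, pm] # the parameter value *is* the latent factor
      E[modules[[pm]], ] <- E[modules[[pm]], ] +
        slope * matrix(latent, nrow = length(modules[[pm]]),
                       ncol = 2L * n, byrow = TRUE)
    }
    expr_blocks[[tp]] <- E
    sample_tabs[[tp]] <- tibble(sample = ids, diet = diet, timepoint = tp)
    physio_tabs[[tp]] <- bind_cols(tibble(animal = ids, timepoint = tp),
                                   as_tibble(P))
  }

  truth <- list(
    planted_regulons = planted_regulons,
    planted_processes = planted_processes,
    linked_parameters = modules,
    de_genes = de_truth
  )
  study <- list(
    expression = bind_cols(tibble(gene = genes),
                           as_tibble(do.call(cbind, expr_blocks))),
    samples = bind_rows(sample_tabs),
    processes = processes,
    regulons = regulons,
    physiology = bind_rows(physio_tabs),
    truth = truth,
    config = cfg
  )
  structure(study, class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat("<synthetic_study>\n")
  cat("  genes:", nrow(x$expression),
      " samples:", nrow(x$samples),
      " timepoints:", paste(unique(x$samples$timepoint), collapse = ", "), "\n")
  cat("  processes:", length(x$processes),
      " regulons:", length(x$regulons),
      " physiological parameters:", ncol(x$physiology) - 2L, "\n")
  cat("  planted regulons:", nrow(x$truth$planted_regulons),
      " linked parameters:", length(x$truth$linked_parameters), "\n")
  invisible(x)
}

#' Write a synthetic study to disk
#'
#' Writes the expression, sample and physiology tables as TSV, the process and
#' regulon collections as GMT, and the truth manifest as JSON. [read_study()]
#' reproduces the study exactly (numeric values serialised at full precision).
#'
#' @param study A `synthetic_study`.
#' @param dir Output directory, created if missing.
#' @return Invisibly, a named character vector of the files written.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "synthetic_study"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (file.access(dir, mode = 2L) != 0L) {
    abort(paste0("directory not writable: ", dir))
  }
  paths <- c(
    expression = file.path(dir, "expression.tsv"),
    samples = file.path(dir, "samples.tsv"),
    physiology = file.path(dir, "physiology.tsv"),
    processes = file.path(dir, "processes.gmt"),
    regulons = file.path(dir, "regulons.gmt"),
    truth = file.path(dir, "truth.json")
  )
  write_tsv_full(study$expression, paths[["expression"]])
  write_tsv_full(study$samples, paths[["samples"]])
  write_tsv_full(study$physiology, paths[["physiology"]])
  write_gmt(study$processes, paths[["processes"]])
  write_gmt(study$regulons, paths[["regulons"]])
  truth <- study$truth
  cfg_out <- unclass(study$config)
  cfg_out$n_per_group <- as.list(cfg_out$n_per_group) # keep timepoint names
  manifest <- list(
    planted_regulons = truth$planted_regulons,
    planted_processes = truth$planted_processes,
    linked_parameters = truth$linked_parameters,
    de_genes = truth$de_genes,
    config = cfg_out
  )
  jsonlite::write_json(manifest, paths[["truth"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}

#' Read a synthetic study written by [write_study()]
#'
#' @param dir Directory containing the study files.
#' @return A `synthetic_study` equal to the one written.
#' @export
read_study <- function(dir) {
  need <- file.path(dir, c("expression.tsv", "samples.tsv", "physiology.tsv",
                           "processes.gmt", "regulons.gmt", "truth.json"))
  missing <- need[!file.exists(need)]
  if (length(missing)) {
    abort(paste0("study files missing: ", paste(missing, collapse = ", ")))
  }
  truth_raw <- jsonlite::read_json(file.path(dir, "truth.json"),
                                   simplifyVector = TRUE)
  cfg <- truth_raw$config
  cfg$n_per_group <- unlist(cfg$n_per_group)
  cfg <- do.call(synth_config, cfg)
  truth <- list(
    planted_regulons = as_tibble(truth_raw$planted_regulons),
    planted_processes = as.character(truth_raw$planted_processes),
    linked_parameters = lapply(truth_raw$linked_parameters, as.character),
    de_genes = as_tibble(truth_raw$de_genes)
  )
  if (nrow(truth$planted_regulons) == 0L) {
    truth$planted_regulons <- tibble(regulon = character(),
                                     direction = integer())
  }
  if (nrow(truth$de_genes) == 0L) {
    truth$de_genes <- tibble(gene = character(), direction = integer())
  }
  study <- list(
    expression = read_tsv_quiet(file.path(dir, "expression.tsv")),
    samples = read_tsv_quiet(file.path(dir, "samples.tsv")),
    processes = read_gmt(file.path(dir, "processes.gmt")),
    regulons = read_gmt(file.path(dir, "regulons.gmt")),
    physiology = read_tsv_quiet(file.path(dir, "physiology.tsv")),
    truth = truth,
    config = cfg
  )
  structure(study, class = "synthetic_study")
}
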