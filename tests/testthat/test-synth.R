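test_that("the same config and seed reproduce the study exactly", {
  s1 <- small_study(seed = 11)
  s2 <- small_study(seed = 11)
  expect_identical(s1$expression, s2$expression)
  expect_identical(s1$samples, s2$samples)
  expect_identical(s1$processes, s2$processes)
  expect_identical(s1$regulons, s2$regulons)
  expect_identical(s1$physiology, s2$physiology)
  expect_identical(s1$truth, s2$truth)
  s3 <- small_study(seed = 12)
  expect_false(identical(s1$expression, s3$expression))
})

test_that("a null configuration plants nothing", {
  s <- small_study(seed = 3, effect_size = 0, link_rho_target = 0)
  expect_equal(nrow(s$truth$planted_regulons), 0)
  expect_equal(nrow(s$truth$de_genes), 0)
  expect_length(s$truth$linked_parameters, 0)
  expect_length(s$truth$planted_processes, 0)
})

test_that("structural invariants hold and infeasible configs are rejected", {
  s <- small_study(seed = 4)
  expect_setequal(s$samples$sample, setdiff(names(s$expression), "gene"))
  expect_setequal(s$physiology$animal, s$samples$sample)
  expect_false(anyDuplicated(s$expression$gene) > 0)
  # planted ids resolve against the generated collections
  expect_true(all(s$truth$planted_regulons$regulon %in% names(s$regulons)))
  expect_true(all(s$truth$planted_processes %in% names(s$processes)))
  for (m in s$truth$linked_parameters) {
    expect_true(all(m %in% s$expression$gene))
  }
  # planted regulon target sets are pairwise disjoint
  planted <- s$regulons[s$truth$planted_regulons$regulon]
  expect_equal(length(unlist(planted)), length(unique(unlist(planted))))
  expect_error(synth_config(n_genes = 100, n_regulons = 5,
                            process_size_range = c(10, 50),
                            regulon_size_range = c(20, 30),
                            n_planted_regulons = 5,
                            link_module_size = 50, n_linked_params = 2),
               "infeasible")
  expect_error(synth_config(n_genes = 100, process_size_range = c(15, 500)),
               "process_size_range")
})

test_that("write then read round-trips every component", {
  s <- small_study(seed = 9)
  dir <- withr::local_tempdir()
  write_study(s, dir)
  s2 <- read_study(dir)
  expect_equal(s2$expression, s$expression, ignore_attr = TRUE)
  expect_equal(s2$samples, s$samples, ignore_attr = TRUE)
  expect_equal(s2$physiology, s$physiology, ignore_attr = TRUE)
  expect_equal(s2$processes, s$processes, ignore_attr = "descriptions")
  expect_equal(s2$regulons, s$regulons, ignore_attr = "descriptions")
  expect_equal(s2$truth$planted_regulons, s$truth$planted_regulons,
               ignore_attr = TRUE)
  expect_identical(s2$truth$linked_parameters, s$truth$linked_parameters)
  # GMT lines have >= 3 tab-separated fields
  gmt <- readLines(file.path(dir, "processes.gmt"))
  expect_true(all(lengths(strsplit(gmt, "\t")) >= 3))
  # truth manifest ids resolve against the written GMT files
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  written_regs <- read_gmt(file.path(dir, "regulons.gmt"))
  written_procs <- read_gmt(file.path(dir, "processes.gmt"))
  expect_true(all(truth$planted_regulons$regulon %in% names(written_regs)))
  expect_true(all(truth$planted_processes %in% names(written_procs)))
})

test_that("planted linked modules attain the target correlation strength", {
  # population Spearman of module genes vs their parameter ~ link_rho_target
  rhos <- vapply(1:20, function(seed) {
    s <- generate_study(synth_config(
      n_genes = 300, n_per_group = c("12w" = 12L), n_processes = 5L,
      process_size_range = c(15L, 40L), n_regulons = 5L,
      regulon_size_range = c(10L, 20L), n_planted_regulons = 0L,
      effect_size = 0, n_physio_params = 4L, n_linked_params = 2L,
      link_module_size = 20L, link_rho_target = 0.9, seed = seed))
    animals <- s$physiology$animal
    X <- as.matrix(s$expression[, animals])
    rownames(X) <- s$expression$gene
    mean(vapply(names(s$truth$linked_parameters), function(pm) {
      mod <- s$truth$linked_parameters[[pm]]
      y <- s$physiology[[pm]]
      mean(abs(apply(X[mod, ], 1, function(g) spearman_cor(g, y)$rho)))
    }, numeric(1)))
  }, numeric(1))
  expect_lt(abs(mean(rhos) - 0.9), 0.1)
})

test_that("planted differential expression is recoverable downstream", {
  hit_rates <- vapply(1:10, function(seed) {
    s <- generate_study(synth_config(n_genes = 2000, seed = seed))
    de <- moderated_ttest(s$expression, s$samples, timepoint = "12w")
    planted <- s$truth$de_genes$gene
    mean(de$fdr[match(planted, de$gene)] < 0.05)
  }, numeric(1))
  expect_gte(mean(hit_rates), 0.9)
})
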