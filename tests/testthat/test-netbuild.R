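test_that("set similarity follows the overlap/jaccard/combined definitions", {
  s <- set_similarity(c("a", "b", "c"), c("b", "c", "d", "e"))
  expect_equal(s$overlap, 2)
  expect_equal(s$coefficient, 2 / 3, tolerance = 1e-15)
  j <- set_similarity(c("a", "b", "c"), c("b", "c", "d", "e"), "jaccard")
  expect_equal(j$coefficient, 2 / 5, tolerance = 1e-15)
  comb <- set_similarity(c("a", "b", "c"), c("b", "c", "d", "e"),
                         "combined", k = 0.25)
  expect_equal(comb$coefficient, 0.25 * 2 / 3 + 0.75 * 2 / 5,
               tolerance = 1e-15)
  for (m in c("overlap", "jaccard", "combined")) {
    expect_equal(set_similarity(letters[1:4], letters[1:4], m)$coefficient, 1)
    expect_equal(set_similarity(letters[1:3], letters[5:8], m)$coefficient, 0)
  }
  expect_error(set_similarity(character(0), "a"), "nonempty")
})

test_that("similarity is symmetric and jaccard <= overlap <= 1", {
  set.seed(61)
  for (i in 1:50) {
    a <- sample(letters, sample(1:10, 1))
    b <- sample(letters, sample(1:10, 1))
    ab <- set_similarity(a, b)
    ba <- set_similarity(b, a)
    expect_identical(ab, ba)
    jac <- set_similarity(a, b, "jaccard")$coefficient
    expect_lte(jac, ab$coefficient)
    expect_lte(ab$coefficient, 1)
    expect_gte(jac, 0)
  }
})

test_that("edge retention is boundary-inclusive with layer-specific cutoffs", {
  u <- sprintf("g%02d", 1:40)
  # process pair at exactly 0.5: |A|=|B|=10, overlap 5
  at_half <- fake_network(c("p1", "p2"), c("process", "process"),
                          list(u[1:10], c(u[6:10], u[21:25])))
  expect_equal(nrow(at_half$edges), 1)
  # just below: overlap 4.9/10 impossible; use 0.49 via sizes 100? use 4/10
  below <- fake_network(c("p1", "p2"), c("process", "process"),
                        list(u[1:10], c(u[7:10], u[21:26])))
  expect_equal(nrow(below$edges), 0)
  # physiology-process at 0.35 kept (0.3 cutoff); regulator-process dropped
  sets <- list(u[1:20], c(u[1:7], u[21:33])) # overlap 7, min 20 -> 0.35
  phys_proc <- fake_network(c("p1", "ph1"), c("process", "physiology"), sets)
  expect_equal(nrow(phys_proc$edges), 1)
  expect_equal(phys_proc$edges$relationship, "physiology-process")
  expect_equal(phys_proc$edges$coefficient, 0.35)
  reg_proc <- fake_network(c("p1", "tf1"), c("process", "regulator"), sets)
  expect_equal(nrow(reg_proc$edges), 0)
})

test_that("disallowed relationship types never appear", {
  u <- sprintf("g%02d", 1:30)
  net <- fake_network(
    c("tf1", "tf2", "ph1", "ph2", "p1"),
    c("regulator", "regulator", "physiology", "physiology", "process"),
    list(u[1:10], u[1:10], u[1:10], u[1:10], u[1:12]))
  expect_false(any(net$edges$relationship %in%
                     c("regulator-regulator", "physiology-physiology")))
  # identical backing sets would otherwise connect tf1-tf2 and ph1-ph2
  expect_true(all(c("regulator-process", "physiology-process") %in%
                    net$edges$relationship))
})

test_that("node filtering respects significance and nonempty backing sets", {
  u <- sprintf("g%02d", 1:30)
  enr <- fake_enrichments(c("sig", "nonsig"), p = c(0.001, 0.2))
  process_sets <- list(sig = u[1:15], nonsig = u[1:15])
  net <- build_network(enr, NULL, NULL, process_sets, universe = u)
  expect_equal(net$nodes$id, "sig")
  # physiology nodes need no p, only a nonempty gene set
  phys <- fake_physio_records(c("full", "empty"), list(u[1:5], character(0)))
  net2 <- build_network(NULL, NULL, phys, list(), universe = u)
  expect_equal(net2$nodes$id, "full")
  expect_warning(build_network(NULL, NULL, NULL, list(), universe = u),
                 "no nodes")
})

test_that("the edge set equals the exhaustive all-pairs oracle", {
  set.seed(62)
  u <- sprintf("g%03d", 1:120)
  n_nodes <- 30
  layers <- sample(c("process", "regulator", "physiology"), n_nodes,
                   replace = TRUE, prob = c(0.5, 0.3, 0.2))
  ids <- paste0(substr(layers, 1, 2), sprintf("%02d", seq_len(n_nodes)))
  sets <- lapply(seq_len(n_nodes), function(i) {
    sample(u, sample(4:25, 1))
  })
  net <- fake_network(ids, layers, sets)
  want <- oracle_edges(ids, layers, sets)
  got <- net$edges
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  expect_setequal(key(got$from, got$to), key(want$a, want$b))
  m <- match(key(got$from, got$to), key(want$a, want$b))
  expect_equal(got$overlap, want$overlap[m])
  expect_equal(got$coefficient, want$coefficient[m], tolerance = 1e-12)
  expect_equal(got$relationship, want$relationship[m])
})

test_that("betweenness, degree and clustering match known graphs", {
  u <- letters
  # path a-b-c via overlapping process sets
  path <- fake_network(c("a", "b", "c"), rep("process", 3),
                       list(u[1:4], c(u[3:4], u[7:8]), u[7:10]))
  expect_equal(nrow(path$edges), 2)
  topo <- topology_stats(path)
  expect_equal(topo$nodes$betweenness[topo$nodes$id == "b"], 1)
  expect_equal(sort(topo$nodes$betweenness), c(0, 0, 1))
  expect_equal(topo$network$density, 2 / 3)
  # K4: all identical sets -> complete graph, zero betweenness everywhere
  k4 <- fake_network(paste0("p", 1:4), rep("process", 4),
                     replicate(4, u[1:5], simplify = FALSE))
  expect_equal(nrow(k4$edges), 6)
  topo4 <- topology_stats(k4)
  expect_equal(topo4$nodes$betweenness, rep(0, 4))
  expect_equal(topo4$nodes$clustering, rep(1, 4))
  expect_equal(topo4$nodes$degree, rep(3L, 4))
})

test_that("betweenness matches the brute-force path-counting oracle", {
  set.seed(63)
  for (i in 1:10) {
    n <- sample(8:20, 1)
    adj <- matrix(0L, n, n)
    for (a in seq_len(n - 1)) {
      for (b in (a + 1):n) {
        if (runif(1) < 0.25) adj[a, b] <- adj[b, a] <- 1L
      }
    }
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    igraph::V(g)$name <- sprintf("v%02d", seq_len(n))
    igraph::V(g)$layer <- "process"
    net <- structure(list(
      nodes = tibble::tibble(id = igraph::V(g)$name, layer = "process"),
      edges = tibble::tibble(from = character(), to = character())[
        seq_len(0), ],
      graph = g), class = "trilayer_network")
    topo <- topology_stats(net)
    want <- oracle_betweenness(adj)
    expect_equal(topo$nodes$betweenness[match(sprintf("v%02d", seq_len(n)),
                                              topo$nodes$id)],
                 want, tolerance = 1e-9)
  }
})

test_that("rebuilding from the same inputs gives identical output bytes", {
  set.seed(64)
  u <- sprintf("g%03d", 1:60)
  ids <- paste0("n", 1:12)
  layers <- rep(c("process", "regulator", "physiology"), each = 4)
  sets <- lapply(1:12, function(i) sample(u, 15))
  f1 <- tempfile(fileext = ".graphml")
  f2 <- tempfile(fileext = ".graphml")
  export_network(fake_network(ids, layers, sets), "graphml", f1)
  export_network(fake_network(ids, layers, sets), "graphml", f2)
  expect_identical(readLines(f1), readLines(f2))
})
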