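test_that("rank_genes orders by descending t with lexical tie-break", {
  de <- tibble::tibble(gene = c("g1", "g2", "g3"), t = c(2, -1, 0.5))
  expect_equal(rank_genes(de)$gene, c("g1", "g3", "g2"))
  tie <- tibble::tibble(gene = c("b", "a"), t = c(1, 1))
  expect_equal(rank_genes(tie)$gene, c("a", "b"))
  # row-order invariance
  set.seed(31)
  for (i in 1:10) {
    de <- tibble::tibble(gene = sprintf("g%03d", 1:50),
                         t = sample(rnorm(40), 50, replace = TRUE))
    shuffled <- de[sample.int(50), ]
    expect_identical(rank_genes(de), rank_genes(shuffled))
  }
})

test_that("enrichment_score reproduces the hand-computed running sum", {
  ranked <- tibble::tibble(gene = paste0("g", 1:5),
                           score = c(2, 1, 0.5, -0.5, -1))
  es <- enrichment_score(ranked, c("g1", "g2"), weight_exponent = 1)
  expect_equal(es$running_sum, c(2 / 3, 1, 2 / 3, 1 / 3, 0),
               tolerance = 1e-15)
  expect_equal(es$es, 1)
  expect_equal(es$leading_edge, c("g1", "g2"))
  # single top gene, unweighted: immediate full increment
  es0 <- enrichment_score(ranked, "g1", weight_exponent = 0)
  expect_equal(es0$es, 1)
})

test_that("enrichment_score rejects degenerate inputs", {
  ranked <- tibble::tibble(gene = paste0("g", 1:4), score = c(2, 1, 0, -1))
  expect_error(enrichment_score(ranked, c("zz")), "does not intersect")
  expect_error(enrichment_score(ranked, paste0("g", 1:4)), "whole universe")
  expect_error(enrichment_score(ranked, "g3", weight_exponent = 1),
               "scores are zero")
})

test_that("negating scores and reversing the list negates the ES", {
  set.seed(32)
  for (i in 1:20) {
    n <- sample(10:50, 1)
    ranked <- random_ranked(n)
    genes <- sample(ranked$gene, sample(2:min(8, n - 1), 1))
    fwd <- enrichment_score(ranked, genes)
    rev_ranked <- tibble::tibble(gene = rev(ranked$gene),
                                 score = rev(-ranked$score))
    bwd <- enrichment_score(rev_ranked, genes)
    expect_equal(abs(bwd$es), abs(fwd$es), tolerance = 1e-12)
    # the sign flips whenever the extremum is unambiguous; an exact tie
    # between the positive and negative deviations leaves the sign to the
    # first-extremum rule
    if (abs(abs(fwd$pos_dev) - abs(fwd$neg_dev)) > 1e-12) {
      expect_equal(bwd$es, -fwd$es, tolerance = 1e-12)
    }
  }
})

test_that("R, C++ and fgsea agree on the enrichment score", {
  set.seed(33)
  for (i in 1:25) {
    n <- sample(20:60, 1)
    ranked <- random_ranked(n)
    pos <- sort(sample(n, sample(2:10, 1)))
    ours <- enrichment_score(ranked, ranked$gene[pos])
    cpp <- trilayer:::es_hits_cpp(abs(ranked$score), as.integer(pos))
    expect_equal(cpp[1], ours$es, tolerance = 1e-14)
    expect_equal(cpp[2], ours$pos_dev, tolerance = 1e-14)
    expect_equal(cpp[3], ours$neg_dev, tolerance = 1e-14)
    fg <- fgsea::calcGseaStat(ranked$score, selectedStats = pos,
                              gseaParam = 1)
    expect_equal(ours$es, fg, tolerance = 1e-12)
  }
})

test_that("size filtering follows the effective-size bounds", {
  ranked <- random_ranked(200, seed = 34)
  sets <- list(tiny = ranked$gene[1:10],
               ok = ranked$gene[5:30],
               huge = ranked$gene[1:150],
               off_universe = c(ranked$gene[1:20], sprintf("x%02d", 1:40)))
  res <- gsea_preranked(ranked, sets, min_size = 15, max_size = 50,
                        n_perm = 100, seed = 1)
  expect_setequal(res$set, c("ok", "off_universe")) # effective size 20
  expect_equal(res$size[res$set == "off_universe"], 20L)
  expect_warning(
    gsea_preranked(ranked, sets["tiny"], min_size = 15, max_size = 50,
                   n_perm = 100, seed = 1),
    "size filter")
})

test_that("a set planted at the top is the most significant, with ES > 0", {
  ranked <- random_ranked(300, seed = 35)
  sets <- c(list(planted = ranked$gene[1:20]),
            lapply(setNames(1:10, paste0("null", 1:10)), function(i) {
              sample(ranked$gene, 25)
            }))
  res <- gsea_preranked(ranked, sets, min_size = 15, max_size = 50,
                        n_perm = 500, seed = 2)
  expect_equal(res$set[1], "planted")
  expect_gt(res$es[res$set == "planted"], 0)
  expect_equal(min(res$p), res$p[res$set == "planted"])
})

test_that("permutations are seeded and ES is independent of their number", {
  ranked <- random_ranked(100, seed = 36)
  sets <- list(a = ranked$gene[10:30], b = sample(ranked$gene, 20))
  r1 <- gsea_preranked(ranked, sets, min_size = 5, max_size = 50,
                       n_perm = 200, seed = 7)
  r2 <- gsea_preranked(ranked, sets, min_size = 5, max_size = 50,
                       n_perm = 200, seed = 7)
  expect_identical(r1, r2)
  r3 <- gsea_preranked(ranked, sets, min_size = 5, max_size = 50,
                       n_perm = 400, seed = 7)
  expect_equal(r3$es[match(r1$set, r3$set)], r1$es) # p resolution only
})

test_that("direction labels and node scores follow the two-run rule", {
  rec <- function(set, p, p_pos, es) {
    tibble::tibble(set = set, size = 20L, es = es, nes = es * 2, p = p,
                   q = p, p_pos = p_pos, p_neg = 1 - p_pos, pos_dev = abs(es),
                   neg_dev = -0.01, leading_edge = list(character()))
  }
  fwd <- dplyr::bind_rows(rec("up_set", 0.001, 0.001, 0.9),
                          rec("down_set", 0.01, 0.9, -0.8),
                          rec("flat", 0.5, 0.5, 0.2))
  bwd <- dplyr::bind_rows(rec("up_set", 0.001, 0.9, -0.9),
                          rec("down_set", 0.01, 0.01, 0.8),
                          rec("flat", 0.5, 0.6, -0.2))
  out <- classify_direction(fwd, bwd, alpha = 0.05)
  expect_equal(out$direction[match(c("up_set", "down_set", "flat"), out$set)],
               c("up", "down", "none"))
  expect_equal(out$node_score[out$set == "up_set"], 3)
  expect_equal(out$node_score[out$set == "down_set"], -2)
  expect_error(classify_direction(fwd, bwd[1:2, ]), "different collections")
})

test_that("a set concentrated at both extremes is labelled 'both'", {
  set.seed(37)
  n <- 300
  ranked <- rank_genes(tibble::tibble(gene = sprintf("g%03d", 1:n),
                                      t = sort(rnorm(n), decreasing = TRUE)))
  bimodal <- c(ranked$gene[1:12], ranked$gene[(n - 11):n])
  sets <- c(list(bimodal = bimodal),
            lapply(setNames(1:8, paste0("null", 1:8)), function(i) {
              sample(ranked$gene, 24)
            }))
  fwd <- gsea_preranked(ranked, sets, min_size = 10, max_size = 50,
                        n_perm = 500, seed = 8)
  rev_ranked <- tibble::tibble(gene = rev(ranked$gene),
                               score = rev(-ranked$score))
  bwd <- gsea_preranked(rev_ranked, sets, min_size = 10, max_size = 50,
                        n_perm = 500, seed = 9)
  out <- classify_direction(fwd, bwd, alpha = 0.05)
  expect_equal(out$direction[out$set == "bimodal"], "both")
  expect_gt(out$node_score[out$set == "bimodal"], 0)
})
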