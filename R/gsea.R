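#' Rank genes by their t-score
#'
#' Orders genes by descending differential-expression t-score; ties are broken
#' lexically by gene id so the ranking is deterministic regardless of input
#' row order.
#'
#' @param de A `trilayer_de` result (or any tibble with `gene` and `t`).
#' @return A tibble with columns `gene` and `score`, ordered for preranked
#'   enrichment.
#' @export
rank_genes <- function(de) {
  if (!is.data.frame(de) || !all(c("gene", "t") %in% names(de))) {
    abort("`de` must have `gene` and `t` columns.")
  }
  de <- filter(de, is.finite(.data$t))
  if (nrow(de) == 0L) abort("no genes with finite t-scores.")
  de |>
    arrange(desc(.data$t), .data$gene) |>
    select(gene = "gene", score = "t")
}

#' Running-sum enrichment score
#'
#' Walks the ranked list; at each member of `genes` ("hit") the running sum
#' increases by \eqn{|s_i|^p / N_R} where \eqn{N_R = \sum_{hits} |s_i|^p}, and
#' at each non-member it decreases by \eqn{1/(N - N_H)}. The enrichment score
#' is the running-sum value of maximal absolute deviation from zero (signed;
#' the first extremum wins on exact ties). The leading edge contains the hits
#' up to and including the extremum (positive ES) or strictly after it
#' (negative ES).
#'
#' @param ranked Output of [rank_genes()] (columns `gene`, `score`).
#' @param genes Character vector, the gene set.
#' @param weight_exponent Nonnegative weighting exponent \eqn{p}; `0` gives
#'   the unweighted Kolmogorov-Smirnov-like statistic, `1` (default) weights
#'   hits by score magnitude.
#' @return A list with `es`, `running_sum` (length = genes in the ranking),
#'   `leading_edge` (character), `pos_dev` and `neg_dev` (the maximal positive
#'   and negative running-sum deviations).
#' @export
#' @examples
#' ranked <- tibble::tibble(gene = paste0("g", 1:5),
#'                          score = c(2, 1, 0.5, -0.5, -1))
#' enrichment_score(ranked, c("g1", "g2"))$es
enrichment_score <- function(ranked, genes, weight_exponent = 1) {
  stopifnot(is.data.frame(ranked), all(c("gene", "score") %in% names(ranked)))
  if (weight_exponent < 0) abort("`weight_exponent` must be nonnegative.")
  hit <- ranked$gene %in% genes
  n_hit <- sum(hit)
  N <- nrow(ranked)
  if (n_hit == 0L) abort("gene set does not intersect the ranked universe.")
  if (n_hit == N) abort("gene set covers the whole universe; miss decrement undefined.")
  w <- abs(ranked$score)^weight_exponent
  nr <- sum(w[hit])
  if (nr == 0) abort("all hit scores are zero; running sum undefined for weight_exponent > 0.")
  inc <- ifelse(hit, w / nr, -1 / (N - n_hit))
  rs <- cumsum(inc)
  i_star <- which.max(abs(rs))
  es <- rs[i_star]
  leading <- if (es >= 0) {
    ranked$gene[hit & seq_len(N) <= i_star]
  } else {
    ranked$gene[hit & seq_len(N) > i_star]
  }
  list(es = es,
       running_sum = rs,
       leading_edge = leading,
       pos_dev = max(0, max(rs)),
       neg_dev = min(0, min(rs)))
}

#' Preranked gene set enrichment with a gene-sampling permutation null
#'
#' For every gene set with effective size (members present in the ranked
#' universe) inside `[min_size, max_size]`, computes the running-sum
#' enrichment score and compares it with a null of `n_perm` random gene sets
#' of the same size drawn from the universe. The permutation p-value is the
#' smoothed same-sign exceedance fraction
#' \eqn{(\#\{|ES_{null}| \ge |ES|\} + 1) / (n_{same sign} + 1)}; NES is ES
#' divided by the mean same-sign null ES; the FDR q-value follows the standard
#' preranked convention (pooled null-vs-observed NES tail ratio, monotone and
#' capped at 1). One-sided p-values for the positive and negative running-sum
#' deviations (`p_pos`, `p_neg`) support direction classification.
#'
#' @param ranked Output of [rank_genes()].
#' @param collection Named list of gene-id vectors (e.g. from [read_gmt()]).
#' @param min_size,max_size Inclusive effective-size filter (defaults 15 and
#'   500).
#' @param weight_exponent Hit-weighting exponent, see [enrichment_score()].
#' @param n_perm Number of permutation draws per set (>= 100; default 1000).
#' @param seed Optional seed for the permutation stream; the caller's RNG
#'   state is restored afterwards.
#' @return A `trilayer_gsea` tibble sorted by `p`: `set`, `size`, `es`, `nes`,
#'   `p`, `q`, `p_pos`, `p_neg`, `pos_dev`, `neg_dev`, `leading_edge`
#'   (list-column). Returns an empty (zero-row) result with a warning when no
#'   set survives the size filter.
#' @export
gsea_preranked <- function(ranked, collection, min_size = 15L,
                           max_size = 500L, weight_exponent = 1,
                           n_perm = 1000L, seed = NULL) {
  if (!length(collection)) abort("`collection` is empty.")
  if (is.null(names(collection)) || anyDuplicated(names(collection))) {
    abort("`collection` must have unique set names.")
  }
  if (min_size < 1L || min_size > max_size) {
    abort("need 1 <= min_size <= max_size.")
  }
  if (n_perm < 100L) abort("`n_perm` must be at least 100.")
  universe <- ranked$gene
  eff <- lapply(collection, function(s) unique(s[s %in% universe]))
  size <- lengths(eff)
  keep <- size >= min_size & size <= max_size & size < length(universe)
  empty <- tibble(set = character(), size = integer(), es = double(),
                  nes = double(), p = double(), q = double(),
                  p_pos = double(), p_neg = double(), pos_dev = double(),
                  neg_dev = double(), leading_edge = list())
  if (!any(keep)) {
    warn("no gene set survives the size filter; returning an empty result.")
    return(structure(empty, class = c("trilayer_gsea", class(empty)),
                     n_perm = n_perm))
  }
  eff <- eff[keep]
  size <- size[keep]
  w <- abs(ranked$score)^weight_exponent

  obs <- lapply(eff, function(s) enrichment_score(ranked, s, weight_exponent))
  es <- map_dbl(obs, "es")
  pos_dev <- map_dbl(obs, "pos_dev")
  neg_dev <- map_dbl(obs, "neg_dev")

  res <- with_seed(seed, {
    null_cache <- new.env(parent = emptyenv())
    null_for <- function(k) {
      key <- as.character(k)
      if (is.null(null_cache[[key]])) {
        null_cache[[key]] <- perm_es_cpp(w, k, as.integer(n_perm))
      }
      null_cache[[key]]
    }
    p <- p_pos <- p_neg <- nes <- numeric(length(eff))
    null_nes <- vector("list", length(eff))
    for (i in seq_along(eff)) {
      nm <- null_for(size[i])
      ne <- nm[, 1]
      pos_mean <- mean(ne[ne >= 0])
      neg_mean <- mean(ne[ne < 0])
      same <- if (es[i] >= 0) ne[ne >= 0] else ne[ne < 0]
      p[i] <- (sum(abs(same) >= abs(es[i])) + 1) / (length(same) + 1)
      p_pos[i] <- (sum(nm[, 2] >= pos_dev[i]) + 1) / (n_perm + 1)
      p_neg[i] <- (sum(nm[, 3] <= neg_dev[i]) + 1) / (n_perm + 1)
      nes[i] <- norm_es(es[i], pos_mean, neg_mean)
      null_nes[[i]] <- norm_es(ne, pos_mean, neg_mean)
    }
    list(p = p, p_pos = p_pos, p_neg = p_neg, nes = nes,
         null_nes = unlist(null_nes))
  })

  q <- gsea_fdr(res$nes, res$null_nes)
  out <- tibble(set = names(eff), size = as.integer(size), es = es,
                nes = res$nes, p = res$p, q = q, p_pos = res$p_pos,
                p_neg = res$p_neg, pos_dev = pos_dev, neg_dev = neg_dev,
                leading_edge = lapply(obs, `[[`, "leading_edge")) |>
    arrange(.data$p, .data$set)
  attr(out, "n_perm") <- n_perm
  attr(out, "weight_exponent") <- weight_exponent
  class(out) <- c("trilayer_gsea", class(out))
  out
}

# ES -> NES using side-specific null means; vectorised
norm_es <- function(es, pos_mean, neg_mean) {
  out <- numeric(length(es))
  pos <- es >= 0
  out[pos] <- if (is.finite(pos_mean) && pos_mean > 0) es[pos] / pos_mean else NA_real_
  out[!pos] <- if (is.finite(neg_mean) && neg_mean < 0) -es[!pos] / neg_mean else NA_real_
  out
}

# standard preranked FDR: for each observed NES, the pooled-null tail fraction
# over the observed tail fraction on the matching sign, monotone, capped at 1
gsea_fdr <- function(obs_nes, null_nes) {
  q <- rep(NA_real_, length(obs_nes))
  for (side in c(1, -1)) {
    o <- if (side > 0) obs_nes >= 0 else obs_nes < 0
    if (!any(o, na.rm = TRUE)) next
    nn <- if (side > 0) null_nes[null_nes >= 0] else null_nes[null_nes < 0]
    ov <- obs_nes[which(o)]
    qi <- vapply(ov, function(v) {
      num <- if (length(nn)) mean(side * nn >= side * v) else 0
      den <- mean(side * ov >= side * v)
      min(1, num / den)
    }, numeric(1))
    # enforce monotonicity: a more extreme NES never has a larger q
    ord <- order(side * ov, decreasing = TRUE)
    qi[ord] <- rev(cummin(rev(qi[ord])))
    q[which(o)] <- qi
  }
  q
}

#' Classify enrichment direction from a forward and a reversed run
#'
#' Combines enrichment results computed on the t-score ranking (`fwd`) and on
#' the negated, reversed ranking (`rev`). Because reversing and negating the
#' ranking exactly negates every enrichment score, direction is judged on each
#' run's one-sided positive-deviation p-value (`p_pos`): a set is `up` when
#' only the forward run shows a significant positive deviation, `down` when
#' only the reversed run does, `both` when both do (members concentrated at
#' both extremes of the ranking), and `none` otherwise. The node score is
#' \eqn{-\log_{10}(\min p)} signed + for `up`/`both` and - for `down`.
#'
#' @param fwd,rev `trilayer_gsea` results for the forward and reversed
#'   rankings over the same collection.
#' @param alpha Significance level for direction calls (default 0.05).
#' @return `fwd` augmented with `direction` (factor: up/down/both/none) and
#'   `node_score`, plus `p_rev` (the reversed run's two-sided p).
#' @export
classify_direction <- function(fwd, rev, alpha = 0.05) {
  stopifnot(is.data.frame(fwd), is.data.frame(rev))
  if (!setequal(fwd$set, rev$set)) {
    abort("forward and reverse runs cover different collections.")
  }
  rev_cols <- rev |>
    select(set = "set", p_rev = "p", p_pos_rev = "p_pos")
  out <- fwd |>
    left_join(rev_cols, by = "set") |>
    mutate(
      direction = dplyr::case_when(
        .data$p_pos < alpha & .data$p_pos_rev < alpha ~ "both",
        .data$p_pos < alpha ~ "up",
        .data$p_pos_rev < alpha ~ "down",
        TRUE ~ "none"
      ),
      node_score = -log10(pmin(.data$p, .data$p_rev)) *
        ifelse(.data$direction == "down", -1, 1)
    ) |>
    select(-"p_pos_rev")
  class(out) <- class(fwd)
  attr(out, "n_perm") <- attr(fwd, "n_perm")
  attr(out, "alpha") <- alpha
  out
}
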