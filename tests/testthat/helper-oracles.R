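# Independent brute-force oracles. Deliberately written as plain loops over
# the defining formulas, sharing no code with the package internals.

# running-sum enrichment score: literal walk over the ranked list
oracle_es <- function(scores, hit, p = 1) {
  N <- length(scores)
  nh <- sum(hit)
  nr <- sum(abs(scores[hit])^p)
  run <- 0
  best <- 0
  rs <- numeric(N)
  for (i in seq_len(N)) {
    if (hit[i]) run <- run + abs(scores[i])^p / nr
    else run <- run - 1 / (N - nh)
    rs[i] <- run
    if (abs(run) > abs(best)) best <- run
  }
  list(es = best, running_sum = rs)
}

# Benjamini-Hochberg step-up from its definition: adjusted p for the i-th
# smallest p is min_{j >= i} min(1, m p_(j) / j)
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(m)
  for (i in seq_len(m)) {
    best <- Inf
    for (j in i:m) best <- min(best, m * ps[j] / j)
    adj[i] <- min(1, best)
  }
  out <- numeric(m)
  out[o] <- adj
  out
}

# average ranks by explicit counting, then the Pearson sum formula on ranks
oracle_rank <- function(x) {
  vapply(seq_along(x), function(i) {
    sum(x < x[i]) + (sum(x == x[i]) + 1) / 2
  }, numeric(1))
}

oracle_spearman <- function(x, y) {
  rx <- oracle_rank(x)
  ry <- oracle_rank(y)
  n <- length(x)
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  den <- sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  rho <- num / den
  tt <- rho * sqrt((n - 2) / (1 - rho^2))
  list(rho = rho, p = 2 * stats::pt(-abs(tt), n - 2))
}

# exact upper-tail hypergeometric by enumerating every k-subset of a small
# universe (first m elements are the "successes")
oracle_hyper_tail <- function(N, m, k, x) {
  subsets <- utils::combn(N, k)
  hits <- colSums(subsets <= m)
  mean(hits >= x)
}

# betweenness via BFS shortest-path counts and the path-composition identity
# sigma_st(v) = sigma_sv * sigma_vt when d(s,v) + d(v,t) = d(s,t)
oracle_betweenness <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  sig <- matrix(0, n, n)
  for (s in seq_len(n)) {
    d[s, s] <- 0
    sig[s, s] <- 1
    frontier <- s
    while (length(frontier)) {
      nxt <- integer(0)
      for (u in frontier) {
        for (v in which(adj[u, ] == 1)) {
          if (!is.finite(d[s, v])) {
            d[s, v] <- d[s, u] + 1
            nxt <- c(nxt, v)
          }
          if (d[s, v] == d[s, u] + 1) sig[s, v] <- sig[s, v] + sig[s, u]
        }
      }
      frontier <- unique(nxt)
    }
  }
  btw <- numeric(n)
  for (v in seq_len(n)) {
    for (s in seq_len(n - 1)) {
      for (t in (s + 1):n) {
        if (s == v || t == v || !is.finite(d[s, t])) next
        if (d[s, v] + d[v, t] == d[s, t]) {
          btw[v] <- btw[v] + sig[s, v] * sig[v, t] / sig[s, t]
        }
      }
    }
  }
  btw
}

# all-pairs edge construction under layer-specific cutoffs, by direct loops
oracle_edges <- function(ids, layers, sets, coef_cutoff = 0.5,
                         physio_cutoff = 0.3,
                         allowed = c("process-process", "regulator-process",
                                     "regulator-physiology",
                                     "physiology-process")) {
  res <- list()
  n <- length(ids)
  rel_name <- function(a, b) {
    ls <- sort(c(a, b))
    if (identical(ls, c("process", "process"))) "process-process"
    else if (identical(ls, c("process", "regulator"))) "regulator-process"
    else if (identical(ls, c("physiology", "regulator"))) "regulator-physiology"
    else if (identical(ls, c("physiology", "process"))) "physiology-process"
    else paste(ls, collapse = "-")
  }
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      rel <- rel_name(layers[i], layers[j])
      if (!rel %in% allowed) next
      ov <- length(intersect(sets[[i]], sets[[j]]))
      if (ov < 1) next
      coef <- ov / min(length(unique(sets[[i]])), length(unique(sets[[j]])))
      cut <- if (rel == "physiology-process") physio_cutoff else coef_cutoff
      if (coef >= cut) {
        res[[length(res) + 1]] <- data.frame(
          a = ids[i], b = ids[j], relationship = rel, overlap = ov,
          coefficient = coef, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(res)) {
    return(data.frame(a = character(), b = character(),
                      relationship = character(), overlap = integer(),
                      coefficient = double()))
  }
  do.call(rbind, res)
}
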