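#' Spearman rank correlation with a t-approximation p-value
#'
#' Computes Spearman's rho as the Pearson correlation of average ranks (ties
#' averaged) after pairwise deletion of missing values, with a two-sided
#' p-value from \eqn{t = \rho\sqrt{(n-2)/(1-\rho^2)}} on \eqn{n - 2} degrees
#' of freedom. A perfect correlation (\eqn{|\rho| = 1}) reports the smallest
#' representable positive p.
#'
#' @param x,y Numeric vectors of equal length.
#' @return A list with `rho`, `p` and `n` (pairs used).
#' @export
#' @examples
#' spearman_cor(1:5, c(2, 4, 6, 8, 10))
spearman_cor <- function(x, y) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length.")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4L) abort("need at least 4 complete pairs.")
  rx <- rank(x); ry <- rank(y)
  if (var(rx) == 0 || var(ry) == 0) {
    abort("zero rank variance; correlation undefined.")
  }
  rho <- cor(rx, ry)
  rho <- max(-1, min(1, rho))
  p <- if (abs(rho) >= 1) {
    .Machine$double.xmin
  } else {
    2 * pt(-abs(rho * sqrt((n - 2) / (1 - rho^2))), df = n - 2L)
  }
  list(rho = rho, p = p, n = n)
}

#' Correlate physiological parameters with gene expression
#'
#' For every parameter and every gene, computes the Spearman correlation
#' across the animals shared between the expression and physiology tables
#' (both diet groups pooled within the timepoint by default, spanning the
#' full phenotype range; set `by_diet` to restrict to one group). A gene
#' belongs to a parameter's correlated set when \eqn{|\rho| >} `rho_cutoff`
#' and \eqn{p <} `alpha`; a parameter is significant when its set is
#' nonempty. Missing parameter values are dropped pairwise (genes are then
#' re-ranked on the reduced animal set).
#'
#' @param expr Expression tibble (`gene` column + sample columns).
#' @param physio Physiology tibble: `animal`, optionally `timepoint`, one
#'   numeric column per parameter.
#' @param timepoint Optional timepoint filter applied to `physio`.
#' @param rho_cutoff Absolute correlation threshold (default 0.8).
#' @param alpha p-value threshold (default 0.05).
#' @param by_diet Optional diet label; with `samples` given, restricts the
#'   animals to that diet group.
#' @param samples Sample table (needed only for `by_diet`).
#' @return A `trilayer_physio` tibble, one row per parameter: `parameter`,
#'   `n_animals`, `n_genes` (significant genes), `significant`, and `genes`,
#'   a list-column of per-gene tibbles (`gene`, `rho`, `p`).
#' @export
correlate_parameters <- function(expr, physio, timepoint = NULL,
                                 rho_cutoff = 0.8, alpha = 0.05,
                                 by_diet = NULL, samples = NULL) {
  stopifnot(is.data.frame(expr), is.data.frame(physio))
  if (!"gene" %in% names(expr)) abort("`expr` must have a `gene` column.")
  if (!"animal" %in% names(physio)) {
    abort("`physio` must have an `animal` column.")
  }
  ph <- physio
  if (!is.null(timepoint) && "timepoint" %in% names(ph)) {
    ph <- filter(ph, .data$timepoint == !!timepoint)
  }
  if (!is.null(by_diet)) {
    if (is.null(samples)) abort("`by_diet` requires `samples`.")
    keep <- samples$sample[samples$diet == by_diet]
    ph <- filter(ph, .data$animal %in% keep)
  }
  animals <- intersect(ph$animal, names(expr))
  if (length(animals) < 4L) {
    abort("fewer than 4 animals shared between expression and physiology.")
  }
  ph <- ph[match(animals, ph$animal), , drop = FALSE]
  X <- as.matrix(expr[, animals])
  rownames(X) <- expr$gene
  params <- setdiff(names(ph), c("animal", "timepoint"))
  params <- params[vapply(ph[params], is.numeric, logical(1))]
  if (!length(params)) abort("no numeric parameter columns in `physio`.")

  rows <- lapply(params, function(pm) {
    yv <- ph[[pm]]
    ok <- is.finite(yv)
    n <- sum(ok)
    if (n < 4L) {
      return(tibble(parameter = pm, n_animals = n, n_genes = 0L,
                    significant = FALSE,
                    genes = list(tibble(gene = character(), rho = double(),
                                        p = double()))))
    }
    Xs <- X[, ok, drop = FALSE]
    R <- t(apply(Xs, 1L, rank))
    ry <- rank(yv[ok])
    Rc <- R - rowMeans(R)
    yc <- ry - mean(ry)
    denom <- sqrt(rowSums(Rc^2) * sum(yc^2))
    rho <- as.vector(Rc %*% yc) / denom
    rho[!is.finite(rho)] <- NA_real_ # constant genes
    rho <- pmax(-1, pmin(1, rho))
    p <- ifelse(abs(rho) >= 1, .Machine$double.xmin,
                2 * pt(-abs(rho * sqrt((n - 2) / (1 - rho^2))), df = n - 2L))
    hit <- !is.na(rho) & abs(rho) > rho_cutoff & p < alpha
    gt <- tibble(gene = rownames(Xs)[hit], rho = rho[hit], p = p[hit]) |>
      arrange(.data$p, .data$gene)
    tibble(parameter = pm, n_animals = n, n_genes = sum(hit),
           significant = sum(hit) > 0L, genes = list(gt))
  })
  out <- bind_rows(rows)
  attr(out, "rho_cutoff") <- rho_cutoff
  attr(out, "alpha") <- alpha
  attr(out, "timepoint") <- timepoint %||% NA_character_
  class(out) <- c("trilayer_physio", class(out))
  out
}
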