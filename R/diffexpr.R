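#' Moderated two-sample t-test for a two-diet contrast
#'
#' Per-gene HFD vs LFD differential expression on log2 values using an
#' equal-variance pooled t-statistic with a fixed-prior variance moderation:
#' the pooled variance \eqn{s_g^2} (df \eqn{d_g = n_A + n_B - 2}) is shrunk
#' towards a prior \eqn{s_0^2} with prior df \eqn{d_0},
#' \deqn{\tilde{s}^2 = (d_0 s_0^2 + d_g s_g^2) / (d_0 + d_g),}
#' and \eqn{t = (\bar{x}_{HFD} - \bar{x}_{LFD}) / (\tilde{s}\sqrt{1/n_A + 1/n_B})}
#' is referred to a t-distribution on \eqn{d_0 + d_g} df. With `prior_df = 0`
#' this is exactly the ordinary pooled two-sample t-test. FDR adjustment is
#' Benjamini-Hochberg.
#'
#' Genes with any missing value among the selected samples are dropped from
#' the test (their count is recorded in the `n_dropped` attribute).
#'
#' @param expr Expression tibble: a `gene` column plus one numeric column per
#'   sample (log2 scale).
#' @param samples Sample table with columns `sample`, `diet` (values "HFD",
#'   "LFD") and optionally `timepoint`.
#' @param timepoint If given, restrict to samples at this timepoint.
#' @param prior_df Nonnegative prior degrees of freedom \eqn{d_0} (default 4).
#' @param prior_var Optional prior variance \eqn{s_0^2}; defaults to the mean
#'   pooled variance across genes.
#' @return A `trilayer_de` tibble with columns `gene`, `logfc` (HFD - LFD,
#'   log2), `t`, `p`, `fdr`, sorted by `p`. Attributes record `prior_df`,
#'   `prior_var`, group sizes and the timepoint.
#' @export
#' @examples
#' study <- generate_study(synth_config(n_genes = 200, seed = 1))
#' de <- moderated_ttest(study$expression, study$samples, timepoint = "5d")
#' head(de)
moderated_ttest <- function(expr, samples, timepoint = NULL,
                            prior_df = 4, prior_var = NULL) {
  stopifnot(is.data.frame(expr), is.data.frame(samples))
  if (!"gene" %in% names(expr)) abort("`expr` must have a `gene` column.")
  if (anyDuplicated(expr$gene)) abort("duplicate gene ids in `expr`.")
  if (!all(c("sample", "diet") %in% names(samples))) {
    abort("`samples` must have `sample` and `diet` columns.")
  }
  if (prior_df < 0) abort("`prior_df` must be nonnegative.")
  smp <- samples
  if (!is.null(timepoint)) {
    if (!"timepoint" %in% names(smp)) {
      abort("`samples` has no `timepoint` column.")
    }
    smp <- filter(smp, .data$timepoint == !!timepoint)
  }
  if (!all(smp$diet %in% c("HFD", "LFD"))) {
    abort("`diet` must be 'HFD' or 'LFD'.")
  }
  smp <- filter(smp, .data$sample %in% names(expr))
  a <- smp$sample[smp$diet == "HFD"]
  b <- smp$sample[smp$diet == "LFD"]
  if (length(a) < 2L || length(b) < 2L) {
    abort("each diet group needs at least 2 samples.")
  }
  X <- as.matrix(expr[, c(a, b)])
  rownames(X) <- expr$gene
  keep <- stats::complete.cases(X)
  n_dropped <- sum(!keep)
  X <- X[keep, , drop = FALSE]
  if (nrow(X) == 0L) abort("no genes with complete data.")

  nA <- length(a); nB <- length(b)
  XA <- X[, a, drop = FALSE]; XB <- X[, b, drop = FALSE]
  mA <- rowMeans(XA); mB <- rowMeans(XB)
  vA <- rowSums((XA - mA)^2) / (nA - 1L)
  vB <- rowSums((XB - mB)^2) / (nB - 1L)
  dg <- nA + nB - 2L
  s2 <- ((nA - 1L) * vA + (nB - 1L) * vB) / dg
  s0 <- if (is.null(prior_var)) mean(s2) else as.numeric(prior_var)
  if (s0 < 0) abort("`prior_var` must be nonnegative.")
  post <- if (is.finite(prior_df)) {
    (prior_df * s0 + dg * s2) / (prior_df + dg)
  } else {
    rep(s0, length(s2))
  }
  degenerate <- post == 0
  if (any(degenerate)) {
    warn(paste0(sum(degenerate), " gene(s) with zero posterior variance; ",
                "their t and p are reported as NA."))
  }
  se <- sqrt(post * (1 / nA + 1 / nB))
  tval <- ifelse(degenerate, NA_real_, (mA - mB) / se)
  df_t <- if (is.finite(prior_df)) prior_df + dg else Inf
  pval <- 2 * pt(-abs(tval), df = df_t)
  out <- tibble(gene = rownames(X), logfc = unname(mA - mB),
                t = unname(tval), p = unname(pval),
                fdr = bh_adjust(unname(pval))) |>
    arrange(.data$p, .data$gene)
  attr(out, "prior_df") <- prior_df
  attr(out, "prior_var") <- s0
  attr(out, "n_hfd") <- nA
  attr(out, "n_lfd") <- nB
  attr(out, "timepoint") <- timepoint %||% NA_character_
  attr(out, "n_dropped") <- n_dropped
  class(out) <- c("trilayer_de", class(out))
  out
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false discovery rate adjustment. Input order is preserved.
#'
#' @param pvalues Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values in `[0, 1]`, same length and order.
#' @export
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))
bh_adjust <- function(pvalues) {
  if (!is.numeric(pvalues)) abort("`pvalues` must be numeric.")
  bad <- !is.na(pvalues) & (pvalues < 0 | pvalues > 1)
  if (any(bad)) abort("p-values must lie in [0, 1].")
  p.adjust(pvalues, method = "BH")
}
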