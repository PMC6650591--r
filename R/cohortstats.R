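#' Two-standard-deviation outlier exclusion
#'
#' Single pass: points with `|x - mean| > n_sd * SD` (sample SD, n-1
#' denominator) are dropped. Applied once, not iteratively; when all values
#' are equal the SD is zero and nothing is removed.
#'
#' @param values numeric vector, length >= 3.
#' @param n_sd exclusion threshold in SD units (default 2).
#' @return list with `keep` (logical mask), `n_removed`, `mean`, `sd`.
#' @export
exclude_outliers <- function(values, n_sd = 2) {
  if (length(values) < 3) stop("need at least 3 values")
  if (!all(is.finite(values))) stop("values must be finite")
  m <- mean(values); s <- sd(values)
  keep <- abs(values - m) <= n_sd * s
  list(keep = keep, n_removed = sum(!keep), mean = m, sd = s)
}

#' Benjamini-Hochberg false discovery rate correction
#'
#' Step-up adjusted p-values (via [stats::p.adjust()]) and the rejection
#' mask at level `q`.
#'
#' @param pvals raw p-values in `[0, 1]`.
#' @param q FDR level (default 0.05).
#' @return list with `p_adj` and logical `reject`.
#' @export
fdr_bh <- function(pvals, q = 0.05) {
  if (any(!is.finite(pvals)) || any(pvals < 0 | pvals > 1))
    stop("p-values must lie in [0, 1]")
  p_adj <- p.adjust(pvals, method = "BH")
  list(p_adj = p_adj, reject = p_adj <= q)
}

#' Nonparametric rank tests used in the cohort pipelines
#'
#' Thin, contract-checked interface over the standard rank tests, always
#' two-sided with midrank tie handling:
#' \describe{
#'   \item{`kruskal_wallis`}{`samples` is a list of >= 2 groups (each n >= 3);
#'     tie-corrected H statistic with chi-squared p.}
#'   \item{`wilcoxon_signed_rank`}{`samples` is a numeric vector of paired
#'     differences (or a list of two paired vectors); exact p for small
#'     samples without ties, normal approximation otherwise; requires >= 5
#'     nonzero differences and rejects all-zero input.}
#'   \item{`mann_whitney`}{`samples` is a list of two independent groups
#'     (each n >= 3); U statistic.}
#' }
#'
#' @param samples see Details per design.
#' @param design one of `"kruskal_wallis"`, `"wilcoxon_signed_rank"`,
#'   `"mann_whitney"`.
#' @return list with `design`, `statistic`, `df` (Kruskal-Wallis only),
#'   `p_value`, `n`.
#' @export
rank_tests <- function(samples,
                       design = c("kruskal_wallis", "wilcoxon_signed_rank",
                                  "mann_whitney")) {
  design <- match.arg(design)
  if (design == "kruskal_wallis") {
    stopifnot(is.list(samples), length(samples) >= 2)
    if (any(vapply(samples, length, 1L) < 3))
      stop("each group needs at least 3 observations")
    ht <- kruskal.test(samples)
    return(list(design = design, statistic = unname(ht$statistic),
                df = unname(ht$parameter), p_value = ht$p.value,
                n = sum(lengths(samples))))
  }
  if (design == "wilcoxon_signed_rank") {
    d <- if (is.list(samples)) {
      stopifnot(length(samples) == 2,
                length(samples[[1]]) == length(samples[[2]]))
      samples[[1]] - samples[[2]]
    } else samples
    nz <- d[d != 0]
    if (length(nz) == 0) stop("all paired differences are zero")
    if (length(nz) < 5) stop("need at least 5 nonzero differences")
    ht <- suppressWarnings(wilcox.test(d, alternative = "two.sided"))
    return(list(design = design, statistic = unname(ht$statistic),
                df = NULL, p_value = ht$p.value, n = length(nz)))
  }
  stopifnot(is.list(samples), length(samples) == 2)
  if (any(vapply(samples, length, 1L) < 3))
    stop("each group needs at least 3 observations")
  ht <- suppressWarnings(wilcox.test(samples[[1]], samples[[2]],
                                     alternative = "two.sided"))
  list(design = design, statistic = unname(ht$statistic), df = NULL,
       p_value = ht$p.value, n = sum(lengths(samples)))
}

#' Spearman rank correlation with two-sided p
#'
#' Pearson correlation of midranks; the p-value uses the exact permutation
#' null for small tie-free samples and the asymptotic approximation
#' otherwise (via [stats::cor.test()]).
#'
#' @param x,y numeric vectors of equal length >= 4; neither constant.
#' @return list with `rho`, `p_value`, `n`.
#' @export
spearman_cor <- function(x, y) {
  if (length(x) != length(y)) stop("lengths differ")
  if (length(x) < 4) stop("need at least 4 pairs")
  if (sd(x) == 0 || sd(y) == 0) stop("rho undefined for constant input")
  ht <- suppressWarnings(cor.test(x, y, method = "spearman",
                                  alternative = "two.sided"))
  list(rho = unname(ht$estimate), p_value = ht$p.value, n = length(x))
}
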