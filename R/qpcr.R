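#' Relative expression by the 2^-ddCt method
#'
#' Classic qPCR relative quantification. Per sample,
#' `dCt = Ct_target - mean(Ct of reference genes)`; then
#' `ddCt = dCt - mean(dCt over calibrator samples)` and the relative
#' expression is `2^-ddCt`. Multiple reference genes are combined by the
#' arithmetic mean of their Ct values (equivalent to the geometric mean of
#' the linear quantities). Samples missing a reference Ct are dropped with a
#' warning. Adding any constant to all Ct values leaves the fold changes
#' unchanged.
#'
#' @param ct Tibble: `sample` column, optional `group` column, one numeric Ct
#'   column per gene.
#' @param target Name of the target gene column.
#' @param refs Character vector of reference gene columns.
#' @param calibrator Value of `group` (or a vector of sample ids if no
#'   `group` column) defining the calibrator samples.
#' @return Tibble with columns `sample`, (`group`,) `dct`, `ddct`,
#'   `rel_expr` (= `2^-ddct`).
#' @examples
#' ct <- tibble::tibble(
#'   sample = c("c1", "t1"), group = c("ctl", "trt"),
#'   goi = c(24, 25), ref = c(20, 20)
#' )
#' delta_delta_ct(ct, "goi", "ref", calibrator = "ctl")
#' @export
delta_delta_ct <- function(ct, target, refs, calibrator) {
  if (!target %in% names(ct)) abort_bad_arg("target gene column not found")
  if (!all(refs %in% names(ct))) abort_bad_arg("reference gene column(s) missing")
  vals <- as.matrix(ct[, c(target, refs)])
  if (any(!is.finite(vals)) ) {
    drop <- !stats::complete.cases(vals)
    rlang::warn(sprintf(
      "dropping %d sample(s) with missing Ct values", sum(drop)
    ))
    ct <- ct[!drop, , drop = FALSE]
  }
  ref_ct <- rowMeans(as.matrix(ct[, refs, drop = FALSE]))
  dct <- ct[[target]] - ref_ct
  cal <- if ("group" %in% names(ct)) {
    ct$group %in% calibrator
  } else {
    ct$sample %in% calibrator
  }
  if (!any(cal)) abort_bad_arg("calibrator group is empty")
  ddct <- dct - mean(dct[cal])
  out <- tibble::tibble(sample = ct$sample)
  if ("group" %in% names(ct)) out$group <- ct$group
  out$dct <- dct
  out$ddct <- ddct
  out$rel_expr <- 2^-ddct
  out
}

#' t-test on log10 relative expression between two groups
#'
#' Companion test for [delta_delta_ct()] output: a two-sample t-test on
#' `log10(rel_expr)` between two groups (the customary scale for fold-change
#' comparisons).
#'
#' @param rel Output of [delta_delta_ct()] with a `group` column.
#' @param groups Length-2 character vector of group labels to compare.
#' @param var_equal Pooled-variance (Student) test if `TRUE` (default).
#' @return One-row tibble: `group1`, `group2`, `mean_log10_1`,
#'   `mean_log10_2`, `estimate` (difference), `statistic`, `p_value`.
#' @export
ddct_t_test <- function(rel, groups, var_equal = TRUE) {
  if (!"group" %in% names(rel)) abort_bad_arg("rel needs a group column")
  x <- log10(rel$rel_expr[rel$group == groups[1]])
  y <- log10(rel$rel_expr[rel$group == groups[2]])
  if (length(x) < 2 || length(y) < 2) {
    abort_bad_arg("each group needs >= 2 samples")
  }
  tt <- stats::t.test(y, x, var.equal = var_equal)
  tibble::tibble(
    group1 = groups[1], group2 = groups[2],
    mean_log10_1 = mean(x), mean_log10_2 = mean(y),
    estimate = mean(y) - mean(x),
    statistic = unname(tt$statistic),
    p_value = tt$p.value
  )
}

#' Per-gene z-score normalization for heatmap display
#'
#' Centres and scales each gene (row) to mean 0 and sd 1 (sample sd, n-1).
#' By default the z-scores are computed over the means of the
#' genotype-by-condition groups — so white in a heatmap represents average
#' expression across groups — and per-sample scaling is available with
#' `groups = NULL`. Constant genes cannot be scaled: their rows are set to 0
#' and their names recorded in attribute `flagged`.
#'
#' @param expr Gene-by-sample table (tibble with `gene` column or matrix).
#' @param groups Optional named assignment of samples to groups (a tibble
#'   with `sample`, `group` columns); if given, columns of the output are the
#'   groups and values are z-scores of group means.
#' @return Tibble: `gene` column plus one column per sample (or per group),
#'   each non-constant row with mean 0 and sd 1; attribute `flagged` lists
#'   constant genes.
#' @examples
#' zscore_by_gene(tibble::tibble(gene = "g", a = 1, b = 2, c = 3))
#' @export
zscore_by_gene <- function(expr, groups = NULL) {
  m <- as_feature_matrix(expr)
  if (!is.null(groups)) {
    if (!all(c("sample", "group") %in% names(groups))) {
      abort_bad_arg("groups needs sample and group columns")
    }
    gl <- groups$group[match(colnames(m), groups$sample)]
    if (anyNA(gl)) abort_bad_arg("every sample column needs a group")
    m <- vapply(
      split(seq_len(ncol(m)), gl),
      function(i) rowMeans(m[, i, drop = FALSE]),
      numeric(nrow(m))
    )
  }
  if (ncol(m) < 2) abort_bad_arg("need at least 2 columns to scale")
  mu <- rowMeans(m)
  sdv <- sqrt(rowSums((m - mu)^2) / (ncol(m) - 1))
  flagged <- rownames(m)[sdv == 0]
  z <- (m - mu) / ifelse(sdv == 0, 1, sdv)
  z[sdv == 0, ] <- 0
  out <- matrix_to_tbl(z)
  attr(out, "flagged") <- flagged
  out
}
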