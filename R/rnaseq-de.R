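#' Median-of-ratios size factors
#'
#' Per-sample scaling factors computed as the median, over genes with strictly
#' positive counts in every sample, of the ratio of the gene's count to its
#' across-sample geometric mean. Normalized counts are `count / size_factor`.
#'
#' @param counts Gene-by-sample counts: tibble with a `gene` first column, or
#'   a rownamed matrix.
#' @param allow_pseudo_reference If no gene has all-positive counts the
#'   default is to error; set `TRUE` to fall back to a pseudo-reference built
#'   from each gene's positive counts only.
#' @return Tibble with columns `sample` and `size_factor` (all positive). The
#'   geometric mean of the factors is stored in attribute `geo_mean`.
#' @examples
#' counts <- tibble::tibble(gene = c("g1", "g2", "g3"), s1 = c(2, 3, 4), s2 = c(4, 6, 8))
#' size_factors(counts)
#' @export
size_factors <- function(counts, allow_pseudo_reference = FALSE) {
  m <- as_feature_matrix(counts)
  if (any(m < 0)) abort_bad_arg("counts must be non-negative")
  logm <- log(m)
  all_pos <- rowSums(is.finite(logm)) == ncol(m)
  if (!any(all_pos)) {
    if (!allow_pseudo_reference) {
      abort_bad_arg(paste0(
        "no gene has positive counts in every sample; rerun with ",
        "allow_pseudo_reference = TRUE to use a positive-count pseudo-reference"
      ))
    }
    # pseudo-reference over each gene's positive counts only
    logm[!is.finite(logm)] <- NA_real_
    geo <- rowMeans(logm, na.rm = TRUE)
    use <- is.finite(geo)
  } else {
    geo <- rowMeans(logm)
    use <- all_pos
  }
  sf <- apply(logm[use, , drop = FALSE] - geo[use], 2, stats::median, na.rm = TRUE)
  sf <- exp(sf)
  out <- tibble::tibble(sample = colnames(m), size_factor = unname(sf))
  attr(out, "geo_mean") <- exp(mean(log(sf)))
  out
}

#' Normalize counts by size factors
#'
#' @inheritParams size_factors
#' @param factors Output of [size_factors()]; computed if `NULL`.
#' @return Tibble in the same gene-by-sample layout with each column divided
#'   by its sample's size factor.
#' @export
normalize_counts <- function(counts, factors = NULL) {
  m <- as_feature_matrix(counts)
  if (is.null(factors)) factors <- size_factors(counts)
  sf <- factors$size_factor[match(colnames(m), factors$sample)]
  if (anyNA(sf)) abort_bad_arg("size factors missing for some samples")
  matrix_to_tbl(sweep(m, 2, sf, `/`))
}

#' Method-of-moments dispersion estimates with trend shrinkage
#'
#' Per-gene negative-binomial dispersion (variance = mu + alpha mu^2)
#' estimated by pooling within-group moments of normalized counts, then
#' shrunk on the log scale toward a fitted `a0 + a1 / mean` trend. Estimates
#' are floored at `floor`.
#'
#' @inheritParams size_factors
#' @param design Design tibble with `sample_id` and `group` columns.
#' @param factors Size factors (computed if `NULL`).
#' @param shrink Weight in (0,1) put on the trend on the log scale.
#' @param floor Minimum dispersion returned.
#' @return Tibble with columns `gene`, `base_mean`, `dispersion_raw`,
#'   `dispersion` (shrunk).
#' @export
estimate_dispersions <- function(counts, design, factors = NULL,
                                 shrink = 0.5, floor = 1e-4) {
  m <- as_feature_matrix(counts)
  design <- validate_design(design)
  m <- match_design(m, design)
  if (all(table(design$group) < 2)) {
    abort_bad_arg("no group has >= 2 replicates; within-group variance undefined")
  }
  norm <- as_feature_matrix(normalize_counts(m, factors))
  groups <- split(seq_len(ncol(norm)), design$group)
  groups <- groups[vapply(groups, length, 1L) >= 2]
  num <- 0
  den <- 0
  for (idx in groups) {
    sub <- norm[, idx, drop = FALSE]
    mu <- rowMeans(sub)
    v <- rowSums((sub - mu)^2) / (length(idx) - 1)
    w <- length(idx) - 1
    num <- num + w * (v - mu)
    den <- den + w * mu^2
  }
  raw <- ifelse(den > 0, num / den, NA_real_)
  base_mean <- rowMeans(norm)
  ok <- is.finite(raw) & raw > 0 & base_mean > 0
  if (sum(ok) >= 10) {
    fit <- stats::lm(raw[ok] ~ I(1 / base_mean[ok]))
    co <- pmax(stats::coef(fit), 0)
    trend <- pmax(co[1] + co[2] / base_mean, floor)
  } else {
    trend <- rep(pmax(stats::median(raw[ok], na.rm = TRUE), floor), length(raw))
  }
  # genes with no observable over-dispersion sit at the floor; the rest are
  # blended with the trend on the log scale
  disp <- rep(floor, length(raw))
  blend <- is.finite(raw) & raw > floor
  disp[blend] <- exp(
    shrink * log(trend[blend]) + (1 - shrink) * log(raw[blend])
  )
  disp[!is.finite(disp)] <- trend[!is.finite(disp)]
  tibble::tibble(
    gene = rownames(m),
    base_mean = unname(base_mean),
    dispersion_raw = unname(raw),
    dispersion = pmax(unname(disp), floor)
  )
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Thin validated wrapper around `stats::p.adjust(method = "BH")`, the
#' correction applied within each caller and contrast.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Step-up adjusted values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  check_probs(p)
  stats::p.adjust(p, method = "BH")
}

# One NB GLM fit (log link, fixed dispersion) for a two-group design.
# Returns c(lfc, p_wald, p_lrt). Small-sample corrections: the Wald
# statistic is scaled by the root quasi-dispersion (residual deviance over
# residual df) and referred to a t distribution on n - 2 df; the deviance
# difference gets a Bartlett-type (n - p)/n scaling before the chi-squared
# reference. Both keep the nominal type-I level at few replicates per group.
fit_nb_gene <- function(y, x01, off, alpha) {
  fam <- MASS::negative.binomial(theta = 1 / alpha)
  X <- cbind(1, x01)
  fit <- tryCatch(
    suppressWarnings(stats::glm.fit(X, y, family = fam, offset = off)),
    error = function(e) NULL
  )
  if (is.null(fit) || !fit$converged) {
    return(c(NA_real_, NA_real_, NA_real_))
  }
  n <- length(y)
  df_res <- n - 2
  b <- stats::coef(fit)[2]
  R <- qr.R(fit$qr)
  se <- sqrt(diag(chol2inv(R)))[2]
  quasi <- max(fit$deviance / df_res, 1e-8)
  p_wald <- 2 * stats::pt(-abs(b / se) / sqrt(quasi), df = df_res)
  fit0 <- suppressWarnings(stats::glm.fit(X[, 1, drop = FALSE], y,
    family = fam, offset = off
  ))
  dev <- max(fit0$deviance - fit$deviance, 0) * df_res / n
  p_lrt <- stats::pchisq(dev, 1, lower.tail = FALSE)
  c(b / log(2), p_wald, p_lrt)
}

#' Call differential expression for one contrast with one caller
#'
#' Three methodologically distinct simplified callers are provided:
#' * `nb_wald` — per-gene negative-binomial log-linear model (size-factor
#'   offset, trend-shrunk dispersion); the Wald statistic of the group
#'   coefficient is scaled by the root quasi-dispersion (residual deviance /
#'   residual df) and referred to a t distribution on `n - 2` df;
#' * `nb_lrt` — likelihood-ratio test of the group term in the same model,
#'   with a Bartlett-type `(n - p)/n` deviance scaling;
#' * `logt` — pooled-variance two-sample t-test on `log2(normalized + 1)`.
#'
#' P-values are BH-adjusted within the contrast. Genes with zero counts in
#' every used sample are dropped before testing (their fold changes are
#' undefined); the dropped identifiers are kept in attribute `dropped`.
#'
#' @inheritParams estimate_dispersions
#' @param contrast Length-2 character vector of group labels,
#'   `c(reference, test)`; reported log2 fold change is test vs reference.
#' @param caller One of `"nb_wald"`, `"nb_lrt"`, `"logt"`.
#' @param dispersions Optional output of [estimate_dispersions()]; computed
#'   from the two contrast groups if `NULL` (ignored by `logt`).
#' @return Tibble with columns `gene`, `contrast`, `caller`, `base_mean`,
#'   `lfc`, `p`, `q`.
#' @export
de_call <- function(counts, design, contrast,
                    caller = c("nb_wald", "nb_lrt", "logt"),
                    factors = NULL, dispersions = NULL) {
  caller <- match.arg(caller)
  m <- as_feature_matrix(counts)
  design <- validate_design(design)
  m <- match_design(m, design)
  if (length(contrast) != 2 || !all(contrast %in% design$group)) {
    abort_bad_arg("contrast must name two groups present in the design")
  }
  if (is.null(factors)) factors <- size_factors(m, allow_pseudo_reference = TRUE)
  keep_s <- design$group %in% contrast
  sub_design <- design[keep_s, ]
  sub <- m[, sub_design$sample_id, drop = FALSE]
  sf <- factors$size_factor[match(colnames(sub), factors$sample)]
  nonzero <- rowSums(sub) > 0
  dropped <- rownames(sub)[!nonzero]
  if (length(dropped)) {
    rlang::inform(sprintf("dropping %d all-zero genes", length(dropped)))
  }
  sub <- sub[nonzero, , drop = FALSE]
  x01 <- as.integer(sub_design$group == contrast[2])
  contrast_label <- paste(contrast[1], "vs", contrast[2], sep = "_")

  if (caller == "logt") {
    norm <- sweep(sub, 2, sf, `/`)
    lg <- log2(norm + 1)
    tt <- row_student_t(
      lg[, x01 == 0, drop = FALSE],
      lg[, x01 == 1, drop = FALSE]
    )
    out <- tibble::tibble(
      gene = rownames(sub),
      base_mean = unname(rowMeans(norm)),
      lfc = tt$mean2 - tt$mean1,
      p = tt$p
    )
  } else {
    if (is.null(dispersions)) {
      dispersions <- estimate_dispersions(sub, sub_design,
        factors = factors[match(colnames(sub), factors$sample), ]
      )
    }
    alpha <- dispersions$dispersion[match(rownames(sub), dispersions$gene)]
    alpha[!is.finite(alpha)] <- 1e-4
    off <- log(sf)
    res <- vapply(
      seq_len(nrow(sub)),
      function(i) fit_nb_gene(sub[i, ], x01, off, alpha[i]),
      numeric(3)
    )
    p <- if (caller == "nb_wald") res[2, ] else res[3, ]
    out <- tibble::tibble(
      gene = rownames(sub),
      base_mean = unname(rowMeans(sweep(sub, 2, sf, `/`))),
      lfc = unname(res[1, ]),
      p = unname(p)
    )
  }
  out$p[!is.finite(out$p)] <- 1
  out$p <- pmin(pmax(out$p, 0), 1)
  out <- dplyr::mutate(out,
    contrast = contrast_label, caller = caller, q = bh_adjust(.data$p),
    .after = "gene"
  )
  attr(out, "dropped") <- dropped
  out
}

#' Extract a significant-gene call set from a DE table
#'
#' @param de_table Output of [de_call()].
#' @param alpha Significance threshold on the BH-adjusted p-value.
#' @param mapper_group Label of the read-mapper run that produced the counts.
#' @return Tibble with columns `contrast`, `caller`, `mapper_group`, `gene`.
#' @export
call_set <- function(de_table, alpha = 0.05, mapper_group = "default") {
  sig <- dplyr::filter(de_table, .data$q < alpha)
  tibble::tibble(
    contrast = sig$contrast, caller = sig$caller,
    mapper_group = mapper_group, gene = sig$gene
  )
}

#' Consensus differential-expression calls
#'
#' A gene enters the consensus set only if, within every mapper group, it is
#' called significant by at least `min_methods` callers, and (optionally) its
#' identifier exists in a declared universe. This is the strict reading of a
#' "significant regardless of mapping strategy by at least two of three
#' methods" rule; `combine = "union"` relaxes the across-mapper intersection.
#'
#' @param call_sets Tibble of stacked [call_set()] rows (columns `contrast`,
#'   `caller`, `mapper_group`, `gene`), all for one contrast.
#' @param min_methods Minimum number of supporting callers per mapper group.
#' @param universe Optional character vector; genes outside it are excluded.
#' @param combine `"intersection"` (default: the rule must hold in every
#'   mapper group) or `"union"` (in at least one).
#' @return Tibble with columns `contrast`, `gene`, `support` (minimum, across
#'   mapper groups, of the number of supporting callers) and one logical
#'   column per mapper group.
#' @export
consensus_calls <- function(call_sets, min_methods = 2, universe = NULL,
                            combine = c("intersection", "union")) {
  combine <- match.arg(combine)
  if (!nrow(call_sets)) abort_bad_arg("call_sets is empty")
  if (dplyr::n_distinct(call_sets$contrast) != 1) {
    abort_bad_arg("call sets span more than one contrast")
  }
  groups <- unique(call_sets$mapper_group)
  support <- dplyr::summarise(
    dplyr::group_by(call_sets, .data$gene, .data$mapper_group),
    n_callers = dplyr::n_distinct(.data$caller), .groups = "drop"
  )
  wide <- tidyr::pivot_wider(support,
    names_from = "mapper_group", values_from = "n_callers", values_fill = 0L
  )
  sup_m <- as.matrix(wide[, groups, drop = FALSE])
  ok_each <- sup_m >= min_methods
  keep <- if (combine == "intersection") {
    rowSums(ok_each) == length(groups)
  } else {
    rowSums(ok_each) > 0
  }
  out <- tibble::tibble(
    contrast = call_sets$contrast[1],
    gene = wide$gene,
    support = apply(sup_m, 1, min)
  )
  for (g in groups) out[[paste0("ok_", g)]] <- ok_each[, g]
  out <- out[keep, ]
  if (!is.null(universe)) out <- dplyr::filter(out, .data$gene %in% universe)
  dplyr::arrange(out, .data$gene)
}
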