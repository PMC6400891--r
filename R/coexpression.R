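#' Select the most variable genes
#'
#' Ranks genes by their across-sample variance and keeps the top `k`. By
#' convention the variance is computed on the normalized counts before the
#' log transform (`on = "raw"`); set `on = "log"` to rank on
#' `log2(normalized + 1)` instead. Ties are broken by stable gene-label
#' order, so the selection is deterministic.
#'
#' @param expr Gene-by-sample table (tibble with `gene` first column, or a
#'   rownamed matrix) of normalized counts.
#' @param k Number of genes to keep (`0 < k <=` gene count).
#' @param on `"raw"` or `"log"`: the scale on which the variance is ranked.
#' @return Tibble in the same layout restricted to the selected genes, in
#'   decreasing-variance order.
#' @export
top_variable_genes <- function(expr, k = 8000, on = c("raw", "log")) {
  on <- match.arg(on)
  m <- as_feature_matrix(expr)
  if (k <= 0 || k > nrow(m)) abort_bad_arg("k must lie in (0, number of genes]")
  v <- if (on == "log") {
    matrixStats_rowVars(log2(m + 1))
  } else {
    matrixStats_rowVars(m)
  }
  ord <- order(-v, rownames(m))
  matrix_to_tbl(m[ord[seq_len(k)], , drop = FALSE])
}

# rowVars without the matrixStats dependency.
matrixStats_rowVars <- function(m) {
  mu <- rowMeans(m)
  rowSums((m - mu)^2) / (ncol(m) - 1)
}

#' Soft-threshold co-expression adjacency
#'
#' Computes `a_ij = |cor(x_i, x_j)|^beta` (unsigned network, the default) or
#' the signed variant `((1 + cor)/2)^beta` between all gene pairs. The power
#' beta soft-thresholds weak correlations toward zero. The diagonal is set to
#' zero. Zero-variance genes have undefined correlations; their rows and
#' columns are zeroed and their names attached as attribute
#' `zero_variance`, with a warning.
#'
#' @param expr Gene-by-sample expression table, typically
#'   `log2(normalized count + 1)`.
#' @param beta Soft-threshold exponent (> 0); 20 is the convention this
#'   package is organized around.
#' @param signed Use the signed transform instead of `|cor|^beta`.
#' @return Symmetric gene-by-gene matrix with entries in \[0, 1\] and zero
#'   diagonal.
#' @export
soft_adjacency <- function(expr, beta = 20, signed = FALSE) {
  m <- as_feature_matrix(expr)
  if (ncol(m) < 3) abort_bad_arg("need at least 3 samples")
  if (beta <= 0) abort_bad_arg("beta must be positive")
  sdv <- sqrt(matrixStats_rowVars(m))
  bad <- sdv == 0 | !is.finite(sdv)
  # correlation via scaled crossproduct (BLAS) for large gene counts
  z <- (m - rowMeans(m)) / ifelse(bad, 1, sdv)
  z[bad, ] <- 0
  r <- tcrossprod(z) / (ncol(m) - 1)
  r[r > 1] <- 1
  r[r < -1] <- -1
  a <- if (signed) ((1 + r) / 2)^beta else abs(r)^beta
  diag(a) <- 0
  if (any(bad)) {
    rlang::warn(sprintf(
      "%d zero-variance gene(s); their adjacency rows were zeroed", sum(bad)
    ))
    a[bad, ] <- 0
    a[, bad] <- 0
  }
  attr(a, "beta") <- beta
  attr(a, "zero_variance") <- rownames(m)[bad]
  a
}

#' Topological overlap matrix
#'
#' For adjacency `a` with connectivities `k_i = sum_u a_iu`, the topological
#' overlap between genes i and j is
#' `TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)` for
#' `i != j`, and `TOM_ii = 1` by convention. It augments direct adjacency
#' with shared-neighbour evidence; a clique with unit adjacency has unit
#' topological overlap everywhere. Isolated pairs (zero denominator) get
#' `TOM_ij = 0`.
#'
#' @param adjacency Symmetric matrix in \[0, 1\] with zero diagonal, from
#'   [soft_adjacency()].
#' @return Symmetric matrix in \[0, 1\] with unit diagonal.
#' @export
tom_similarity <- function(adjacency) {
  a <- adjacency
  if (!isSymmetric(unname(a))) abort_bad_arg("adjacency must be symmetric")
  if (any(a < 0 | a > 1)) abort_bad_arg("adjacency entries must lie in [0, 1]")
  k <- rowSums(a)
  shared <- crossprod(a) # sum_u a_iu a_uj (diagonal irrelevant: a_ii = 0)
  den <- outer(k, k, pmin) + 1 - a
  tom <- (shared + a) / den
  tom[den <= 0] <- 0
  diag(tom) <- 1
  tom[tom > 1] <- 1
  tom[tom < 0] <- 0
  dimnames(tom) <- dimnames(a)
  tom
}

# Fast dist construction from a full symmetric matrix (avoids as.dist copy
# overhead on large inputs).
dissim_as_dist <- function(d) {
  n <- nrow(d)
  out <- d[lower.tri(d)]
  attr(out, "Size") <- n
  attr(out, "Labels") <- rownames(d)
  attr(out, "Diag") <- FALSE
  attr(out, "Upper") <- FALSE
  attr(out, "method") <- "tom_dissimilarity"
  class(out) <- "dist"
  out
}

#' Detect co-expression modules from a topological overlap matrix
#'
#' Average-linkage hierarchical clustering on the dissimilarity `1 - TOM`,
#' followed by a static tree cut at `cut_height`; clusters smaller than
#' `min_module_size` are sent to the `"grey"` non-module. Modules whose
#' eigengenes correlate above `1 - merge_height` are then merged iteratively.
#' Surviving modules are labelled with the conventional colour palette in
#' decreasing size order (`turquoise` largest, then `blue`, `brown`, ...).
#'
#' @param tom TOM from [tom_similarity()].
#' @param expr The expression table the TOM was built from (needed for
#'   eigengene-based merging); may be `NULL` to skip merging.
#' @param min_module_size Minimum genes per module.
#' @param cut_height Static cut height on the dendrogram (dissimilarity
#'   scale).
#' @param merge_height Modules with eigengene correlation `> 1 - merge_height`
#'   are merged.
#' @return Tibble with columns `gene`, `module` (colour label or `"grey"`).
#' @export
detect_modules <- function(tom, expr = NULL, min_module_size = 30,
                           cut_height = 0.99, merge_height = 0.25) {
  if (nrow(tom) < 2) abort_bad_arg("need at least 2 genes")
  d <- 1 - tom
  hc <- stats::hclust(dissim_as_dist(d), method = "average")
  cl <- stats::cutree(hc, h = cut_height)
  genes <- rownames(tom)
  sizes <- table(cl)
  keep <- names(sizes)[sizes >= min_module_size]
  lab <- ifelse(cl %in% as.integer(keep), as.character(cl), "grey")
  names(lab) <- genes
  if (!is.null(expr) && length(unique(lab[lab != "grey"])) > 1) {
    lab <- merge_close_modules(lab, expr, merge_height)
  }
  # colour labels by decreasing size
  mods <- names(sort(table(lab[lab != "grey"]), decreasing = TRUE))
  colours <- c(
    utils::head(module_palette, length(mods)),
    if (length(mods) > length(module_palette)) {
      sprintf("module%02d", seq_len(length(mods) - length(module_palette)))
    }
  )
  final <- ifelse(lab == "grey", "grey", colours[match(lab, mods)])
  tibble::tibble(gene = genes, module = unname(final))
}

merge_close_modules <- function(lab, expr, merge_height) {
  repeat {
    assign_tbl <- tibble::tibble(gene = names(lab), module = unname(lab))
    me <- module_eigengenes(expr, assign_tbl)
    mods <- setdiff(colnames(me)[-1], "grey")
    if (length(mods) < 2) {
      return(lab)
    }
    cc <- stats::cor(as.matrix(me[, mods]))
    diag(cc) <- -Inf
    top <- which(cc == max(cc), arr.ind = TRUE)[1, ]
    if (max(cc) <= 1 - merge_height) {
      return(lab)
    }
    from <- mods[top[2]]
    to <- mods[top[1]]
    lab[lab == from] <- to
  }
}

#' Module eigengenes
#'
#' The eigengene of a module is the first principal component of its
#' gene-standardized expression, with samples as observations, scaled to
#' unit norm and sign-oriented so that its correlation with the module's
#' mean expression profile is positive. A one-gene module falls back to that
#' gene's standardized profile, with a warning.
#'
#' @param expr Gene-by-sample expression table.
#' @param assignment Tibble with columns `gene`, `module` from
#'   [detect_modules()]; the `"grey"` non-module is skipped.
#' @return Tibble: `sample` column plus one unit-norm column per module.
#' @export
module_eigengenes <- function(expr, assignment) {
  m <- as_feature_matrix(expr)
  mods <- setdiff(unique(assignment$module), "grey")
  if (!length(mods)) abort_bad_arg("no non-grey modules to summarise")
  out <- purrr::map(mods, function(mod) {
    g <- intersect(assignment$gene[assignment$module == mod], rownames(m))
    sub <- m[g, , drop = FALSE]
    if (nrow(sub) == 1) {
      rlang::warn(sprintf("module '%s' has a single gene", mod))
      z <- drop(scale(sub[1, ]))
      return(z / sqrt(sum(z^2)))
    }
    z <- t(scale(t(sub))) # standardize genes across samples
    z[!is.finite(z)] <- 0
    sv <- svd(t(z), nu = 1, nv = 0)
    e <- sv$u[, 1]
    if (stats::cor(e, colMeans(z)) < 0) e <- -e
    e
  })
  names(out) <- mods
  dplyr::bind_cols(tibble::tibble(sample = colnames(m)), tibble::as_tibble(out))
}

#' Correlate module eigengenes with sample traits
#'
#' Pearson correlation of each eigengene with each 0/1-coded sample trait
#' (for example wild type = 0 / mutant = 1, dark = 0 / red = 1), with the
#' two-sided p-value from `t = r sqrt((n-2)/(1-r^2))` on `n - 2` degrees of
#' freedom. Both `r` and `r^2` are reported.
#'
#' @param eigengenes Tibble from [module_eigengenes()].
#' @param traits Tibble with a `sample` column and one numeric 0/1 column per
#'   trait (see [study_design()]'s `genotype_code`, `condition_code`).
#' @return Tibble of class `module_trait_cor` with columns `module`, `trait`,
#'   `r`, `r_squared`, `p`.
#' @export
module_trait_cor <- function(eigengenes, traits) {
  if (!"sample" %in% names(traits)) abort_bad_arg("traits needs a sample column")
  tr <- traits[match(eigengenes$sample, traits$sample), , drop = FALSE]
  trait_names <- setdiff(names(tr), "sample")
  n <- nrow(eigengenes)
  if (n < 3) abort_bad_arg("need at least 3 samples")
  constant <- trait_names[vapply(trait_names, function(t) stats::sd(tr[[t]]) == 0, TRUE)]
  if (length(constant)) {
    rlang::warn(sprintf(
      "trait '%s' is constant; correlation undefined",
      paste(constant, collapse = "', '")
    ))
  }
  mods <- setdiff(names(eigengenes), "sample")
  out <- tidyr::expand_grid(module = mods, trait = trait_names)
  vals <- purrr::pmap(out, function(module, trait) {
    x <- eigengenes[[module]]
    y <- tr[[trait]]
    if (trait %in% constant) {
      return(c(NA_real_, NA_real_))
    }
    r <- stats::cor(x, y)
    tstat <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
    c(r, 2 * stats::pt(-abs(tstat), n - 2))
  })
  out$r <- vapply(vals, `[`, 1, i = 1)
  out$r_squared <- out$r^2
  out$p <- vapply(vals, `[`, 1, i = 2)
  class(out) <- c("module_trait_cor", class(out))
  out
}

#' @export
autoplot.module_trait_cor <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(
    x = .data$trait, y = .data$module, fill = .data$r
  )) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%.2f\n(%.3g)", .data$r, .data$p)
    ), size = 3) +
    ggplot2::scale_fill_gradient2(
      low = "#2c7bb6", mid = "white", high = "#d7191c", limits = c(-1, 1)
    ) +
    ggplot2::labs(x = NULL, y = NULL, fill = "r") +
    ggplot2::theme_minimal()
}

#' Export within-module edges above a topological-overlap threshold
#'
#' Emits the edge list used for network visualization: within-module gene
#' pairs whose topological overlap is at least `threshold`, ordered by
#' module then by gene labels, with `source < target` so no pair repeats.
#' Genes with no qualifying edge do not appear.
#'
#' @param tom TOM from [tom_similarity()].
#' @param assignment Module assignment tibble from [detect_modules()].
#' @param threshold Minimum topological overlap for an edge (in (0, 1\];
#'   0.2 by convention here).
#' @return Tibble with columns `source`, `target`, `weight`, `module`.
#' @export
export_edges <- function(tom, assignment, threshold = 0.2) {
  if (threshold < 0 || threshold > 1) abort_bad_arg("threshold must lie in [0, 1]")
  mods <- setdiff(sort(unique(assignment$module)), "grey")
  out <- purrr::map(mods, function(mod) {
    g <- sort(intersect(assignment$gene[assignment$module == mod], rownames(tom)))
    if (length(g) < 2) {
      return(NULL)
    }
    sub <- tom[g, g, drop = FALSE]
    idx <- which(upper.tri(sub) & sub >= threshold, arr.ind = TRUE)
    if (!nrow(idx)) {
      return(NULL)
    }
    tibble::tibble(
      source = g[idx[, 1]], target = g[idx[, 2]],
      weight = sub[idx], module = mod
    )
  })
  out <- dplyr::bind_rows(out)
  if (!nrow(out)) {
    return(tibble::tibble(
      source = character(0), target = character(0),
      weight = numeric(0), module = character(0)
    ))
  }
  dplyr::arrange(out, .data$module, .data$source, .data$target)
}

#' Permutation test for the module membership of a gene set
#'
#' Tests whether a set of module genes sits closer to the module core than a
#' random same-size subset of the module would. The statistic is the mean
#' module membership (kME: Pearson correlation of each gene's expression
#' profile with the module eigengene) over the set; the null redraws
#' same-size subsets uniformly from the module's genes. The upper-tail p
#' uses the `(exceedances + 1) / (n_perm + 1)` convention.
#'
#' @param gene_set Character vector, a subset of the module's genes.
#' @param module_genes Character vector of all genes in the module.
#' @param expr Gene-by-sample expression table.
#' @param eigengene Numeric vector: the module eigengene across samples (a
#'   column of [module_eigengenes()]).
#' @param n_perm Number of permutations.
#' @param seed Integer seed.
#' @return A `perm_overlap`-style object of class `perm_membership` with the
#'   observed mean kME, null sample, and p-value.
#' @export
module_membership_test <- function(gene_set, module_genes, expr, eigengene,
                                   n_perm = 10000, seed = 1L) {
  m <- as_feature_matrix(expr)
  if (!length(gene_set)) abort_bad_arg("gene_set is empty")
  if (!all(gene_set %in% module_genes)) {
    abort_bad_arg("gene_set must be a subset of the module's genes")
  }
  if (length(gene_set) > length(module_genes)) {
    abort_bad_arg("gene_set larger than the module")
  }
  if (n_perm < 1) abort_bad_arg("n_perm must be >= 1")
  kme <- drop(stats::cor(t(m[module_genes, , drop = FALSE]), eigengene))
  names(kme) <- module_genes
  observed <- mean(kme[gene_set])
  k <- length(gene_set)
  null <- numeric(n_perm)
  withr::with_seed(seed, {
    for (i in seq_len(n_perm)) {
      null[i] <- mean(kme[sample.int(length(module_genes), k)])
    }
  })
  exceed <- sum(null >= observed)
  structure(
    list(
      observed = observed, exceedances = exceed,
      p = (exceed + 1) / (n_perm + 1),
      null_mean = mean(null), null_var = stats::var(null), null = null,
      n_perm = n_perm, seed = seed, convention = "plus_one"
    ),
    class = c("perm_membership", "perm_overlap")
  )
}

#' Run the full co-expression pipeline
#'
#' Convenience wrapper chaining [top_variable_genes()] (on normalized
#' counts), the log2 transform, [soft_adjacency()], [tom_similarity()],
#' [detect_modules()], [module_eigengenes()], [module_trait_cor()] and
#' [export_edges()].
#'
#' @param norm_counts Normalized counts (gene-by-sample tibble or matrix).
#' @param traits Trait tibble (see [module_trait_cor()]).
#' @param top_k Number of most-variable genes to keep.
#' @param beta Soft-threshold exponent.
#' @param to_threshold Edge-export TOM threshold.
#' @param ... Passed to [detect_modules()].
#' @return Object of class `coexpr_network`: list with `modules`,
#'   `eigengenes`, `module_trait`, `edges`, `tom`, and the parameters.
#'   Supports `tidy()` (gene-module table) and `glance()`.
#' @export
coexpression_network <- function(norm_counts, traits, top_k = 8000, beta = 20,
                                 to_threshold = 0.2, ...) {
  sel <- top_variable_genes(norm_counts, k = min(top_k, nrow(as_feature_matrix(norm_counts))))
  expr <- matrix_to_tbl(log2(as_feature_matrix(sel) + 1))
  adj <- soft_adjacency(expr, beta = beta)
  tom <- tom_similarity(adj)
  rm(adj)
  modules <- detect_modules(tom, expr = expr, ...)
  me <- module_eigengenes(expr, modules)
  structure(
    list(
      modules = modules,
      eigengenes = me,
      module_trait = module_trait_cor(me, traits),
      edges = export_edges(tom, modules, threshold = to_threshold),
      tom = tom,
      expr = expr,
      params = list(top_k = top_k, beta = beta, to_threshold = to_threshold)
    ),
    class = "coexpr_network"
  )
}

#' @export
print.coexpr_network <- function(x, ...) {
  n_mod <- sum(unique(x$modules$module) != "grey")
  cat(sprintf(
    "Co-expression network: %d genes, %d modules (+ grey), %d edges >= %.2f\n",
    nrow(x$modules), n_mod, nrow(x$edges), x$params$to_threshold
  ))
  invisible(x)
}

#' @export
tidy.coexpr_network <- function(x, ...) {
  kme <- purrr::map(
    setdiff(names(x$eigengenes), "sample"),
    function(mod) {
      g <- x$modules$gene[x$modules$module == mod]
      m <- as_feature_matrix(x$expr)[g, , drop = FALSE]
      tibble::tibble(
        gene = g, module = mod,
        kme = drop(stats::cor(t(m), x$eigengenes[[mod]]))
      )
    }
  )
  dplyr::left_join(x$modules, dplyr::bind_rows(kme), by = c("gene", "module"))
}

#' @export
glance.coexpr_network <- function(x, ...) {
  tibble::tibble(
    n_genes = nrow(x$modules),
    n_modules = sum(unique(x$modules$module) != "grey"),
    n_grey = sum(x$modules$module == "grey"),
    n_edges = nrow(x$edges),
    beta = x$params$beta
  )
}
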