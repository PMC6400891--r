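#' Exact hypergeometric tail for the overlap of two random subsets
#'
#' When two subsets of sizes `n_a` and `n_b` are drawn independently and
#' uniformly without replacement from one shared universe of size `N`, their
#' overlap is hypergeometric: conditioning on the first draw,
#' `X ~ Hypergeometric(N, n_a, n_b)`. This exact upper tail `P(X >= k)` is
#' the analytic oracle for [permutation_overlap_p()] whenever the A-to-B
#' mapping is one-to-one; `stats::phyper` evaluates it stably in log space.
#'
#' @param N Universe size.
#' @param n_a,n_b Sizes of the two drawn subsets.
#' @param k Observed overlap.
#' @return `P(X >= k)`, a number in (0, 1].
#' @examples
#' analytic_overlap_p(20, 5, 8, 5) # choose(8,5)/choose(20,5)
#' @export
analytic_overlap_p <- function(N, n_a, n_b, k) {
  if (n_a > N || n_b > N || n_a < 0 || n_b < 0) {
    abort_bad_arg("draw sizes must lie in [0, N]")
  }
  if (k < 0 || k > min(n_a, n_b)) {
    abort_bad_arg("infeasible k: need 0 <= k <= min(n_a, n_b)")
  }
  stats::phyper(k - 1, n_a, N - n_a, n_b, lower.tail = FALSE)
}

new_perm_overlap <- function(observed, null, n_perm, seed, convention) {
  exceed <- sum(null >= observed)
  p <- switch(convention,
    plus_one = (exceed + 1) / (n_perm + 1),
    raw = max(exceed / n_perm, 1 / n_perm)
  )
  structure(
    list(
      observed = observed,
      exceedances = exceed,
      p = p,
      null_mean = mean(null),
      null_var = stats::var(null),
      null = null,
      n_perm = n_perm,
      seed = seed,
      convention = convention
    ),
    class = "perm_overlap"
  )
}

#' @export
print.perm_overlap <- function(x, ...) {
  cat(sprintf(
    "Overlap permutation test (%d permutations, seed %s, %s convention)\n",
    x$n_perm, format(x$seed), x$convention
  ))
  cat(sprintf(
    "  observed overlap %d | null mean %.2f (var %.2f) | exceedances %d\n",
    x$observed, x$null_mean, x$null_var, x$exceedances
  ))
  cat(sprintf("  p = %.4g\n", x$p))
  invisible(x)
}

# Shared permutation engine. gene_of_a: integer gene index (in 1..N_b) of
# each item of universe A. Draws n_a items from A, maps to distinct gene ids,
# draws n_b from universe B, counts shared gene ids.
perm_overlap_engine <- function(gene_of_a, N_b, n_a, n_b, observed, n_perm,
                                seed, convention) {
  if (n_perm < 1) abort_bad_arg("n_perm must be >= 1")
  if (n_a > length(gene_of_a)) abort_bad_arg("n_a exceeds universe A size")
  if (n_b > N_b) abort_bad_arg("n_b exceeds universe B size")
  if (observed < 0) abort_bad_arg("observed overlap must be >= 0")
  n_A <- length(gene_of_a)
  null <- integer(n_perm)
  in_b <- logical(N_b)
  withr::with_seed(seed, {
    for (i in seq_len(n_perm)) {
      ga <- gene_of_a[sample.int(n_A, n_a)]
      ga <- unique(ga[!is.na(ga)])
      bsel <- sample.int(N_b, n_b)
      in_b[bsel] <- TRUE
      null[i] <- sum(in_b[ga])
      in_b[bsel] <- FALSE
    }
  })
  new_perm_overlap(observed, null, n_perm, seed, convention)
}

#' Permutation test for the overlap of two feature sets in linked universes
#'
#' Draws `n_a` items uniformly without replacement from universe A (for
#' example, protein spots) and `n_b` from universe B (genes), translates the
#' A-draw through a possibly many-to-one item-to-gene mapping, and counts the
#' distinct shared gene identifiers. Repeating `n_perm` times yields the null
#' distribution of the overlap; the upper-tail p-value for the observed
#' overlap is reported. Because spots sharing one gene contribute a single
#' identifier, duplication in the mapping shifts the null relative to the
#' one-to-one hypergeometric tail of [analytic_overlap_p()].
#'
#' Two p-value conventions are available: the default `"plus_one"` computes
#' `(exceedances + 1) / (n_perm + 1)`, a valid permutation p that is never 0;
#' `"raw"` reports the plain exceedance proportion floored at `1 / n_perm`
#' (the convention under which a zero-exceedance result at 10,000
#' permutations prints as 0.0001).
#'
#' @param n_a,n_b Numbers of items drawn from universes A and B.
#' @param observed Observed overlap (distinct shared gene identifiers).
#' @param universe_a Size of universe A, or a character vector of item labels.
#' @param universe_b Size of universe B, or a character vector of gene labels.
#' @param mapping Optional tibble with columns `spot` (or `gene_a`) and
#'   `gene` (or `gene_b`) mapping universe-A items to universe-B genes.
#'   `NULL` means the identity: each A item is its own gene inside B (A is
#'   then treated as a subset of B).
#' @param n_perm Number of permutations.
#' @param seed Integer seed (recorded in the result).
#' @param convention `"plus_one"` or `"raw"` (see Details).
#' @return A `perm_overlap` object: observed overlap, exceedance count, `p`,
#'   null mean/variance, the null sample, `n_perm`, `seed`, `convention`.
#'   Supports [print()], [generics::tidy()], [generics::glance()] and
#'   [ggplot2::autoplot()].
#' @examples
#' permutation_overlap_p(
#'   n_a = 5, n_b = 8, observed = 3,
#'   universe_a = 20, universe_b = 20, n_perm = 500, seed = 1
#' )
#' @export
permutation_overlap_p <- function(n_a, n_b, observed, universe_a, universe_b,
                                  mapping = NULL, n_perm = 10000, seed = 1L,
                                  convention = c("plus_one", "raw")) {
  convention <- match.arg(convention)
  b_labels <- if (is.numeric(universe_b) && length(universe_b) == 1) {
    NULL
  } else {
    as.character(universe_b)
  }
  N_b <- if (is.null(b_labels)) universe_b else length(b_labels)
  if (is.null(mapping)) {
    n_A <- if (is.numeric(universe_a) && length(universe_a) == 1) {
      universe_a
    } else {
      length(universe_a)
    }
    if (n_A > N_b) abort_bad_arg("identity mapping needs universe A inside B")
    gene_of_a <- seq_len(n_A) # A items are distinct genes within B
  } else {
    cols <- intersect(c("spot", "gene_a"), names(mapping))
    gcol <- intersect(c("gene", "gene_b"), names(mapping))
    if (!length(cols) || !length(gcol)) {
      abort_bad_arg("mapping needs columns spot/gene_a and gene/gene_b")
    }
    a_labels <- if (is.numeric(universe_a) && length(universe_a) == 1) {
      mapping[[cols[1]]]
    } else {
      as.character(universe_a)
    }
    map_gene <- mapping[[gcol[1]]][match(a_labels, mapping[[cols[1]]])]
    if (is.null(b_labels)) {
      abort_bad_arg("a mapped universe B must be given as labels")
    }
    gene_of_a <- match(map_gene, b_labels)
    if (any(is.na(gene_of_a) & !is.na(map_gene))) {
      abort_bad_arg("mapping contains genes outside universe B")
    }
  }
  perm_overlap_engine(
    gene_of_a, N_b, n_a, n_b, observed, n_perm, seed, convention
  )
}

#' Cross-species overlap permutation test through an ortholog map
#'
#' As [permutation_overlap_p()], but universe A is a different species'
#' gene universe linked to universe B by a one-to-one (injective) ortholog
#' map: each permutation draws `n_a` genes from A, translates them through
#' the map, draws `n_b` genes from B, and counts the overlap in B labels.
#' Typically universe A is restricted to the genes that have orthologs
#' (so the map is total on A).
#'
#' @inheritParams permutation_overlap_p
#' @param ortholog_map Tibble with columns `gene_a`, `gene_b`; must be
#'   injective in both columns. A-genes without a row are unmapped and can
#'   never overlap.
#' @return A `perm_overlap` object.
#' @export
cross_species_overlap_p <- function(n_a, n_b, observed, universe_a, universe_b,
                                    ortholog_map, n_perm = 10000, seed = 1L,
                                    convention = c("plus_one", "raw")) {
  convention <- match.arg(convention)
  if (anyDuplicated(ortholog_map$gene_a) || anyDuplicated(ortholog_map$gene_b)) {
    abort_bad_arg("ortholog map must be one-to-one (injective)")
  }
  a_labels <- if (is.numeric(universe_a) && length(universe_a) == 1) {
    # labels default to the mapped genes padded with unmapped placeholders
    c(
      ortholog_map$gene_a,
      sprintf(".unmapped_%d", seq_len(max(0, universe_a - nrow(ortholog_map))))
    )[seq_len(universe_a)]
  } else {
    as.character(universe_a)
  }
  b_labels <- if (is.numeric(universe_b) && length(universe_b) == 1) {
    NULL
  } else {
    as.character(universe_b)
  }
  if (is.null(b_labels)) {
    N_b <- universe_b
    gene_b_idx <- match(ortholog_map$gene_b, unique(ortholog_map$gene_b))
    if (nrow(ortholog_map) > N_b) abort_bad_arg("map image exceeds universe B")
    gene_of_a <- gene_b_idx[match(a_labels, ortholog_map$gene_a)]
  } else {
    N_b <- length(b_labels)
    gene_of_a <- match(
      ortholog_map$gene_b[match(a_labels, ortholog_map$gene_a)], b_labels
    )
  }
  perm_overlap_engine(
    gene_of_a, N_b, n_a, n_b, observed, n_perm, seed, convention
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.perm_overlap <- function(x, ...) {
  tibble::tibble(
    observed = x$observed,
    null_mean = x$null_mean,
    null_var = x$null_var,
    exceedances = x$exceedances,
    p_value = x$p
  )
}

#' @export
glance.perm_overlap <- function(x, ...) {
  tibble::tibble(
    p_value = x$p, n_perm = x$n_perm, seed = x$seed, convention = x$convention
  )
}

#' @export
autoplot.perm_overlap <- function(object, ...) {
  df <- tibble::tibble(overlap = object$null)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$overlap)) +
    ggplot2::geom_histogram(binwidth = 1, fill = "grey70", colour = "grey30") +
    ggplot2::geom_vline(
      xintercept = object$observed, colour = "firebrick", linewidth = 0.8
    ) +
    ggplot2::labs(
      x = "null overlap", y = "permutations",
      title = sprintf(
        "Observed overlap %d, p = %.4g (%d permutations)",
        object$observed, object$p, object$n_perm
      )
    ) +
    ggplot2::theme_minimal()
}
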