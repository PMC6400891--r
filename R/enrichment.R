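#' Fisher's exact GO-term enrichment
#'
#' One-sided over-representation test per term: with `A` genes annotated to
#' the term in the universe, `S` of them in the study set, the p-value is the
#' hypergeometric upper tail of the 2x2 table (in-term/not by in-study/not).
#' The expected study-set count `E = A |study| / |universe|` is reported
#' alongside, matching the conventional A/S/E/p enrichment-table layout
#' (E is kept at full precision; round only for presentation).
#'
#' `mode = "elim"` offers a simple decorrelation for hierarchically related
#' terms: terms are processed leaves first, and the annotated genes of any
#' term already significant at `elim_alpha` are removed from its ancestors
#' before those are tested. A term with no significant descendants gets its
#' classic p-value. The heavier weighted decorrelation algorithms used by
#' dedicated GO packages are intentionally not reproduced.
#'
#' @param study Character vector of study genes; must lie inside `universe`.
#' @param annotation Tibble with columns `gene`, `term` (one row per pair).
#' @param universe Character vector: the gene universe.
#' @param alpha Presentation threshold: rows with `p < alpha` are returned;
#'   `alpha = 1` returns the full table (including saturated terms at p = 1).
#' @param mode `"classic"` or `"elim"`.
#' @param term_parents Optional tibble with columns `term`, `parent` (a
#'   directed acyclic child-to-parent relation); required for `"elim"`.
#' @param elim_alpha Significance level at which a descendant's genes are
#'   eliminated from its ancestors (defaults to `alpha`).
#' @return Tibble with columns `term`, `A`, `S`, `E`, `p`, sorted by `p`.
#' @examples
#' ann <- tibble::tibble(gene = c("g1", "g2", "g3", "g4"), term = "GO:1")
#' fisher_enrichment(c("g1", "g2", "g3", "g4", "g5"), ann,
#'   universe = sprintf("g%d", 1:10), alpha = 1
#' )
#' @export
fisher_enrichment <- function(study, annotation, universe, alpha = 0.05,
                              mode = c("classic", "elim"),
                              term_parents = NULL, elim_alpha = alpha) {
  mode <- match.arg(mode)
  study <- unique(study)
  universe <- unique(universe)
  bad <- setdiff(study, universe)
  if (length(bad)) {
    abort_bad_arg(sprintf(
      "study genes outside the universe: %s",
      paste(utils::head(bad, 5), collapse = ", ")
    ))
  }
  if (!nrow(annotation)) abort_bad_arg("annotation is empty")
  ann <- dplyr::filter(
    dplyr::distinct(annotation, .data$gene, .data$term),
    .data$gene %in% universe
  )
  N <- length(universe)
  n_study <- length(study)
  by_term <- split(ann$gene, ann$term)
  terms <- names(by_term)

  test_term <- function(genes) {
    A <- length(genes)
    S <- sum(genes %in% study)
    p <- stats::phyper(S - 1, A, N - A, n_study, lower.tail = FALSE)
    c(A = A, S = S, p = p)
  }

  if (mode == "classic") {
    res <- vapply(by_term, test_term, numeric(3))
  } else {
    if (is.null(term_parents)) {
      abort_bad_arg("elim mode needs a term_parents table")
    }
    res <- elim_fisher(by_term, term_parents, study, N, n_study, elim_alpha)
  }
  out <- tibble::tibble(
    term = terms,
    A = as.integer(res["A", ]),
    S = as.integer(res["S", ]),
    E = res["A", ] * n_study / N,
    p = res["p", ]
  )
  if (alpha < 1) out <- dplyr::filter(out, .data$p < alpha)
  out <- dplyr::arrange(out, .data$p)
  class(out) <- c("enrichment_tbl", class(out))
  out
}

# elim: test leaf-upward; genes of significant descendants are removed from
# ancestors before testing.
elim_fisher <- function(by_term, term_parents, study, N, n_study, elim_alpha) {
  terms <- names(by_term)
  parents <- split(term_parents$parent, term_parents$term)
  # ancestors by transitive closure
  ancestors_of <- function(tm) {
    seen <- character(0)
    frontier <- parents[[tm]]
    while (length(frontier)) {
      frontier <- setdiff(frontier, seen)
      seen <- c(seen, frontier)
      frontier <- unlist(parents[frontier], use.names = FALSE)
    }
    seen
  }
  anc <- lapply(stats::setNames(terms, terms), ancestors_of)
  depth <- vapply(anc, length, 1L)
  # most specific terms (most ancestors) are tested first
  order_terms <- terms[order(-depth)]
  removed <- stats::setNames(vector("list", length(terms)), terms)
  res <- matrix(NA_real_, 3, length(terms),
    dimnames = list(c("A", "S", "p"), terms)
  )
  for (tm in order_terms) {
    genes <- setdiff(by_term[[tm]], removed[[tm]])
    A <- length(genes)
    S <- sum(genes %in% study)
    p <- stats::phyper(S - 1, A, N - A, n_study, lower.tail = FALSE)
    res[, tm] <- c(A, S, p)
    if (is.finite(p) && p < elim_alpha) {
      for (up in intersect(anc[[tm]], terms)) {
        removed[[up]] <- union(removed[[up]], by_term[[tm]])
      }
    }
  }
  res[, terms, drop = FALSE]
}

#' @export
autoplot.enrichment_tbl <- function(object, ...) {
  df <- dplyr::mutate(object,
    term = stats::reorder(.data$term, -log10(.data$p))
  )
  ggplot2::ggplot(df, ggplot2::aes(
    x = -log10(.data$p), y = .data$term, size = .data$S,
    colour = .data$S / pmax(.data$E, .Machine$double.eps)
  )) +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = expression(-log[10](p)), y = NULL,
      colour = "S / E", size = "S"
    ) +
    ggplot2::theme_minimal()
}
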