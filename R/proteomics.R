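#' Relative spot volumes
#'
#' Normalizes every 2D-gel spot volume against the total spot volume of its
#' gel, so each gel's relative volumes sum to one. This removes per-gel
#' staining and loading differences (a gel-wise multiplicative rescaling
#' leaves the output unchanged).
#'
#' @param volumes Gel-by-spot table: tibble with a `gel` first column and one
#'   numeric column per spot (or a rownamed matrix, gels in rows).
#' @return Tibble in the same layout; every row sums to 1.
#' @examples
#' v <- tibble::tibble(gel = "g1", s1 = 2, s2 = 3, s3 = 5)
#' relative_spot_volumes(v)
#' @export
relative_spot_volumes <- function(volumes) {
  m <- as_feature_matrix(volumes)
  if (any(m < 0)) abort_bad_arg("spot volumes must be non-negative")
  tot <- rowSums(m)
  if (any(tot <= 0)) {
    abort_bad_arg(sprintf(
      "gel(s) with zero total volume: %s",
      paste(rownames(m)[tot <= 0], collapse = ", ")
    ))
  }
  matrix_to_tbl(m / tot, id_col = "gel")
}

#' Differential spot abundance by Student's t-test
#'
#' Per-spot pooled-variance two-sample t-test on relative spot volumes
#' between two gel groups. Deliberately, no multiple-testing correction is
#' applied across spots: significance is thresholded on the raw p-value
#' (conventional for 2D-gel densitometry at `p < 0.01`, and the convention
#' this package follows); interpret the flagged count accordingly.
#'
#' @param volumes Normalized gel-by-spot table from [relative_spot_volumes()].
#' @param design Gel design tibble with `sample_id` (gel label) and `group`.
#' @param comparison Length-2 character vector of group labels
#'   `c(reference, test)`.
#' @param alpha Raw-p significance threshold (default 0.01).
#' @return Tibble with columns `spot`, `comparison`, `mean_ref`, `mean_test`,
#'   `log2_ratio`, `p`, `significant`. A spot with zero variance and equal
#'   means in both groups reports `p = 1`.
#' @export
dep_t_test <- function(volumes, design, comparison, alpha = 0.01) {
  m <- as_feature_matrix(volumes) # gels x spots
  design <- validate_design(design)
  m <- match_design(t(m), design) # spots x gels
  if (length(comparison) != 2 || !all(comparison %in% design$group)) {
    abort_bad_arg("comparison must name two groups present in the design")
  }
  g1 <- design$sample_id[design$group == comparison[1]]
  g2 <- design$sample_id[design$group == comparison[2]]
  tt <- row_student_t(m[, g1, drop = FALSE], m[, g2, drop = FALSE])
  check_probs(tt$p)
  tibble::tibble(
    spot = rownames(m),
    comparison = paste(comparison[1], "vs", comparison[2], sep = "_"),
    mean_ref = tt$mean1,
    mean_test = tt$mean2,
    log2_ratio = log2(tt$mean2 / tt$mean1),
    p = tt$p,
    significant = tt$p < alpha
  )
}

#' Collapse significant spots to gene-level sets
#'
#' Maps spots through a (possibly many-to-one) spot-to-gene table and reports
#' the redundancy accounting: total spot calls, non-redundant spots (distinct
#' spots collapsed across comparisons), unique gene identifiers, and unmapped
#' spots. Unmapped spots are tolerated and counted, never silently dropped.
#'
#' @param spots Character vector of spot identifiers, or a tibble with
#'   columns `spot` and optionally `comparison` (rows are spot calls; the same
#'   spot may appear under several comparisons).
#' @param spot_map Tibble with columns `spot`, `gene` (`NA` gene = unmapped).
#' @return List with `genes` (sorted unique mapped gene identifiers) and
#'   `summary`, a one-row tibble: `n_calls`, `n_spots` (non-redundant),
#'   `n_genes`, `n_unmapped`.
#' @examples
#' map <- tibble::tibble(spot = c("s1", "s2", "s3", "s4"), gene = c("g1", "g1", "g2", "g2"))
#' collapse_spots_to_genes(c("s1", "s2", "s3", "s4"), map)
#' @export
collapse_spots_to_genes <- function(spots, spot_map) {
  if (is.data.frame(spots)) {
    calls <- spots$spot
  } else {
    calls <- as.character(spots)
  }
  uniq <- unique(calls)
  gene <- spot_map$gene[match(uniq, spot_map$spot)]
  unmapped <- uniq[is.na(gene)]
  genes <- sort(unique(gene[!is.na(gene)]))
  list(
    genes = genes,
    summary = tibble::tibble(
      n_calls = length(calls),
      n_spots = length(uniq),
      n_genes = length(genes),
      n_unmapped = length(unmapped)
    )
  )
}
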