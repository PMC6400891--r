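# Internal helpers shared across modules.

# Conventional module colour palette, largest module first; "grey"/"gray" is
# reserved for the non-module.
module_palette <- c(
  "turquoise", "blue", "brown", "yellow", "green", "red", "black", "pink",
  "magenta", "purple", "greenyellow", "tan", "salmon", "cyan", "midnightblue",
  "lightcyan", "grey60", "lightgreen", "lightyellow", "royalblue", "darkred",
  "darkgreen", "darkturquoise", "darkgrey", "orange", "darkorange", "white",
  "skyblue", "saddlebrown", "steelblue", "paleturquoise", "violet",
  "darkolivegreen", "darkmagenta"
)

abort_bad_arg <- function(msg) {
  rlang::abort(msg, class = "duomics_error")
}

#' Convert a gene-by-sample tibble to a numeric matrix
#'
#' User-facing tabular interfaces carry features in a first identifier column
#' (`gene`, `spot`, ...) and one numeric column per sample. This converts to
#' the rownamed matrix used internally, and passes matrices through untouched.
#'
#' @param x A data frame whose first column holds feature identifiers, or a
#'   numeric matrix with rownames.
#' @return Numeric matrix, features in rows.
#' @keywords internal
#' @noRd
as_feature_matrix <- function(x) {
  if (is.matrix(x)) {
    storage.mode(x) <- "double"
    return(x)
  }
  if (!is.data.frame(x)) {
    abort_bad_arg("expected a data frame or matrix of feature-by-sample values")
  }
  ids <- as.character(x[[1]])
  if (anyDuplicated(ids)) {
    abort_bad_arg("duplicated feature identifiers in first column")
  }
  m <- as.matrix(x[, -1, drop = FALSE])
  if (!is.numeric(m)) abort_bad_arg("non-numeric sample columns")
  rownames(m) <- ids
  m
}

# Inverse of as_feature_matrix(): matrix -> tibble with id column `id_col`.
matrix_to_tbl <- function(m, id_col = "gene") {
  tibble::as_tibble(m, rownames = id_col)
}

# Pooled-variance (Student) two-sample t-test, vectorized over matrix rows.
# Returns tibble(mean1, mean2, stat, df, p). Zero pooled variance with equal
# means gives p = 1; zero pooled variance with unequal means gives p = 0.
row_student_t <- function(m1, m2) {
  n1 <- ncol(m1)
  n2 <- ncol(m2)
  if (n1 < 2 || n2 < 2) abort_bad_arg("need at least 2 observations per group")
  mu1 <- unname(rowMeans(m1))
  mu2 <- unname(rowMeans(m2))
  ss1 <- unname(rowSums((m1 - mu1)^2))
  ss2 <- unname(rowSums((m2 - mu2)^2))
  df <- n1 + n2 - 2
  sp2 <- (ss1 + ss2) / df
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  d <- mu2 - mu1
  stat <- ifelse(se > 0, d / se, ifelse(d == 0, 0, Inf * sign(d)))
  p <- ifelse(se > 0, 2 * stats::pt(-abs(stat), df),
    ifelse(d == 0, 1, 0)
  )
  tibble::tibble(mean1 = mu1, mean2 = mu2, stat = stat, df = df, p = p)
}

# Check p-values lie in [0,1].
check_probs <- function(p, what = "p") {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    abort_bad_arg(sprintf("%s values must lie in [0, 1]", what))
  }
  invisible(p)
}
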