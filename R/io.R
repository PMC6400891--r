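#' Read and write the package's tabular formats
#'
#' Thin TSV wrappers around readr for the formats the pipeline consumes and
#' emits: gene-by-sample counts (first column `gene`), design tables,
#' gel-by-spot volume tables (first column `gel`), two-column spot-to-gene /
#' ortholog maps, two-column gene-term annotations, and edge lists.
#'
#' @param path File path.
#' @param x Tibble to write.
#' @return `read_omics_tsv()` returns a tibble; writers return `x`
#'   invisibly.
#' @name omics_io
NULL

#' @rdname omics_io
#' @export
read_omics_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

#' @rdname omics_io
#' @export
write_omics_tsv <- function(x, path) {
  readr::write_tsv(x, path, progress = FALSE)
  invisible(x)
}

#' Write a simulation truth object as JSON
#'
#' @param truth Truth list from a `simulate_*` function.
#' @param path Output path.
#' @export
write_truth_json <- function(truth, path) {
  if (!requireNamespace("jsonlite", quietly = TRUE)) {
    abort_bad_arg("jsonlite is required to write truth JSON")
  }
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA)
  invisible(truth)
}
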