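#' Build a factorial genotype-by-light study design
#'
#' Constructs the sample annotation table for a two-genotype, two-light-
#' condition factorial experiment. The default RNA-seq design has four
#' biological replicates per group (16 samples); gels for 2D-gel proteomics
#' conventionally use six replicates per group (`n_reps = 6`).
#'
#' Trait codings follow the field convention used downstream by
#' [module_trait_cor()]: wild type = 0, mutant = 1; dark = 0, red light = 1.
#'
#' @param n_reps Replicates per genotype-by-condition group (>= 2).
#' @param genotypes Length-2 character vector, reference genotype first.
#' @param conditions Length-2 character vector, reference condition first.
#' @param prefix Prefix for sample identifiers.
#' @return A tibble with columns `sample_id`, `genotype`, `condition`,
#'   `replicate`, the 0/1 codings `genotype_code` and `condition_code`, and
#'   the combined `group` label (`<genotype>_<condition>`).
#' @examples
#' study_design() # 16 RNA samples
#' study_design(n_reps = 6, prefix = "gel") # 24 gels
#' @export
study_design <- function(n_reps = 4, genotypes = c("WT", "phyA"),
                         conditions = c("dark", "red"), prefix = "s") {
  if (n_reps < 2) abort_bad_arg("every group needs >= 2 replicates")
  if (length(genotypes) != 2 || length(conditions) != 2) {
    abort_bad_arg("exactly two genotypes and two conditions are expected")
  }
  d <- tidyr::expand_grid(
    genotype = factor(genotypes, levels = genotypes),
    condition = factor(conditions, levels = conditions),
    replicate = seq_len(n_reps)
  )
  d <- dplyr::mutate(d,
    genotype_code = as.integer(genotype == genotypes[2]),
    condition_code = as.integer(condition == conditions[2]),
    group = paste(genotype, condition, sep = "_"),
    sample_id = sprintf(
      "%s_%s_%s_r%d", prefix, .data$genotype, .data$condition, .data$replicate
    )
  )
  validate_design(dplyr::select(
    d, "sample_id", "genotype", "condition", "replicate",
    "genotype_code", "condition_code", "group"
  ))
}

validate_design <- function(design) {
  need <- c("sample_id", "group")
  if (!all(need %in% names(design))) {
    abort_bad_arg("design must have sample_id and group columns")
  }
  if (anyDuplicated(design$sample_id)) {
    abort_bad_arg("sample_ids must be unique")
  }
  if (any(table(design$group) < 2)) {
    abort_bad_arg("every genotype-by-condition group needs >= 2 replicates")
  }
  tibble::as_tibble(design)
}

# Align the columns of a count/expression matrix with a design table.
match_design <- function(m, design) {
  design <- validate_design(design)
  if (!setequal(colnames(m), design$sample_id)) {
    abort_bad_arg("matrix column names must match design sample_ids exactly")
  }
  m[, design$sample_id, drop = FALSE]
}
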