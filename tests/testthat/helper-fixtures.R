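# Shared small fixtures, all built in code.

# A null configuration: no planted effects, no modules.
null_config <- function(n_genes = 2000, seed = 1L, ...) {
  args <- list(
    n_genes = n_genes, seed = seed,
    n_de_genotype = 0, n_de_light = 0, n_de_interaction = 0,
    module_sizes = integer(0), module_traits = character(0),
    module_trait_strength = numeric(0)
  )
  args <- utils::modifyList(args, list(...))
  do.call(sim_config, args)
}

# A small structured configuration for fast end-to-end tests; any sim_config
# argument may be overridden.
small_config <- function(seed = 1L, ...) {
  args <- list(
    n_genes = 800, seed = seed,
    n_de_genotype = 60, n_de_light = 40, n_de_interaction = 20,
    module_sizes = c(60, 50), module_traits = c("genotype", "condition"),
    module_trait_strength = c(0.95, 0.95),
    n_spots = 60, n_dep_genotype = 10, n_dep_light = 5,
    n_dep_interaction = 3
  )
  args <- utils::modifyList(args, list(...))
  do.call(sim_config, args)
}

counts_tbl <- function(m) {
  tibble::as_tibble(m, rownames = "gene")
}

# Trait table in the layout module_trait_cor() expects.
design_traits <- function(design) {
  tibble::tibble(
    sample = design$sample_id,
    genotype = design$genotype_code,
    condition = design$condition_code
  )
}
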