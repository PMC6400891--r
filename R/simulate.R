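#' Configuration for the synthetic multi-omics generator
#'
#' Bundles every tunable of the generator with defaults that mirror the
#' factorial seedling study the package is organized around: 16 RNA-seq
#' samples (2 genotypes x 2 light conditions x 4 replicates), 24 gels
#' (6 replicates per group), ~24,000 genes, 218 protein spots with a
#' many-to-one spot-to-gene map, twelve latent-factor co-expression modules,
#' and planted genotype-, light- and interaction-driven differential
#' expression in log2 units.
#'
#' @param n_genes Number of genes in the simulated universe.
#' @param seed Integer seed; every generator output is a pure function of its
#'   inputs and this seed.
#' @param baseline_meanlog,baseline_sdlog Log-normal law for per-gene baseline
#'   mean counts.
#' @param disp_asymptote,disp_over_mean,disp_sdlog Negative-binomial
#'   dispersion trend `alpha(mu) = disp_asymptote + disp_over_mean / mu` with
#'   log-normal scatter `disp_sdlog` around it (variance = mu + alpha mu^2).
#' @param disp_fixed If non-NULL, a single positive dispersion used for all
#'   genes (overrides the trend; values near zero give the Poisson limit).
#' @param libsize_range Range of per-sample library-size factors (uniform).
#' @param n_de_genotype,n_de_light,n_de_interaction Sizes of the planted DE
#'   blocks outside modules.
#' @param lfc_genotype,lfc_light,lfc_interaction Absolute planted log2 fold
#'   changes for the blocks (signs alternate within a block).
#' @param module_sizes Integer vector of module sizes (12 modules by default).
#' @param module_traits Character vector, one of `"genotype"`, `"condition"`,
#'   `"interaction"`, `"none"` per module: which sample covariate drives the
#'   module's latent profile (`"none"` = co-expressed but trait-free).
#' @param module_trait_strength Per-module correlation (in \[0, 1\]) between
#'   the latent profile and the driving trait; the complementary variance is
#'   a module-specific profile orthogonalized within groups, so the planted
#'   group effect of a module gene is exactly
#'   `loading * module_amp * strength` (ignored for `"none"` modules). Two
#'   modules of the same trait stay separable as long as the product of their
#'   strengths is well below 1.
#' @param loading_range Per-gene loading range on the module latent profile.
#' @param core_frac Fraction of each module planted as "core" genes whose
#'   loading is twice the module background.
#' @param n_spots Number of 2D-gel protein spots.
#' @param frac_duplicated_spot_genes Fraction of spots whose gene identifier
#'   duplicates another spot's (many-to-one map); 0 gives a bijection.
#' @param n_dep_genotype,n_dep_light,n_dep_interaction Numbers of spots with
#'   planted protein-level effects per factor.
#' @param dep_lfc Absolute protein log2 fold change for planted spots.
#' @param frac_discordant Of the planted genotype-effect spots whose gene is
#'   also a transcript-level DE gene, the fraction whose protein effect sign
#'   opposes the transcript effect (the transcript/protein discordance motif).
#' @param spot_base_meanlog2,spot_base_sdlog2 Log2-normal law for baseline
#'   spot volumes.
#' @param spot_noise_sdlog2 Residual sd of log2 spot volumes (0.29 ~ 20% CV).
#' @param gel_scale_range Range of per-gel multiplicative intensity factors
#'   (removed by [relative_spot_volumes()]).
#' @param n_terms,term_size_range Number of annotation terms and the
#'   (log-uniform) range of term sizes.
#' @param n_enriched_terms,enrichment_odds Number of terms planted as enriched
#'   in the planted DE genes, and the odds ratio of the over-sampling.
#' @return A named list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 24000,
                       seed = 1L,
                       baseline_meanlog = log(100),
                       baseline_sdlog = 1.5,
                       disp_asymptote = 0.05,
                       disp_over_mean = 2,
                       disp_sdlog = 0.3,
                       disp_fixed = NULL,
                       libsize_range = c(0.7, 1.4),
                       n_de_genotype = 400,
                       n_de_light = 300,
                       n_de_interaction = 150,
                       lfc_genotype = 3,
                       lfc_light = 3,
                       lfc_interaction = 2,
                       module_sizes = c(
                         600, 500, 400, 350, 300, 250,
                         200, 150, 120, 100, 80, 50
                       ),
                       module_traits = c(
                         "genotype", "condition", "genotype", "condition",
                         "interaction", "none", "none", "none",
                         "none", "none", "none", "none"
                       ),
                       module_trait_strength = c(
                         0.95, 0.95, 0.7, 0.7, 0.9, 1, 1, 1, 1, 1, 1, 1
                       ),
                       module_amp = 3,
                       loading_range = c(0.8, 1.4),
                       core_frac = 0.1,
                       n_spots = 218,
                       frac_duplicated_spot_genes = 0.35,
                       n_dep_genotype = 25,
                       n_dep_light = 12,
                       n_dep_interaction = 8,
                       dep_lfc = 1,
                       frac_discordant = 0.6,
                       spot_base_meanlog2 = 10,
                       spot_base_sdlog2 = 1.5,
                       spot_noise_sdlog2 = 0.29,
                       gel_scale_range = c(0.5, 2),
                       n_terms = 200,
                       term_size_range = c(5, 200),
                       n_enriched_terms = 5,
                       enrichment_odds = 5) {
  cfg <- as.list(environment())
  if (cfg$n_genes < 1) abort_bad_arg("n_genes must be positive")
  if (!is.null(cfg$disp_fixed) && cfg$disp_fixed <= 0) {
    abort_bad_arg("dispersion must be positive")
  }
  if (cfg$disp_asymptote <= 0 || cfg$disp_over_mean < 0) {
    abort_bad_arg("dispersion trend parameters must be positive")
  }
  if (length(cfg$module_sizes) != length(cfg$module_traits) ||
    length(cfg$module_sizes) != length(cfg$module_trait_strength)) {
    abort_bad_arg(
      "module_sizes, module_traits and module_trait_strength must have equal length"
    )
  }
  if (any(cfg$module_trait_strength < 0 | cfg$module_trait_strength > 1)) {
    abort_bad_arg("module_trait_strength must lie in [0, 1]")
  }
  if (cfg$frac_duplicated_spot_genes < 0 || cfg$frac_duplicated_spot_genes > 1) {
    abort_bad_arg("frac_duplicated_spot_genes must lie in [0, 1]")
  }
  if (cfg$frac_discordant < 0 || cfg$frac_discordant > 1) {
    abort_bad_arg("frac_discordant must lie in [0, 1]")
  }
  n_planted <- sum(cfg$module_sizes) + cfg$n_de_genotype + cfg$n_de_light +
    cfg$n_de_interaction
  if (n_planted > cfg$n_genes) {
    abort_bad_arg("module and DE block sizes exceed n_genes")
  }
  structure(cfg, class = "sim_config")
}

gene_labels <- function(n) sprintf("gene_%05d", seq_len(n))

# Per-gene planted effect tables shared by counts and spot simulators.
plan_signals <- function(cfg) {
  genes <- gene_labels(cfg$n_genes)
  n_mod <- length(cfg$module_sizes)
  idx <- seq_len(sum(cfg$module_sizes) + cfg$n_de_genotype + cfg$n_de_light +
    cfg$n_de_interaction)
  pool <- sample(genes, length(idx)) # random placement in the universe
  take <- function(n) {
    out <- pool[seq_len(n)]
    pool <<- pool[-seq_len(n)]
    out
  }
  module <- rep("grey", cfg$n_genes)
  names(module) <- genes
  loading <- numeric(cfg$n_genes)
  names(loading) <- genes
  core <- character(0)
  mod_names <- sprintf("M%02d", seq_len(n_mod))
  mod_members <- vector("list", n_mod)
  for (m in seq_len(n_mod)) {
    mem <- take(cfg$module_sizes[m])
    mod_members[[m]] <- mem
    module[mem] <- mod_names[m]
    w <- stats::runif(length(mem), cfg$loading_range[1], cfg$loading_range[2])
    n_core <- max(1L, floor(cfg$core_frac * length(mem)))
    w[seq_len(n_core)] <- 2 * mean(cfg$loading_range)
    core <- c(core, mem[seq_len(n_core)])
    loading[mem] <- w
  }
  alt_sign <- function(n) rep_len(c(1, -1), n)
  blk <- function(n, lfc) {
    g <- take(n)
    stats::setNames(alt_sign(n) * lfc, g)
  }
  list(
    genes = genes,
    beta_geno = blk(cfg$n_de_genotype, cfg$lfc_genotype),
    beta_light = blk(cfg$n_de_light, cfg$lfc_light),
    beta_inter = blk(cfg$n_de_interaction, cfg$lfc_interaction),
    module = module,
    loading = loading,
    core_genes = core,
    module_names = mod_names,
    module_members = mod_members
  )
}

# Latent per-sample profile for one module (log2 units). The trait part uses
# the centered 0/1 coding (so the planted between-level shift is exactly
# module_amp * strength); the module-specific part is orthogonalized within
# genotype-by-condition groups so it adds no systematic group effect, and is
# scaled to the complementary variance.
module_latent <- function(type, strength, design, cfg) {
  g <- design$genotype_code
  l <- design$condition_code
  trait <- switch(type,
    genotype = g,
    condition = l,
    interaction = g * l,
    none = rep(0, nrow(design)),
    abort_bad_arg(sprintf("unknown module trait type '%s'", type))
  )
  cc <- if (type == "none") 0 else strength
  noise <- stats::rnorm(nrow(design))
  noise <- noise - stats::ave(noise, design$group) # no group component
  s_noise <- stats::sd(noise)
  target_sd <- 0.5 * sqrt(1 - cc^2)
  if (s_noise > 0 && target_sd > 0) {
    noise <- noise * target_sd / s_noise
  } else {
    noise <- noise * 0
  }
  cfg$module_amp * (cc * (trait - mean(trait)) + noise)
}

# Planted per-contrast transcript effects. With modules = FALSE only the
# directly planted DE blocks are listed (the DE answer key); with
# modules = TRUE the module-derived shifts (loading * amp * strength, which
# ride on top of each module's shared latent noise) are folded in as well —
# the full set of genes carrying any systematic group effect.
planted_de_table <- function(plan, cfg, modules = FALSE) {
  eff <- function(beta) {
    tibble::tibble(gene = names(beta), lfc = unname(beta))
  }
  mod_eff <- function(types) {
    keep <- if (modules) which(cfg$module_traits %in% types) else integer(0)
    if (!length(keep)) {
      return(tibble::tibble(gene = character(0), lfc = numeric(0)))
    }
    purrr::map_dfr(keep, function(m) {
      g <- plan$module_members[[m]]
      tibble::tibble(
        gene = g,
        lfc = plan$loading[g] * cfg$module_amp * cfg$module_trait_strength[m]
      )
    })
  }
  comb <- function(...) {
    dplyr::summarise(
      dplyr::group_by(dplyr::bind_rows(...), .data$gene),
      lfc = sum(.data$lfc), .groups = "drop"
    )
  }
  # The four canonical comparisons; lfc is level2 vs level1 of the contrast.
  list(
    WT_dark_vs_WT_red = comb(eff(plan$beta_light), mod_eff("condition")),
    phyA_dark_vs_phyA_red = comb(
      eff(plan$beta_light), eff(plan$beta_inter),
      mod_eff(c("condition", "interaction"))
    ),
    WT_dark_vs_phyA_dark = comb(eff(plan$beta_geno), mod_eff("genotype")),
    WT_red_vs_phyA_red = comb(
      eff(plan$beta_geno), eff(plan$beta_inter),
      mod_eff(c("genotype", "interaction"))
    )
  )
}

#' Simulate a negative-binomial count matrix with planted structure
#'
#' Generates gene-by-sample counts for a factorial design. Per-gene log2 mean
#' is baseline + genotype, light and interaction block effects + the gene's
#' loading on its module's latent per-sample profile; counts are drawn from a
#' negative binomial with a mean-dependent dispersion trend, and per-sample
#' library-size factors are applied. Everything planted is recorded in the
#' returned truth object so downstream calls have an answer key.
#'
#' @param design A design tibble from [study_design()].
#' @param config A [sim_config()].
#' @return A list with elements `counts` (tibble: `gene` column plus one
#'   column per sample), `design`, and `truth` (list: `de_genes` — tibble of
#'   contrast/gene/planted lfc for the directly planted DE blocks;
#'   `trait_responsive` — the same plus module-derived group shifts, i.e.
#'   every gene with any systematic group effect; `module_assignment` —
#'   tibble gene/module with `"grey"` for unassigned; `core_genes`;
#'   `module_loading`; `baseline_mean`; `dispersion`; `library_factors`;
#'   `seed`).
#' @examples
#' sim <- simulate_counts(study_design(), sim_config(n_genes = 500, seed = 7))
#' dim(sim$counts)
#' @export
simulate_counts <- function(design = study_design(), config = sim_config()) {
  design <- validate_design(design)
  cfg <- config
  withr::with_seed(cfg$seed, {
    plan <- plan_signals(cfg)
    n <- cfg$n_genes
    ns <- nrow(design)
    baseline <- stats::rlnorm(n, cfg$baseline_meanlog, cfg$baseline_sdlog)
    if (is.null(cfg$disp_fixed)) {
      trend <- cfg$disp_asymptote + cfg$disp_over_mean / baseline
      alpha <- stats::rlnorm(n, log(trend), cfg$disp_sdlog)
    } else {
      alpha <- rep(cfg$disp_fixed, n)
    }
    lib <- stats::runif(ns, cfg$libsize_range[1], cfg$libsize_range[2])
    g <- design$genotype_code
    l <- design$condition_code
    log2mu <- matrix(log2(baseline), n, ns)
    add <- function(beta, covariate) {
      i <- match(names(beta), plan$genes)
      log2mu[i, ] <<- log2mu[i, ] + outer(unname(beta), covariate)
    }
    add(plan$beta_geno, g)
    add(plan$beta_light, l)
    add(plan$beta_inter, g * l)
    for (m in seq_along(plan$module_names)) {
      z <- module_latent(
        cfg$module_traits[m], cfg$module_trait_strength[m], design, cfg
      )
      i <- match(plan$module_members[[m]], plan$genes)
      log2mu[i, ] <- log2mu[i, ] + outer(plan$loading[plan$module_members[[m]]], z)
    }
    mu <- sweep(2^log2mu, 2, lib, `*`)
    counts <- matrix(
      stats::rnbinom(n * ns, mu = mu, size = rep(1 / alpha, ns)),
      n, ns,
      dimnames = list(plan$genes, design$sample_id)
    )
    truth <- list(
      de_genes = dplyr::bind_rows(planted_de_table(plan, cfg), .id = "contrast"),
      trait_responsive = dplyr::bind_rows(
        planted_de_table(plan, cfg, modules = TRUE),
        .id = "contrast"
      ),
      module_assignment = tibble::tibble(
        gene = plan$genes, module = unname(plan$module[plan$genes])
      ),
      core_genes = plan$core_genes,
      module_loading = tibble::tibble(
        gene = plan$genes, loading = unname(plan$loading[plan$genes])
      ),
      baseline_mean = stats::setNames(baseline, plan$genes),
      dispersion = stats::setNames(alpha, plan$genes),
      library_factors = stats::setNames(lib, design$sample_id),
      seed = cfg$seed
    )
    list(counts = matrix_to_tbl(counts), design = design, truth = truth)
  })
}

#' Simulate 2D-gel spot volumes with a many-to-one spot-to-gene map
#'
#' Log-normal spot volumes for a gel-by-spot table under the protein design
#' (six replicates per group by default). A configurable fraction of spots
#' shares gene identifiers with other spots, emulating proteolytic forms and
#' modified versions of one protein resolving as several spots. Planted
#' protein effects can oppose the transcript effect for spots mapped to
#' transcript-level DE genes (the discordance motif); pass the RNA truth to
#' plant that structure.
#'
#' @param design_protein Gel design from [study_design()] (6 reps per group).
#' @param config A [sim_config()].
#' @param truth_rna Optional truth from [simulate_counts()]; if supplied,
#'   planted genotype-effect spots are preferentially mapped to transcript DE
#'   genes and `frac_discordant` of them get the opposite effect sign.
#' @return List with `volumes` (tibble: `gel` column + one column per spot),
#'   `design`, `spot_map` (tibble spot/gene), and `truth` (list: `dep_spots`
#'   tibble of spot/factor/protein lfc, `discordant_genes`, `n_unique_genes`,
#'   `seed`).
#' @export
simulate_spot_volumes <- function(design_protein = study_design(n_reps = 6, prefix = "gel"),
                                  config = sim_config(),
                                  truth_rna = NULL) {
  design <- validate_design(design_protein)
  cfg <- config
  withr::with_seed(cfg$seed + 1L, {
    genes <- gene_labels(cfg$n_genes)
    n_spots <- cfg$n_spots
    n_unique <- max(1L, round(n_spots * (1 - cfg$frac_duplicated_spot_genes)))
    if (n_unique > cfg$n_genes) {
      abort_bad_arg("n_spots exceeds the gene universe after deduplication")
    }
    spot_ids <- sprintf("spot_%03d", seq_len(n_spots))

    # Prefer transcript-level genotype-DE genes for a portion of the mapped
    # genes so the discordance motif is realizable.
    rna_geno <- character(0)
    if (!is.null(truth_rna)) {
      rna_geno <- unique(truth_rna$de_genes$gene[
        truth_rna$de_genes$contrast == "WT_dark_vs_phyA_dark"
      ])
    }
    n_from_de <- min(length(rna_geno), cfg$n_dep_genotype, n_unique)
    mapped <- c(
      if (n_from_de > 0) sample(rna_geno, n_from_de),
      sample(setdiff(genes, rna_geno), n_unique - n_from_de)
    )
    gene_of_spot <- c(
      mapped,
      if (n_spots > n_unique) sample(mapped, n_spots - n_unique, replace = TRUE)
    )
    names(gene_of_spot) <- spot_ids

    beta <- matrix(0, n_spots, 3, dimnames = list(spot_ids, c("geno", "light", "inter")))
    pool <- sample(spot_ids)
    take <- function(n) {
      out <- pool[seq_len(n)]
      pool <<- pool[-seq_len(n)]
      out
    }
    # genotype-effect spots: those mapped to RNA DE genes first
    de_spots <- spot_ids[gene_of_spot %in% rna_geno]
    geno_spots <- utils::head(
      unique(c(de_spots, take(cfg$n_dep_genotype))), cfg$n_dep_genotype
    )
    discordant <- character(0)
    if (!is.null(truth_rna) && length(de_spots)) {
      rna_lfc <- truth_rna$de_genes[
        truth_rna$de_genes$contrast == "WT_dark_vs_phyA_dark",
      ]
      sgn <- sign(rna_lfc$lfc[match(gene_of_spot[geno_spots], rna_lfc$gene)])
      sgn[is.na(sgn)] <- rep_len(c(1, -1), sum(is.na(sgn)))
      n_disc <- round(cfg$frac_discordant * sum(!is.na(sgn)))
      flip <- rep(1, length(geno_spots))
      shared <- which(gene_of_spot[geno_spots] %in% rna_lfc$gene)
      flip[utils::head(shared, n_disc)] <- -1
      beta[geno_spots, "geno"] <- flip * sgn * cfg$dep_lfc
      discordant <- unique(gene_of_spot[geno_spots[utils::head(shared, n_disc)]])
    } else {
      beta[geno_spots, "geno"] <- rep_len(c(1, -1), length(geno_spots)) * cfg$dep_lfc
    }
    beta[take(cfg$n_dep_light), "light"] <- rep_len(c(1, -1), cfg$n_dep_light) * cfg$dep_lfc
    beta[take(cfg$n_dep_interaction), "inter"] <-
      rep_len(c(1, -1), cfg$n_dep_interaction) * cfg$dep_lfc

    g <- design$genotype_code
    l <- design$condition_code
    base <- stats::rnorm(n_spots, cfg$spot_base_meanlog2, cfg$spot_base_sdlog2)
    log2v <- matrix(base, n_spots, nrow(design)) +
      outer(beta[, "geno"], g) + outer(beta[, "light"], l) +
      outer(beta[, "inter"], g * l) +
      matrix(
        stats::rnorm(n_spots * nrow(design), 0, cfg$spot_noise_sdlog2),
        n_spots
      )
    gel_scale <- stats::runif(nrow(design), cfg$gel_scale_range[1], cfg$gel_scale_range[2])
    vol <- sweep(2^log2v, 2, gel_scale, `*`)
    dimnames(vol) <- list(spot_ids, design$sample_id)

    dep_spots <- tibble::as_tibble(beta, rownames = "spot")
    dep_spots <- tidyr::pivot_longer(dep_spots, -"spot",
      names_to = "factor", values_to = "lfc"
    )
    dep_spots <- dplyr::filter(dep_spots, .data$lfc != 0)
    list(
      volumes = matrix_to_tbl(t(vol), id_col = "gel"),
      design = design,
      spot_map = tibble::tibble(spot = spot_ids, gene = unname(gene_of_spot)),
      truth = list(
        dep_spots = dep_spots,
        discordant_genes = discordant,
        n_unique_genes = length(unique(gene_of_spot)),
        gel_scale = stats::setNames(gel_scale, design$sample_id),
        seed = cfg$seed
      )
    )
  })
}

#' Simulate a gene-to-term annotation table with planted enrichment
#'
#' Terms draw members uniformly from the gene universe except for the planted
#' enriched terms, which over-sample a designated study set at a stated odds
#' ratio. With `enrichment_odds = 1` every term is null and downstream Fisher
#' p-values are uniform.
#'
#' @param genes Character vector: the gene universe.
#' @param config A [sim_config()].
#' @param study Character vector of genes the enriched terms over-sample
#'   (typically planted DE genes); may be empty, in which case all terms are
#'   null.
#' @return List with `annotation` (tibble gene/term, one row per pair) and
#'   `truth` (list: `enriched_terms`, `seed`).
#' @export
simulate_go_annotation <- function(genes, config = sim_config(), study = character(0)) {
  cfg <- config
  if (!length(genes)) abort_bad_arg("gene universe must be nonempty")
  if (cfg$n_terms < 1) abort_bad_arg("need at least one term")
  if (cfg$term_size_range[2] > length(genes)) {
    abort_bad_arg("term sizes cannot exceed the universe size")
  }
  withr::with_seed(cfg$seed + 2L, {
    terms <- sprintf("GO:%07d", seq_len(cfg$n_terms))
    sizes <- round(exp(stats::runif(
      cfg$n_terms, log(cfg$term_size_range[1]), log(cfg$term_size_range[2])
    )))
    enriched <- utils::head(terms, min(cfg$n_enriched_terms, cfg$n_terms))
    w_base <- rep(1, length(genes))
    w_enr <- ifelse(genes %in% study, cfg$enrichment_odds, 1)
    ann <- purrr::map2(terms, sizes, function(tm, sz) {
      w <- if (tm %in% enriched && length(study)) w_enr else w_base
      tibble::tibble(gene = sample(genes, sz, prob = w), term = tm)
    })
    list(
      annotation = dplyr::bind_rows(ann),
      truth = list(
        enriched_terms = if (length(study)) enriched else character(0),
        seed = cfg$seed
      )
    )
  })
}

#' Simulate a partial one-to-one ortholog map between two gene universes
#'
#' Emulates a reciprocal-best-hit ortholog table: `n_pairs` genes of universe
#' A map injectively into universe B.
#'
#' @param universe_a,universe_b Character vectors of labels, or single
#'   integers taken as universe sizes (labels are generated).
#' @param n_pairs Number of mapped pairs; at most the smaller universe size.
#' @param seed Integer seed.
#' @return Tibble with columns `gene_a`, `gene_b`; both columns duplicate-free.
#' @examples
#' simulate_ortholog_map(10, 20, 5, seed = 1)
#' @export
simulate_ortholog_map <- function(universe_a, universe_b, n_pairs, seed = 1L) {
  lab <- function(u, pre) {
    if (is.numeric(u) && length(u) == 1) sprintf("%s_%05d", pre, seq_len(u)) else as.character(u)
  }
  a <- lab(universe_a, "a")
  b <- lab(universe_b, "b")
  if (n_pairs > min(length(a), length(b))) {
    abort_bad_arg("n_pairs exceeds a universe size")
  }
  withr::with_seed(seed, {
    tibble::tibble(
      gene_a = if (n_pairs > 0) sample(a, n_pairs) else character(0),
      gene_b = if (n_pairs > 0) sample(b, n_pairs) else character(0)
    )
  })
}
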