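test_that("median-of-ratios size factors match hand computation and DESeq2", {
  # identical columns -> unit factors
  m <- matrix(c(5, 9, 13, 5, 9, 13), ncol = 2,
    dimnames = list(c("g1", "g2", "g3"), c("s1", "s2"))
  )
  expect_equal(size_factors(m)$size_factor, c(1, 1))

  # hand example: every gene ratio is (1/sqrt(2), sqrt(2))
  counts <- tibble::tibble(
    gene = c("g1", "g2", "g3"), s1 = c(2, 3, 4), s2 = c(4, 6, 8)
  )
  expect_equal(size_factors(counts)$size_factor, c(1 / sqrt(2), sqrt(2)),
    tolerance = 1e-12
  )

  # independent oracle on a random matrix
  set.seed(1)
  r <- matrix(rnbinom(600, mu = 80, size = 5), nrow = 100,
    dimnames = list(sprintf("g%d", 1:100), sprintf("s%d", 1:6))
  )
  r[r == 0] <- 1
  ours <- size_factors(r)$size_factor
  oracle <- DESeq2::estimateSizeFactorsForMatrix(r)
  expect_equal(ours, unname(oracle), tolerance = 1e-8)
})

test_that("scaling one sample scales its factor; normalization is idempotent", {
  set.seed(2)
  m <- matrix(rpois(400, 50) + 1, nrow = 100,
    dimnames = list(sprintf("g%d", 1:100), sprintf("s%d", 1:4))
  )
  f0 <- size_factors(m)$size_factor
  m2 <- m
  m2[, 3] <- m2[, 3] * 4
  f1 <- size_factors(m2)$size_factor
  # ratios to the geometric mean shift identically for all samples
  expect_equal(f1[3] / f0[3] / (f1[1] / f0[1]), 4, tolerance = 1e-9)

  # idempotence up to the shared geometric-mean convention
  norm <- normalize_counts(m)
  f_norm <- size_factors(norm)$size_factor
  expect_equal(f_norm / mean(f_norm), rep(1, 4), tolerance = 1e-9)
  expect_equal(f_norm, rep(1, 4), tolerance = 0.05)
})

test_that("size factors error without an all-positive gene unless fallback", {
  m <- matrix(c(0, 5, 3, 0), 2, dimnames = list(c("g1", "g2"), c("s1", "s2")))
  expect_error(size_factors(m), "pseudo")
  expect_silent(sf <- size_factors(m, allow_pseudo_reference = TRUE))
  expect_true(all(sf$size_factor > 0))
})

test_that("dispersion estimation recovers the simulated law", {
  d <- study_design()
  # Poisson data -> estimates near the floor
  simp <- simulate_counts(d, null_config(n_genes = 800, seed = 4, disp_fixed = 1e-8))
  dp <- estimate_dispersions(simp$counts, d)
  expect_lt(median(dp$dispersion), 0.02)

  # alpha = 0.2 -> median inside [0.1, 0.4] at 2000 genes
  sim2 <- simulate_counts(d, null_config(n_genes = 2000, seed = 5, disp_fixed = 0.2))
  d2 <- estimate_dispersions(sim2$counts, d)
  expect_gt(median(d2$dispersion), 0.1)
  expect_lt(median(d2$dispersion), 0.4)

  # constant gene sits at the floor
  m <- matrix(7, 4, 4, dimnames = list(paste0("g", 1:4), d$sample_id[1:4]))
  m[2:4, ] <- matrix(rpois(12, 40) + 1, 3)
  dd <- estimate_dispersions(m, d[1:4, ],
    factors = tibble::tibble(sample = colnames(m), size_factor = rep(1, 4))
  )
  expect_equal(unname(dd$dispersion[dd$gene == "g1"]), 1e-4)
})

test_that("bh_adjust follows the step-up rule", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_equal(bh_adjust(0.2), 0.2)
  p <- runif(50)
  expect_true(all(bh_adjust(p) >= p))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("de_call handles null genes, bad callers and absent groups", {
  d <- study_design()
  sim <- simulate_counts(d, small_config(seed = 6))
  expect_error(
    de_call(sim$counts, d, c("WT_dark", "nope"), "logt"),
    "groups present"
  )
  expect_error(
    de_call(sim$counts, d, c("WT_dark", "phyA_dark"), "magic"),
    "arg"
  )

  # a gene identical in both groups: lfc 0, p ~ 1 under logt
  m <- as.matrix(sim$counts[, -1])
  rownames(m) <- sim$counts$gene
  sub_ids <- d$sample_id[d$group %in% c("WT_dark", "phyA_dark")]
  m[1, sub_ids] <- 64
  de <- suppressMessages(de_call(counts_tbl(m), d, c("WT_dark", "phyA_dark"), "logt",
    factors = tibble::tibble(sample = colnames(m), size_factor = rep(1, ncol(m)))
  ))
  row1 <- de[de$gene == rownames(m)[1], ]
  expect_equal(row1$lfc, 0)
  expect_equal(row1$p, 1)

  # all-zero genes are dropped and reported
  m[2, ] <- 0
  de2 <- suppressMessages(de_call(counts_tbl(m), d, c("WT_dark", "phyA_dark"), "logt"))
  expect_false(rownames(m)[2] %in% de2$gene)
  expect_true(rownames(m)[2] %in% attr(de2, "dropped"))
})

test_that("callers control type-I error under the global null", {
  d <- study_design()
  sim <- simulate_counts(d, null_config(n_genes = 2000, seed = 12))
  band <- 3 * sqrt(0.05 * 0.95 / 2000)
  for (cl in c("nb_wald", "nb_lrt", "logt")) {
    de <- suppressMessages(de_call(sim$counts, d, c("WT_dark", "phyA_dark"), cl))
    expect_lt(abs(mean(de$p < 0.05) - 0.05), band + 1e-9)
  }
})

test_that("nb_wald is well powered for strong planted effects", {
  # planted log2FC = 3, dispersion 0.1, 4 replicates per group
  d <- study_design()
  cfg <- sim_config(
    n_genes = 1500, seed = 8, n_de_genotype = 150, lfc_genotype = 3,
    n_de_light = 0, n_de_interaction = 0, disp_fixed = 0.1,
    module_sizes = integer(0), module_traits = character(0),
    module_trait_strength = numeric(0)
  )
  sim <- simulate_counts(d, cfg)
  de <- suppressMessages(de_call(sim$counts, d, c("WT_dark", "phyA_dark"), "nb_wald"))
  truth <- sim$truth$de_genes
  tg <- truth$gene[truth$contrast == "WT_dark_vs_phyA_dark"]
  power <- mean(tg %in% de$gene[de$q < 0.05])
  expect_gt(power, 0.8)
})

test_that("consensus rule: >= min_methods in every mapper group", {
  mk <- function(gene, caller, grp) {
    tibble::tibble(
      contrast = "c1", caller = caller, mapper_group = grp, gene = gene
    )
  }
  # enumerate support patterns for two mapper groups, three callers
  callers <- c("a", "b", "c")
  for (nA in 0:3) {
    for (nB in 0:3) {
      sets <- dplyr::bind_rows(
        if (nA > 0) mk("g", callers[seq_len(nA)], "mapper_a"),
        if (nB > 0) mk("g", callers[seq_len(nB)], "mapper_b"),
        mk("anchor", callers, "mapper_a"), mk("anchor", callers, "mapper_b")
      )
      cons <- consensus_calls(sets, min_methods = 2)
      expect_equal("g" %in% cons$gene, nA >= 2 && nB >= 2,
        info = sprintf("support %d/%d", nA, nB)
      )
    }
  }

  # universe filter
  sets <- dplyr::bind_rows(mk("g1", callers, "m1"), mk("g2", callers, "m1"))
  cons_u <- consensus_calls(sets, universe = "g1")
  expect_equal(cons_u$gene, "g1")

  # monotonicity: lowering min_methods never shrinks the set
  set.seed(3)
  rnd <- dplyr::bind_rows(lapply(1:40, function(i) {
    mk(
      paste0("g", i), sample(callers, sample(0:3, 1)),
      sample(c("m1", "m2"), 1)
    )
  }))
  rnd <- rnd[!is.na(rnd$caller), ]
  for (k in 3:2) {
    hi <- consensus_calls(rnd, min_methods = k)$gene
    lo <- consensus_calls(rnd, min_methods = k - 1)$gene
    expect_true(all(hi %in% lo))
  }

  expect_error(consensus_calls(mk("g", "a", "m")[0, ]), "empty")
  two <- dplyr::bind_rows(mk("g", "a", "m"), mk("h", "a", "m"))
  two$contrast <- c("c1", "c2")
  expect_error(consensus_calls(two), "one contrast")
})
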