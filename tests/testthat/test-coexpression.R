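test_that("variance filter keeps the top-k and drops constants", {
  set.seed(5)
  m <- matrix(rpois(200 * 8, 30), 200,
    dimnames = list(sprintf("g%03d", 1:200), paste0("s", 1:8))
  )
  # identity at k = n
  all_g <- top_variable_genes(m, k = 200)
  expect_setequal(all_g$gene, rownames(m))

  # constant gene is excluded at k = n - 1
  m["g001", ] <- 42
  sel <- top_variable_genes(m, k = 199)
  expect_false("g001" %in% sel$gene)

  # planted high-variance block always selected
  m2 <- m
  m2[2:21, seq(1, 8, 2)] <- m2[2:21, seq(1, 8, 2)] * 20
  sel2 <- top_variable_genes(m2, k = 50)
  expect_true(all(rownames(m)[2:21] %in% sel2$gene))

  expect_error(top_variable_genes(m, k = 0), "k must")
  expect_error(top_variable_genes(m, k = 300), "k must")
})

test_that("soft adjacency implements |cor|^beta with safe degenerate handling", {
  x <- rnorm(16)
  m <- rbind(g1 = x, g2 = 2 * x + 1, g3 = -0.5 * x + rnorm(16, sd = 1e-8))
  colnames(m) <- paste0("s", 1:16)
  a <- soft_adjacency(m, beta = 6)
  expect_equal(a["g1", "g2"], 1, tolerance = 1e-9)
  expect_equal(diag(a), c(g1 = 0, g2 = 0, g3 = 0))

  # direct evaluation at cor = -0.9, beta = 20 (orthogonal construction)
  set.seed(8)
  z <- rnorm(400)
  e <- rnorm(400)
  e <- residuals(lm(e ~ z))
  y <- -0.9 * scale(z)[, 1] + sqrt(1 - 0.81) * scale(e)[, 1]
  mm <- rbind(a = scale(z)[, 1], b = y)
  colnames(mm) <- paste0("s", 1:400)
  r <- cor(mm["a", ], mm["b", ])
  a2 <- soft_adjacency(mm, beta = 20)
  expect_equal(a2["a", "b"], abs(r)^20, tolerance = 1e-10)
  expect_lt(abs(abs(r) - 0.9), 1e-6)

  # independent noise is crushed at beta = 20
  set.seed(9)
  noise <- matrix(rnorm(200 * 16), 200,
    dimnames = list(sprintf("n%03d", 1:200), paste0("s", 1:16))
  )
  an <- soft_adjacency(noise, beta = 20)
  expect_lt(median(an[upper.tri(an)]), 0.01)

  # zero-variance gene: warned and zeroed
  noise[1, ] <- 3
  expect_warning(az <- soft_adjacency(noise, beta = 20), "zero-variance")
  expect_true(all(az[1, ] == 0))
  expect_equal(attr(az, "zero_variance"), "n001")
})

test_that("TOM formula: clique, empty graph, and bounds", {
  # 3-clique with unit adjacency: (1 + 1) / (2 + 1 - 1) = 1
  a <- matrix(1, 3, 3, dimnames = list(paste0("g", 1:3), paste0("g", 1:3)))
  diag(a) <- 0
  tom <- tom_similarity(a)
  expect_equal(unname(tom[upper.tri(tom)]), rep(1, 3))
  expect_equal(unname(diag(tom)), rep(1, 3))

  # all-zero adjacency -> off-diagonal zero
  z <- matrix(0, 4, 4)
  tz <- tom_similarity(z)
  expect_true(all(tz[upper.tri(tz)] == 0))

  # random adjacency: symmetric with entries in [0, 1]
  set.seed(10)
  r <- abs(cor(matrix(rnorm(12 * 30), 12)))^4
  diag(r) <- 0
  tr <- tom_similarity(r)
  expect_true(isSymmetric(tr))
  expect_true(all(tr >= 0 & tr <= 1))
  expect_error(tom_similarity(r - 0.5), "\\[0, 1\\]")
})

test_that("modules are recovered from planted latent factors", {
  # two latent-factor modules of 200 genes + 600 independent genes
  set.seed(11)
  n_s <- 16
  z1 <- rnorm(n_s)
  z2 <- rnorm(n_s)
  expr <- rbind(
    t(sapply(1:200, function(i) runif(1, 0.8, 1.4) * z1 + rnorm(n_s, sd = 0.4))),
    t(sapply(1:200, function(i) runif(1, 0.8, 1.4) * z2 + rnorm(n_s, sd = 0.4))),
    matrix(rnorm(600 * n_s), 600)
  )
  dimnames(expr) <- list(sprintf("g%04d", 1:1000), paste0("s", 1:n_s))
  truth <- rep(c("m1", "m2", "grey"), c(200, 200, 600))
  tom <- tom_similarity(soft_adjacency(expr, beta = 20))
  mods <- detect_modules(tom, expr = counts_tbl(expr), min_module_size = 30)
  ari <- mclust::adjustedRandIndex(mods$module, truth)
  expect_gt(ari, 0.8)
  # colour labels: largest module first in the conventional palette
  expect_true(all(c("turquoise", "blue") %in% mods$module))

  # all-independent genes: nearly everything grey
  noise <- matrix(rnorm(400 * n_s), 400,
    dimnames = list(sprintf("n%04d", 1:400), paste0("s", 1:n_s))
  )
  tom_n <- tom_similarity(soft_adjacency(noise, beta = 20))
  mods_n <- detect_modules(tom_n, expr = counts_tbl(noise))
  expect_gte(mean(mods_n$module == "grey"), 0.95)

  # one perfectly correlated block -> exactly one non-grey module
  block <- rbind(
    matrix(rep(z1, each = 50), 50, byrow = FALSE) + rnorm(50 * n_s, sd = 1e-3),
    matrix(rnorm(100 * n_s), 100)
  )
  dimnames(block) <- list(sprintf("b%03d", 1:150), paste0("s", 1:n_s))
  tom_b <- tom_similarity(soft_adjacency(block, beta = 12))
  mods_b <- detect_modules(tom_b, expr = counts_tbl(block), min_module_size = 20)
  non_grey <- setdiff(unique(mods_b$module), "grey")
  expect_equal(length(non_grey), 1)
  in_mod <- mods_b$gene[mods_b$module == non_grey]
  expect_true(all(sprintf("b%03d", 1:50) %in% in_mod))
})

test_that("eigengenes are unit-norm, sign-oriented, PCA-optimal", {
  set.seed(12)
  n_s <- 12
  z <- rnorm(n_s)
  m <- t(sapply(1:30, function(i) 1.2 * z + rnorm(n_s, sd = 0.3)))
  dimnames(m) <- list(sprintf("g%02d", 1:30), paste0("s", 1:n_s))
  assign_tbl <- tibble::tibble(gene = rownames(m), module = "blue")
  me <- module_eigengenes(counts_tbl(m), assign_tbl)
  e <- me$blue
  expect_equal(sum(e^2), 1, tolerance = 1e-10)
  # orientation: positive correlation with the module mean profile
  expect_gt(cor(e, colMeans(t(scale(t(m))))), 0)

  # identical genes: eigengene equals the shared standardized profile
  ident <- m[rep(1, 5), ]
  rownames(ident) <- paste0("i", 1:5)
  me_i <- module_eigengenes(
    counts_tbl(ident), tibble::tibble(gene = rownames(ident), module = "red")
  )
  prof <- scale(ident[1, ])[, 1]
  prof <- prof / sqrt(sum(prof^2))
  expect_equal(abs(cor(me_i$red, prof)), 1, tolerance = 1e-10)

  # variance explained >= any single member gene's standardized profile
  zm <- t(scale(t(m)))
  var_e <- sum((zm %*% e)^2)
  var_single <- max(sapply(1:nrow(zm), function(i) {
    u <- zm[i, ] / sqrt(sum(zm[i, ]^2))
    sum((zm %*% u)^2)
  }))
  expect_gte(var_e + 1e-8, var_single)

  # antisymmetry: flipping all member values flips the eigengene
  me_f <- module_eigengenes(counts_tbl(-m), assign_tbl)
  expect_equal(me_f$blue, -e, tolerance = 1e-8)

  # single-gene module warns
  expect_warning(
    module_eigengenes(
      counts_tbl(m),
      tibble::tibble(gene = c(rownames(m)[1], rownames(m)[2:30]),
        module = c("solo", rep("blue", 29)))
    ),
    "single gene"
  )
})

test_that("module-trait correlation handles exact, null and degenerate traits", {
  d <- study_design()
  traits <- design_traits(d)
  g <- d$genotype_code
  e1 <- (g - mean(g)) / sqrt(sum((g - mean(g))^2))
  # orthogonal-to-trait eigengene in a balanced design
  e2 <- rep(c(1, -1), 8)
  e2 <- (e2 - mean(e2)) / sqrt(sum((e2 - mean(e2))^2))
  me <- tibble::tibble(sample = d$sample_id, m1 = e1, m2 = e2)
  res <- module_trait_cor(me, traits)
  r11 <- res[res$module == "m1" & res$trait == "genotype", ]
  expect_equal(r11$r, 1, tolerance = 1e-12)
  expect_lt(r11$p, 1e-12)
  r21 <- res[res$module == "m2" & res$trait == "genotype", ]
  expect_equal(r21$r, 0, tolerance = 1e-12)
  expect_equal(r21$p, 1, tolerance = 1e-9)
  expect_equal(res$r_squared, res$r^2)

  const <- tibble::tibble(sample = d$sample_id, flat = rep(1, 16))
  expect_warning(rc <- module_trait_cor(me, const), "constant")
  expect_true(all(is.na(rc$r)))

  expect_s3_class(autoplot(res), "ggplot")
})

test_that("edge export respects threshold, ordering and module boundaries", {
  set.seed(13)
  n_s <- 10
  z <- rnorm(n_s)
  m <- rbind(
    t(sapply(1:6, function(i) z + rnorm(n_s, sd = 1e-4))),
    matrix(rnorm(4 * n_s), 4)
  )
  dimnames(m) <- list(sprintf("g%02d", 1:10), paste0("s", 1:n_s))
  tom <- tom_similarity(soft_adjacency(m, beta = 6))
  assign_tbl <- tibble::tibble(
    gene = rownames(m), module = rep(c("turquoise", "grey"), c(6, 4))
  )
  # clique module at threshold ~1: all C(6,2) edges
  edges <- export_edges(tom, assign_tbl, threshold = 0.9)
  expect_equal(nrow(edges), choose(6, 2))
  expect_true(all(edges$source < edges$target))
  expect_true(all(edges$weight >= 0.9))

  # threshold 0 -> all within-module pairs; grey never exports
  all_edges <- export_edges(tom, assign_tbl, threshold = 0)
  expect_equal(nrow(all_edges), choose(6, 2))
  expect_false(any(all_edges$source %in% sprintf("g%02d", 7:10)))

  # threshold 1 on a noisy TOM: typically empty, never an error
  none <- export_edges(tom, assign_tbl, threshold = 1)
  expect_true(all(none$weight == 1))
})

test_that("module-membership permutation test behaves at the boundaries", {
  set.seed(14)
  n_s <- 16
  z <- rnorm(n_s)
  core <- t(sapply(1:10, function(i) 2 * z + rnorm(n_s, sd = 0.2)))
  rest <- t(sapply(1:60, function(i) 1 * z + rnorm(n_s, sd = 1.2)))
  m <- rbind(core, rest)
  dimnames(m) <- list(sprintf("g%02d", 1:70), paste0("s", 1:n_s))
  assign_tbl <- tibble::tibble(gene = rownames(m), module = "turquoise")
  me <- module_eigengenes(counts_tbl(m), assign_tbl)

  # whole module as the set: p = 1 exactly
  res_all <- module_membership_test(
    rownames(m), rownames(m), counts_tbl(m), me$turquoise,
    n_perm = 50, seed = 1
  )
  expect_equal(res_all$p, 1)

  # planted core: very high membership
  res_core <- module_membership_test(
    rownames(m)[1:10], rownames(m), counts_tbl(m), me$turquoise,
    n_perm = 2000, seed = 2
  )
  expect_lte(res_core$p, 0.001)

  # n_perm = 1 resolves to 0.5 or 1 under the plus-one convention
  res1 <- module_membership_test(
    rownames(m)[1:5], rownames(m), counts_tbl(m), me$turquoise,
    n_perm = 1, seed = 3
  )
  expect_true(res1$p %in% c(0.5, 1))

  expect_error(
    module_membership_test("absent", rownames(m), counts_tbl(m), me$turquoise),
    "subset"
  )
})

test_that("the pipeline wrapper is deterministic and exposes broom methods", {
  sim <- simulate_counts(study_design(), small_config(seed = 15))
  norm <- normalize_counts(sim$counts)
  traits <- design_traits(sim$design)
  n1 <- coexpression_network(norm, traits, top_k = 300, beta = 10)
  n2 <- coexpression_network(norm, traits, top_k = 300, beta = 10)
  expect_identical(n1$modules, n2$modules)
  expect_identical(n1$edges, n2$edges)

  td <- tidy(n1)
  expect_true(all(c("gene", "module", "kme") %in% names(td)))
  gl <- glance(n1)
  expect_equal(gl$beta, 10)
  expect_output(print(n1), "Co-expression network")
})
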