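test_that("mean connectivity decreases with the soft power and noise is not
           scale-free at beta 1", {
  sim <- generate_dataset(generator_config(n_genes = 100,
                                           samples_per_stage = c(10, 10, 10),
                                           n_dynamic_de = 0,
                                           n_rewired_pairs = 0,
                                           n_modules = 0,
                                           trait_module_index = 0,
                                           seed = 3))
  scan <- suppressWarnings(soft_threshold_scan(sim$dataset, powers = 1:10))
  expect_true(all(diff(scan$mean_connectivity) <= 1e-12))
  expect_lt(scan$fit_r2[1], 0.3)
})

test_that("modular data reach a high scale-free fit at some power", {
  sim <- generate_dataset(generator_config(n_genes = 300,
                                           samples_per_stage = c(20, 20, 20),
                                           n_dynamic_de = 0,
                                           n_rewired_pairs = 0,
                                           n_modules = 4, module_size = 50,
                                           seed = 7))
  scan <- suppressWarnings(soft_threshold_scan(sim$dataset))
  expect_gte(max(scan$fit_r2, na.rm = TRUE), 0.8)
  expect_true(attr(scan, "chosen_beta") %in% scan$power)
  d0 <- expression_dataset(matrix(1, 25, 6,
                                  dimnames = list(sprintf("g%d", 1:25),
                                                  sprintf("s%d", 1:6))))
  expect_error(soft_threshold_scan(d0), "constant")
})

test_that("TOM matches its closed forms and the triple-loop oracle", {
  # two isolated genes
  a0 <- matrix(0, 2, 2, dimnames = list(c("x", "y"), c("x", "y")))
  t0 <- tom_matrix(a0)
  expect_equal(t0["x", "y"], 0)
  # complete 3-gene unit adjacency
  a1 <- matrix(1, 3, 3) - diag(3)
  dimnames(a1) <- list(letters[1:3], letters[1:3])
  t1 <- tom_matrix(a1)
  expect_equal(t1["a", "b"], 1)
  # random adjacency vs triple loop, and range invariant
  set.seed(6)
  r <- matrix(runif(100), 10)
  a <- (r + t(r)) / 2
  diag(a) <- 0
  dimnames(a) <- list(sprintf("g%d", 1:10), sprintf("g%d", 1:10))
  tom <- tom_matrix(a)
  expect_equal(tom, tom_oracle(a), tolerance = 1e-12)
  expect_true(all(tom >= 0 & tom <= 1 + 1e-12))
  expect_error(tom_matrix(a * 2), "\\[0, 1\\]")
})

test_that("module detection separates clean blocks and recovers planted
           modules", {
  # two perfect blocks of 40
  d2 <- 1 - diag(80)
  d2[1:40, 1:40] <- 0
  d2[41:80, 41:80] <- 0
  dimnames(d2) <- list(sprintf("g%02d", 1:80), sprintf("g%02d", 1:80))
  asg <- detect_modules(d2, min_module_size = 30)
  expect_equal(length(asg$sizes), 2L)
  expect_equal(unname(asg$sizes), c(40L, 40L))
  expect_equal(names(asg$sizes)[1], "turquoise")
  # all-identical genes collapse to one module
  d1 <- matrix(0, 60, 60, dimnames = list(sprintf("g%02d", 1:60),
                                          sprintf("g%02d", 1:60)))
  expect_equal(length(detect_modules(d1)$sizes), 1L)

  # planted latent-factor modules: ARI >= 0.8 against the truth
  sim <- generate_dataset(generator_config(n_genes = 200,
                                           samples_per_stage = c(20, 20, 20),
                                           n_dynamic_de = 0,
                                           n_rewired_pairs = 0,
                                           n_modules = 4, module_size = 50,
                                           noise_sd = 0.5, seed = 13))
  adj <- adjacency_matrix(sim$dataset, 6)
  asg2 <- detect_modules(1 - tom_matrix(adj), min_module_size = 30,
                         exprs = sim$dataset)
  sc <- score_recovery(sim$truth, found_modules = asg2)
  expect_gte(sc$value[sc$metric == "module_ari"], 0.8)

  # labels are invariant under gene permutation (relabel equivalence)
  set.seed(99)
  perm <- sample(nrow(adj))
  diss_p <- (1 - tom_matrix(adj))[perm, perm]
  asg3 <- detect_modules(diss_p, min_module_size = 30)
  asg2b <- detect_modules(1 - tom_matrix(adj), min_module_size = 30)
  genes <- rownames(adj)
  expect_equal(mclust::adjustedRandIndex(asg2b$module_of[genes],
                                         asg3$module_of[genes]), 1)
})

test_that("eigengenes equal the SVD first component and represent members", {
  sim <- generate_dataset(generator_config(n_genes = 60,
                                           samples_per_stage = c(10, 10, 10),
                                           n_dynamic_de = 0,
                                           n_rewired_pairs = 0,
                                           n_modules = 1, module_size = 30,
                                           seed = 17))
  d <- sim$dataset
  members <- names(sim$truth$module_of)[sim$truth$module_of == "M1"]
  me <- module_eigengene(d, members)
  expect_equal(sum(me^2), 1, tolerance = 1e-9)
  # oracle: svd of the standardized submatrix, up to sign
  z <- t(scale(t(d$values[members, ])))
  v <- svd(z)$v[, 1]
  expect_equal(abs(unname(me)), abs(v), tolerance = 1e-9)
  expect_gt(mean(cor(t(d$values[members, ]), me)), 0)

  # single-gene module: eigengene is that gene's z-scores up to norm
  g1 <- module_eigengene(d, members[1])
  zz <- as.numeric(scale(d$values[members[1], ]))
  expect_equal(unname(g1), zz / sqrt(sum(zz^2)), tolerance = 1e-9)
  # two identical genes
  d2 <- d
  d2$values[2, ] <- d2$values[1, ]
  g2 <- module_eigengene(d2, rownames(d2$values)[1:2])
  expect_equal(abs(cor(g2, d2$values[1, ])), 1, tolerance = 1e-9)

  # eigengene explains at least an average member's variance share
  var_share <- function(v, x) mean(cor(t(x), v)^2)
  expect_gte(var_share(me, d$values[members, ]),
             mean(apply(d$values[members, ], 1, function(g)
               var_share(g, d$values[members, ]))) - 1e-9)
})

test_that("module-trait correlation: exact match, t-distribution p, and
           null uniformity", {
  sim <- generate_dataset(generator_config(n_genes = 120,
                                           samples_per_stage = c(19, 19, 18),
                                           n_dynamic_de = 0,
                                           n_rewired_pairs = 0,
                                           n_modules = 2, module_size = 40,
                                           seed = 23))
  d <- sim$dataset
  adj <- adjacency_matrix(d, 6)
  asg <- detect_modules(1 - tom_matrix(adj), exprs = d)
  me <- module_eigengenes(d, asg)

  # trait equal to an eigengene: r = 1, p = 0
  tr <- data.frame(self = me[, 1], row.names = rownames(me))
  mt <- module_trait_correlation(me, tr)
  expect_equal(unname(mt$r[1, 1]), 1, tolerance = 1e-12)
  expect_equal(unname(mt$p[1, 1]), 0)

  # r = 0.55 at n = 56 is in the 1e-5 order (t-distribution oracle)
  r <- 0.55; n <- 56
  p <- 2 * pt(-abs(r * sqrt(n - 2) / sqrt(1 - r^2)), n - 2)
  expect_lt(p, 1e-4); expect_gt(p, 1e-7)

  # random traits give uniform p-values
  set.seed(71)
  many <- as.data.frame(matrix(rnorm(56 * 400), 56))
  rownames(many) <- rownames(me)
  mtn <- module_trait_correlation(me[, 1, drop = FALSE], many)
  expect_gt(suppressWarnings(ks.test(as.numeric(mtn$p), "punif"))$p.value,
            0.01)

  # planted trait tracks its module's factor: top |r| across modules
  mt2 <- module_trait_correlation(me, d$traits)
  planted <- names(sim$truth$module_of)[sim$truth$module_of ==
                                          sim$truth$trait$module]
  top_mod <- rownames(mt2$r)[which.max(abs(mt2$r[, "module_trait"]))]
  top_genes <- names(asg$module_of)[asg$module_of == sub("^ME", "", top_mod)]
  expect_gt(length(intersect(top_genes, planted)) / length(planted), 0.8)
})

test_that("gene significance and module membership behave as planted", {
  sim <- generate_dataset(generator_config(n_genes = 120,
                                           samples_per_stage = c(15, 15, 15),
                                           n_dynamic_de = 0,
                                           n_rewired_pairs = 0,
                                           n_modules = 2, module_size = 40,
                                           noise_sd = 0.3, seed = 29))
  d <- sim$dataset
  adj <- adjacency_matrix(d, 6)
  asg <- detect_modules(1 - tom_matrix(adj), exprs = d)
  gsmm <- gene_significance_and_mm(d, d$traits, asg)
  expect_true(all(gsmm$gs >= 0 & gsmm$gs <= 1 + 1e-12))
  expect_true(all(abs(gsmm$mm) <= 1 + 1e-12))
  # members of the trait-linked planted module carry higher GS
  members <- names(sim$truth$module_of)[sim$truth$module_of ==
                                          sim$truth$trait$module]
  others <- setdiff(rownames(d$values), members)
  expect_gt(median(gsmm$gs[members, "module_trait"]),
            median(gsmm$gs[others, "module_trait"]))
  # a gene perfectly aligned with its module eigengene has |MM| ~ 1
  me <- module_eigengenes(d, asg)
  d$values[1, ] <- me[, 1]
  gs2 <- gene_significance_and_mm(d, d$traits, asg)
  # the eigengene is recomputed from the modified matrix, so agreement is
  # near- but not exactly perfect
  expect_gt(abs(unname(gs2$mm[1, 1])), 0.999)
})

test_that("intramodular connectivity sums within-module adjacency", {
  a <- matrix(c(0, 0.6, 0.6, 0), 2,
              dimnames = list(c("g1", "g2"), c("g1", "g2")))
  asg <- structure(list(module_of = c(g1 = "blue", g2 = "blue"),
                        sizes = c(blue = 2L)),
                   class = "ModuleAssignment")
  k <- intramodular_connectivity(a, asg)
  expect_equal(unname(k), c(0.6, 0.6))

  set.seed(37)
  n <- 30
  r <- matrix(runif(n * n), n)
  a2 <- (r + t(r)) / 2; diag(a2) <- 0
  dimnames(a2) <- list(sprintf("g%02d", 1:n), sprintf("g%02d", 1:n))
  mod <- setNames(rep(c("blue", "brown", "grey"), each = 10), rownames(a2))
  asg2 <- structure(list(module_of = mod,
                         sizes = c(blue = 10L, brown = 10L)),
                    class = "ModuleAssignment")
  k2 <- intramodular_connectivity(a2, asg2)
  for (g in c("g01", "g15")) {
    mates <- setdiff(names(mod)[mod == mod[g]], g)
    expect_equal(unname(k2[g]), sum(a2[g, mates]), tolerance = 1e-12)
  }
  expect_true(all(is.na(k2[mod == "grey"])))
  hubs <- module_hub_table(a2, asg2, top_n = 3)
  expect_equal(nrow(hubs), 6L)
  expect_true(all(diff(hubs$k_im[hubs$module == "blue"]) <= 0))
})
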