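# Co-expression network construction, TOM, module detection, eigengenes
# and MM/GS screening, checked against hand calculations and
# brute-force oracles.

test_that("similarity is |Pearson correlation| and matches the sum formula", {
  x <- c(1, 2, 3, 4)
  y <- c(1, 2, 2, 4)
  expr <- rbind(g1 = x, g2 = y, g3 = -2 * x)
  colnames(expr) <- paste0("s", 1:4)
  s <- similarity(expr)
  expect_equal(unname(diag(s)), rep(1, 3))
  expect_equal(s["g1", "g3"], 1)  # perfect anticorrelation, absolute value
  # direct evaluation of the covariance-over-sd-products sum formula
  num <- sum((x - mean(x)) * (y - mean(y)))
  den <- sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(s["g1", "g2"], abs(num / den), tolerance = 1e-12)
})

test_that("similarity rejects tiny sample counts and flat genes by name", {
  expr <- rbind(g1 = c(1, 2, 3), flatgene = c(5, 5, 5))
  colnames(expr) <- paste0("s", 1:3)
  expect_error(similarity(expr), "flatgene")
  expr2 <- rbind(g1 = c(1, 2), g2 = c(2, 1))
  colnames(expr2) <- paste0("s", 1:2)
  expect_error(similarity(expr2), "3 samples")
})

test_that("adjacency is the elementwise power with zero diagonal", {
  set.seed(1)
  s <- abs(stats::cor(matrix(rnorm(200), 20, 10)))
  a1 <- adjacency(s, 1)
  expect_equal(a1[upper.tri(a1)], s[upper.tri(s)])
  expect_true(all(diag(a1) == 0))
  expect_equal(adjacency(matrix(0.5, 2, 2), 4)[1, 2], 0.0625)
  a6 <- adjacency(s, 6)
  oracle <- s^6; diag(oracle) <- 0
  expect_lt(max(abs(a6 - oracle)), 1e-15)
})

test_that("TOM matches the hand-worked 3-gene case and the loop oracle", {
  a <- matrix(0.5, 3, 3); diag(a) <- 0
  tom <- topological_overlap(a)
  expect_equal(unname(tom[1, 2]), 0.5, tolerance = 1e-15)  # 0.75 / 1.5
  expect_equal(unname(diag(tom)), rep(1, 3))

  zero <- matrix(0, 4, 4)
  tz <- topological_overlap(zero)
  expect_true(all(tz[upper.tri(tz)] == 0))

  set.seed(2)
  a20 <- random_adjacency(20)
  expect_lt(max(abs(topological_overlap(a20) - tom_oracle(a20))), 1e-10)

  asym <- a20; asym[1, 2] <- asym[1, 2] + 0.01
  expect_error(topological_overlap(asym), "symmetric")
})

test_that("S, A and TOM stay within [0, 1] on random valid inputs", {
  set.seed(3)
  for (i in 1:10) {
    expr <- matrix(rnorm(30 * 12), 30, 12,
                   dimnames = list(paste0("g", 1:30), paste0("s", 1:12)))
    s <- similarity(expr)
    a <- adjacency(s, sample(1:8, 1))
    tom <- topological_overlap(a)
    for (m in list(s, a, tom)) {
      expect_true(all(m >= -1e-12 & m <= 1 + 1e-12))
    }
  }
})

test_that("dissimilarity is the exact complement of TOM", {
  set.seed(4)
  tom <- topological_overlap(random_adjacency(10))
  d <- dissimilarity(tom)
  off <- upper.tri(tom) | lower.tri(tom)
  expect_lt(max(abs(d[off] + tom[off] - 1)), 1e-14)
  expect_true(all(diag(d) == 0))
  expect_equal(dissimilarity(matrix(1, 2, 2))[1, 2], 0)
  expect_equal(dissimilarity(matrix(0, 2, 2))[1, 2], 1)
})

test_that("scale-free fit index is high for exact power-law degrees", {
  set.seed(5)
  # degrees drawn from p(k) ~ k^-2.5
  k <- (1:2000)^(-1 / 1.5)
  k <- sample(1:50, 3000, replace = TRUE, prob = (1:50)^(-2.5))
  expect_gte(coexhub:::scale_free_fit(k), 0.9)
})

test_that("soft-threshold pick honours the cut and mean-k monotonicity", {
  cfg <- simulation_config(n_genes = 120, n_samples = 60,
                           module_sizes = c(30, 30), seed = 6)
  sim <- generate_modular_expression(cfg)
  pick <- pick_soft_threshold(sim$expr, candidates = 1:10)
  expect_true(all(diff(pick$fit_table$mean_k) < 0))
  pick0 <- pick_soft_threshold(sim$expr, candidates = 3:10, r2_cut = 0)
  expect_equal(pick0$beta, 3)
})

test_that("tree cutting separates clean blocks and enforces the size floor", {
  d <- matrix(1, 40, 40)
  d[1:20, 1:20] <- 0
  d[21:40, 21:40] <- 0
  diag(d) <- 0
  rownames(d) <- colnames(d) <- paste0("g", 1:40)
  labels <- cluster_cut(d, min_module_size = 10, reattach = FALSE)
  expect_equal(length(unique(labels)), 2)
  expect_equal(length(unique(labels[1:20])), 1)
  expect_equal(length(unique(labels[21:40])), 1)

  d5 <- matrix(1, 25, 25)
  d5[1:5, 1:5] <- 0
  diag(d5) <- 0
  # add mild noise so background genes do not form spurious blocks
  set.seed(7)
  noise <- matrix(runif(625, 0, 0.01), 25)
  d5 <- pmin(d5 + (noise + t(noise)) / 2, 1)
  diag(d5) <- 0
  labs5 <- cluster_cut(d5, min_module_size = 10, reattach = FALSE)
  expect_true(all(labs5 == 0))

  expect_error(cluster_cut(d, min_module_size = 1), "min_module_size")
})

test_that("module eigengene is the shared profile for a rank-1 module", {
  set.seed(8)
  profile <- rnorm(20)
  expr <- do.call(rbind, lapply(1:5, function(i) 2 * profile + i))
  rownames(expr) <- paste0("g", 1:5)
  colnames(expr) <- paste0("s", 1:20)
  me <- module_eigengene(expr, rep(1L, 5))
  expect_equal(abs(stats::cor(me[1, ], profile)), 1, tolerance = 1e-10)
  expect_gt(stats::cor(me[1, ], profile), 0)       # sign convention
  expect_equal(stats::sd(me[1, ]), 1, tolerance = 1e-10)
  # negating every member leaves module membership unchanged
  me_neg <- module_eigengene(-expr, rep(1L, 5))
  expect_equal(abs(stats::cor(expr[1, ], me_neg[1, ])),
               abs(stats::cor(expr[1, ], me[1, ])), tolerance = 1e-10)
  expect_error(module_eigengene(expr, c(1L, 2L, 2L, 2L, 2L)), "fewer than 2")
})

test_that("eigengenes recover planted latent factors", {
  cfg <- simulation_config(n_genes = 200, n_samples = 100,
                           module_sizes = c(40, 40), seed = 9)
  sim <- generate_modular_expression(cfg)
  me <- module_eigengene(sim$expr, sim$truth$module)
  for (m in 1:2) {
    expect_gte(abs(stats::cor(me[m, ], sim$truth$factors[m, ])), 0.9)
  }
})

test_that("module merging rejoins an artificially split module", {
  cfg <- simulation_config(n_genes = 120, n_samples = 80,
                           module_sizes = c(40, 30), seed = 10)
  sim <- generate_modular_expression(cfg)
  labels <- sim$truth$module
  split <- labels
  split[which(labels == 1)[1:20]] <- 3L    # split module 1 in two
  merged <- merge_modules(sim$expr, split, cut_height = 0.25)
  expect_equal(length(unique(merged[merged != 0])), 2)
  expect_equal(length(unique(merged[labels == 1])), 1)
  # orthogonal modules stay apart
  merged2 <- merge_modules(sim$expr, labels, cut_height = 0.25)
  expect_equal(length(unique(merged2[merged2 != 0])), 2)
})

test_that("module-trait correlation and its t-test p-values are correct", {
  cfg <- simulation_config(n_genes = 80, n_samples = 50,
                           module_sizes = c(20, 20), seed = 11)
  sim <- generate_modular_expression(cfg)
  me <- module_eigengene(sim$expr, sim$truth$module)
  traits <- data.frame(sample = colnames(me), trait = me["module_1", ])
  mt <- module_trait(me, traits)
  self <- mt[mt$module == "module_1", ]
  expect_equal(self$r, 1, tolerance = 1e-10)
  expect_lt(self$p, 1e-12)
  # r = 0.3 at n = 372 is deep in significance
  expect_lt(coexhub:::cor_pvalue(0.3, 372), 1e-7)
  # p-value matches cor.test
  r <- stats::cor(me["module_2", ], traits$trait)
  ct <- stats::cor.test(me["module_2", ], traits$trait)
  expect_equal(coexhub:::cor_pvalue(r, 50), ct$p.value, tolerance = 1e-10)
  expect_error(module_trait(me, data.frame(sample = "nope", trait = 1)),
               "mismatch")
})

test_that("module-trait p-values are calibrated under the null", {
  set.seed(12)
  me <- matrix(rnorm(50), 1, 50,
               dimnames = list("module_1", paste0("s", 1:50)))
  hits <- vapply(1:1000, function(i) {
    tr <- data.frame(sample = colnames(me), trait = rnorm(50))
    module_trait(me, tr)$p < 0.05
  }, logical(1))
  expect_gt(mean(hits), 0.03)
  expect_lt(mean(hits), 0.07)
})

test_that("MM and GS behave at the fixed points and separate planted genes", {
  cfg <- simulation_config(n_genes = 150, n_samples = 100,
                           module_sizes = c(40, 30), trait_cor = 0.7,
                           seed = 13)
  sim <- generate_modular_expression(cfg)
  me <- module_eigengene(sim$expr, sim$truth$module)
  scores <- gene_scores(sim$expr, me, sim$truth$module, sim$truth$trait)
  # a pseudo-gene equal to its eigengene has MM = 1
  expr2 <- rbind(sim$expr[sim$truth$module == 1, ], me1 = me["module_1", ])
  labels2 <- c(rep(1L, 40), 1L)
  me2 <- module_eigengene(expr2, labels2)
  s2 <- gene_scores(expr2, me2, labels2, sim$truth$trait)
  expect_gte(abs(s2$mm[s2$gene == "me1"]), 0.99)
  # trait-linked members out-score everyone else on |GS|
  in_mod <- sim$truth$module == sim$truth$trait_module
  expect_gt(mean(abs(scores$gs[in_mod])), mean(abs(scores$gs[!in_mod])))
  expect_true(all(is.na(scores$mm[sim$truth$module == 0])))
})

test_that("key-gene screening is strict, restrictable and monotone", {
  tab <- data.frame(
    gene = paste0("g", 1:10),
    module = c(rep(1L, 5), rep(2L, 5)),
    mm = c(0.8, 0.95, 0.85, 0.5, 0.99, 0.9, 0.81, 0.2, 0.85, 0.7),
    gs = c(0.5, 0.25, 0.1, 0.9, 0.3, 0.21, 0.15, 0.9, -0.4, 0.3)
  )
  got <- screen_key_genes(tab, 0.8, 0.2)
  oracle <- tab$gene[abs(tab$mm) > 0.8 & abs(tab$gs) > 0.2]
  expect_setequal(got, oracle)
  expect_false("g1" %in% got)          # MM exactly 0.8 excluded
  expect_true("g9" %in% got)           # negative GS counts in absolute value
  expect_setequal(screen_key_genes(tab, 0.8, 0.2, module = 1),
                  intersect(oracle, tab$gene[tab$module == 1]))
  for (th in c(0.5, 0.7, 0.9)) {
    expect_true(all(screen_key_genes(tab, th + 0.05, 0.2) %in%
                      screen_key_genes(tab, th, 0.2)))
    expect_true(all(screen_key_genes(tab, 0.5, th) %in%
                      screen_key_genes(tab, 0.5, th - 0.1)))
  }
})

test_that("gene-order permutation permutes labels equivariantly", {
  cfg <- simulation_config(n_genes = 150, n_samples = 80,
                           module_sizes = c(40, 30), seed = 14)
  sim <- generate_modular_expression(cfg)
  res1 <- wgcna_modules(sim$expr, sim$traits, beta = 6)
  set.seed(14)
  perm <- sample(nrow(sim$expr))
  res2 <- wgcna_modules(sim$expr[perm, ], sim$traits, beta = 6)
  expect_gte(mclust::adjustedRandIndex(res1$labels[perm], res2$labels), 0.999)
})

test_that("outlier samples are flagged by low mean inter-sample correlation", {
  # samples share a strong per-gene baseline profile; one sample is
  # replaced by unrelated noise and should be flagged
  set.seed(15)
  baseline <- rnorm(200, sd = 3)
  expr <- vapply(1:30, function(s) baseline + rnorm(200, sd = 0.5),
                 numeric(200))
  rownames(expr) <- paste0("g", 1:200)
  colnames(expr) <- sprintf("s%02d", 1:30)
  expr[, "s01"] <- rnorm(200, sd = 3)
  flagged <- flag_outlier_samples(expr, z_cut = -2.5)
  expect_identical(flagged, "s01")
  expect_length(flag_outlier_samples(expr[, -1], z_cut = -2.5), 0)
})
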