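# Generators: determinism, planted-structure calibration, and
# round-trips through the plain-text writers/readers.

test_that("expression generator is deterministic and validates input", {
  cfg <- simulation_config(n_genes = 50, n_samples = 30,
                           module_sizes = c(10, 10), seed = 7)
  a <- generate_modular_expression(cfg)
  b <- generate_modular_expression(cfg)
  expect_identical(a, b)
  expect_error(simulation_config(n_genes = 10, module_sizes = c(8, 8)),
               "exceeds")
  expect_error(simulation_config(within_module_cor = 1), "within_module_cor")
  expect_error(simulation_config(trait_module = 9), "trait_module")
})

test_that("zero within-module correlation gives independent genes", {
  cfg <- simulation_config(n_genes = 40, n_samples = 2000,
                           module_sizes = c(40), within_module_cor = 0,
                           seed = 3)
  sim <- generate_modular_expression(cfg)
  cc <- stats::cor(t(sim$expr))
  expect_lt(mean(abs(cc[upper.tri(cc)])), 0.05)
})

test_that("planted module and trait correlations are calibrated", {
  within <- trait <- numeric(20)
  for (s in seq_len(20)) {
    cfg <- simulation_config(n_genes = 500, n_samples = 100,
                             module_sizes = c(60, 50, 40, 30),
                             within_module_cor = 0.64, trait_cor = 0.7,
                             seed = s)
    sim <- generate_modular_expression(cfg)
    cors <- unlist(lapply(1:4, function(m) {
      cc <- stats::cor(t(sim$expr[sim$truth$module == m, ]))
      cc[upper.tri(cc)]
    }))
    within[s] <- mean(cors)
    trait[s] <- stats::cor(sim$truth$trait,
                           sim$truth$factors[cfg$trait_module, ])
  }
  expect_gte(mean(within), 0.54)
  expect_lte(mean(within), 0.74)
  expect_lt(abs(mean(trait) - 0.7), 0.1)
})

test_that("multi-study generator enforces group sizes and recovers the effect", {
  expect_error(generate_multi_study(2, 2, 10), "at least 3")
  expect_error(generate_multi_study(1, 10, 10), "k_studies")
  big <- generate_multi_study(3, 5000, 5000, true_smd = 0.8, tau = 0,
                              seed = 4)
  g <- study_smd_all(big)$g
  expect_true(all(abs(g - 0.8) < 0.1))
  null_pooled <- vapply(1:40, function(s) {
    st <- generate_multi_study(6, 30, 30, true_smd = 0, tau = 0, seed = s)
    pool_fixed(study_smd_all(st))$pooled
  }, numeric(1))
  expect_lt(abs(mean(null_pooled)), 0.05)
})

test_that("between-study heterogeneity inflates Q and I2 as expected", {
  sim_i2 <- function(tau) {
    vapply(1:100, function(s) {
      st <- generate_multi_study(
        8, c(78, 9, 9, 3, 8, 4, 3, 372), c(88, 10, 7, 3, 10, 8, 3, 50),
        true_smd = 0.3, tau = tau, seed = s
      )
      r <- pool_random(study_smd_all(st))
      c(r$Q, r$I2)
    }, numeric(2))
  }
  het <- sim_i2(0.4)
  hom <- sim_i2(0)
  # with tau = 0.4 high I2 is common; with tau = 0 it is rare
  expect_gte(mean(het[2, ] > 50), 0.4)
  expect_lte(mean(hom[2, ] > 50), 0.15)
  expect_gt(mean(het[2, ]), mean(hom[2, ]) + 20)
  # mean Q tracks its DerSimonian-Laird expectation df + tau^2 * C
  st <- generate_multi_study(
    8, c(78, 9, 9, 3, 8, 4, 3, 372), c(88, 10, 7, 3, 10, 8, 3, 50),
    true_smd = 0.3, tau = 0, seed = 1
  )
  w <- 1 / study_smd_all(st)$var_g
  expect_lt(abs(mean(het[1, ]) - (7 + 0.16 * (sum(w) - sum(w^2) / sum(w)))) /
              mean(het[1, ]), 0.25)
})

test_that("interaction network generator hits the target mean degree", {
  expect_error(generate_interaction_network(character(0), 2), "nonempty")
  full <- generate_interaction_network(letters[1:4], mean_degree = 3,
                                       seed = 1)
  expect_equal(nrow(full), 6)
  expect_true(all(node_degrees(full) == 3))
  hi <- generate_interaction_network(letters[1:10], 4,
                                     score_range = c(0.9, 1), seed = 2)
  expect_equal(nrow(filter_edges(hi, 0.4)), nrow(hi))
  md <- vapply(1:20, function(s) {
    e <- generate_interaction_network(sprintf("g%03d", 1:100), 8, seed = s)
    mean(node_degrees(e))
  }, numeric(1))
  expect_gte(mean(md), 7)
  expect_lte(mean(md), 9)
})

test_that("survival generator respects censoring and hazard ratio", {
  s0 <- generate_survival(100, rep(0:1, 50), hazard_ratio = 2,
                          censor_rate = 0, seed = 1)
  expect_true(all(s0$event == 1))
  cens <- vapply(1:20, function(s) {
    mean(1 - generate_survival(500, rep(0:1, 250), hazard_ratio = 2,
                               censor_rate = 0.3, seed = s)$event)
  }, numeric(1))
  expect_lt(abs(mean(cens) - 0.3), 0.05)
  hr <- vapply(1:100, function(s) {
    logrank(generate_survival(400, rep(0:1, each = 200), hazard_ratio = 2,
                              censor_rate = 0.2, seed = s))$hazard_ratio
  }, numeric(1))
  expect_gte(mean(hr >= 1.6 & hr <= 2.5), 0.9)
})

test_that("gene-set generator plants sets verbatim", {
  bg <- sprintf("g%03d", 1:100)
  expect_length(generate_gene_sets(bg, 0, seed = 1), 0)
  planted <- bg[1:20]
  sets <- generate_gene_sets(bg, 10, planted_set = planted, seed = 1)
  expect_identical(sets$planted, planted)
  expect_error(generate_gene_sets(bg, 2, planted_set = c("nope")),
               "subset")
})

test_that("all generated tables round-trip losslessly through TSV/GMT", {
  dir <- withr::local_tempdir()
  cfg <- simulation_config(n_genes = 30, n_samples = 10,
                           module_sizes = c(10), seed = 5)
  sim <- generate_modular_expression(cfg)
  p <- file.path(dir, "expr.tsv")
  write_expression_tsv(sim$expr, p)
  expect_equal(read_expression_tsv(p), sim$expr)
  p <- file.path(dir, "traits.tsv")
  write_trait_tsv(sim$traits, p)
  expect_equal(read_trait_tsv(p), sim$traits)
  edges <- generate_interaction_network(rownames(sim$expr), 3, seed = 5)
  p <- file.path(dir, "edges.tsv")
  write_edges_tsv(edges, p)
  expect_equal(read_edges_tsv(p), edges)
  surv <- generate_survival(20, rep(0:1, 10), 1.5, 0.2, seed = 5)
  p <- file.path(dir, "surv.tsv")
  write_survival_tsv(surv, p)
  expect_equal(read_survival_tsv(p), surv)
  sets <- generate_gene_sets(rownames(sim$expr), 5,
                             set_size_range = c(3, 8), seed = 5)
  p <- file.path(dir, "sets.gmt")
  write_gmt(sets, p)
  expect_identical(read_gmt(p), sets)
  studies <- generate_multi_study(3, 5, 6, 0.4, 0.1, seed = 5)
  p <- file.path(dir, "studies.tsv")
  write_studies_tsv(studies, p)
  back <- read_studies_tsv(p)
  expect_equal(back, lapply(studies, function(s) {
    list(study_id = s$study_id, case = s$case, control = s$control)
  }), tolerance = 1e-10)
})
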