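# Synthetic-data generators with planted ground truth. Every input the
# pipeline consumes can be generated here, so all downstream stages are
# testable without any external download.

#' Simulation configuration for modular expression data
#'
#' Describes a genes x samples expression matrix containing planted
#' co-expression modules built from a latent-factor model: each gene in
#' module m is `sqrt(r) * factor_m + sqrt(1 - r) * noise`, which gives an
#' expected pairwise within-module correlation of exactly `r` when
#' `noise_sd = 1`. Genes not assigned to any module are pure noise
#' (label 0, the "grey" convention). One module drives a continuous
#' sample trait.
#'
#' @param n_genes Total number of genes.
#' @param n_samples Number of samples.
#' @param module_sizes Integer vector, genes per planted module; must sum
#'   to at most `n_genes`. Remaining genes are unassigned noise.
#' @param within_module_cor Target within-module correlation in `[0, 1)`.
#'   Either a single value for all modules or one value per module.
#' @param trait_module Index (1-based) of the module whose latent factor
#'   drives the trait.
#' @param trait_cor Target correlation in `[0, 1)` between the trait and
#'   the trait module's latent factor.
#' @param noise_sd Standard deviation of the per-gene noise term.
#' @param seed Integer seed; a fixed seed gives byte-identical output.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_genes = 500L, n_samples = 150L,
                              module_sizes = c(60L, 50L, 40L, 30L),
                              within_module_cor = 0.64,
                              trait_module = 1L, trait_cor = 0.7,
                              noise_sd = 1, seed = 1L) {
  n_genes <- check_count(n_genes, "n_genes", min = 1L)
  n_samples <- check_count(n_samples, "n_samples", min = 2L)
  module_sizes <- vapply(module_sizes, check_count, integer(1),
                         name = "module_sizes", min = 2L)
  if (sum(module_sizes) > n_genes) {
    stop_input("sum(module_sizes) exceeds n_genes")
  }
  k <- length(module_sizes)
  if (!length(within_module_cor) %in% c(1L, k)) {
    stop_input("`within_module_cor` must have length 1 or one value per module")
  }
  within_module_cor <- vapply(seq_along(within_module_cor), function(i) {
    check_fraction(within_module_cor[i], "within_module_cor", hi_open = TRUE)
  }, numeric(1))
  if (length(within_module_cor) == 1L) {
    within_module_cor <- rep(within_module_cor, k)
  }
  trait_module <- check_count(trait_module, "trait_module", min = 1L)
  if (k > 0 && trait_module > k) stop_input("`trait_module` exceeds module count")
  trait_cor <- check_fraction(trait_cor, "trait_cor", hi_open = TRUE)
  if (!is.numeric(noise_sd) || noise_sd <= 0) {
    stop_input("`noise_sd` must be positive")
  }
  structure(list(
    n_genes = n_genes, n_samples = n_samples, module_sizes = module_sizes,
    within_module_cor = within_module_cor, trait_module = trait_module,
    trait_cor = trait_cor, noise_sd = noise_sd, seed = check_seed(seed)
  ), class = "simulation_config")
}

#' Generate an expression matrix with planted co-expression modules
#'
#' @param config A [simulation_config()].
#' @return List with elements:
#'   \describe{
#'     \item{expr}{genes x samples numeric matrix (`g1..gN` x `s1..sM`).}
#'     \item{truth}{planted ground truth: `module` (integer label per
#'       gene, 0 = unassigned), `factors` (modules x samples latent factor
#'       matrix), `trait` (sample-length numeric vector).}
#'     \item{traits}{data frame (`sample`, `trait`) ready for
#'       [write_trait_tsv()].}
#'   }
#' @export
generate_modular_expression <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(derive_seed(config$seed, "expression"))
  n_g <- config$n_genes
  n_s <- config$n_samples
  sizes <- config$module_sizes
  k <- length(sizes)

  labels <- integer(n_g)
  if (k > 0) labels[seq_len(sum(sizes))] <- rep(seq_len(k), sizes)

  factors <- matrix(stats::rnorm(max(k, 1) * n_s), nrow = max(k, 1))
  expr <- matrix(0, nrow = n_g, ncol = n_s)
  for (g in seq_len(n_g)) {
    m <- labels[g]
    eps <- stats::rnorm(n_s, sd = config$noise_sd)
    if (m == 0L) {
      expr[g, ] <- eps
    } else {
      r <- config$within_module_cor[m]
      expr[g, ] <- sqrt(r) * factors[m, ] + sqrt(1 - r) * eps
    }
  }
  rownames(expr) <- sprintf("g%04d", seq_len(n_g))
  colnames(expr) <- sprintf("s%04d", seq_len(n_s))

  tm <- min(config$trait_module, max(k, 1L))
  trait <- config$trait_cor * factors[tm, ] +
    sqrt(1 - config$trait_cor^2) * stats::rnorm(n_s)

  rownames(factors) <- if (k > 0) sprintf("module_%d", seq_len(k)) else "module_1"
  colnames(factors) <- colnames(expr)

  list(
    expr = expr,
    truth = list(module = stats::setNames(labels, rownames(expr)),
                 factors = factors, trait = trait,
                 trait_module = tm),
    traits = data.frame(sample = colnames(expr), trait = trait,
                        stringsAsFactors = FALSE)
  )
}

#' Generate independent two-group studies sharing a common effect
#'
#' Study `i` draws its own standardized effect `delta_i ~ N(true_smd,
#' tau^2)`, then per-sample values `N(0, 1)` for controls and
#' `N(delta_i, 1)` for cases — the classical random-effects data model.
#'
#' @param k_studies Number of studies (>= 2).
#' @param n_cases,n_controls Integer vectors of group sizes (recycled to
#'   `k_studies`); every group must have at least 3 samples.
#' @param true_smd Common underlying standardized mean difference.
#' @param tau Between-study heterogeneity SD (>= 0).
#' @param seed Integer seed.
#' @return List of study tables, each `list(study_id, case, control)`.
#' @export
generate_multi_study <- function(k_studies, n_cases, n_controls,
                                 true_smd = 0, tau = 0, seed = 1L) {
  k_studies <- check_count(k_studies, "k_studies", min = 2L)
  n_cases <- rep_len(as.integer(n_cases), k_studies)
  n_controls <- rep_len(as.integer(n_controls), k_studies)
  if (any(n_cases < 3L) || any(n_controls < 3L)) {
    stop_input("every study group must have at least 3 samples")
  }
  if (!is.numeric(tau) || tau < 0) stop_input("`tau` must be >= 0")
  set.seed(derive_seed(check_seed(seed), "multistudy"))
  lapply(seq_len(k_studies), function(i) {
    delta <- stats::rnorm(1, mean = true_smd, sd = tau)
    list(
      study_id = sprintf("study_%02d", i),
      case = stats::rnorm(n_cases[i], mean = delta, sd = 1),
      control = stats::rnorm(n_controls[i], mean = 0, sd = 1)
    )
  })
}

#' Generate a scored interaction network
#'
#' Erdos-Renyi graph over the supplied genes with edge probability
#' `mean_degree / (n - 1)`, undirected, no self-loops, no duplicate
#' pairs; confidence scores drawn uniformly from `score_range`.
#'
#' @param genes Character vector of node names.
#' @param mean_degree Target mean node degree (< number of genes).
#' @param score_range Numeric length-2 interval for uniform scores.
#' @param seed Integer seed.
#' @return Data frame (`geneA`, `geneB`, `score`).
#' @export
generate_interaction_network <- function(genes, mean_degree,
                                         score_range = c(0.15, 1),
                                         seed = 1L) {
  if (length(genes) == 0) stop_input("`genes` must be nonempty")
  genes <- as.character(genes)
  n <- length(genes)
  if (!is.numeric(mean_degree) || mean_degree < 0 || mean_degree >= n) {
    stop_input("`mean_degree` must be in [0, number of genes)")
  }
  stopifnot(length(score_range) == 2, score_range[1] <= score_range[2])
  set.seed(derive_seed(check_seed(seed), "network"))
  p <- if (n > 1) min(1, mean_degree / (n - 1)) else 0
  pairs <- utils::combn(n, 2)
  keep <- stats::runif(ncol(pairs)) < p
  pairs <- pairs[, keep, drop = FALSE]
  data.frame(
    geneA = genes[pairs[1, ]],
    geneB = genes[pairs[2, ]],
    score = stats::runif(ncol(pairs), score_range[1], score_range[2]),
    stringsAsFactors = FALSE
  )
}

# Probability a subject in a group with event rate `rate` is censored by
# an independent Uniform(0, c) censoring time: P(C < T).
censor_prob <- function(cmax, rate) {
  (1 - exp(-rate * cmax)) / (rate * cmax)
}

#' Generate survival records with a group-dependent hazard
#'
#' Event times are exponential with rate 1 for group 0 and rate
#' `hazard_ratio` for group 1. Censoring times are Uniform(0, c) with `c`
#' solved numerically so the expected overall censoring fraction equals
#' `censor_rate` (0 disables censoring).
#'
#' @param n Number of subjects; `group` is recycled to this length.
#' @param group Binary (0/1) group labels.
#' @param hazard_ratio Hazard of group 1 relative to group 0 (> 0).
#' @param censor_rate Target fraction of censored subjects in `[0, 1)`.
#' @param seed Integer seed.
#' @return Data frame (`sample`, `time`, `event`, `group`).
#' @export
generate_survival <- function(n, group = rep(0:1, length.out = n),
                              hazard_ratio = 1, censor_rate = 0.2,
                              seed = 1L) {
  n <- check_count(n, "n", min = 2L)
  group <- as.integer(rep_len(group, n))
  if (!all(group %in% c(0L, 1L))) stop_input("`group` must be binary 0/1")
  if (!is.numeric(hazard_ratio) || hazard_ratio <= 0) {
    stop_input("`hazard_ratio` must be positive")
  }
  censor_rate <- check_fraction(censor_rate, "censor_rate", hi_open = TRUE)
  set.seed(derive_seed(check_seed(seed), "survival"))

  rate <- ifelse(group == 1L, hazard_ratio, 1)
  times <- stats::rexp(n, rate = rate)
  if (censor_rate == 0) {
    event <- rep(1L, n)
  } else {
    p1 <- mean(group)
    target <- function(cmax) {
      (1 - p1) * censor_prob(cmax, 1) + p1 * censor_prob(cmax, hazard_ratio) -
        censor_rate
    }
    cmax <- stats::uniroot(target, lower = 1e-8, upper = 1e6, tol = 1e-10)$root
    cens <- stats::runif(n, 0, cmax)
    event <- as.integer(times <= cens)
    times <- pmin(times, cens)
  }
  data.frame(
    sample = sprintf("p%04d", seq_len(n)),
    time = times, event = event, group = group,
    stringsAsFactors = FALSE
  )
}

#' Generate a gene-set collection, optionally planting one exact set
#'
#' @param background Character vector: the gene universe.
#' @param n_sets Number of random sets to draw.
#' @param set_size_range Integer length-2 interval of set sizes.
#' @param planted_set Optional character vector; included verbatim as set
#'   `"planted"`. Must be a subset of `background`.
#' @param seed Integer seed.
#' @return Named list of character vectors (GMT-writable).
#' @export
generate_gene_sets <- function(background, n_sets,
                               set_size_range = c(10L, 50L),
                               planted_set = NULL, seed = 1L) {
  background <- as.character(background)
  n_sets <- check_count(n_sets, "n_sets", min = 0L)
  stopifnot(length(set_size_range) == 2)
  if (max(set_size_range) > length(background)) {
    stop_input("set sizes exceed the background size")
  }
  if (!is.null(planted_set) && !all(planted_set %in% background)) {
    stop_input("`planted_set` must be a subset of `background`")
  }
  set.seed(derive_seed(check_seed(seed), "genesets"))
  sets <- lapply(seq_len(n_sets), function(i) {
    size <- sample(seq(set_size_range[1], set_size_range[2]), 1)
    sample(background, size)
  })
  names(sets) <- if (n_sets > 0) sprintf("set_%03d", seq_len(n_sets)) else character(0)
  if (!is.null(planted_set)) sets$planted <- as.character(planted_set)
  sets
}
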