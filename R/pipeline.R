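# End-to-end orchestration: overlap -> wgcna -> meta -> ppi -> hub ->
# diagnostics, driven by a flat config, communicating only via files in
# the run directory so any stage can be re-run standalone. Emits a
# machine-readable JSON run report plus a human-readable log.

#' Default pipeline configuration
#'
#' All thresholds default to the conventional screen values: DEG
#' p < 0.05 and |log2FC| > 1, target support >= 3 databases, automatic
#' soft threshold at scale-free fit 0.8, minimum module size 10,
#' eigengene merge height 0.25, MM > 0.8 and GS > 0.2, interaction
#' score >= 0.4, degree >= 8, significance 0.05 and Egger flag 0.1.
#'
#' @param ... Named overrides of any config entry.
#' @return Named list (the pipeline config).
#' @export
default_config <- function(...) {
  cfg <- list(
    stages = c("overlap", "wgcna", "meta", "ppi", "hub", "diagnostics"),
    # input paths (set by the caller or by run_demo)
    deg_table = NULL, targets_table = NULL, expression = NULL,
    traits = NULL, studies = NULL, edges = NULL, survival = NULL,
    gene_sets = NULL,
    outdir = NULL, seed = 1L,
    # thresholds
    p_thresh = 0.05, lfc_thresh = 1, use_q = FALSE, min_databases = 3L,
    beta = NULL, r2_cut = 0.8, min_module_size = 10L,
    merge_cut_height = 0.25, mm_thresh = 0.8, gs_thresh = 0.2,
    min_score = 0.4, min_degree = 8L, alpha = 0.05, egger_alpha = 0.1,
    class_trait = "class"
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown) > 0) {
    stop_input("unknown config entries: ", paste(unknown, collapse = ", "))
  }
  cfg[names(dots)] <- dots
  cfg
}

#' Read a pipeline config from a YAML file
#'
#' @param path YAML file of flat key-value entries; unspecified keys take
#'   the [default_config()] values.
#' @export
read_config <- function(path) {
  do.call(default_config, yaml::read_yaml(path))
}

stage_inputs <- list(
  overlap = c("deg_table", "targets_table"),
  wgcna = c("expression", "traits"),
  meta = "studies",
  ppi = "edges",
  hub = character(0),
  diagnostics = c("expression", "traits", "survival")
)
stage_deps <- list(hub = c("wgcna", "ppi"))

validate_config <- function(cfg) {
  bad <- setdiff(cfg$stages, names(stage_inputs))
  if (length(bad) > 0) stop_input("unknown stage(s): ", paste(bad, collapse = ", "))
  for (st in cfg$stages) {
    for (dep in stage_deps[[st]]) {
      if (!dep %in% cfg$stages) {
        stop_input("stage '", st, "' requires stage '", dep, "' to be enabled")
      }
    }
  }
  for (st in cfg$stages) {
    for (inp in stage_inputs[[st]]) {
      p <- cfg[[inp]]
      if (is.null(p)) stop_input("stage '", st, "' needs input `", inp, "`")
      if (!file.exists(p)) {
        stop_input("stage '", st, "' input `", inp, "` not found: ", p)
      }
    }
  }
  if (is.null(cfg$outdir)) stop_input("`outdir` must be set")
  invisible(cfg)
}

pipeline_log <- function(state, stage, msg) {
  line <- sprintf("[%s] %-11s %s",
                  format(Sys.time(), "%Y-%m-%d %H:%M:%S"), stage, msg)
  cat(line, "\n", sep = "", file = state$logfile, append = TRUE)
  message(line)
}

register_output <- function(state, path) {
  state$outputs[[basename(path)]] <- list(
    path = path, md5 = unname(tools::md5sum(path))
  )
  state
}

#' Run the hub-gene discovery pipeline
#'
#' Validates the config fail-fast (missing inputs or stage dependencies
#' abort before any stage runs), executes the enabled stages in order
#' (overlap, wgcna, meta, ppi, hub, diagnostics), writes every stage
#' output plus the resolved config into `cfg$outdir`, and returns the
#' run report (also written as `run_report.json`).
#'
#' @param cfg Config list from [default_config()] or [read_config()].
#' @return The run report list, invisibly.
#' @export
run_pipeline <- function(cfg) {
  validate_config(cfg)
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  state <- new.env()
  state$logfile <- file.path(cfg$outdir, "run.log")
  cat("", file = state$logfile)
  state$outputs <- list()
  report <- list(seed = cfg$seed, stages = cfg$stages)

  cfg_out <- file.path(cfg$outdir, "resolved_config.yaml")
  yaml::write_yaml(cfg[!vapply(cfg, is.null, logical(1))], cfg_out)
  state <- register_output(state, cfg_out)

  overlap_genes <- NULL
  wres <- NULL
  key_genes <- NULL
  degrees <- NULL
  high_conn <- NULL
  hubs <- NULL
  expr <- NULL
  traits <- NULL

  if ("overlap" %in% cfg$stages) {
    deg_tab <- read_deg_tsv(cfg$deg_table)
    tgt_tab <- utils::read.delim(cfg$targets_table, stringsAsFactors = FALSE)
    degs <- select_deg(deg_tab, cfg$p_thresh, cfg$lfc_thresh, cfg$use_q)
    targets <- filter_targets(tgt_tab, cfg$min_databases)
    overlap_genes <- overlap_targets(degs, targets)
    p <- file.path(cfg$outdir, "overlap_genes.txt")
    writeLines(overlap_genes, p)
    state <- register_output(state, p)
    pipeline_log(state, "overlap", sprintf(
      "%d DEGs x %d targets -> %d overlapping genes",
      length(degs), length(targets), length(overlap_genes)))
    report$overlap <- list(n_deg = length(degs), n_targets = length(targets),
                           n_overlap = length(overlap_genes))
  }

  if ("wgcna" %in% cfg$stages || "diagnostics" %in% cfg$stages) {
    expr <- read_expression_tsv(cfg$expression)
    traits <- read_trait_tsv(cfg$traits)
  }

  if ("wgcna" %in% cfg$stages) {
    if (!is.null(overlap_genes)) {
      expr_net <- expr[rownames(expr) %in% overlap_genes, , drop = FALSE]
    } else {
      expr_net <- expr
    }
    trait_cols <- setdiff(names(traits), c("sample", cfg$class_trait))
    wres <- wgcna_modules(
      expr_net, traits[, c("sample", trait_cols[1])],
      beta = cfg$beta, r2_cut = cfg$r2_cut,
      min_module_size = cfg$min_module_size,
      merge_cut_height = cfg$merge_cut_height
    )
    mt <- wres$module_trait
    trait_module <- as.integer(sub("^module_", "",
                                   mt$module[which.max(abs(mt$r))]))
    key_genes <- screen_key_genes(wres$scores, cfg$mm_thresh, cfg$gs_thresh,
                                  module = trait_module)
    mod_tab <- wres$scores
    p1 <- file.path(cfg$outdir, "modules.tsv")
    utils::write.table(format(mod_tab, digits = 6), p1, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    p2 <- file.path(cfg$outdir, "eigengenes.tsv")
    utils::write.table(
      data.frame(module = rownames(wres$eigengenes),
                 format(wres$eigengenes, digits = 6), check.names = FALSE),
      p2, sep = "\t", quote = FALSE, row.names = FALSE)
    p3 <- file.path(cfg$outdir, "module_trait.tsv")
    utils::write.table(format(mt, digits = 6), p3, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    p4 <- file.path(cfg$outdir, "key_genes.txt")
    writeLines(key_genes, p4)
    for (p in c(p1, p2, p3, p4)) state <- register_output(state, p)
    if (!is.null(wres$fit_table)) {
      p5 <- file.path(cfg$outdir, "soft_threshold.tsv")
      utils::write.table(format(wres$fit_table, digits = 6), p5, sep = "\t",
                         quote = FALSE, row.names = FALSE)
      state <- register_output(state, p5)
    }
    pipeline_log(state, "wgcna", sprintf(
      "beta=%d, %d modules over %d genes; trait module %d; %d key genes",
      wres$beta, length(unique(wres$labels[wres$labels != 0])),
      nrow(expr_net), trait_module, length(key_genes)))
    report$wgcna <- list(
      beta = wres$beta,
      n_modules = length(unique(wres$labels[wres$labels != 0])),
      trait_module = trait_module,
      trait_module_r = mt$r[which.max(abs(mt$r))],
      trait_module_p = mt$p[which.max(abs(mt$r))],
      key_genes = key_genes
    )
  }

  if ("meta" %in% cfg$stages) {
    studies <- read_studies_tsv(cfg$studies)
    meta <- meta_analyze(studies, cfg$alpha, 50, cfg$egger_alpha)
    p1 <- file.path(cfg$outdir, "meta_summary.json")
    jsonlite::write_json(list(
      pooled = meta$selected$pooled, ci_low = meta$selected$ci_low,
      ci_high = meta$selected$ci_high, model = meta$model,
      Q = meta$selected$Q, df = meta$selected$df, p_Q = meta$selected$p_Q,
      I2 = meta$selected$I2, tau2 = meta$selected$tau2,
      egger_p = if (is.null(meta$egger)) NA else meta$egger$p
    ), p1, auto_unbox = TRUE, digits = NA)
    p2 <- file.path(cfg$outdir, "forest.tsv")
    utils::write.table(format(meta$effects, digits = 6), p2, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    state <- register_output(state, p1)
    state <- register_output(state, p2)
    pipeline_log(state, "meta", sprintf(
      "%d studies; %s model; pooled SMD = %.3f [%.3f, %.3f]; I2 = %.1f%%",
      nrow(meta$effects), meta$model, meta$selected$pooled,
      meta$selected$ci_low, meta$selected$ci_high, meta$selected$I2))
    report$meta <- list(pooled = meta$selected$pooled, model = meta$model,
                        I2 = meta$selected$I2, p_Q = meta$selected$p_Q)
  }

  if ("ppi" %in% cfg$stages) {
    edges <- read_edges_tsv(cfg$edges)
    kept <- main_component(filter_edges(edges, cfg$min_score))
    degrees <- node_degrees(kept)
    high_conn <- high_connectivity(degrees, cfg$min_degree)
    p1 <- file.path(cfg$outdir, "filtered_edges.tsv")
    write_edges_tsv(kept, p1)
    p2 <- file.path(cfg$outdir, "degrees.tsv")
    utils::write.table(
      data.frame(gene = names(degrees), degree = as.integer(degrees)),
      p2, sep = "\t", quote = FALSE, row.names = FALSE)
    p3 <- file.path(cfg$outdir, "high_connectivity.txt")
    writeLines(high_conn, p3)
    for (p in c(p1, p2, p3)) state <- register_output(state, p)
    pipeline_log(state, "ppi", sprintf(
      "%d -> %d edges after score >= %.2f + main component; %d genes with degree >= %d",
      nrow(edges), nrow(kept), cfg$min_score, length(high_conn),
      cfg$min_degree))
    report$ppi <- list(n_edges_in = nrow(edges), n_edges_kept = nrow(kept),
                       n_high_connectivity = length(high_conn))
  }

  if ("hub" %in% cfg$stages) {
    hubs <- hub_intersect(key_genes, high_conn, degrees)
    p <- file.path(cfg$outdir, "hub_genes.txt")
    writeLines(hubs, p)
    state <- register_output(state, p)
    pipeline_log(state, "hub", sprintf(
      "%d key genes x %d high-connectivity genes -> %d hub genes",
      length(key_genes), length(high_conn), length(hubs)))
    report$hub_genes <- hubs
  }

  if ("diagnostics" %in% cfg$stages) {
    diag_report <- list()
    genes_to_test <- if (!is.null(hubs) && length(hubs) > 0) {
      hubs
    } else if (!is.null(key_genes)) {
      utils::head(key_genes, 5)
    } else {
      character(0)
    }
    if (cfg$class_trait %in% names(traits) && length(genes_to_test) > 0) {
      labels <- traits[[cfg$class_trait]][match(colnames(expr), traits$sample)]
      aucs <- lapply(genes_to_test, function(g) {
        r <- roc_auc(expr[g, ], labels)
        list(gene = g, auc = r$auc, p = r$p)
      })
      diag_report$auc <- aucs
      pipeline_log(state, "diagnostics", sprintf(
        "ROC on %d gene(s); AUC range [%.3f, %.3f]", length(aucs),
        min(vapply(aucs, `[[`, numeric(1), "auc")),
        max(vapply(aucs, `[[`, numeric(1), "auc"))))
    }
    surv <- read_survival_tsv(cfg$survival)
    km <- km_curve(surv)
    lr <- logrank(surv)
    p1 <- file.path(cfg$outdir, "km_curves.tsv")
    utils::write.table(format(km$table, digits = 6), p1, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    p2 <- file.path(cfg$outdir, "logrank.json")
    jsonlite::write_json(list(
      chi2 = lr$chi2, p = lr$p, hazard_ratio = lr$hazard_ratio,
      hr_ci_low = lr$hr_ci[1], hr_ci_high = lr$hr_ci[2],
      median_survival = as.list(km$median)
    ), p2, auto_unbox = TRUE, digits = NA)
    state <- register_output(state, p1)
    state <- register_output(state, p2)
    diag_report$logrank <- list(chi2 = lr$chi2, p = lr$p,
                                hazard_ratio = lr$hazard_ratio)
    pipeline_log(state, "diagnostics", sprintf(
      "log-rank chi2 = %.3f, p = %.4g, HR = %.3f", lr$chi2, lr$p,
      lr$hazard_ratio))
    if (!is.null(cfg$gene_sets) && !is.null(key_genes) && !is.null(expr)) {
      sets <- read_gmt(cfg$gene_sets)
      enr <- ora(intersect(key_genes, rownames(expr)), rownames(expr), sets)
      p3 <- file.path(cfg$outdir, "ora.tsv")
      utils::write.table(format(enr, digits = 6), p3, sep = "\t",
                         quote = FALSE, row.names = FALSE)
      state <- register_output(state, p3)
      diag_report$top_set <- if (nrow(enr) > 0) enr$set[which.min(enr$p)] else NA
      pipeline_log(state, "diagnostics", sprintf(
        "ORA over %d sets; top set by p: %s", nrow(enr),
        diag_report$top_set))
    }
    report$diagnostics <- diag_report
  }

  report$outputs <- state$outputs
  rp <- file.path(cfg$outdir, "run_report.json")
  jsonlite::write_json(report, rp, auto_unbox = TRUE, digits = NA,
                       null = "null")
  pipeline_log(state, "done", paste("report written to", rp))
  invisible(report)
}

#' Generate synthetic inputs and run the full pipeline (demo)
#'
#' Generates every pipeline input with planted ground truth — a modular
#' expression matrix whose first module drives the trait, a
#' differential-expression and a target-prediction table that both
#' recover the planted genes, a multi-study effect, a scored interaction
#' network and a survival table — then executes [run_pipeline()] on
#' them.
#'
#' @param seed Integer master seed for every generator.
#' @param outdir Output directory (created; refuses to overwrite an
#'   existing non-empty directory unless `force = TRUE`).
#' @param force Overwrite an existing output directory.
#' @param n_genes,n_samples Simulation scale (defaults 500 x 150).
#' @return List: `report` (the run report) and `truth` (the planted
#'   ground truth).
#' @export
run_demo <- function(seed = 1L, outdir = tempfile("coexhub_demo_"),
                     force = FALSE, n_genes = 500L, n_samples = 150L) {
  seed <- check_seed(seed)
  if (dir.exists(outdir) && length(list.files(outdir)) > 0 && !force) {
    stop_input("`outdir` exists and is non-empty; use force = TRUE")
  }
  indir <- file.path(outdir, "inputs")
  dir.create(indir, recursive = TRUE, showWarnings = FALSE)

  # four planted modules at 12/10/8/6% of the gene count (60/50/40/30 at
  # the default 500 genes)
  module_sizes <- pmax(round(n_genes * c(0.12, 0.10, 0.08, 0.06)), 2L)
  sim_cfg <- simulation_config(n_genes = n_genes, n_samples = n_samples,
                               module_sizes = module_sizes, seed = seed)
  sim <- generate_modular_expression(sim_cfg)
  truth <- sim$truth
  genes <- rownames(sim$expr)
  planted <- names(truth$module)[truth$module != 0]

  set.seed(derive_seed(seed, "demo-tables"))
  # DEG statistics: planted module genes are clearly differential;
  # unassigned genes are a mixed bag, as in a real screen.
  is_mod <- truth$module != 0
  deg_tab <- data.frame(
    gene = genes,
    logFC = ifelse(is_mod,
                   sample(c(-1, 1), n_genes, TRUE) * stats::runif(n_genes, 1.2, 3),
                   stats::rnorm(n_genes, 0, 1.2)),
    pvalue = ifelse(is_mod, stats::runif(n_genes, 0, 0.04),
                    stats::runif(n_genes)),
    stringsAsFactors = FALSE
  )
  # Target predictions: planted genes supported by >= 3 of 12 databases.
  tgt_tab <- data.frame(
    gene = genes,
    n_databases = ifelse(is_mod, sample(3:12, n_genes, TRUE),
                         sample(0:12, n_genes, TRUE)),
    stringsAsFactors = FALSE
  )
  # Class label for ROC: trait dichotomized at its median.
  traits <- sim$traits
  traits$class <- dichotomize_median(traits$trait)

  studies <- generate_multi_study(
    8, c(78, 9, 9, 3, 8, 4, 3, 372), c(88, 10, 7, 3, 10, 8, 3, 50),
    true_smd = 0.3, tau = 0.4, seed = seed
  )
  edges <- generate_interaction_network(genes, mean_degree = 16, seed = seed)

  # Survival: groups from the median-split expression of a planted
  # trait-module gene, with an unfavorable hazard for the high group.
  surv_gene <- planted[1]
  surv_group <- dichotomize_median(sim$expr[surv_gene, ])
  surv <- generate_survival(n_samples, surv_group, hazard_ratio = 1.77,
                            censor_rate = 0.2, seed = seed)
  trait_genes <- names(truth$module)[truth$module == truth$trait_module]
  gene_sets <- generate_gene_sets(
    genes, n_sets = 20,
    planted_set = utils::head(trait_genes, 30), seed = seed
  )

  paths <- list(
    deg_table = file.path(indir, "deg_table.tsv"),
    targets_table = file.path(indir, "targets.tsv"),
    expression = file.path(indir, "expression.tsv"),
    traits = file.path(indir, "traits.tsv"),
    studies = file.path(indir, "studies.tsv"),
    edges = file.path(indir, "edges.tsv"),
    survival = file.path(indir, "survival.tsv"),
    gene_sets = file.path(indir, "gene_sets.gmt")
  )
  utils::write.table(deg_tab, paths$deg_table, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(tgt_tab, paths$targets_table, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_expression_tsv(sim$expr, paths$expression)
  write_trait_tsv(traits, paths$traits)
  write_studies_tsv(studies, paths$studies)
  write_edges_tsv(edges, paths$edges)
  write_survival_tsv(surv, paths$survival)
  write_gmt(gene_sets, paths$gene_sets)

  cfg <- do.call(default_config,
                 c(paths, list(outdir = file.path(outdir, "run"),
                               seed = seed)))
  report <- run_pipeline(cfg)
  list(report = report, truth = truth, config = cfg)
}
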