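# Weighted gene co-expression network construction from first
# principles: absolute-correlation similarity -> soft-threshold power
# adjacency -> topological overlap -> dissimilarity -> tree cutting ->
# module eigengenes -> module merging -> module-trait correlation ->
# module membership (MM) / gene significance (GS) screening.
#
# Conventions (standard for unsigned TOM networks):
#   * adjacency diagonal is 0 inside connectivity and shared-neighbor
#     sums; the reported TOM diagonal is 1; the dissTOM diagonal is 0.

#' Absolute-correlation similarity matrix
#'
#' `S[x, y] = |cor(x, y)|`, the elementwise absolute Pearson correlation
#' between gene expression vectors (an unsigned network).
#'
#' @param expr Numeric genes x samples matrix with at least 3 samples.
#' @return Symmetric matrix in `[0, 1]` with unit diagonal.
#' @export
similarity <- function(expr) {
  check_expression_matrix(expr)
  if (ncol(expr) < 3) stop_input("need at least 3 samples")
  v <- apply(expr, 1, stats::var)
  if (any(v == 0)) {
    stop_input("zero-variance gene(s): ",
               paste(utils::head(rownames(expr)[v == 0], 5), collapse = ", "))
  }
  s <- abs(stats::cor(t(expr)))
  diag(s) <- 1
  s
}

#' Soft-threshold power adjacency
#'
#' Raises the similarity matrix elementwise to the power `beta`. The
#' diagonal is set to 0 so downstream connectivity sums exclude
#' self-adjacency.
#'
#' @param S Similarity matrix from [similarity()].
#' @param beta Positive integer soft-threshold exponent.
#' @return Adjacency matrix in `[0, 1]`, zero diagonal, with attribute
#'   `beta`.
#' @export
adjacency <- function(S, beta) {
  beta <- check_count(beta, "beta", min = 1L)
  stopifnot(is.matrix(S))
  a <- S^beta
  diag(a) <- 0
  attr(a, "beta") <- beta
  a
}

# Scale-free topology fit for one connectivity vector: bin log-degree,
# regress log10(p(k)) on log10(k), return R^2 signed by -slope so a
# decreasing (power-law-like) degree distribution scores positive.
scale_free_fit <- function(k, nbins = 10L) {
  k <- k[k > 0]
  if (length(k) < 2) return(NA_real_)
  bins <- cut(k, breaks = nbins)
  pk <- tapply(k, bins, length) / length(k)
  km <- tapply(k, bins, mean)
  keep <- !is.na(pk) & pk > 0 & km > 0
  if (sum(keep) < 3) return(NA_real_)
  fit <- stats::lm(log10(pk[keep]) ~ log10(km[keep]))
  r2 <- summary(fit)$r.squared
  slope <- stats::coef(fit)[2]
  unname(r2 * -sign(slope))
}

#' Choose the soft-threshold exponent by scale-free topology fit
#'
#' For each candidate `beta`, builds the power adjacency, computes each
#' gene's connectivity `k`, bins `k` into `nbins` intervals and
#' regresses `log10(p(k))` on `log10(k)`. The signed fit index is
#' `R^2 * sign(-slope)`. Returns the smallest candidate whose signed
#' fit reaches `r2_cut` (the usual "first beta over the cut" rule), or
#' the best-fitting candidate when none reaches it.
#'
#' @param expr Numeric genes x samples matrix.
#' @param candidates Integer vector of candidate exponents.
#' @param r2_cut Signed scale-free fit cutoff (default 0.8).
#' @param nbins Number of connectivity bins (default 10).
#' @param min_mean_k Minimum mean connectivity for a candidate to be
#'   eligible (default 1): very large exponents can nudge the fit index
#'   up while collapsing the network to near-zero connectivity, which
#'   makes the degree distribution — and everything downstream —
#'   meaningless. Ignored if no candidate reaches it.
#' @return List with `beta` (chosen exponent) and `fit_table` (data
#'   frame: `beta`, `signed_r2`, `mean_k`).
#' @export
pick_soft_threshold <- function(expr, candidates = 1:20, r2_cut = 0.8,
                                nbins = 10L, min_mean_k = 1) {
  if (length(candidates) == 0) stop_input("`candidates` must be nonempty")
  r2_cut <- check_fraction(r2_cut, "r2_cut", lo = 0, hi = 1)
  S <- similarity(expr)
  candidates <- sort(unique(as.integer(candidates)))
  rows <- lapply(candidates, function(b) {
    a <- adjacency(S, b)
    k <- rowSums(a)
    if (all(k == 0)) stop_input("all connectivities are zero at beta = ", b)
    data.frame(beta = b, signed_r2 = scale_free_fit(k, nbins), mean_k = mean(k))
  })
  fit <- do.call(rbind, rows)
  eligible <- fit$mean_k >= min_mean_k
  if (!any(eligible)) eligible <- rep(TRUE, nrow(fit))
  ok <- which(eligible & !is.na(fit$signed_r2) & fit$signed_r2 >= r2_cut)
  beta <- if (length(ok) > 0) {
    fit$beta[ok[1]]
  } else {
    fit$beta[eligible][which.max(fit$signed_r2[eligible])]
  }
  list(beta = beta, fit_table = fit)
}

#' Topological overlap matrix
#'
#' For genes X != Y with adjacency `a` and connectivity `k = rowSums(a)`:
#' `omega_XY = (l_XY + a_XY) / (min(k_X, k_Y) + 1 - a_XY)`, where
#' `l_XY = sum_u a_Xu a_uY` counts shared-neighbor adjacency. The
#' diagonal is reported as 1.
#'
#' @param A Symmetric adjacency matrix in `[0, 1]` with zero diagonal.
#' @return TOM matrix in `[0, 1]` with unit diagonal and attribute
#'   `connectivity` (per-gene `k`).
#' @export
topological_overlap <- function(A) {
  stopifnot(is.matrix(A))
  if (max(abs(A - t(A))) > 1e-8) stop_input("adjacency must be symmetric")
  if (any(A < -1e-12) || any(A > 1 + 1e-12)) {
    stop_input("adjacency entries must lie in [0, 1]")
  }
  if (any(diag(A) != 0)) stop_input("adjacency diagonal must be zero")
  l <- A %*% A
  k <- rowSums(A)
  kmin <- outer(k, k, pmin)
  tom <- (l + A) / (kmin + 1 - A)
  diag(tom) <- 1
  dimnames(tom) <- dimnames(A)
  attr(tom, "connectivity") <- k
  tom
}

#' Topological overlap dissimilarity
#'
#' `dissTOM = 1 - TOM`, with a zero diagonal: the clustering distance.
#'
#' @param tom TOM matrix from [topological_overlap()].
#' @return Dissimilarity matrix with zero diagonal.
#' @export
dissimilarity <- function(tom) {
  stopifnot(is.matrix(tom))
  if (any(tom < -1e-12) || any(tom > 1 + 1e-12)) {
    stop_input("TOM entries must lie in [0, 1]")
  }
  d <- 1 - tom
  diag(d) <- 0
  attr(d, "connectivity") <- NULL
  d
}

# Default static cut height. Co-expression trees separate into a low
# band of within-module joins and a dense band of background joins near
# 1, with wide empty spacings between the bands; cutting inside such a
# spacing recovers the modules. Candidates are the 30 widest spacings
# between consecutive merge heights; among them the cut yielding the
# most clusters of >= min_size genes wins, ties broken by the wider
# gap. Gap width alone can favour a spacing below a single very tight
# module (splitting off that module and shattering the rest), while
# counting clusters over arbitrary heights would favour cuts inside the
# background band where spurious size-qualified clusters abound —
# restricting the count to the widest gaps avoids both failure modes.
# If no candidate yields a qualifying cluster the widest gap is
# returned and the size floor will unassign everything.
widest_gap_cut <- function(hc, min_size, top_k = 30L) {
  hs <- sort(unique(hc$height))
  if (length(hs) < 2) return(hs[1])
  gaps <- diff(hs)
  ord <- utils::head(order(gaps, decreasing = TRUE), top_k)
  best_h <- (hs[ord[1]] + hs[ord[1] + 1]) / 2
  best_nq <- 0L
  best_gap <- 0
  for (i in ord) {
    h <- (hs[i] + hs[i + 1]) / 2
    nq <- sum(table(stats::cutree(hc, h = h)) >= min_size)
    if (nq > best_nq || (nq == best_nq && nq > 0L && gaps[i] > best_gap)) {
      best_nq <- nq
      best_gap <- gaps[i]
      best_h <- h
    }
  }
  best_h
}

# Renumber module labels so label 1 is the largest module; 0 stays 0.
renumber_by_size <- function(labels) {
  nz <- labels[labels != 0]
  if (length(nz) == 0) return(labels)
  sizes <- sort(table(nz), decreasing = TRUE)
  map <- stats::setNames(seq_along(sizes), names(sizes))
  out <- labels
  out[labels != 0] <- map[as.character(nz)]
  stats::setNames(as.integer(out), names(labels))
}

#' Cut a dissimilarity tree into modules (dynamic-hybrid style)
#'
#' Builds an average-linkage hierarchical tree on the dissimilarity and
#' cuts it at a static height. By default the height is placed in a gap
#' of the tree's merge-height distribution: co-expression trees separate
#' into a low band of within-module joins and a dense band of
#' background joins near 1, and the cut that maximizes gap width times
#' the number of size-qualified clusters lands between the two even
#' when modules differ in tightness. Branches smaller
#' than `min_module_size` fall to the unassigned label 0, and — the
#' hybrid step — each unassigned gene is optionally reattached to the
#' module whose eigengene it correlates with most strongly, provided
#' that correlation exceeds `reattach_floor`. Surviving modules are
#' renumbered by decreasing size.
#'
#' @param diss Square symmetric dissimilarity matrix (from
#'   [dissimilarity()]).
#' @param min_module_size Minimum genes per module (>= 2; default 10).
#' @param cut_height Static cut height; `NULL` (default) uses the
#'   widest-gap rule above.
#' @param expr Expression matrix; required when `reattach = TRUE`
#'   (eigengene correlations need the data).
#' @param reattach Run the hybrid reattachment step (default `TRUE`
#'   when `expr` is supplied).
#' @param reattach_floor Minimum absolute eigengene correlation for
#'   reattachment (default 0.3).
#' @return Named integer label vector (0 = unassigned).
#' @export
cluster_cut <- function(diss, min_module_size = 10L, cut_height = NULL,
                        expr = NULL, reattach = !is.null(expr),
                        reattach_floor = 0.3) {
  stopifnot(is.matrix(diss), nrow(diss) == ncol(diss))
  if (max(abs(diss - t(diss))) > 1e-8) stop_input("`diss` must be symmetric")
  min_module_size <- check_count(min_module_size, "min_module_size", min = 2L)
  check_flag(reattach, "reattach")
  if (reattach && is.null(expr)) {
    stop_input("`expr` is required for the reattachment step")
  }

  hc <- stats::hclust(stats::as.dist(diss), method = "average")
  if (is.null(cut_height)) {
    cut_height <- widest_gap_cut(hc, min_module_size)
  }
  labels <- stats::cutree(hc, h = cut_height)
  sizes <- table(labels)
  labels[labels %in% as.integer(names(sizes)[sizes < min_module_size])] <- 0L
  labels <- renumber_by_size(labels)
  if (!is.null(rownames(diss))) names(labels) <- rownames(diss)

  if (reattach && any(labels == 0L) && any(labels != 0L)) {
    me <- module_eigengene(expr, labels)
    grey <- which(labels == 0L)
    cors <- stats::cor(t(expr[grey, , drop = FALSE]), t(me))
    best <- max.col(abs(cors), ties.method = "first")
    hit <- abs(cors)[cbind(seq_along(grey), best)] > reattach_floor
    labels[grey[hit]] <- as.integer(sub("^module_", "", rownames(me)))[best[hit]]
    labels <- renumber_by_size(labels)
  }
  labels
}

#' Module eigengenes
#'
#' For each module, standardizes every member gene across samples and
#' takes the first principal component score over samples — a one-vector
#' summary of the module's expression. Each eigengene is rescaled to
#' unit variance and sign-aligned so it correlates positively with the
#' module's mean standardized expression.
#'
#' @param expr Numeric genes x samples matrix.
#' @param labels Integer module labels per gene (0 = unassigned,
#'   excluded); every module must have at least 2 genes.
#' @return Numeric modules x samples matrix with rownames
#'   `module_<label>`.
#' @export
module_eigengene <- function(expr, labels) {
  check_expression_matrix(expr)
  stopifnot(length(labels) == nrow(expr))
  mods <- sort(unique(labels[labels != 0]))
  if (length(mods) == 0) stop_input("no assigned modules")
  me <- matrix(NA_real_, nrow = length(mods), ncol = ncol(expr),
               dimnames = list(sprintf("module_%d", mods), colnames(expr)))
  for (i in seq_along(mods)) {
    members <- which(labels == mods[i])
    if (length(members) < 2) {
      stop_input("module ", mods[i], " has fewer than 2 genes")
    }
    x <- t(scale(t(expr[members, , drop = FALSE])))
    sv <- svd(x, nu = 0, nv = 1)
    e <- sv$v[, 1]
    e <- e / stats::sd(e)
    if (stats::cor(e, colMeans(x)) < 0) e <- -e
    me[i, ] <- e
  }
  me
}

#' Merge similar modules by eigengene clustering
#'
#' Clusters module eigengenes with average linkage on the dissimilarity
#' `1 - cor(ME_i, ME_j)`, merges every group of modules joined below
#' `cut_height`, recomputes eigengenes, and iterates to a fixed point.
#'
#' @param expr Numeric genes x samples matrix.
#' @param labels Integer module labels per gene.
#' @param cut_height Eigengene dissimilarity below which modules merge
#'   (in `(0, 1)`; default 0.25, i.e. merge at correlation > 0.75).
#' @return Named integer label vector, renumbered by decreasing size.
#' @export
merge_modules <- function(expr, labels, cut_height = 0.25) {
  cut_height <- check_fraction(cut_height, "cut_height",
                               lo = 0, hi = 1, lo_open = TRUE, hi_open = TRUE)
  labels <- renumber_by_size(labels)
  repeat {
    mods <- sort(unique(labels[labels != 0]))
    if (length(mods) < 2) break
    me <- module_eigengene(expr, labels)
    d <- 1 - stats::cor(t(me))
    hc <- stats::hclust(stats::as.dist(d), method = "average")
    groups <- stats::cutree(hc, h = cut_height)
    if (max(table(groups)) == 1L) break
    map <- stats::setNames(mods[stats::ave(seq_along(mods), groups,
                                           FUN = min)], mods)
    labels[labels != 0] <- map[as.character(labels[labels != 0])]
    labels <- renumber_by_size(labels)
  }
  labels
}

#' Module-trait correlations
#'
#' Pearson correlation between every module eigengene and every numeric
#' trait, with two-sided p-values from the t transform
#' `t = r * sqrt((n - 2) / (1 - r^2))`.
#'
#' @param me Modules x samples eigengene matrix.
#' @param traits Data frame with a `sample` column matching `colnames(me)`
#'   and one or more numeric trait columns.
#' @param alpha Significance flag level (default 0.05).
#' @return Data frame (`module`, `trait`, `r`, `p`, `significant`).
#' @export
module_trait <- function(me, traits, alpha = 0.05) {
  stopifnot(is.matrix(me), is.data.frame(traits), "sample" %in% names(traits))
  missing <- setdiff(colnames(me), traits$sample)
  extra <- setdiff(traits$sample, colnames(me))
  if (length(missing) > 0 || length(extra) > 0) {
    stop_input("sample mismatch between eigengenes and traits; ",
               "missing from traits: ", paste(missing, collapse = ", "),
               "; absent from eigengenes: ", paste(extra, collapse = ", "))
  }
  traits <- traits[match(colnames(me), traits$sample), , drop = FALSE]
  trait_cols <- setdiff(names(traits), "sample")
  n <- ncol(me)
  out <- expand.grid(module = rownames(me), trait = trait_cols,
                     stringsAsFactors = FALSE)
  out$r <- mapply(function(m, tr) {
    stats::cor(me[m, ], traits[[tr]])
  }, out$module, out$trait)
  out$p <- cor_pvalue(out$r, n)
  out$significant <- out$p < alpha
  out
}

# Two-sided p-value for a Pearson correlation via the t transform.
cor_pvalue <- function(r, n) {
  r <- pmin(pmax(r, -1), 1)
  t <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  2 * stats::pt(-abs(t), df = n - 2)
}

#' Per-gene module membership (MM) and gene significance (GS)
#'
#' MM is the correlation of a gene's expression with its own module's
#' eigengene; GS is the correlation with the sample trait. Unassigned
#' genes (label 0) get `NA` MM but still receive a GS.
#'
#' @param expr Numeric genes x samples matrix.
#' @param me Modules x samples eigengene matrix.
#' @param labels Integer module labels per gene.
#' @param trait Numeric trait vector aligned with `colnames(expr)`.
#' @return Data frame (`gene`, `module`, `mm`, `gs`).
#' @export
gene_scores <- function(expr, me, labels, trait) {
  check_expression_matrix(expr)
  stopifnot(length(labels) == nrow(expr), length(trait) == ncol(expr))
  mm <- rep(NA_real_, nrow(expr))
  for (m in sort(unique(labels[labels != 0]))) {
    key <- sprintf("module_%d", m)
    if (!key %in% rownames(me)) {
      stop_input("no eigengene for module ", m)
    }
    idx <- which(labels == m)
    mm[idx] <- stats::cor(t(expr[idx, , drop = FALSE]), me[key, ])
  }
  gs <- as.vector(stats::cor(t(expr), trait))
  data.frame(gene = rownames(expr), module = as.integer(labels),
             mm = mm, gs = gs, stringsAsFactors = FALSE)
}

#' Screen key genes by module membership and gene significance
#'
#' Selects genes with `|MM| > mm_thresh` AND `|GS| > gs_thresh` (both
#' strict), optionally restricted to one module.
#'
#' @param scores Data frame from [gene_scores()].
#' @param mm_thresh Module-membership cutoff (default 0.8).
#' @param gs_thresh Gene-significance cutoff (default 0.2).
#' @param module Optional module label to restrict to.
#' @return Character vector of key genes.
#' @export
screen_key_genes <- function(scores, mm_thresh = 0.8, gs_thresh = 0.2,
                             module = NULL) {
  stopifnot(is.data.frame(scores),
            all(c("gene", "module", "mm", "gs") %in% names(scores)))
  mm_thresh <- check_fraction(mm_thresh, "mm_thresh")
  gs_thresh <- check_fraction(gs_thresh, "gs_thresh")
  keep <- !is.na(scores$mm) &
    abs(scores$mm) > mm_thresh & abs(scores$gs) > gs_thresh
  if (!is.null(module)) keep <- keep & scores$module == module
  as.character(scores$gene[keep])
}

#' Flag outlier samples by average inter-sample correlation
#'
#' Optional pre-step before network construction: computes each sample's
#' mean correlation with all other samples, z-scores those means, and
#' flags samples below `z_cut`.
#'
#' @param expr Numeric genes x samples matrix.
#' @param z_cut Z-score threshold (default -2.5).
#' @return Character vector of flagged sample names (possibly empty).
#' @export
flag_outlier_samples <- function(expr, z_cut = -2.5) {
  check_expression_matrix(expr)
  cc <- stats::cor(expr)
  diag(cc) <- NA
  m <- rowMeans(cc, na.rm = TRUE)
  z <- (m - mean(m)) / stats::sd(m)
  colnames(expr)[z < z_cut]
}

#' Run the full co-expression module analysis
#'
#' Convenience wrapper: similarity, soft-threshold choice (unless `beta`
#' is given), adjacency, TOM, dissimilarity, tree cutting, module
#' merging, eigengenes, module-trait correlation and MM/GS scores.
#'
#' @param expr Numeric genes x samples matrix.
#' @param traits Data frame (`sample`, numeric trait columns); the first
#'   trait column is used for GS.
#' @param beta Soft threshold; `NULL` (default) picks it by scale-free
#'   fit over `candidates`.
#' @param candidates Candidate soft thresholds (default 1:20).
#' @param r2_cut Scale-free fit cutoff for the automatic choice.
#' @param min_module_size Minimum module size (default 10).
#' @param merge_cut_height Eigengene merge height (default 0.25).
#' @param cut_height Static tree cut height (default: 0.99 quantile).
#' @param reattach_floor Hybrid reattachment correlation floor.
#' @return List: `beta`, `fit_table`, `labels`, `eigengenes`,
#'   `module_trait`, `scores`.
#' @export
wgcna_modules <- function(expr, traits, beta = NULL, candidates = 1:20,
                          r2_cut = 0.8, min_module_size = 10L,
                          merge_cut_height = 0.25, cut_height = NULL,
                          reattach_floor = 0.3) {
  fit_table <- NULL
  if (is.null(beta)) {
    pick <- pick_soft_threshold(expr, candidates, r2_cut)
    beta <- pick$beta
    fit_table <- pick$fit_table
  }
  S <- similarity(expr)
  A <- adjacency(S, beta)
  tom <- topological_overlap(A)
  diss <- dissimilarity(tom)
  labels <- cluster_cut(diss, min_module_size, cut_height = cut_height,
                        expr = expr, reattach_floor = reattach_floor)
  if (any(labels != 0)) {
    labels <- merge_modules(expr, labels, merge_cut_height)
  }
  me <- module_eigengene(expr, labels)
  mt <- module_trait(me, traits)
  trait_col <- setdiff(names(traits), "sample")[1]
  trait <- traits[[trait_col]][match(colnames(expr), traits$sample)]
  scores <- gene_scores(expr, me, labels, trait)
  list(beta = beta, fit_table = fit_table, labels = labels,
       eigengenes = me, module_trait = mt, scores = scores)
}
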