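# Independent brute-force oracles used to cross-check the package's
# linear-algebra and graph implementations. Deliberately naive (loops,
# BFS, direct summation) and kept free of the code paths they check.

# Triple-loop topological overlap: omega_xy = (l_xy + a_xy) /
# (min(k_x, k_y) + 1 - a_xy), l_xy = sum_u a_xu a_uy, diagonal 1.
tom_oracle <- function(A) {
  n <- nrow(A)
  k <- rowSums(A)
  out <- diag(1, n)
  for (x in seq_len(n)) {
    for (y in seq_len(n)) {
      if (x == y) next
      l <- 0
      for (u in seq_len(n)) l <- l + A[x, u] * A[u, y]
      out[x, y] <- (l + A[x, y]) / (min(k[x], k[y]) + 1 - A[x, y])
    }
  }
  out
}

# Random symmetric adjacency with zero diagonal, entries in [0, 1].
random_adjacency <- function(n) {
  m <- matrix(stats::runif(n * n), n)
  a <- (m + t(m)) / 2
  diag(a) <- 0
  a
}

# Connected components by hand-rolled BFS over an edge data frame.
bfs_components <- function(edges) {
  nodes <- sort(unique(c(edges$geneA, edges$geneB)))
  adj <- lapply(stats::setNames(nodes, nodes), function(x) character(0))
  for (i in seq_len(nrow(edges))) {
    a <- edges$geneA[i]; b <- edges$geneB[i]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  comp <- stats::setNames(rep(NA_integer_, length(nodes)), nodes)
  cid <- 0L
  for (start in nodes) {
    if (!is.na(comp[start])) next
    cid <- cid + 1L
    queue <- start
    comp[start] <- cid
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      for (w in adj[[v]]) {
        if (is.na(comp[w])) {
          comp[w] <- cid
          queue <- c(queue, w)
        }
      }
    }
  }
  split(names(comp), comp)
}

# Direct-summation inverse-variance pooling (fixed and DL random),
# written independently of the package's meta code.
pool_oracle <- function(g, v) {
  w <- 1 / v
  pooled_f <- sum(w * g) / sum(w)
  se_f <- sqrt(1 / sum(w))
  q <- sum(w * (g - pooled_f)^2)
  df <- length(g) - 1
  tau2 <- max(0, (q - df) / (sum(w) - sum(w^2) / sum(w)))
  i2 <- if (q > 0) max(0, (q - df) / q) * 100 else 0
  wr <- 1 / (v + tau2)
  pooled_r <- sum(wr * g) / sum(wr)
  se_r <- sqrt(1 / sum(wr))
  list(fixed = c(pooled = pooled_f, se = se_f),
       random = c(pooled = pooled_r, se = se_r),
       Q = q, df = df, tau2 = tau2, I2 = i2)
}

# Rank-statistic AUC: fraction of (positive, negative) pairs where the
# positive scores higher, ties counted one half.
auc_rank_oracle <- function(score, label) {
  pos <- score[label == 1]
  neg <- score[label == 0]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + (p > q) + 0.5 * (p == q)
  }
  tot / (length(pos) * length(neg))
}

# Random small study list for meta oracle tests.
random_studies <- function(k, n_min = 5, n_max = 40) {
  lapply(seq_len(k), function(i) {
    list(study_id = paste0("s", i),
         case = stats::rnorm(sample(n_min:n_max, 1), mean = stats::runif(1, -1, 1)),
         control = stats::rnorm(sample(n_min:n_max, 1)))
  })
}

# Random edge list (possibly with duplicates/self-loops to exercise
# deduplication).
random_edges <- function(n_nodes, n_edges, messy = FALSE) {
  genes <- sprintf("n%02d", seq_len(n_nodes))
  a <- sample(genes, n_edges, replace = TRUE)
  b <- sample(genes, n_edges, replace = TRUE)
  df <- data.frame(geneA = a, geneB = b, score = stats::runif(n_edges),
                   stringsAsFactors = FALSE)
  if (!messy) df <- df[df$geneA != df$geneB, ]
  df
}
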