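# Interaction-network filtering: confidence-score cutoff, restriction
# to the main connected component, node degrees, high-connectivity
# selection, and the key-gene / high-degree intersection that nominates
# hub genes.

# Canonicalize an edge data frame: drop self-loops, orient pairs
# lexicographically, deduplicate keeping the maximum score.
dedupe_edges <- function(edges) {
  stopifnot(is.data.frame(edges),
            all(c("geneA", "geneB", "score") %in% names(edges)))
  edges$geneA <- as.character(edges$geneA)
  edges$geneB <- as.character(edges$geneB)
  edges <- edges[edges$geneA != edges$geneB, , drop = FALSE]
  a <- pmin(edges$geneA, edges$geneB)
  b <- pmax(edges$geneA, edges$geneB)
  key <- paste(a, b, sep = "\r")
  ord <- order(key, -edges$score)
  keep <- !duplicated(key[ord])
  out <- data.frame(geneA = a[ord][keep], geneB = b[ord][keep],
                    score = edges$score[ord][keep],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Filter interaction edges by confidence score
#'
#' Retains edges with `score >= min_score` — i.e. deletes interactions
#' scored strictly below the cutoff, so a score exactly at the cutoff
#' survives.
#'
#' @param edges Data frame (`geneA`, `geneB`, `score` in `[0, 1]`).
#' @param min_score Confidence cutoff (default 0.4).
#' @return Deduplicated, filtered edge data frame.
#' @export
filter_edges <- function(edges, min_score = 0.4) {
  min_score <- check_fraction(min_score, "min_score")
  edges <- dedupe_edges(edges)
  if (any(edges$score < 0 | edges$score > 1)) {
    stop_input("scores must lie in [0, 1]")
  }
  out <- edges[edges$score >= min_score, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Restrict a network to its main connected component
#'
#' Keeps the subgraph induced by the largest connected component; ties
#' on size are broken by the lexicographically smallest member gene.
#'
#' @param edges Edge data frame (`geneA`, `geneB`, `score`).
#' @return Edge data frame restricted to the main component.
#' @export
main_component <- function(edges) {
  edges <- dedupe_edges(edges)
  if (nrow(edges) == 0) stop_input("graph is empty")
  g <- igraph::graph_from_data_frame(edges[, c("geneA", "geneB")],
                                     directed = FALSE)
  comp <- igraph::components(g)
  sizes <- comp$csize
  best_size <- max(sizes)
  cand <- which(sizes == best_size)
  if (length(cand) > 1) {
    smallest <- vapply(cand, function(ci) {
      min(igraph::V(g)$name[comp$membership == ci])
    }, character(1))
    cand <- cand[which(smallest == min(smallest))[1]]
  }
  keep_nodes <- igraph::V(g)$name[comp$membership == cand]
  out <- edges[edges$geneA %in% keep_nodes & edges$geneB %in% keep_nodes, ,
               drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Node degrees of an undirected network
#'
#' Degree = number of distinct incident neighbors after deduplication.
#'
#' @param edges Edge data frame.
#' @return Named integer vector, sorted by decreasing degree then name.
#' @export
node_degrees <- function(edges) {
  edges <- dedupe_edges(edges)
  nodes <- c(edges$geneA, edges$geneB)
  if (length(nodes) == 0) {
    return(stats::setNames(integer(0), character(0)))
  }
  deg <- table(nodes)
  out <- stats::setNames(as.integer(deg), names(deg))
  out[order(-out, names(out))]
}

#' Select high-connectivity genes
#'
#' @param degrees Named integer vector from [node_degrees()].
#' @param min_degree Inclusive degree cutoff (default 8).
#' @return Character vector of genes with degree >= `min_degree`,
#'   ordered by decreasing degree then name.
#' @export
high_connectivity <- function(degrees, min_degree = 8L) {
  min_degree <- check_count(min_degree, "min_degree", min = 1L)
  keep <- degrees[degrees >= min_degree]
  names(keep)[order(-keep, names(keep))]
}

#' Nominate hub genes: key genes with high network connectivity
#'
#' Intersects the module-screened key genes with the high-connectivity
#' gene list; the result is ordered by decreasing degree (when
#' `degrees` is supplied) then name.
#'
#' @param key_genes Character vector from [screen_key_genes()].
#' @param high_conn Character vector from [high_connectivity()].
#' @param degrees Optional named degree vector used for ordering.
#' @return Character vector of hub genes.
#' @export
hub_intersect <- function(key_genes, high_conn, degrees = NULL) {
  hubs <- intersect(as.character(key_genes), as.character(high_conn))
  if (!is.null(degrees) && length(hubs) > 0) {
    d <- degrees[hubs]
    d[is.na(d)] <- 0L
    hubs <- hubs[order(-d, hubs)]
  } else {
    hubs <- sort(hubs)
  }
  hubs
}
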