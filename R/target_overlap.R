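# Threshold-based selection of differentially expressed genes and
# set intersections with predicted miRNA target lists (the Venn stages
# of a target-discovery screen).

#' Select differentially expressed genes by p-value and fold-change
#'
#' Applies the classical screen: significance below `p_thresh` AND
#' absolute log2 fold-change above `lfc_thresh`, both strict
#' inequalities.
#'
#' @param table Data frame with columns `gene`, `logFC`, `pvalue` and
#'   optionally `qvalue`.
#' @param p_thresh Significance cutoff (default 0.05).
#' @param lfc_thresh Absolute log2 fold-change cutoff (default 1).
#' @param use_q If `TRUE`, threshold the `qvalue` column instead of
#'   `pvalue` (errors if absent). A common alternative preset is
#'   `use_q = TRUE, p_thresh = 0.01`.
#' @return Character vector of selected genes.
#' @export
select_deg <- function(table, p_thresh = 0.05, lfc_thresh = 1, use_q = FALSE) {
  stopifnot(is.data.frame(table),
            all(c("gene", "logFC", "pvalue") %in% names(table)))
  check_flag(use_q, "use_q")
  if (!is.finite(p_thresh) || !is.finite(lfc_thresh) || lfc_thresh < 0) {
    stop_input("thresholds must be finite and `lfc_thresh` >= 0")
  }
  p <- if (use_q) {
    if (!"qvalue" %in% names(table)) {
      stop_input("`use_q = TRUE` but the table has no `qvalue` column")
    }
    table$qvalue
  } else {
    table$pvalue
  }
  as.character(table$gene[p < p_thresh & abs(table$logFC) > lfc_thresh])
}

#' Intersect two or more gene sets
#'
#' @param sets List of at least two character vectors.
#' @return Character vector: the exact intersection (order-independent,
#'   duplicates removed).
#' @export
intersect_sets <- function(sets) {
  stopifnot(is.list(sets))
  if (length(sets) < 2) stop_input("need at least 2 sets to intersect")
  Reduce(intersect, lapply(sets, function(s) unique(as.character(s))))
}

#' Filter predicted targets by database support
#'
#' Retains genes predicted as targets by at least `min_databases`
#' prediction databases (inclusive).
#'
#' @param table Data frame with columns `gene` and `n_databases`.
#' @param min_databases Minimum number of supporting databases (>= 1).
#' @return Character vector of retained genes.
#' @export
filter_targets <- function(table, min_databases = 3L) {
  stopifnot(is.data.frame(table),
            all(c("gene", "n_databases") %in% names(table)))
  min_databases <- check_count(min_databases, "min_databases", min = 1L)
  as.character(table$gene[table$n_databases >= min_databases])
}

#' Overlap differentially expressed genes with predicted targets
#'
#' @param degs Character vector of differentially expressed genes.
#' @param targets Character vector of predicted target genes.
#' @return Character vector: the intersection.
#' @export
overlap_targets <- function(degs, targets) {
  intersect(unique(as.character(degs)), unique(as.character(targets)))
}
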