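# Readers and writers for the pipeline's plain-text interchange formats.
# Expression: TSV, first column gene IDs, header row sample IDs.
# Trait: TSV sample -> numeric trait columns. Edge list: geneA, geneB, score.
# Gene sets: GMT. Survival: sample, time, event, group.

#' Write an expression matrix to TSV
#'
#' @param expr Numeric genes x samples matrix with gene rownames and sample
#'   colnames.
#' @param path Output file path.
#' @export
write_expression_tsv <- function(expr, path) {
  check_expression_matrix(expr)
  df <- data.frame(gene = rownames(expr), expr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an expression matrix from TSV
#'
#' @param path File written by [write_expression_tsv()] (first column gene
#'   ID, remaining columns one sample each).
#' @return Numeric genes x samples matrix.
#' @export
read_expression_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- as.character(df[[1]])
  m
}

#' Write a sample trait table to TSV
#'
#' @param traits Data frame with a `sample` column and one or more numeric
#'   trait columns.
#' @param path Output file path.
#' @export
write_trait_tsv <- function(traits, path) {
  stopifnot(is.data.frame(traits), "sample" %in% names(traits))
  utils::write.table(traits, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample trait table from TSV
#' @param path File written by [write_trait_tsv()].
#' @export
read_trait_tsv <- function(path) {
  utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
}

#' Write a scored edge list to TSV
#'
#' @param edges Data frame with columns `geneA`, `geneB`, `score`.
#' @param path Output file path.
#' @export
write_edges_tsv <- function(edges, path) {
  stopifnot(all(c("geneA", "geneB", "score") %in% names(edges)))
  utils::write.table(edges[, c("geneA", "geneB", "score")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a scored edge list from TSV
#' @param path Three-column TSV (geneA, geneB, score).
#' @export
read_edges_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  names(df)[1:3] <- c("geneA", "geneB", "score")
  df$geneA <- as.character(df$geneA)
  df$geneB <- as.character(df$geneB)
  df$score <- as.numeric(df$score)
  df
}

#' Write a survival table to TSV
#'
#' @param records Data frame with columns `sample`, `time`, `event`
#'   (0/1) and `group` (0/1).
#' @param path Output file path.
#' @export
write_survival_tsv <- function(records, path) {
  stopifnot(all(c("sample", "time", "event", "group") %in% names(records)))
  utils::write.table(records[, c("sample", "time", "event", "group")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a survival table from TSV
#' @param path File written by [write_survival_tsv()].
#' @export
read_survival_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  df$sample <- as.character(df$sample)
  df
}

#' Write gene sets in GMT format
#'
#' One line per set: name, description, then tab-separated members.
#'
#' @param sets Named list of character vectors.
#' @param path Output file path.
#' @param descriptions Optional character vector of per-set descriptions
#'   (defaults to the set name).
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  stopifnot(is.list(sets))
  if (length(sets) > 0 && is.null(names(sets))) {
    stop_input("gene sets must be named")
  }
  if (is.null(descriptions)) descriptions <- names(sets)
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read gene sets from a GMT file
#' @param path GMT file path.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
    parts[-(1:2)]
  })
  names(sets) <- vapply(lines, function(l) {
    strsplit(l, "\t", fixed = TRUE)[[1]][1]
  }, character(1), USE.NAMES = FALSE)
  sets
}

#' Read a differential-expression statistics table from TSV
#'
#' Expected columns: `gene`, `logFC`, `pvalue` and optionally `qvalue`.
#'
#' @param path TSV file path.
#' @export
read_deg_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene", "logFC", "pvalue")
  if (!all(need %in% names(df))) {
    stop_input("differential-expression table needs columns: ",
               paste(need, collapse = ", "))
  }
  df
}

#' Read per-study expression values for meta-analysis (long form)
#'
#' Long-form TSV with columns `study`, `group` (case/control), `value`.
#'
#' @param path TSV file path.
#' @return List of study tables as produced by [generate_multi_study()].
#' @export
read_studies_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("study", "group", "value") %in% names(df)))
  if (!all(df$group %in% c("case", "control"))) {
    stop_input("`group` must be 'case' or 'control'")
  }
  ids <- unique(df$study)
  lapply(ids, function(s) {
    sub <- df[df$study == s, ]
    list(study_id = as.character(s),
         case = sub$value[sub$group == "case"],
         control = sub$value[sub$group == "control"])
  })
}

#' Write per-study expression values (long form)
#' @param studies List of study tables (`study_id`, `case`, `control`).
#' @param path Output file path.
#' @export
write_studies_tsv <- function(studies, path) {
  df <- do.call(rbind, lapply(studies, function(s) {
    data.frame(
      study = s$study_id,
      group = rep(c("case", "control"), c(length(s$case), length(s$control))),
      value = c(s$case, s$control),
      stringsAsFactors = FALSE
    )
  }))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
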