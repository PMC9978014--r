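#' Read an OTU count table from a tab-separated file
#'
#' The expected layout is OTUs as rows (first column = OTU ids, header =
#' sample ids), the conventional export of OTU-clustering pipelines.
#' Orientation is auto-detected: the longer axis is taken to be the OTUs
#' (community surveys have far more taxa than samples); a square table
#' defaults to OTUs-as-rows. Set `orientation` explicitly to override.
#'
#' @param path path to a TSV file.
#' @param min_count drop OTUs whose total count across all samples is
#'   below this value. The default 2 removes singletons, the usual
#'   guard against spurious OTUs.
#' @param orientation `"auto"`, `"otus_rows"` or `"samples_rows"`.
#' @return an [otu_table].
#' @export
read_otu_table <- function(path, min_count = 2,
                           orientation = c("auto", "otus_rows",
                                           "samples_rows")) {
  orientation <- match.arg(orientation)
  stopifnot(min_count >= 0)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(df[[1]])
  header <- names(df)[-1]
  if (anyDuplicated(ids) || anyDuplicated(header))
    stop("duplicated row or column ids in ", path)
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m))
    stop("non-numeric cells in ", path)
  dimnames(m) <- list(ids, header)
  if (any(m < 0)) stop("negative counts in ", path)
  if (orientation == "auto")
    orientation <- if (nrow(m) >= ncol(m)) "otus_rows" else "samples_rows"
  if (orientation == "otus_rows") m <- t(m)
  # rows are now samples
  keep <- colSums(m) >= min_count
  m <- m[, keep, drop = FALSE]
  if (ncol(m) == 0) stop("no OTUs left after min_count filtering")
  if (any(rowSums(m) == 0))
    stop("sample(s) empty after filtering: ",
         paste(rownames(m)[rowSums(m) == 0], collapse = ", "))
  otu_table(m)
}

#' Read a rooted phylogeny with branch lengths
#'
#' Thin wrapper over [ape::read.tree()] with the validity checks the
#' downstream phylogenetic null models rely on: labelled tips, unique
#' labels, non-negative branch lengths.
#'
#' @param path path to a newick file.
#' @return an [ape::phylo] object.
#' @export
read_tree <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  if (!grepl("(", txt, fixed = TRUE))  # single-tip newick like "A:0;"
    txt <- paste0("(", sub(";\\s*$", "", txt), ");")
  tree <- tryCatch(ape::read.tree(text = txt),
                   error = function(e) stop("malformed newick in ", path,
                                            ": ", conditionMessage(e)))
  if (is.null(tree)) stop("malformed newick in ", path)
  if (is.null(tree$tip.label) || any(!nzchar(tree$tip.label)))
    stop("tree has unlabeled tips")
  if (anyDuplicated(tree$tip.label))
    stop("duplicated tip labels")
  if (is.null(tree$edge.length))
    stop("tree has no branch lengths")
  if (any(tree$edge.length < 0))
    stop("negative branch lengths")
  tree
}

#' Read a per-sample environmental table
#'
#' CSV with samples as rows (first column = sample ids) and one column
#' per environmental variable. Non-numeric cells become `NA` with a
#' warning; they are handled pairwise-complete downstream, never
#' imputed. Zero-variance columns are kept but flagged in the
#' `"zero_variance"` attribute.
#'
#' @param path path to a CSV file.
#' @return a numeric data.frame, rownames = sample ids.
#' @export
read_env_table <- function(path) {
  df <- utils::read.csv(path, header = TRUE, check.names = FALSE,
                        stringsAsFactors = FALSE)
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids)) stop("duplicated sample ids in ", path)
  df <- df[, -1, drop = FALSE]
  out <- as.data.frame(lapply(df, function(col) {
    if (is.numeric(col)) return(col)
    suppressWarnings(num <- as.numeric(col))
    if (anyNA(num) && !all(is.na(num) == is.na(col)))
      warning("non-numeric cells coerced to NA")
    num
  }), check.names = FALSE)
  rownames(out) <- ids
  all_na <- vapply(out, function(v) all(is.na(v)), logical(1))
  if (any(all_na))
    stop("all-missing column(s): ", paste(names(out)[all_na], collapse = ", "))
  zv <- vapply(out, function(v) stats::var(v, na.rm = TRUE) == 0, logical(1))
  zv[is.na(zv)] <- FALSE
  attr(out, "zero_variance") <- names(out)[zv]
  out
}

#' Align an environmental table to an OTU table
#'
#' Exact, case-sensitive id matching; errors when the two share no
#' samples.
#'
#' @param env data.frame from [read_env_table()].
#' @param table an [otu_table].
#' @return `env` restricted and reordered to the table's samples.
#' @export
align_env <- function(env, table) {
  shared <- intersect(rownames(table$counts), rownames(env))
  if (length(shared) == 0)
    stop("no overlap between environmental and OTU table sample ids")
  env[shared, , drop = FALSE]
}

fmt6 <- function(x) {
  if (is.numeric(x)) signif(x, 6) else x
}

#' Write a result to disk
#'
#' Deterministic writers: numeric values are rounded to 6 significant
#' digits and list keys are sorted, so identical inputs yield
#' byte-identical files.
#'
#' @param result a data.frame/matrix (`tsv`), list (`json`) or
#'   `cooccurrence_network` (`graphml`).
#' @param path output file path.
#' @param format one of `"json"`, `"tsv"`, `"graphml"`.
#' @return invisibly, `path`.
#' @export
write_results <- function(result, path, format = c("json", "tsv", "graphml")) {
  format <- match.arg(format)
  if (format == "graphml") {
    if (!inherits(result, "cooccurrence_network"))
      stop("graphml output is only supported for networks")
    igraph::write_graph(result$graph, path, format = "graphml")
  } else if (format == "tsv") {
    if (is.matrix(result))
      result <- data.frame(id = rownames(result), fmt6(result),
                           check.names = FALSE)
    else if (is.data.frame(result))
      result[] <- lapply(result, fmt6)
    else stop("tsv output needs a data.frame or matrix")
    utils::write.table(result, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    jsonlite::write_json(round_rec(result), path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  invisible(path)
}

# recursive 6-significant-digit rounding with sorted keys, for stable JSON
round_rec <- function(x) {
  if (is.atomic(x) && !is.null(names(x))) x <- as.list(x)
  if (is.list(x)) {
    if (!is.null(names(x)) && all(nzchar(names(x))))
      x <- x[order(names(x))]
    lapply(x, round_rec)
  } else if (is.matrix(x)) {
    signif(x, 6)
  } else if (is.numeric(x)) {
    signif(x, 6)
  } else x
}

#' Read a numeric square matrix written as TSV
#'
#' Counterpart of `write_results(..., format = "tsv")` for pairwise
#' matrices (e.g. betaNTI): first column row ids, header column ids.
#'
#' @param path TSV path.
#' @return numeric matrix with dimnames.
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  m
}
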