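#' Construct an OTU count table
#'
#' The central container of the package: a non-negative integer count
#' matrix with samples as rows and OTUs as columns, optionally annotated
#' with a taxonomy string per OTU and a habitat (group) label per sample.
#'
#' @param counts numeric matrix of non-negative integer counts, rows =
#'   samples, columns = OTUs; must carry unique row and column names.
#' @param taxonomy optional named character vector, names = OTU ids.
#' @param habitat optional named character vector, names = sample ids,
#'   values = group labels (e.g. fruiting body vs mycosphere).
#' @return an object of class `otu_table`: a list with elements
#'   `counts`, `taxonomy`, `habitat`.
#' @examples
#' m <- matrix(c(5L, 0L, 3L, 2L, 4L, 1L), nrow = 2,
#'             dimnames = list(c("s1", "s2"), c("otu1", "otu2", "otu3")))
#' tab <- otu_table(m)
#' n_samples(tab)
#' @export
otu_table <- function(counts, taxonomy = NULL, habitat = NULL) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("`counts` must have sample (row) and OTU (column) names")
  if (anyDuplicated(rownames(counts)))
    stop("duplicated sample ids: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]),
               collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    stop("duplicated OTU ids: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]),
               collapse = ", "))
  if (!is.numeric(counts) || anyNA(counts))
    stop("counts must be numeric and complete")
  if (any(counts < 0)) stop("negative counts are not allowed")
  if (any(abs(counts - round(counts)) > 1e-8))
    stop("counts must be integers (got fractional values); ",
         "relative abundances are computed, never stored")
  storage.mode(counts) <- "integer"
  if (any(rowSums(counts) == 0))
    stop("empty sample(s): ",
         paste(rownames(counts)[rowSums(counts) == 0], collapse = ", "))
  if (!is.null(taxonomy)) {
    taxonomy <- taxonomy[intersect(names(taxonomy), colnames(counts))]
  }
  if (!is.null(habitat)) {
    if (!all(rownames(counts) %in% names(habitat)))
      stop("habitat labels missing for some samples")
    habitat <- habitat[rownames(counts)]
  }
  structure(list(counts = counts, taxonomy = taxonomy, habitat = habitat),
            class = "otu_table")
}

#' @export
print.otu_table <- function(x, ...) {
  cat("otu_table:", nrow(x$counts), "samples x", ncol(x$counts), "OTUs\n")
  if (!is.null(x$habitat))
    cat("habitats:", paste(names(table(x$habitat)), table(x$habitat),
                           sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' @rdname otu_table
#' @param x an `otu_table`.
#' @export
n_samples <- function(x) nrow(x$counts)

#' @rdname otu_table
#' @export
n_otus <- function(x) ncol(x$counts)

#' Subset an OTU table
#'
#' @param x an `otu_table`.
#' @param samples,otus character vectors of ids to keep (default: all).
#' @param drop_empty drop samples whose total becomes zero (default
#'   FALSE: an empty sample raises an error, mirroring the constructor).
#' @return an `otu_table` restricted to the requested ids.
#' @export
subset_otu_table <- function(x, samples = rownames(x$counts),
                             otus = colnames(x$counts),
                             drop_empty = FALSE) {
  stopifnot(inherits(x, "otu_table"))
  missing_s <- setdiff(samples, rownames(x$counts))
  missing_o <- setdiff(otus, colnames(x$counts))
  if (length(missing_s) || length(missing_o))
    stop("unknown ids: ", paste(c(missing_s, missing_o), collapse = ", "))
  m <- x$counts[samples, otus, drop = FALSE]
  if (drop_empty) m <- m[rowSums(m) > 0, , drop = FALSE]
  otu_table(m,
            taxonomy = x$taxonomy,
            habitat = if (!is.null(x$habitat)) x$habitat[rownames(m)])
}

#' Within-sample relative abundances
#'
#' Converts counts to row-stochastic proportions P_ij, the proportion of
#' OTU j in community i. Proportions are always derived on demand from
#' counts and never stored in files.
#'
#' @param table an `otu_table`, or a numeric matrix (samples x OTUs).
#' @return numeric matrix of proportions; each row sums to 1.
#' @export
relative_abundance <- function(table) {
  m <- if (inherits(table, "otu_table")) table$counts else as.matrix(table)
  rs <- rowSums(m)
  if (any(rs == 0))
    stop("zero-total sample(s): ",
         paste(rownames(m)[rs == 0], collapse = ", "))
  m / rs
}
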