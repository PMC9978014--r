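#' Prevalence filter
#'
#' Keeps OTUs detected (nonzero count) in at least
#' `ceiling(min_fraction * n_samples)` samples — the usual guard before
#' correlation networks, where rarely-observed OTUs produce unstable
#' rank correlations.
#'
#' @param table an [otu_table].
#' @param min_fraction minimum fraction of samples (default 2/3).
#' @return the filtered [otu_table].
#' @export
prevalence_filter <- function(table, min_fraction = 2 / 3) {
  stopifnot(inherits(table, "otu_table"),
            min_fraction > 0, min_fraction <= 1)
  need <- ceiling(min_fraction * nrow(table$counts))
  keep <- colSums(table$counts > 0) >= need
  if (!any(keep)) stop("no OTU passes the prevalence filter")
  subset_otu_table(table, otus = colnames(table$counts)[keep])
}

# all-pairs Spearman with t-approximation p-values (average-rank ties)
spearman_matrix <- function(m) {
  n <- nrow(m)
  ranks <- apply(m, 2, rank)
  r <- stats::cor(ranks)
  r[r > 1] <- 1; r[r < -1] <- -1
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  p[abs(r) == 1] <- 0
  list(r = r, p = p)
}

#' Build a thresholded Spearman co-occurrence network
#'
#' All-pairs Spearman rank correlation between OTUs across samples
#' (average-rank tie handling; p from the t-distribution
#' approximation); an edge is kept when |r| > `r_min` and p < `p_max`
#' (both strict). Zero-variance OTUs are excluded before correlation,
#' and OTUs without any retained edge do not appear as nodes.
#'
#' @param table an [otu_table] with at least 4 samples (typically
#'   pre-filtered with [prevalence_filter()]).
#' @param r_min minimum |Spearman r| (default 0.8).
#' @param p_max maximum p-value (default 0.01).
#' @param correction `"none"` (default; raw p as the threshold is
#'   conventionally applied) or `"bh"` for Benjamini-Hochberg over all
#'   OTU pairs.
#' @param use_relative correlate relative abundances instead of counts
#'   (identical unless sequencing depths differ, since ranks are
#'   depth-invariant within a sample only under equal depths).
#' @return object of class `cooccurrence_network`: `graph` (igraph,
#'   with `r`, `p`, `sign` edge attributes and `|r|` as `weight`),
#'   `edges` and `nodes` data.frames, `params`.
#' @export
build_network <- function(table, r_min = 0.8, p_max = 0.01,
                          correction = c("none", "bh"),
                          use_relative = FALSE) {
  correction <- match.arg(correction)
  stopifnot(inherits(table, "otu_table"))
  m <- if (use_relative) relative_abundance(table) else table$counts
  if (nrow(m) < 4) stop("need at least 4 samples for Spearman p-values")
  zv <- apply(m, 2, function(x) stats::var(x) == 0)
  if (any(zv)) {
    warning("excluding ", sum(zv), " zero-variance OTU(s)")
    m <- m[, !zv, drop = FALSE]
  }
  sp <- spearman_matrix(m)
  ut <- upper.tri(sp$r)
  if (correction == "bh")
    sp$p[ut] <- stats::p.adjust(sp$p[ut], method = "BH")
  keep <- ut & abs(sp$r) > r_min & sp$p < p_max
  idx <- which(keep, arr.ind = TRUE)
  otus <- colnames(m)
  edges <- data.frame(
    otu1 = otus[idx[, 1]], otu2 = otus[idx[, 2]],
    r = sp$r[keep], p = sp$p[keep],
    sign = ifelse(sp$r[keep] > 0, "positive", "negative"),
    row.names = NULL)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = otus))
  g <- igraph::delete_vertices(g, igraph::degree(g) == 0)
  igraph::E(g)$weight <- abs(igraph::E(g)$r)
  nodes <- data.frame(otu_id = igraph::V(g)$name,
                      degree = unname(igraph::degree(g)),
                      row.names = NULL)
  structure(list(graph = g, edges = edges, nodes = nodes,
                 params = list(r_min = r_min, p_max = p_max,
                               correction = correction,
                               use_relative = use_relative)),
            class = "cooccurrence_network")
}

#' @export
print.cooccurrence_network <- function(x, ...) {
  cat("co-occurrence network:", nrow(x$nodes), "nodes,",
      nrow(x$edges), "edges",
      sprintf("(|r| > %g, p < %g)\n", x$params$r_min, x$params$p_max))
  invisible(x)
}

#' Network topology summary
#'
#' The usual co-occurrence descriptors: average degree AD = 2E/V,
#' average (local) clustering coefficient ACC with nodes of degree < 2
#' contributing 0, average path distance APD (mean unweighted shortest
#' path within the largest connected component), graph density
#' GD = 2E/(V(V-1)), and modularity from Louvain community detection.
#' Louvain depends on vertex order, so it is rerun `n_restarts` times
#' under seeded vertex permutations; the mean and sd of modularity and
#' the best partition's module labels are reported.
#'
#' @param net a `cooccurrence_network` with at least one edge.
#' @param n_restarts modularity restarts (default 20).
#' @param seed integer seed.
#' @return list: `n_nodes`, `n_edges`, `average_degree`,
#'   `clustering_coefficient`, `path_distance`, `density`,
#'   `modularity_mean`, `modularity_sd`, `n_modules`, `module_sizes`,
#'   `modules` (named membership vector of the best partition),
#'   `component_coverage` (fraction of nodes in the largest component),
#'   `edge_sign_fractions`.
#' @export
topology <- function(net, n_restarts = 20, seed = 1L) {
  stopifnot(inherits(net, "cooccurrence_network"))
  g <- net$graph
  v <- igraph::vcount(g)
  e <- igraph::ecount(g)
  if (e == 0) stop("empty network")
  gu <- igraph::delete_edge_attr(g, "weight")  # topology is unweighted
  comp <- igraph::components(gu)
  giant <- igraph::induced_subgraph(
    gu, which(comp$membership == which.max(comp$csize)))
  acc <- mean(igraph::transitivity(gu, type = "localundirected",
                                   isolates = "zero"))
  set.seed(seed)
  mods <- numeric(n_restarts)
  best <- NULL
  for (k in seq_len(n_restarts)) {
    perm <- sample.int(v)
    gp <- igraph::permute(gu, perm)
    cl <- igraph::cluster_louvain(gp)
    mods[k] <- igraph::modularity(cl)
    memb <- igraph::membership(cl)[perm]  # back to original order
    if (is.null(best) || mods[k] > max(mods[seq_len(k - 1)]))
      best <- memb
  }
  names(best) <- igraph::V(gu)$name
  sign_tab <- table(factor(net$edges$sign, c("positive", "negative")))
  list(n_nodes = v, n_edges = e,
       average_degree = 2 * e / v,
       clustering_coefficient = acc,
       path_distance = igraph::mean_distance(giant, unconnected = FALSE),
       density = 2 * e / (v * (v - 1)),
       modularity_mean = mean(mods),
       modularity_sd = stats::sd(mods),
       n_modules = length(unique(best)),
       module_sizes = as.integer(sort(table(best), decreasing = TRUE)),
       modules = best,
       component_coverage = max(comp$csize) / v,
       edge_sign_fractions = as.numeric(sign_tab) / e)
}

#' Annotate network nodes with external classifications
#'
#' Attaches abundance class, niche category, taxonomy and module id to
#' each node and summarises the composition. Ids that cannot be
#' resolved are labelled `"unknown"`.
#'
#' @param net a `cooccurrence_network`.
#' @param classification optional [classify_abundance()] result.
#' @param niche optional [classify_specialists()] result.
#' @param taxonomy optional named character vector otu_id -> lineage.
#' @param modules optional named membership vector (from [topology()]).
#' @return the network with an augmented `nodes` data.frame, node
#'   attributes set on `graph`, and a `node_fractions` list of
#'   per-class node shares.
#' @export
annotate_nodes <- function(net, classification = NULL, niche = NULL,
                           taxonomy = NULL, modules = NULL) {
  stopifnot(inherits(net, "cooccurrence_network"))
  ids <- net$nodes$otu_id
  pull <- function(map) {
    out <- unname(map[ids])
    out[is.na(out)] <- "unknown"
    out
  }
  fracs <- list()
  if (!is.null(classification)) {
    net$nodes$abundance_class <- pull(classification$category)
    fracs$abundance_class <-
      table(net$nodes$abundance_class) / length(ids)
  }
  if (!is.null(niche)) {
    map <- stats::setNames(niche$taxa$category, niche$taxa$otu_id)
    net$nodes$niche_category <- pull(map)
    fracs$niche_category <-
      table(net$nodes$niche_category) / length(ids)
  }
  if (!is.null(taxonomy)) {
    net$nodes$taxonomy <- pull(taxonomy)
    fracs$taxonomy <- table(net$nodes$taxonomy) / length(ids)
  }
  if (!is.null(modules)) {
    mm <- modules[ids]
    net$nodes$module <- unname(mm)
  }
  for (col in setdiff(names(net$nodes), c("otu_id", "degree")))
    net$graph <- igraph::set_vertex_attr(net$graph, col,
                                         value = net$nodes[[col]])
  net$node_fractions <- lapply(fracs, function(x) {
    v <- as.numeric(x); names(v) <- names(x); v
  })
  net
}
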