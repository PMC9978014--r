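# Independent brute-force oracles and tiny fixture builders.
# These deliberately re-derive every quantity from first principles so
# they share no code with the implementation under test.

make_table <- function(m, ...) {
  if (is.null(rownames(m))) rownames(m) <- sprintf("s%d", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- sprintf("o%d", seq_len(ncol(m)))
  otu_table(m, ...)
}

random_table <- function(n_s, n_o, seed, lambda = 5) {
  set.seed(seed)
  m <- matrix(rpois(n_s * n_o, lambda), n_s, n_o)
  m[1, ] <- m[1, ] + 1  # guard against empty samples
  make_table(m)
}

# Bray-Curtis from the definition: sum |x-y| / sum (x+y)
brute_bray <- function(x, y) sum(abs(x - y)) / sum(x + y)

# abundance-weighted betaMNTD: explicit double loop over present OTUs
brute_beta_mntd <- function(rel, d, s1, s2) {
  a <- which(rel[s1, ] > 0)
  b <- which(rel[s2, ] > 0)
  ids <- colnames(rel)
  term1 <- sum(vapply(a, function(j)
    rel[s1, j] * min(d[ids[j], ids[b]]), numeric(1)))
  term2 <- sum(vapply(b, function(j)
    rel[s2, j] * min(d[ids[j], ids[a]]), numeric(1)))
  0.5 * (term1 + term2)
}

# Levins' B from the definition
brute_levins <- function(p) {
  q <- p / sum(p)
  1 / sum(q^2)
}

toy_tree <- function() ape::read.tree(text = "((A:1,B:1):1,C:2);")

# all permutations of 1..n (n small), as a list
combinat_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in combinat_perms(n - 1))
    for (k in 0:(n - 1))
      out[[length(out) + 1]] <- append(p, n, after = k)
  out
}

# wrap an edge list into the network container so topology() can be
# exercised on hand-built graphs
toy_network <- function(edges) {
  g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  igraph::E(g)$r <- edges$r
  igraph::E(g)$p <- edges$p
  igraph::E(g)$weight <- abs(edges$r)
  structure(list(graph = g, edges = edges,
                 nodes = data.frame(otu_id = igraph::V(g)$name,
                                    degree = unname(igraph::degree(g))),
                 params = list(r_min = 0.8, p_max = 0.01,
                               correction = "none",
                               use_relative = FALSE)),
            class = "cooccurrence_network")
}

plain_edges <- function(pairs) {
  data.frame(otu1 = pairs[, 1], otu2 = pairs[, 2],
             r = 1, p = 1e-6, sign = "positive")
}

write_toy_otu_tsv <- function(path, m) {
  df <- data.frame(otu_id = colnames(m), t(m), check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}
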