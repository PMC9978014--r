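test_that("prevalence filter applies the two-thirds rule", {
  set.seed(6)
  m <- matrix(rpois(12 * 4, 3) + 1L, 12, 4)
  m[9:12, 2] <- 0L   # present in 8 of 12
  m[8:12, 3] <- 0L   # present in 7 of 12
  m[2:12, 4] <- 0L
  tab <- make_table(m)
  filt <- prevalence_filter(tab, 2 / 3)
  expect_true(all(c("o1", "o2") %in% colnames(filt$counts)))
  expect_false(any(c("o3", "o4") %in% colnames(filt$counts)))

  all_present <- prevalence_filter(tab, 1)
  expect_equal(colnames(all_present$counts), "o1")
  expect_error(prevalence_filter(make_table(diag(3) + 0L) , 1), "no OTU")
})

test_that("perfectly concordant and discordant OTUs form signed edges", {
  x <- c(1L, 3L, 5L, 7L, 9L, 11L, 13L, 15L, 17L, 19L, 21L, 23L)
  m <- cbind(up1 = x, up2 = x * 2L + 1L, down = rev(x) * 3L)
  rownames(m) <- paste0("s", 1:12)
  net <- build_network(make_table(m), r_min = 0.8, p_max = 0.01)
  e <- net$edges
  key <- paste(e$otu1, e$otu2)
  expect_equal(e$r[key == "up1 up2"], 1)
  expect_equal(e$sign[key == "up1 up2"], "positive")
  expect_equal(e$r[key == "up1 down"], -1)
  expect_equal(e$sign[key == "up1 down"], "negative")
})

test_that("edge set equals brute-force all-pairs Spearman filtering", {
  tab <- random_table(12, 10, seed = 14, lambda = 6)
  suppressWarnings(net <- build_network(tab, r_min = 0.6, p_max = 0.05))
  m <- tab$counts
  keep <- apply(m, 2, var) > 0
  m <- m[, keep, drop = FALSE]
  expected <- character(0)
  for (i in seq_len(ncol(m) - 1)) for (j in (i + 1):ncol(m)) {
    ct <- suppressWarnings(
      cor.test(m[, i], m[, j], method = "spearman", exact = FALSE))
    if (abs(ct$estimate) > 0.6 && ct$p.value < 0.05)
      expected <- c(expected, paste(colnames(m)[i], colnames(m)[j]))
  }
  got <- paste(net$edges$otu1, net$edges$otu2)
  expect_setequal(got, expected)

  # row/column permutations of the table leave the edge set unchanged
  perm <- sample(ncol(tab$counts))
  tab_p <- otu_table(tab$counts[sample(nrow(tab$counts)), perm])
  suppressWarnings(net_p <- build_network(tab_p, r_min = 0.6, p_max = 0.05))
  expect_setequal(
    paste(pmin(net$edges$otu1, net$edges$otu2),
          pmax(net$edges$otu1, net$edges$otu2)),
    paste(pmin(net_p$edges$otu1, net_p$edges$otu2),
          pmax(net_p$edges$otu1, net_p$edges$otu2)))
})

test_that("tightening thresholds never adds edges", {
  tab <- random_table(12, 15, seed = 23, lambda = 4)
  edge_key <- function(r_min, p_max) {
    suppressWarnings(n <- build_network(tab, r_min = r_min, p_max = p_max))
    paste(n$edges$otu1, n$edges$otu2)
  }
  loose <- edge_key(0.4, 0.2)
  expect_true(all(edge_key(0.6, 0.2) %in% loose))
  expect_true(all(edge_key(0.4, 0.02) %in% loose))
  expect_true(all(edge_key(0.8, 0.01) %in% edge_key(0.6, 0.05)))
})

test_that("topology metrics are exact on hand-computed graphs", {
  k3 <- toy_network(plain_edges(cbind(c("a", "b", "c"), c("b", "c", "a"))))
  t3 <- topology(k3, n_restarts = 5, seed = 1)
  expect_equal(t3$average_degree, 2)
  expect_equal(t3$clustering_coefficient, 1)
  expect_equal(t3$path_distance, 1)
  expect_equal(t3$density, 1)

  path <- toy_network(plain_edges(cbind(c("a", "b"), c("b", "c"))))
  tp <- topology(path, n_restarts = 5, seed = 1)
  expect_equal(tp$average_degree, 4 / 3)
  expect_equal(tp$clustering_coefficient, 0)
  expect_equal(tp$path_distance, 4 / 3)
  expect_equal(tp$density, 2 / 3)
  expect_equal(tp$component_coverage, 1)
})

test_that("modularity restarts recover planted cliques reproducibly", {
  clique <- function(prefix) {
    v <- paste0(prefix, 1:5)
    t(combn(v, 2))
  }
  edges <- plain_edges(rbind(clique("a"), clique("b"),
                             cbind("a1", "b1")))
  net <- toy_network(edges)
  topo <- topology(net, n_restarts = 20, seed = 9)
  memb <- topo$modules
  expect_equal(length(unique(memb[paste0("a", 1:5)])), 1)
  expect_equal(length(unique(memb[paste0("b", 1:5)])), 1)
  expect_false(memb["a1"] == memb["b1"])
  expect_lt(topo$modularity_sd, 0.05)

  # bitwise-stable given the seed
  topo2 <- topology(net, n_restarts = 20, seed = 9)
  expect_identical(topo$modules, topo2$modules)
  expect_identical(topo$modularity_mean, topo2$modularity_mean)
})

test_that("node annotation reports hand-countable fractions", {
  net <- toy_network(plain_edges(cbind(c("a", "b", "c"), c("b", "c", "d"))))
  cls <- list(category = c(a = "abundant", b = "abundant",
                           c = "rare", d = "rare"))
  class(cls) <- "abundance_classification"
  niche <- list(taxa = data.frame(
    otu_id = c("a", "b", "c"),
    category = c("generalist", "neutral", "neutral")))
  class(niche) <- "niche_breadth_result"
  ann <- annotate_nodes(net, classification = cls, niche = niche)
  expect_equal(ann$node_fractions$abundance_class[["abundant"]], 0.5)
  expect_equal(ann$node_fractions$abundance_class[["rare"]], 0.5)
  expect_equal(sum(ann$node_fractions$niche_category), 1)
  expect_equal(ann$node_fractions$niche_category[["unknown"]], 0.25)

  all_ab <- annotate_nodes(net, classification = list(
    category = c(a = "abundant", b = "abundant", c = "abundant",
                 d = "abundant")))
  expect_equal(all_ab$node_fractions$abundance_class[["abundant"]], 1)
})
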