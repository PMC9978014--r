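test_that("relative abundance is row-stochastic", {
  tab <- make_table(matrix(c(2L, 2L, 0L, 0L), nrow = 1))
  expect_equal(unname(relative_abundance(tab)[1, ]), c(0.5, 0.5, 0, 0))

  tab1 <- make_table(matrix(c(7L), nrow = 1))
  expect_equal(unname(relative_abundance(tab1)[1, 1]), 1)

  tab2 <- random_table(6, 20, seed = 3)
  expect_equal(unname(rowSums(relative_abundance(tab2))), rep(1, 6))

  m <- matrix(c(1L, 0L, 0L, 0L), nrow = 2)
  dimnames(m) <- list(c("a", "b"), c("x", "y"))
  expect_error(otu_table(m), "empty sample")
})

test_that("abundant/rare partition respects the 0.01% boundary", {
  # three OTUs with mean relative abundance 0.02%, 0.005%, exactly 0.01%
  rel <- matrix(c(2e-4, 5e-5, 1e-4), nrow = 4, ncol = 3, byrow = TRUE)
  rel <- cbind(rel, 1 - rowSums(rel))
  colnames(rel) <- c("mid", "low", "edge", "dominant")
  rownames(rel) <- paste0("s", 1:4)
  cls <- classify_abundance(rel)
  expect_equal(unname(cls$category[c("mid", "low", "edge", "dominant")]),
               c("abundant", "rare", "abundant", "abundant"))
  expect_equal(sum(cls$otu_fraction), 1)
  expect_equal(sum(cls$abundance_fraction), 1)
})

test_that("raising the threshold never grows the abundant set", {
  rel <- relative_abundance(random_table(8, 60, seed = 11, lambda = 2))
  prev <- NULL
  for (thr in c(1e-4, 1e-3, 1e-2, 5e-2)) {
    ab <- names(which(classify_abundance(rel, thr)$category == "abundant"))
    if (!is.null(prev)) expect_true(all(ab %in% prev))
    prev <- ab
  }
  # per-sample-max scope is at least as inclusive as the mean scope
  ab_mean <- classify_abundance(rel, 1e-3)$category == "abundant"
  ab_max <- classify_abundance(rel, 1e-3, scope = "per_sample_max")$category == "abundant"
  expect_true(all(ab_max[ab_mean]))
})

test_that("alpha diversity closed forms hold", {
  uni <- make_table(matrix(rep(5L, 8), nrow = 1))
  d <- alpha_diversity(uni)
  expect_equal(d$richness, 8)
  expect_equal(d$shannon, log(8))
  expect_equal(d$pielou, 1)
  expect_equal(d$chao1, 8)  # no singletons

  # S_obs = 10, F1 = 5, F2 = 2 -> classic Chao1 = 10 + 25/4
  x <- c(rep(1L, 5), rep(2L, 2), 5L, 8L, 13L)
  tab <- make_table(matrix(x, nrow = 1))
  expect_equal(alpha_diversity(tab)$chao1, 16.25)
  expect_equal(alpha_diversity(tab)$richness, 10)

  # F2 = 0 switches to the bias-corrected form
  x2 <- c(rep(1L, 4), 5L, 9L)
  expect_equal(alpha_diversity(make_table(matrix(x2, nrow = 1)))$chao1,
               6 + 4 * 3 / 2)
  # F1 = 0, F2 = 0 -> Chao1 = S_obs
  x3 <- c(4L, 5L, 9L)
  expect_equal(alpha_diversity(make_table(matrix(x3, nrow = 1)))$chao1, 3)

  # estimators never fall below observed richness
  tab_r <- random_table(5, 40, seed = 9, lambda = 1)
  dr <- alpha_diversity(tab_r)
  expect_true(all(dr$chao1 >= dr$richness))
  expect_true(all(dr$ace >= dr$richness - 1e-9, na.rm = TRUE))
  expect_true(all(dr$shannon >= 0))
})

test_that("group comparisons separate what is separated", {
  # identical groups: F = 0, p = 1, shared letter
  v <- rep(c(1, 2, 3, 4), 2)
  g <- rep(c("a", "b"), each = 4)
  res <- compare_groups(v, g)
  expect_gt(res$p.value, 0.99)
  expect_equal(unname(res$letters["a"]), unname(res$letters["b"]))

  # two groups ten sd apart
  set.seed(1)
  v2 <- c(rnorm(6), rnorm(6, mean = 10))
  res2 <- compare_groups(v2, rep(c("a", "b"), each = 6))
  expect_lt(res2$p.value, 1e-3)
  expect_false(res2$letters["a"] == res2$letters["b"])

  # three groups, one shifted: the shifted one gets its own letter
  set.seed(2)
  v3 <- c(rnorm(6), rnorm(6), rnorm(6, mean = 10))
  g3 <- rep(c("a", "b", "c"), each = 6)
  res3 <- compare_groups(v3, g3)
  expect_equal(res3$method, "anova_tukey")
  expect_lt(res3$p.value, 1e-3)
  expect_equal(unname(res3$letters["a"]), unname(res3$letters["b"]))
  expect_false(res3$letters["c"] %in% res3$letters[c("a", "b")])
  expect_equal(nrow(res3$pairwise), 3)
})

test_that("PCoA reproduces Bray-Curtis geometry", {
  m <- matrix(c(5L, 0L, 2L, 1L,
                5L, 0L, 2L, 1L,   # duplicate of sample 1
                0L, 7L, 1L, 0L,
                2L, 2L, 2L, 2L), nrow = 4, byrow = TRUE)
  tab <- make_table(m)
  ord <- pcoa_bray(tab)
  expect_equal(ord$distances["s1", "s2"], 0)
  expect_equal(ord$scores["s1", ], ord$scores["s2", ])

  disjoint <- make_table(matrix(c(1L, 0L, 0L, 1L, 1L, 1L), nrow = 3,
                                byrow = TRUE))
  expect_equal(pcoa_bray(disjoint)$distances["s1", "s2"], 1)

  # brute-force Bray-Curtis on a random 4-sample toy
  tab2 <- random_table(4, 12, seed = 5)
  d <- pcoa_bray(tab2)$distances
  for (i in 1:3) for (j in (i + 1):4)
    expect_equal(d[i, j], brute_bray(tab2$counts[i, ], tab2$counts[j, ]),
                 tolerance = 1e-12)

  # full-dimension scores reconstruct the distances when no negative
  # eigenvalues were clipped
  ord2 <- pcoa_bray(tab2)
  if (ord2$negative_eigenvalues == 0) {
    rec <- as.matrix(dist(ord2$scores))
    expect_equal(unname(rec), unname(ord2$distances), tolerance = 1e-6)
  }
  expect_true(all(diff(ord2$explained) <= 1e-12))
  expect_error(pcoa_bray(make_table(matrix(c(1L, 2L), 2, 1))), "3 samples")
})
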