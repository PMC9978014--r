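test_that("betaMNTD matches hand path-sums and brute force", {
  tree <- toy_tree()  # ((A:1,B:1):1,C:2)
  rel <- matrix(c(1, 0, 0,
                  0, 1, 0), 2, 3, byrow = TRUE,
                dimnames = list(c("x", "y"), c("A", "B", "C")))
  expect_equal(beta_mntd(rel, tree, c("x", "y")), 2)

  # identical profiles share every OTU -> 0
  rel2 <- rbind(x = c(A = 0.5, B = 0.5, C = 0), y = c(0.5, 0.5, 0))
  colnames(rel2) <- c("A", "B", "C")
  expect_equal(beta_mntd(rel2, tree, c("x", "y")), 0)

  # brute-force double loop on random toys, plus symmetry
  for (s in 1:10) {
    set.seed(s)
    nt <- 8
    tr <- ape::rphylo(nt, 1, 0)
    tr$tip.label <- paste0("t", 1:nt)
    m <- matrix(rpois(4 * nt, 2), 4, nt,
                dimnames = list(paste0("s", 1:4), tr$tip.label))
    m[rowSums(m) == 0, 1] <- 1
    rel3 <- m / rowSums(m)
    d <- ape::cophenetic.phylo(tr)
    full <- beta_mntd(rel3, tr)
    expect_equal(full, t(full))
    for (i in 1:3) for (j in (i + 1):4)
      expect_equal(full[i, j],
                   brute_beta_mntd(rel3, d, i, j), tolerance = 1e-10)
  }
})

test_that("betaMNTD agrees with an independent phylogenetics library", {
  skip_if_not_installed("picante")
  set.seed(8)
  tr <- ape::rphylo(15, 1, 0)
  tr$tip.label <- paste0("t", 1:15)
  m <- matrix(rpois(6 * 15, 3), 6, 15,
              dimnames = list(paste0("s", 1:6), tr$tip.label))
  m[rowSums(m) == 0, 1] <- 1
  rel <- m / rowSums(m)
  ours <- beta_mntd(rel, tr)
  ref <- as.matrix(picante::comdistnt(m, ape::cophenetic.phylo(tr),
                                      abundance.weighted = TRUE))
  expect_equal(unname(ours), unname(ref), tolerance = 1e-10)
})

test_that("Monte-Carlo betaNTI approaches the exhaustive tip-shuffle value", {
  tree <- ape::read.tree(text = "((A:1,B:2):1,(C:1.5,D:0.5):2);")
  rel <- matrix(c(0.7, 0.3, 0, 0,
                  0, 0, 0.4, 0.6), 2, 4, byrow = TRUE,
                dimnames = list(c("x", "y"), c("A", "B", "C", "D")))
  d <- ape::cophenetic.phylo(tree)[colnames(rel), colnames(rel)]
  nulls <- vapply(combinat_perms(4), function(p)
    brute_beta_mntd(rel, `dimnames<-`(d[p, p], dimnames(d)), "x", "y"),
    numeric(1))
  expect_length(nulls, 24)
  obs <- brute_beta_mntd(rel, d, "x", "y")
  exhaustive <- (obs - mean(nulls)) / sd(nulls)

  mc <- beta_nti(rel, tree, n_null = 999, seed = 2)
  expect_lt(abs(mc$bnti["x", "y"] - exhaustive), 0.2)
  expect_equal(mc$obs["x", "y"], obs, tolerance = 1e-12)
})

test_that("betaNTI is invariant to uniform branch-length scaling", {
  set.seed(12)
  tr <- ape::rphylo(10, 1, 0)
  tr$tip.label <- paste0("t", 1:10)
  m <- matrix(rpois(5 * 10, 3) + rbinom(5 * 10, 1, 0.5), 5, 10,
              dimnames = list(paste0("s", 1:5), tr$tip.label))
  rel <- m / rowSums(m)
  tr10 <- tr
  tr10$edge.length <- tr$edge.length * 10
  a <- beta_nti(rel, tr, n_null = 99, seed = 7)
  b <- beta_nti(rel, tr10, n_null = 99, seed = 7)
  expect_equal(a$bnti, b$bnti, tolerance = 1e-9)
})

test_that("Raup-Crick Bray hits its limiting values", {
  # identical samples drawn from a pool where every OTU is common:
  # observed dissimilarity 0 undercuts essentially every null
  m <- matrix(rep(c(10L, 12L, 8L, 10L, 9L), 6), 6, 5, byrow = TRUE,
              dimnames = list(paste0("s", 1:6), paste0("o", 1:5)))
  rc <- rc_bray(make_table(m), n_null = 199, seed = 3)
  expect_lt(rc["s1", "s2"], -0.95)

  # disjoint samples of OTUs that are frequent in the metacommunity
  m2 <- rbind(
    s1 = c(10L, 10L, 10L, 0L, 0L, 0L),
    s2 = c(0L, 0L, 0L, 10L, 10L, 10L),
    s3 = c(5L, 5L, 5L, 5L, 5L, 5L),
    s4 = c(5L, 5L, 5L, 5L, 5L, 5L),
    s5 = c(6L, 4L, 5L, 6L, 4L, 5L),
    s6 = c(4L, 6L, 5L, 4L, 6L, 5L))
  colnames(m2) <- paste0("o", 1:6)
  rc2 <- rc_bray(make_table(m2), n_null = 199, seed = 3)
  expect_gt(rc2["s1", "s2"], 0.95)

  expect_true(all(rc2 >= -1 & rc2 <= 1))
  expect_error(rc_bray(make_table(matrix(1L, 1, 3)), n_null = 99), "2 samples")
})

test_that("process classification applies the two-metric thresholds", {
  ids <- c("a", "b", "c", "d")
  bnti <- matrix(0, 4, 4, dimnames = list(ids, ids))
  rc <- matrix(0, 4, 4, dimnames = list(ids, ids))
  set_pair <- function(m, i, j, v) { m[i, j] <- v; m[j, i] <- v; m }
  bnti <- set_pair(bnti, "a", "b", -2.3); rc <- set_pair(rc, "a", "b", 0.1)
  bnti <- set_pair(bnti, "a", "c", 0.4);  rc <- set_pair(rc, "a", "c", 0.99)
  bnti <- set_pair(bnti, "a", "d", 1.0);  rc <- set_pair(rc, "a", "d", 0.2)
  bnti <- set_pair(bnti, "b", "c", 2.6);  rc <- set_pair(rc, "b", "c", 0.0)
  bnti <- set_pair(bnti, "b", "d", 0.0);  rc <- set_pair(rc, "b", "d", -0.99)
  bnti <- set_pair(bnti, "c", "d", 1.5);  rc <- set_pair(rc, "c", "d", 0.95)

  res <- classify_processes(bnti, rc)
  got <- setNames(res$pairs$process,
                  paste(res$pairs$sample1, res$pairs$sample2))
  expect_equal(unname(got["a b"]), "homogeneous_selection")
  expect_equal(unname(got["a c"]), "dispersal_limitation")
  expect_equal(unname(got["a d"]), "undominated")
  expect_equal(unname(got["b c"]), "heterogeneous_selection")
  expect_equal(unname(got["b d"]), "homogenizing_dispersal")
  expect_equal(unname(got["c d"]), "undominated")  # boundary tie
  expect_equal(sum(res$fractions), 1)
  expect_true(all(res$fractions >= 0))
})

test_that("the full attribution wrapper covers all pairs", {
  ds <- simulate_community(sim_config(n_otus = 60, depth = 2000, seed = 2))
  asm <- assembly_processes(ds$table, ds$tree, n_null = 99, seed = 2)
  expect_equal(nrow(asm$pairs), choose(12, 2))
  expect_equal(sum(asm$fractions), 1)
  rederive <- classify_processes(asm$bnti_detail, asm$rc_matrix)
  expect_equal(rederive$pairs$process, asm$pairs$process)
})
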