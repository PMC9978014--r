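# fast row minima via max.col (C-level); m must have >= 1 column
row_mins <- function(m) {
  m[cbind(seq_len(nrow(m)), max.col(-m, ties.method = "first"))]
}

# patristic distance matrix aligned to the OTUs of `rel`
aligned_cophenetic <- function(rel, tree) {
  missing <- setdiff(colnames(rel)[colSums(rel) > 0], tree$tip.label)
  if (length(missing))
    stop("OTU(s) missing from the tree: ",
         paste(missing, collapse = ", "))
  keep <- intersect(colnames(rel), tree$tip.label)
  d <- ape::cophenetic.phylo(tree)[keep, keep]
  list(d = d, rel = rel[, keep, drop = FALSE])
}

# betaMNTD between all sample pairs given a patristic matrix.
# M[j, s] = distance from OTU j to its nearest neighbour present in
# sample s (0 when j itself is present), so
# betaMNTD = 0.5 * (W M + (W M)') with W the relative abundances.
beta_mntd_matrix <- function(w, d) {
  n_s <- nrow(w)
  m <- matrix(0, ncol(w), n_s)
  for (s in seq_len(n_s)) {
    idx <- which(w[s, ] > 0)
    m[, s] <- if (length(idx) == 1) d[, idx]
              else row_mins(d[, idx, drop = FALSE])
  }
  x <- w %*% m
  out <- 0.5 * (x + t(x))
  diag(out) <- 0
  dimnames(out) <- list(rownames(w), rownames(w))
  out
}

#' Between-sample mean nearest taxon distance (betaMNTD)
#'
#' Abundance-weighted phylogenetic turnover between two communities:
#' each OTU present in one sample contributes its patristic distance to
#' the nearest relative present in the other sample, weighted by its
#' within-sample relative abundance, and the two directed sums are
#' averaged. OTUs shared by both samples contribute distance zero.
#'
#' @param rel relative-abundance matrix ([relative_abundance()]).
#' @param tree rooted phylogeny whose tips cover every OTU that occurs
#'   in `rel`.
#' @param pair character vector of two sample ids; `NULL` (default)
#'   returns the full pairwise matrix.
#' @return a single betaMNTD value, or the symmetric samples-x-samples
#'   matrix when `pair` is `NULL`.
#' @export
beta_mntd <- function(rel, tree, pair = NULL) {
  al <- aligned_cophenetic(rel, tree)
  full <- beta_mntd_matrix(al$rel, al$d)
  if (is.null(pair)) return(full)
  stopifnot(length(pair) == 2, all(pair %in% rownames(full)))
  full[pair[1], pair[2]]
}

#' Beta nearest taxon index (betaNTI)
#'
#' Standardised effect size of [beta_mntd()] against a null in which
#' tip labels are shuffled across the whole phylogeny (equivalently,
#' rows and columns of the patristic matrix are jointly permuted),
#' independently for each of `n_null` replicates:
#' betaNTI = (obs - mean_null) / sd_null. |betaNTI| >= 2 is read as
#' deterministic selection, the sign separating heterogeneous (+) from
#' homogeneous (-) selection.
#'
#' @inheritParams beta_mntd
#' @param n_null null replicates (default 999, minimum 99).
#' @param seed integer seed.
#' @return object of class `beta_nti_result`: matrices `bnti`,
#'   `obs`, `null_mean`, `null_sd` (samples x samples); entries with a
#'   degenerate null (sd = 0) are `NA` and counted in `n_degenerate`.
#' @export
beta_nti <- function(rel, tree, n_null = 999, seed = 1L) {
  stopifnot(n_null >= 99)
  al <- aligned_cophenetic(rel, tree)
  w <- al$rel
  d <- al$d
  obs <- beta_mntd_matrix(w, d)
  n_taxa <- ncol(w)
  set.seed(seed)
  sum1 <- sum2 <- matrix(0, nrow(w), nrow(w))
  for (k in seq_len(n_null)) {
    perm <- sample.int(n_taxa)
    bk <- beta_mntd_matrix(w, d[perm, perm])
    sum1 <- sum1 + bk
    sum2 <- sum2 + bk^2
  }
  mu <- sum1 / n_null
  sdv <- sqrt(pmax(sum2 / n_null - mu^2, 0) * n_null / (n_null - 1))
  bnti <- (obs - mu) / sdv
  degen <- sdv == 0
  diag(degen) <- FALSE
  bnti[degen] <- NA
  diag(bnti) <- 0
  structure(list(bnti = bnti, obs = obs, null_mean = mu, null_sd = sdv,
                 n_null = n_null, seed = seed,
                 n_degenerate = sum(degen[upper.tri(degen)])),
            class = "beta_nti_result")
}

# one null metacommunity draw for every sample: observed richness kept,
# species picked with probability ~ occurrence frequency, individuals
# then allocated ~ metacommunity relative abundance
rc_null_draw <- function(richness, depths, occ_p, meta_p) {
  n_otu <- length(occ_p)
  out <- matrix(0, length(richness), n_otu)
  for (i in seq_along(richness)) {
    sp <- sample.int(n_otu, richness[i], prob = occ_p)
    extra <- depths[i] - richness[i]
    counts <- rep(1, richness[i])
    if (extra > 0)
      counts <- counts + stats::rmultinom(1, extra, meta_p[sp])[, 1]
    out[i, sp] <- counts
  }
  out
}

#' Raup-Crick with Bray-Curtis dissimilarity (RC_Bray)
#'
#' For every sample pair, the observed Bray-Curtis dissimilarity is
#' ranked against `n_null` dissimilarities between null communities
#' that keep each sample's observed richness and total abundance while
#' drawing species with probability proportional to their occurrence
#' frequency across samples and allocating individuals proportionally
#' to metacommunity relative abundance. RC = 2 x (fraction of nulls
#' below the observation, ties counted half) - 1, so RC is in
#' \[-1, 1\]: near +1 the pair is more dissimilar than expected by
#' chance (dispersal limitation when selection is absent), near -1 less
#' dissimilar (homogenising dispersal).
#'
#' @param table an [otu_table] with at least 2 samples.
#' @param n_null null replicates (default 999, minimum 99).
#' @param seed integer seed.
#' @return symmetric samples-x-samples matrix of RC_Bray values.
#' @export
rc_bray <- function(table, n_null = 999, seed = 1L) {
  stopifnot(inherits(table, "otu_table"), n_null >= 99)
  counts <- table$counts
  if (nrow(counts) < 2) stop("need at least 2 samples")
  richness <- rowSums(counts > 0)
  depths <- rowSums(counts)
  occ_p <- colSums(counts > 0) / nrow(counts)
  meta_p <- colSums(counts) / sum(counts)
  obs <- as.matrix(vegan::vegdist(counts, method = "bray"))
  n_s <- nrow(counts)
  below <- ties <- matrix(0, n_s, n_s)
  set.seed(seed)
  for (k in seq_len(n_null)) {
    nullc <- rc_null_draw(richness, depths, occ_p, meta_p)
    dk <- as.matrix(vegan::vegdist(nullc, method = "bray"))
    below <- below + (dk < obs - 1e-12)
    ties <- ties + (abs(dk - obs) <= 1e-12)
  }
  rc <- 2 * ((below + 0.5 * ties) / n_null) - 1
  diag(rc) <- 0
  dimnames(rc) <- list(rownames(counts), rownames(counts))
  rc
}

#' Classify sample pairs into the five assembly processes
#'
#' The two-metric scheme: |betaNTI| >= 2 indicates deterministic
#' selection, heterogeneous (betaNTI >= +2) or homogeneous
#' (betaNTI <= -2); among the remaining (stochastic) pairs,
#' RC_Bray > 0.95 indicates dispersal limitation, RC_Bray < -0.95
#' homogenising dispersal, and |RC_Bray| <= 0.95 the undominated
#' fraction (drift and weak, mixed processes).
#'
#' @param bnti betaNTI matrix (or a `beta_nti_result`).
#' @param rc RC_Bray matrix from [rc_bray()], on the same samples.
#' @return object of class `assembly_result`: data.frame `pairs`
#'   (`sample1`, `sample2`, `bnti`, `rc_bray`, `process`), named vector
#'   `fractions` over the five processes (sums to 1 over classifiable
#'   pairs), and `n_excluded` pairs with undefined betaNTI.
#' @export
classify_processes <- function(bnti, rc) {
  if (inherits(bnti, "beta_nti_result")) bnti <- bnti$bnti
  if (!identical(rownames(bnti), rownames(rc)))
    stop("betaNTI and RC matrices must cover identical samples")
  ids <- rownames(bnti)
  iu <- which(upper.tri(bnti), arr.ind = TRUE)
  b <- bnti[iu]
  r <- rc[iu]
  process <- ifelse(is.na(b), NA_character_,
             ifelse(b >= 2, "heterogeneous_selection",
             ifelse(b <= -2, "homogeneous_selection",
             ifelse(r > 0.95, "dispersal_limitation",
             ifelse(r < -0.95, "homogenizing_dispersal",
                    "undominated")))))
  pairs <- data.frame(sample1 = ids[iu[, 1]], sample2 = ids[iu[, 2]],
                      bnti = b, rc_bray = r, process = process,
                      row.names = NULL)
  lv <- c("heterogeneous_selection", "homogeneous_selection",
          "dispersal_limitation", "homogenizing_dispersal",
          "undominated")
  ok <- !is.na(process)
  fractions <- as.numeric(table(factor(process[ok], lv)) / sum(ok))
  names(fractions) <- lv
  structure(list(pairs = pairs, fractions = fractions,
                 n_excluded = sum(!ok)),
            class = "assembly_result")
}

#' @export
print.assembly_result <- function(x, ...) {
  cat("assembly processes over", nrow(x$pairs), "sample pairs",
      if (x$n_excluded) paste0("(", x$n_excluded, " excluded)"), "\n")
  print(round(x$fractions, 3))
  invisible(x)
}

#' Full assembly-process attribution for one community subset
#'
#' Convenience wrapper running [beta_nti()] (on a tree pruned to the
#' subset's OTUs), [rc_bray()] and [classify_processes()] in sequence.
#'
#' @inheritParams rc_bray
#' @param tree phylogeny covering the table's OTUs.
#' @return an `assembly_result` with the `beta_nti_result` attached as
#'   `$bnti_detail` and the RC matrix as `$rc_matrix`.
#' @export
assembly_processes <- function(table, tree, n_null = 999, seed = 1L) {
  rel <- relative_abundance(table)
  present <- colnames(rel)[colSums(rel) > 0]
  pruned <- ape::keep.tip(tree, intersect(tree$tip.label, present))
  bn <- beta_nti(rel, pruned, n_null = n_null, seed = seed)
  rc <- rc_bray(table, n_null = n_null, seed = seed + 1L)
  res <- classify_processes(bn, rc)
  res$bnti_detail <- bn
  res$rc_matrix <- rc
  res
}
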