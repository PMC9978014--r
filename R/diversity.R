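#' Partition OTUs into abundant and rare taxa
#'
#' An OTU is *abundant* when its mean relative abundance across the
#' samples under consideration is at or above `threshold` (default
#' 0.01 percent), otherwise *rare*; the boundary value counts as abundant.
#' With `scope = "per_sample_max"` the maximum across samples is used
#' instead of the mean.
#'
#' @param rel relative-abundance matrix from [relative_abundance()].
#' @param threshold proportion in (0, 1); default `1e-4` (0.01 percent).
#' @param scope `"mean"` (default) or `"per_sample_max"`.
#' @return an object of class `abundance_classification`: list with
#'   `category` (named character, `"abundant"`/`"rare"`), `otu_fraction`
#'   and `abundance_fraction` (per-class shares of OTU richness and of
#'   total reads), `threshold`, `scope`.
#' @export
classify_abundance <- function(rel, threshold = 1e-4,
                               scope = c("mean", "per_sample_max")) {
  scope <- match.arg(scope)
  stopifnot(threshold > 0, threshold < 1)
  stat <- switch(scope,
                 mean = colMeans(rel),
                 per_sample_max = apply(rel, 2, max))
  category <- ifelse(stat >= threshold, "abundant", "rare")
  names(category) <- colnames(rel)
  otu_fraction <- c(abundant = mean(category == "abundant"),
                    rare = mean(category == "rare"))
  mass <- colMeans(rel)
  abundance_fraction <- c(
    abundant = sum(mass[category == "abundant"]),
    rare = sum(mass[category == "rare"])) / sum(mass)
  structure(list(category = category, otu_fraction = otu_fraction,
                 abundance_fraction = abundance_fraction,
                 threshold = threshold, scope = scope),
            class = "abundance_classification")
}

chao1_estimate <- function(x) {
  s_obs <- sum(x > 0)
  f1 <- sum(x == 1)
  f2 <- sum(x == 2)
  if (f1 == 0) return(s_obs)
  if (f2 == 0) return(s_obs + f1 * (f1 - 1) / 2)  # bias-corrected, F2 = 0
  s_obs + f1^2 / (2 * f2)
}

ace_estimate <- function(x, rare_cutoff = 10) {
  x <- x[x > 0]
  s_abund <- sum(x > rare_cutoff)
  rare <- x[x <= rare_cutoff]
  s_rare <- length(rare)
  n_rare <- sum(rare)
  f1 <- sum(rare == 1)
  if (s_rare == 0) return(s_abund)
  c_ace <- 1 - f1 / n_rare
  if (c_ace == 0) {
    warning("ACE undefined: all rare OTUs are singletons")
    return(NA_real_)
  }
  fi <- tabulate(rare, nbins = rare_cutoff)
  gamma2 <- max(s_rare / c_ace * sum(seq_len(rare_cutoff) *
                                       (seq_len(rare_cutoff) - 1) * fi) /
                  (n_rare * (n_rare - 1)) - 1, 0)
  s_abund + s_rare / c_ace + f1 / c_ace * gamma2
}

#' Per-sample alpha diversity
#'
#' Observed richness, Shannon H (natural log), Pielou evenness
#' J = H / ln(richness), and the Chao1 and ACE richness estimators.
#' Chao1 uses the classic form S_obs + F1^2 / (2 F2), switching to the
#' bias-corrected form when no doubletons exist; ACE uses the standard
#' abundance-based coverage estimator with rare-abundance cutoff
#' `rare_cutoff`.
#'
#' @param table an [otu_table] (counts are required: the richness
#'   estimators need singleton and doubleton frequencies).
#' @param rare_cutoff ACE rare-class upper bound (default 10).
#' @return data.frame, one row per sample, columns `richness`,
#'   `shannon`, `pielou`, `chao1`, `ace`.
#' @export
alpha_diversity <- function(table, rare_cutoff = 10) {
  stopifnot(inherits(table, "otu_table"))
  m <- table$counts
  if (all(rowSums(m) <= 1 + 1e-6) && any(m %% 1 != 0))
    stop("alpha_diversity needs counts, not proportions")
  res <- t(apply(m, 1, function(x) {
    x <- x[x > 0]
    s <- length(x)
    p <- x / sum(x)
    h <- -sum(p * log(p))
    c(richness = s,
      shannon = h,
      pielou = if (s >= 2) h / log(s) else NA_real_,
      chao1 = chao1_estimate(x),
      ace = ace_estimate(x, rare_cutoff))
  }))
  data.frame(sample_id = rownames(m), res, row.names = NULL)
}

# compact letter display: letters = maximal cliques of the
# "not significantly different" graph, ordered by group mean
cld_letters <- function(groups, diff_pairs, means) {
  g <- igraph::make_full_graph(length(groups))
  igraph::V(g)$name <- groups
  if (nrow(diff_pairs) > 0) {
    drop <- apply(diff_pairs, 1, function(p)
      igraph::get_edge_ids(g, match(p, groups)))
    g <- igraph::delete_edges(g, drop[drop > 0])
  }
  cl <- igraph::max_cliques(g)
  # order cliques by the best (highest) mean they contain
  ord <- order(vapply(cl, function(v) -max(means[v]), numeric(1)))
  cl <- cl[ord]
  lab <- stats::setNames(rep("", length(groups)), groups)
  for (i in seq_along(cl))
    lab[cl[[i]]] <- paste0(lab[cl[[i]]], letters[i])
  lab
}

#' Compare an alpha-diversity metric across groups
#'
#' One-way ANOVA with Tukey HSD letters for three or more groups; with
#' exactly two groups a Welch t-test is used and the letters reduce to
#' same/different at `alpha`. Groups sharing a letter do not differ at
#' the chosen level.
#'
#' @param values numeric vector, one value per sample.
#' @param groups group label per sample.
#' @param alpha significance level for the letter display (default 0.05).
#' @return list with `method`, `statistic`, `p.value`, `letters`
#'   (named by group), and `pairwise` (data.frame of pairwise
#'   comparisons, `NULL` for the two-group case).
#' @export
compare_groups <- function(values, groups, alpha = 0.05) {
  groups <- as.factor(groups)
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  if (any(table(groups) < 2)) stop("every group needs at least 2 samples")
  means <- tapply(values, groups, mean)
  lev <- levels(groups)
  if (nlevels(groups) == 2) {
    tt <- stats::t.test(values ~ groups)
    diff_pairs <- if (tt$p.value < alpha)
      matrix(lev, ncol = 2) else matrix(character(0), ncol = 2)
    return(list(method = "t.test", statistic = unname(tt$statistic),
                p.value = tt$p.value,
                letters = cld_letters(lev, diff_pairs, means),
                pairwise = NULL))
  }
  fit <- stats::aov(values ~ groups)
  an <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$groups
  pairs <- do.call(rbind, strsplit(rownames(tk), "-", fixed = TRUE))
  sig <- tk[, "p adj"] < alpha
  list(method = "anova_tukey",
       statistic = an[["F value"]][1],
       p.value = an[["Pr(>F)"]][1],
       letters = cld_letters(lev, pairs[sig, , drop = FALSE], means),
       pairwise = data.frame(group1 = pairs[, 1], group2 = pairs[, 2],
                             diff = tk[, "diff"], p_adj = tk[, "p adj"],
                             row.names = NULL))
}

#' Principal coordinates analysis on Bray-Curtis dissimilarity
#'
#' Classical metric MDS ([stats::cmdscale()]) on the Bray-Curtis
#' distances between samples. Negative eigenvalues, if any, are clipped
#' to zero for the explained-variance shares (recorded in
#' `negative_eigenvalues`), and each axis is sign-canonicalised so its
#' largest-magnitude score is positive.
#'
#' @param table an [otu_table].
#' @param k number of axes to return (default `n - 1`).
#' @return list of class `ordination_result`: `distances` (Bray-Curtis
#'   matrix), `scores` (samples x axes), `explained` (per-axis share),
#'   `eigenvalues`, `negative_eigenvalues` (count clipped).
#' @export
pcoa_bray <- function(table, k = NULL) {
  stopifnot(inherits(table, "otu_table"))
  m <- table$counts
  if (nrow(m) < 3) stop("PCoA needs at least 3 samples")
  d <- vegan::vegdist(m, method = "bray")
  if (is.null(k)) k <- nrow(m) - 1
  fit <- suppressWarnings(stats::cmdscale(d, k = k, eig = TRUE))
  eig <- fit$eig
  n_neg <- sum(eig < -1e-8)
  if (n_neg > 0)
    message("PCoA: ", n_neg,
            " negative eigenvalue(s) clipped to zero for explained",
            " variance")
  pos <- pmax(eig, 0)
  scores <- fit$points
  # canonical sign: largest-|score| coordinate positive on each axis
  for (j in seq_len(ncol(scores))) {
    i <- which.max(abs(scores[, j]))
    if (scores[i, j] < 0) scores[, j] <- -scores[, j]
  }
  colnames(scores) <- paste0("PCo", seq_len(ncol(scores)))
  structure(list(distances = as.matrix(d), scores = scores,
                 explained = (pos / sum(pos))[seq_len(ncol(scores))],
                 eigenvalues = eig, negative_eigenvalues = n_neg),
            class = "ordination_result")
}
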