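#' Configuration for the synthetic community generator
#'
#' Defaults emulate a 12-sample survey of a single habitat with the
#' abundance structure amplicon surveys show: a log-normal *core* of
#' abundant OTUs holding nearly all reads, plus a *satellite* tail of
#' low-abundance OTUs (the classic core-satellite decomposition of
#' species-abundance distributions) that makes rare OTUs (mean
#' relative abundance < 0.01 percent) the majority of observed richness while
#' contributing a negligible read share. The phylogeny is a depth-1
#' pure-birth tree; the niche trait evolves by Brownian motion on a
#' depth-rescaled tree (`trait_delta` < 1 concentrates divergence near
#' the root), so niche optima are clade-conserved rather than merely
#' autocorrelated. The assembly regime is selectable.
#'
#' @param n_samples number of communities (default 12).
#' @param n_otus metacommunity species-pool size (default 300).
#' @param regime `"neutral"`, `"selection"` or `"dispersal_limitation"`.
#' @param meanlog,sdlog log-normal parameters of the core abundance
#'   component (defaults 0, 1.5: top core OTU around ten percent
#'   relative abundance, tens of effectively contributing taxa).
#' @param core_fraction fraction of pool OTUs in the abundant core
#'   (default 0.4).
#' @param satellite_scale,satellite_sdlog satellite OTU weights are
#'   log-normal with median `satellite_scale` times the core median and
#'   spread `satellite_sdlog` (defaults 4e-3 and 1, placing satellites
#'   at roughly 1e-6 to 1e-4 relative abundance).
#' @param bm_rate Brownian-motion variance rate per unit tree depth
#'   (default 1; traits are z-scored before filtering, so only the
#'   shape of the trait distribution matters).
#' @param trait_delta exponent of the node-depth rescaling applied to
#'   the tree before trait evolution (default 0.3; 1 = plain Brownian
#'   motion; smaller values concentrate trait divergence in the deep
#'   branches, strengthening niche conservatism).
#' @param env_values niche optima imposed on the two sample halves
#'   under the selection regime, on the z-scored trait scale (default
#'   `c(-1, 1)`).
#' @param sigma Gaussian niche-filter width on the z-scored trait scale
#'   (default 0.5: strong filtering, each environment admits roughly
#'   one trait standard deviation around its optimum).
#' @param n_pools number of disjoint source pools for the dispersal
#'   regime (default 2).
#' @param depth sequencing depth per sample (default 50000, a typical
#'   per-sample 16S amplicon depth; at much shallower depths the rare
#'   tail of the log-normal pool falls below the detection limit and
#'   rare taxa no longer dominate the observed richness).
#' @param seed master seed; all component streams derive from it.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_samples = 12, n_otus = 300,
                       regime = c("neutral", "selection",
                                  "dispersal_limitation"),
                       meanlog = 0, sdlog = 1.5, core_fraction = 0.4,
                       satellite_scale = 4e-3, satellite_sdlog = 1,
                       bm_rate = 1, trait_delta = 0.3,
                       env_values = c(-1, 1), sigma = 0.5,
                       n_pools = 2, depth = 50000, seed = 1L) {
  regime <- match.arg(regime)
  stopifnot(n_samples >= 4, n_otus >= 2, depth >= 100, sigma > 0,
            n_pools >= 2, length(env_values) == 2,
            core_fraction > 0, core_fraction <= 1,
            satellite_scale > 0, trait_delta > 0, trait_delta <= 1)
  structure(list(n_samples = n_samples, n_otus = n_otus, regime = regime,
                 meanlog = meanlog, sdlog = sdlog,
                 core_fraction = core_fraction,
                 satellite_scale = satellite_scale,
                 satellite_sdlog = satellite_sdlog,
                 bm_rate = bm_rate, trait_delta = trait_delta,
                 env_values = env_values, sigma = sigma,
                 n_pools = n_pools, depth = depth,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# per-component seeds derived once from the master seed
component_seeds <- function(config) {
  set.seed(config$seed)
  stats::setNames(sample.int(.Machine$integer.max - 1, 4),
                  c("tree", "community", "env", "extra"))
}

# Pagel's-delta-style depth rescaling: node depth t -> t^delta.
# delta < 1 pushes divergence toward the root, so a trait evolved on
# the rescaled tree is close to constant within clades.
rescale_depth <- function(tree, delta) {
  dep <- ape::node.depth.edgelength(tree)
  dep <- (dep / max(dep[seq_len(ape::Ntip(tree))]))^delta
  tree$edge.length <- dep[tree$edge[, 2]] - dep[tree$edge[, 1]]
  tree
}

#' Simulate a phylogeny with conserved niche traits
#'
#' Pure-birth tree with `n_otus` tips, rescaled to total depth 1; one
#' continuous niche trait evolved by Brownian motion along the
#' branches. The trait is evolved on a depth-rescaled copy of the tree
#' (exponent `trait_delta`), which concentrates divergence in the deep
#' branches: clades then carry cohesive niche optima instead of the
#' frequent between-clade convergence plain Brownian motion produces.
#' The returned tree itself keeps its original branch lengths.
#'
#' @param config a [sim_config()].
#' @return list: `tree` (phylo, tips `OTU_0001` ...), `traits` (named
#'   numeric, raw trait values; z-scoring happens at filtering time).
#' @export
simulate_tree_and_traits <- function(config) {
  seeds <- component_seeds(config)
  set.seed(seeds["tree"])
  tree <- ape::rphylo(config$n_otus, birth = 1, death = 0)
  depth <- max(ape::node.depth.edgelength(tree))
  tree$edge.length <- tree$edge.length / depth
  tree$tip.label <- sprintf("OTU_%04d", seq_len(config$n_otus))
  traits <- ape::rTraitCont(rescale_depth(tree, config$trait_delta),
                            model = "BM", sigma = sqrt(config$bm_rate))
  names(traits) <- tree$tip.label
  list(tree = tree, traits = traits)
}

#' Simulate a community dataset with known assembly regime
#'
#' Metacommunity relative abundances are drawn from the core-satellite
#' log-normal mixture described in [sim_config()]; each
#' sample's expected composition is then shaped by the regime:
#' *neutral* samples share the metacommunity expectation, *selection*
#' samples weight it by a Gaussian niche filter
#' exp(-(z_j - env_i)^2 / (2 sigma^2)) on z-scored traits with the two
#' sample halves at contrasting optima, and *dispersal_limitation*
#' samples draw only from one of `n_pools` disjoint, randomly assigned
#' OTU pools. Counts are multinomial at the configured depth.
#'
#' @param config a [sim_config()].
#' @param tree,traits from [simulate_tree_and_traits()]; generated when
#'   omitted.
#' @return list of class `synthetic_dataset`: `table` ([otu_table]),
#'   `tree`, `env` (data.frame from [simulate_env_table()]),
#'   `truth` (regime, per-OTU niche optimum, per-sample gradient and
#'   pool id), `config`, `seeds`.
#' @export
simulate_community <- function(config, tree = NULL, traits = NULL) {
  if (is.null(tree)) {
    tt <- simulate_tree_and_traits(config)
    tree <- tt$tree
    traits <- tt$traits
  }
  seeds <- component_seeds(config)
  set.seed(seeds["community"])
  n_s <- config$n_samples
  n_o <- config$n_otus
  n_core <- max(1, round(config$core_fraction * n_o))
  is_core <- seq_len(n_o) %in% sample.int(n_o, n_core)
  meta <- numeric(n_o)
  meta[is_core] <- stats::rlnorm(n_core, config$meanlog, config$sdlog)
  meta[!is_core] <- stats::rlnorm(
    n_o - n_core, config$meanlog + log(config$satellite_scale),
    config$satellite_sdlog)
  meta_p <- meta / sum(meta)
  z <- (traits - mean(traits)) / stats::sd(traits)
  half <- rep(config$env_values, each = ceiling(n_s / 2))[seq_len(n_s)]
  pool_of_otu <- sample(rep_len(seq_len(config$n_pools), n_o))
  pool_of_sample <- rep_len(seq_len(config$n_pools), n_s)
  expected <- matrix(meta_p, n_s, n_o, byrow = TRUE)
  if (config$regime == "selection") {
    w <- exp(-outer(half, z, "-")^2 / (2 * config$sigma^2))
    expected <- expected * w
  } else if (config$regime == "dispersal_limitation") {
    mask <- outer(pool_of_sample, pool_of_otu, "==")
    expected <- expected * mask
  }
  tot <- rowSums(expected)
  if (any(tot == 0))
    stop("degenerate filter: a sample has zero expected abundance")
  expected <- expected / tot
  counts <- t(vapply(seq_len(n_s),
                     function(i) stats::rmultinom(1, config$depth,
                                                  expected[i, ])[, 1],
                     integer(n_o)))
  sample_ids <- sprintf("S%02d", seq_len(n_s))
  dimnames(counts) <- list(sample_ids, tree$tip.label)
  # drop OTUs never observed: they exist in the pool, not the data
  observed <- colSums(counts) > 0
  table <- otu_table(counts[, observed, drop = FALSE])
  gradient <- switch(config$regime,
                     selection = half,
                     dispersal_limitation = as.numeric(pool_of_sample),
                     neutral = NULL)
  env <- simulate_env_table(config, gradient = gradient)
  truth <- list(regime = config$regime,
                niche_optimum = z,
                gradient = stats::setNames(if (is.null(gradient))
                  env$gradient else gradient, sample_ids),
                pool_of_sample = stats::setNames(pool_of_sample,
                                                 sample_ids),
                pool_of_otu = stats::setNames(pool_of_otu,
                                              tree$tip.label))
  structure(list(table = table, tree = tree, env = env, truth = truth,
                 config = config, seeds = seeds),
            class = "synthetic_dataset")
}

#' Simulate the environmental table
#'
#' One `gradient` column carrying the variable that actually shaped the
#' communities (for the neutral regime: an inert standard-normal
#' gradient) plus `n_noise` independent standard-normal noise
#' variables, for type-I-error checks of the Mantel screen.
#'
#' @param config a [sim_config()].
#' @param gradient per-sample gradient values; `NULL` draws an inert
#'   one.
#' @param n_noise number of noise variables (default 3).
#' @return data.frame, rownames = sample ids, columns `gradient`,
#'   `noise1` ...; units are arbitrary (z-scored trait scale).
#' @export
simulate_env_table <- function(config, gradient = NULL, n_noise = 3) {
  seeds <- component_seeds(config)
  set.seed(seeds["env"])
  n_s <- config$n_samples
  if (is.null(gradient)) gradient <- stats::rnorm(n_s)
  out <- data.frame(gradient = gradient)
  for (k in seq_len(n_noise))
    out[[paste0("noise", k)]] <- stats::rnorm(n_s)
  rownames(out) <- sprintf("S%02d", seq_len(n_s))
  out
}

#' Write a synthetic dataset to a directory
#'
#' Emits `table.tsv` (OTUs x samples, the conventional orientation),
#' `tree.nwk`, `env.csv` and `truth.json`, the formats the loaders in
#' this package read back.
#'
#' @param dataset a `synthetic_dataset`.
#' @param dir output directory (created if needed).
#' @return invisibly, the directory.
#' @export
write_synthetic_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  counts <- t(dataset$table$counts)  # OTUs as rows
  df <- data.frame(otu_id = rownames(counts), counts, check.names = FALSE)
  utils::write.table(df, file.path(dir, "table.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  ape::write.tree(dataset$tree, file.path(dir, "tree.nwk"))
  env <- data.frame(sample_id = rownames(dataset$env), dataset$env,
                    check.names = FALSE)
  utils::write.table(env, file.path(dir, "env.csv"), sep = ",",
                     quote = FALSE, row.names = FALSE)
  truth <- dataset$truth
  truth$config <- unclass(dataset$config)
  jsonlite::write_json(round_rec(truth), file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
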