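#' Levins' niche breadth
#'
#' B_j = 1 / sum_i q_ij^2, where q_ij is OTU j's distribution over the N
#' communities: q_ij = P_ij / sum_i P_ij with P_ij the within-sample
#' relative abundance. Under this across-community normalisation B lies
#' in \[1, N\]: 1 for an OTU confined to a single sample, N for one
#' spread perfectly evenly over all N samples.
#'
#' @param rel relative-abundance matrix ([relative_abundance()]).
#' @param otu a single OTU id.
#' @return Levins' B for that OTU.
#' @seealso [levins_b_all()] for the vectorised form.
#' @export
levins_b <- function(rel, otu) {
  if (!otu %in% colnames(rel)) stop("unknown OTU: ", otu)
  p <- rel[, otu]
  if (sum(p) == 0) stop("OTU ", otu, " is absent from every sample; B undefined")
  q <- p / sum(p)
  1 / sum(q^2)
}

#' @rdname levins_b
#' @return for `levins_b_all`: named numeric vector of B over all OTUs,
#'   `NA` for OTUs absent everywhere.
#' @export
levins_b_all <- function(rel) {
  cs <- colSums(rel)
  q <- sweep(rel, 2, ifelse(cs > 0, cs, NA), "/")
  1 / colSums(q^2)
}

#' Community mean niche breadth with bootstrap spread
#'
#' B_m is the unweighted mean of Levins' B over an OTU set; its spread
#' is the standard deviation of the mean over `n_boot` bootstrap
#' resamples of the OTU set (resampling OTUs with replacement).
#'
#' @param rel relative-abundance matrix.
#' @param otus OTU ids to average over (OTUs absent from all samples are
#'   dropped).
#' @param n_boot bootstrap replicates (default 100).
#' @param seed integer seed.
#' @return list: `b_m`, `boot_sd`, `n_otus`, `n_boot`, `b` (the per-OTU
#'   values used).
#' @export
community_bm <- function(rel, otus = colnames(rel), n_boot = 100,
                         seed = 1L) {
  stopifnot(n_boot >= 1)
  if (length(otus) == 0) stop("empty OTU set")
  if (!all(otus %in% colnames(rel)))
    stop("unknown OTUs: ",
         paste(setdiff(otus, colnames(rel)), collapse = ", "))
  b <- levins_b_all(rel[, otus, drop = FALSE])
  b <- b[!is.na(b)]
  if (length(b) == 0) stop("no OTU in the set occurs in any sample")
  set.seed(seed)
  boots <- vapply(seq_len(n_boot),
                  function(i) mean(sample(b, replace = TRUE)),
                  numeric(1))
  boot_sd <- if (n_boot == 1) {
    warning("n_boot = 1: bootstrap sd is 0 by construction")
    0
  } else stats::sd(boots)
  list(b_m = mean(b), boot_sd = boot_sd, n_otus = length(b),
       n_boot = n_boot, b = b)
}

# number of 2x2 checkerboard units in the incidence matrix; the swap
# null cannot mix when there are fewer than 2
checkerboard_units <- function(counts) {
  a <- counts > 0
  co <- crossprod(a)            # species x species co-occurrences
  r <- diag(co)
  cu <- outer(r, r, function(x, y) x) - co
  cu <- cu * t(cu)
  sum(cu[upper.tri(cu)])
}

row_proportion_null <- function(counts, n_perm) {
  p <- colSums(counts) / sum(counts)
  depths <- rowSums(counts)
  sims <- array(0L, dim = c(nrow(counts), ncol(counts), n_perm))
  for (k in seq_len(n_perm))
    sims[, , k] <- t(vapply(depths,
                            function(d) stats::rmultinom(1, d, p)[, 1],
                            integer(ncol(counts))))
  sims
}

#' Classify OTUs as generalists, specialists or neutral
#'
#' Observed Levins' B per OTU is compared against a permutation null: in
#' each permutation the count matrix is randomised (default
#' `count_swap`, a quasiswap that preserves every row and column total
#' exactly on integer counts) and B recomputed. An OTU whose observed B
#' exceeds the upper envelope quantile is a habitat generalist, one
#' below the lower quantile a specialist, anything inside the envelope
#' neutral. Matrices too sparse for the swap to mix (< 2 checkerboard
#' units) fall back to the `row_proportion` null (sample totals
#' redistributed multinomially at metacommunity proportions) with a
#' warning.
#'
#' @param table an [otu_table] with at least 2 samples.
#' @param n_perm number of permutations (default 1000, minimum 99).
#' @param conf two-sided envelope coverage (default 0.95).
#' @param null_model `"count_swap"` (default) or `"row_proportion"`.
#' @param seed integer seed.
#' @param n_boot bootstrap replicates for the community B_m summary.
#' @return object of class `niche_breadth_result`: data.frame `taxa`
#'   (`otu_id`, `b`, `null_lower`, `null_upper`, `category`), `b_m`
#'   list from [community_bm()], `fractions` (per-category OTU-count and
#'   summed-relative-abundance shares), and the call parameters.
#' @export
classify_specialists <- function(table, n_perm = 1000, conf = 0.95,
                                 null_model = c("count_swap",
                                                "row_proportion"),
                                 seed = 1L, n_boot = 100) {
  stopifnot(inherits(table, "otu_table"), n_perm >= 99,
            conf > 0, conf < 1)
  null_model <- match.arg(null_model)
  counts <- table$counts
  if (nrow(counts) < 2) stop("need at least 2 samples")
  if (null_model == "count_swap" && checkerboard_units(counts) < 2) {
    warning("matrix too sparse for the swap null (< 2 checkerboard ",
            "units); falling back to row_proportion")
    null_model <- "row_proportion"
  }
  rel <- relative_abundance(counts)
  b_obs <- levins_b_all(rel)

  if (null_model == "count_swap") {
    nm <- vegan::nullmodel(counts, "quasiswap_count")
    sims <- stats::simulate(nm, nsim = n_perm, seed = seed)
  } else {
    set.seed(seed)
    sims <- row_proportion_null(counts, n_perm)
  }
  null_b <- matrix(NA_real_, n_perm, ncol(counts))
  for (k in seq_len(n_perm)) {
    sk <- sims[, , k]
    null_b[k, ] <- levins_b_all(sk / rowSums(sk))
  }
  alpha <- (1 - conf) / 2
  qs <- apply(null_b, 2, stats::quantile,
              probs = c(alpha, 1 - alpha), na.rm = TRUE)
  category <- ifelse(is.na(b_obs), NA_character_,
                     ifelse(b_obs > qs[2, ], "generalist",
                            ifelse(b_obs < qs[1, ], "specialist",
                                   "neutral")))
  taxa <- data.frame(otu_id = colnames(counts), b = unname(b_obs),
                     null_lower = unname(qs[1, ]),
                     null_upper = unname(qs[2, ]),
                     category = unname(category), row.names = NULL)
  present <- !is.na(category)
  mass <- colMeans(rel)[present]
  cat_p <- category[present]
  lv <- c("generalist", "specialist", "neutral")
  fractions <- data.frame(
    category = lv,
    otu_fraction = as.numeric(table(factor(cat_p, lv)) / sum(present)),
    abundance_fraction = vapply(lv, function(l)
      sum(mass[cat_p == l]) / sum(mass), numeric(1)),
    row.names = NULL)
  bm <- community_bm(rel, n_boot = n_boot, seed = seed)
  structure(list(taxa = taxa, b_m = bm, fractions = fractions,
                 n_perm = n_perm, conf = conf, null_model = null_model,
                 seed = seed),
            class = "niche_breadth_result")
}

#' @export
print.niche_breadth_result <- function(x, ...) {
  cat("niche breadth over", nrow(x$taxa), "OTUs; B_m =",
      round(x$b_m$b_m, 3), "+/-", round(x$b_m$boot_sd, 3),
      sprintf("(%d bootstraps)\n", x$b_m$n_boot))
  print(x$fractions)
  invisible(x)
}
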