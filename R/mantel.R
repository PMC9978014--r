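#' Single-variable environmental distance matrix
#'
#' Pairwise Euclidean distance on one environmental variable, i.e.
#' |x_i - x_k|, optionally after z-scoring. Samples with a missing
#' value are dropped (pairwise-complete policy; the retained ids are
#' the matrix dimnames).
#'
#' @param env data.frame from [read_env_table()].
#' @param variable column name.
#' @param standardize z-score the variable first (default FALSE; for a
#'   single variable this only rescales all distances by 1/sd).
#' @return symmetric distance matrix over the non-missing samples.
#' @export
env_distance <- function(env, variable, standardize = FALSE) {
  if (!variable %in% colnames(env)) stop("unknown variable: ", variable)
  x <- env[[variable]]
  names(x) <- rownames(env)
  x <- x[!is.na(x)]
  if (length(x) < 3) stop("need >= 3 samples with values for ", variable)
  if (stats::sd(x) == 0) stop("zero-variance variable: ", variable)
  if (standardize) x <- (x - mean(x)) / stats::sd(x)
  d <- abs(outer(x, x, "-"))
  diag(d) <- 0
  d
}

#' Mantel test with Spearman correlation
#'
#' Correlates the lower triangles of two pairwise sample matrices with
#' Spearman's rank correlation; significance comes from jointly
#' permuting the rows and columns of `m2`. The p-value is two-sided:
#' p = (1 + #\{|r_null| >= |r_obs|\}) / (n_perm + 1).
#'
#' Matrices are aligned on their shared sample ids; samples present in
#' only one matrix (e.g. dropped for missing environmental values) are
#' excluded from both sides.
#'
#' @param m1 pairwise matrix, typically betaNTI.
#' @param m2 pairwise matrix, typically an [env_distance()].
#' @param n_perm permutations (default 999, minimum 99).
#' @param seed integer seed.
#' @return list of class `mantel_result`: `r`, `p.value`, `n_perm`,
#'   `n_samples`, `n_pairs`.
#' @export
mantel_spearman <- function(m1, m2, n_perm = 999, seed = 1L) {
  stopifnot(n_perm >= 99)
  if (is.null(rownames(m1)) || is.null(rownames(m2)))
    stop("matrices must carry sample ids as dimnames")
  shared <- intersect(rownames(m1), rownames(m2))
  if (length(shared) < 3)
    stop("matrices share fewer than 3 samples")
  m1 <- m1[shared, shared]
  m2 <- m2[shared, shared]
  lt <- lower.tri(m1)
  v1 <- m1[lt]
  r_obs <- stats::cor(v1, m2[lt], method = "spearman")
  n <- length(shared)
  set.seed(seed)
  r_null <- vapply(seq_len(n_perm), function(k) {
    p <- sample.int(n)
    stats::cor(v1, m2[p, p][lt], method = "spearman")
  }, numeric(1))
  p <- (1 + sum(abs(r_null) >= abs(r_obs) - 1e-12)) / (n_perm + 1)
  structure(list(r = r_obs, p.value = p, n_perm = n_perm,
                 n_samples = n, n_pairs = sum(lt)),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("Mantel (Spearman): r = %.4f, p = %.4g (%d permutations, %d pairs)\n",
              x$r, x$p.value, x$n_perm, x$n_pairs))
  invisible(x)
}

#' Mantel screen of betaNTI against every environmental variable
#'
#' Runs [mantel_spearman()] of a betaNTI matrix against the
#' single-variable Euclidean distances of each environmental column.
#' Zero-variance variables are skipped with a warning. No multiplicity
#' correction is applied by default; `correction = "bh"` adds a
#' BH-adjusted column.
#'
#' @param bnti betaNTI matrix (or `beta_nti_result`).
#' @param env environmental data.frame.
#' @param n_perm,seed passed to [mantel_spearman()].
#' @param correction `"none"` or `"bh"`.
#' @return data.frame: `variable`, `r`, `p`, (`p_adj`,) `n_pairs`.
#' @export
mantel_env_screen <- function(bnti, env, n_perm = 999, seed = 1L,
                              correction = c("none", "bh")) {
  correction <- match.arg(correction)
  if (inherits(bnti, "beta_nti_result")) bnti <- bnti$bnti
  rows <- lapply(colnames(env), function(v) {
    d <- tryCatch(env_distance(env, v), error = function(e) NULL)
    if (is.null(d)) {
      warning("skipping variable ", v, " (constant or too few values)")
      return(NULL)
    }
    mt <- mantel_spearman(bnti, d, n_perm = n_perm, seed = seed)
    data.frame(variable = v, r = mt$r, p = mt$p.value,
               n_pairs = mt$n_pairs)
  })
  out <- do.call(rbind, rows)
  if (!is.null(out) && correction == "bh")
    out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out
}
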