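#!/usr/bin/env Rscript
# Mantel screen: betaNTI phylogenetic turnover against the Euclidean
# distances of every environmental variable (the true gradient plus
# inert noise variables).

suppressMessages(library(commassembly))

seed <- 42L
for (regime in c("neutral", "selection", "dispersal_limitation")) {
  dir <- file.path("results/data", regime)
  out <- file.path("results", regime)
  bnti <- read_matrix_tsv(file.path(out, "bnti.tsv"))
  env <- read_env_table(file.path(dir, "env.csv"))
  mt <- mantel_env_screen(bnti, env, n_perm = 999, seed = seed)
  write_results(mt, file.path(out, "mantel.tsv"), "tsv")
  cat(regime, "\n")
  for (i in seq_len(nrow(mt)))
    cat(sprintf("  %-10s r = %6.3f  p = %.3f\n",
                mt$variable[i], mt$r[i], mt$p[i]))
}
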