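#!/usr/bin/env Rscript
# Levins' niche breadth and generalist/specialist classification for the
# abundant and rare subcommunities of each simulated dataset.

suppressMessages(library(commassembly))

seed <- 42L
for (regime in c("neutral", "selection", "dispersal_limitation")) {
  dir <- file.path("results/data", regime)
  tab <- read_otu_table(file.path(dir, "table.tsv"), min_count = 0)
  cls <- classify_abundance(relative_abundance(tab))
  out <- file.path("results", regime)
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  for (class in c("abundant", "rare")) {
    otus <- names(cls$category)[cls$category == class]
    sub <- subset_otu_table(tab, otus = otus, drop_empty = TRUE)
    res <- suppressWarnings(
      classify_specialists(sub, n_perm = 999, seed = seed))
    write_results(res$taxa,
                  file.path(out, paste0("niche_", class, ".tsv")), "tsv")
    fr <- setNames(res$fractions$otu_fraction, res$fractions$category)
    cat(sprintf(
      "%-21s %-8s B_m %5.2f +/- %5.3f | gen %4.1f%% spec %4.1f%% neutral %4.1f%% (%s null)\n",
      regime, class, res$b_m$b_m, res$b_m$boot_sd,
      100 * fr["generalist"], 100 * fr["specialist"], 100 * fr["neutral"],
      res$null_model))
  }
}
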