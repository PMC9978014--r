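#' Configuration for the end-to-end pipeline
#'
#' @param otu_path,tree_path,env_path input files
#'   ([read_otu_table()] / [read_tree()] / [read_env_table()] formats).
#' @param habitat optional named character vector sample_id -> group;
#'   when given, every stage runs per habitat group.
#' @param min_count OTU total-count filter at load (default 2).
#' @param abundance_threshold abundant/rare cutoff (default 1e-4).
#' @param r_min,p_max network thresholds (defaults 0.8, 0.01).
#' @param prevalence network prevalence filter (default 2/3).
#' @param n_null null-model replicates for betaNTI and RC_Bray
#'   (default 199; minimum 99).
#' @param n_perm permutations for the niche-breadth null and the Mantel
#'   tests (default 199; minimum 99).
#' @param n_boot bootstrap replicates for B_m (default 100).
#' @param n_restarts modularity restarts (default 20).
#' @param seed master seed.
#' @param out_dir output directory.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(otu_path, tree_path, env_path = NULL,
                            habitat = NULL, min_count = 2,
                            abundance_threshold = 1e-4,
                            r_min = 0.8, p_max = 0.01,
                            prevalence = 2 / 3,
                            n_null = 199, n_perm = 199, n_boot = 100,
                            n_restarts = 20, seed = 1L,
                            out_dir = "pipeline_out") {
  stopifnot(n_null >= 99, n_perm >= 99)
  for (p in c(otu_path, tree_path, env_path))
    if (!file.exists(p)) stop("input file not found: ", p)
  structure(as.list(environment()), class = "pipeline_config")
}

subset_label <- function(group, class) {
  if (is.null(group)) class else paste(group, class, sep = "_")
}

#' Run the full inference chain
#'
#' Sequence: load inputs; partition OTUs into abundant/rare; alpha
#' diversity with group comparison; Bray-Curtis PCoA; Levins' niche
#' breadth with generalist/specialist classification; betaNTI +
#' RC_Bray assembly-process attribution per abundance class;
#' co-occurrence network with topology; Mantel screen of betaNTI
#' against every environmental variable. Every stage writes its table
#' under `out_dir` and the whole result surface lands in
#' `report.json`, which is byte-identical across reruns with the same
#' config and seed.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, the report list.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  table <- read_otu_table(config$otu_path, min_count = config$min_count)
  tree <- read_tree(config$tree_path)
  env <- if (!is.null(config$env_path)) {
    align_env(read_env_table(config$env_path), table)
  }
  groups <- if (is.null(config$habitat)) {
    list(all = rownames(table$counts))
  } else {
    split(names(config$habitat), config$habitat)
  }
  report <- list(config = lapply(unclass(config), function(x)
    if (is.character(x) && length(x) == 1) x else unclass(x)))
  for (gname in names(groups)) {
    gtab <- subset_otu_table(table, samples = groups[[gname]])
    rel <- relative_abundance(gtab)
    cls <- classify_abundance(rel, threshold = config$abundance_threshold)
    div <- alpha_diversity(gtab)
    by_class <- split(names(cls$category), cls$category)
    g_report <- list(
      n_samples = nrow(gtab$counts), n_otus = ncol(gtab$counts),
      abundance_partition = list(
        otu_fraction = as.list(cls$otu_fraction),
        abundance_fraction = as.list(cls$abundance_fraction)))
    write_results(
      data.frame(otu_id = names(cls$category),
                 category = unname(cls$category)),
      file.path(config$out_dir, paste0("partition_", gname, ".tsv")),
      "tsv")
    write_results(div, file.path(config$out_dir,
                                 paste0("diversity_", gname, ".tsv")),
                  "tsv")
    if (nrow(gtab$counts) >= 3) {
      ord <- pcoa_bray(gtab)
      g_report$pcoa_explained <- ord$explained[1:2]
    }
    for (cl_name in names(by_class)) {
      otus <- by_class[[cl_name]]
      lab <- subset_label(gname, cl_name)
      # samples without any OTU of this class drop out of the subset
      sub <- subset_otu_table(gtab, otus = otus, drop_empty = TRUE)
      if (ncol(sub$counts) < 3 || nrow(sub$counts) < 4) next
      niche <- classify_specialists(sub, n_perm = config$n_perm,
                                    seed = config$seed,
                                    n_boot = config$n_boot)
      asm <- assembly_processes(sub, tree, n_null = config$n_null,
                                seed = config$seed)
      write_results(niche$taxa,
                    file.path(config$out_dir,
                              paste0("niche_", lab, ".tsv")), "tsv")
      write_results(asm$pairs,
                    file.path(config$out_dir,
                              paste0("assembly_", lab, ".tsv")), "tsv")
      g_report$subsets[[cl_name]] <- list(
        n_otus = ncol(sub$counts),
        b_m = niche$b_m$b_m, b_m_boot_sd = niche$b_m$boot_sd,
        niche_fractions = stats::setNames(
          as.list(niche$fractions$otu_fraction),
          niche$fractions$category),
        process_fractions = as.list(asm$fractions),
        n_pairs = nrow(asm$pairs), n_excluded = asm$n_excluded)
      if (!is.null(env)) {
        mt <- mantel_env_screen(asm$bnti_detail, env,
                                n_perm = config$n_perm,
                                seed = config$seed)
        write_results(mt, file.path(config$out_dir,
                                    paste0("mantel_", lab, ".tsv")),
                      "tsv")
        g_report$subsets[[cl_name]]$mantel <- stats::setNames(
          lapply(seq_len(nrow(mt)),
                 function(i) list(r = mt$r[i], p = mt$p[i])),
          mt$variable)
      }
    }
    net <- tryCatch({
      filt <- prevalence_filter(gtab, config$prevalence)
      suppressWarnings(build_network(filt, r_min = config$r_min,
                                     p_max = config$p_max))
    }, error = function(e) NULL)
    if (!is.null(net) && nrow(net$edges) > 0) {
      topo <- topology(net, n_restarts = config$n_restarts,
                       seed = config$seed)
      net <- annotate_nodes(net, classification = cls,
                            modules = topo$modules)
      write_results(net, file.path(config$out_dir,
                                   paste0("network_", gname, ".graphml")),
                    "graphml")
      g_report$network <- topo[c("n_nodes", "n_edges", "average_degree",
                                 "clustering_coefficient",
                                 "path_distance", "density",
                                 "modularity_mean", "modularity_sd",
                                 "n_modules")]
    }
    report[[gname]] <- g_report
  }
  write_results(report, file.path(config$out_dir, "report.json"), "json")
  invisible(report)
}
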