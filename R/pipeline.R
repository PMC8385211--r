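# Full-analysis orchestration: simulate or ingest -> rarefy -> relative
# abundance -> classify -> assembly nulls (total and per subcommunity) ->
# enrichment -> network -> metrics -> robustness -> report. Every stage
# seed derives deterministically from the master seed, and no output file
# carries a timestamp, so identical config + seed gives byte-identical
# outputs.

#' Pipeline configuration
#'
#' Either `counts_path`/`metadata_path`/`tree_path` point at input files,
#' or `preset` names a synthetic regime from [regime_preset()].
#'
#' @param counts_path,metadata_path,tree_path input files (TSV, TSV,
#'   Newick); ignored when `preset` is given.
#' @param preset synthetic preset name, see [regime_preset()].
#' @param n_otus,n_samples_per_group synthetic sizes (preset mode only).
#' @param depth rarefaction depth; `NULL` uses the smallest sample total.
#' @param rare_cut,abundant_cut classification thresholds (fractions).
#' @param r_threshold,p_threshold network edge thresholds.
#' @param min_total network prevalence filter (total reads), see
#'   [filter_min_sequences()].
#' @param alpha enrichment significance level.
#' @param null_reps null-model replicates for betaNTI and RC-Bray
#'   (default 999; 199 is the documented fast mode).
#' @param subcommunities run betaNTI for the CRT/ART/AT subcommunities on
#'   the pruned tree with renormalized abundances (default TRUE).
#' @param robustness_reps replicates for the random-removal robustness
#'   curve.
#' @param env_var environmental variable used for niche optima.
#' @param seed master seed (required).
#' @param outdir output directory.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(counts_path = NULL, metadata_path = NULL,
                            tree_path = NULL, preset = NULL,
                            n_otus = 300, n_samples_per_group = 24,
                            depth = NULL, rare_cut = 1e-4,
                            abundant_cut = 1e-2, r_threshold = 0.8,
                            p_threshold = 0.01, min_total = 21,
                            alpha = 0.05, null_reps = 999,
                            subcommunities = TRUE, robustness_reps = 30,
                            env_var = "temperature", seed, outdir) {
  if (missing(seed)) stop("a seed is required")
  if (is.null(preset) &&
      (is.null(counts_path) || is.null(metadata_path) || is.null(tree_path))) {
    stop("give either input paths or a synthetic preset")
  }
  stopifnot(
    rare_cut > 0, rare_cut < abundant_cut, abundant_cut <= 1,
    r_threshold >= 0, r_threshold <= 1,
    p_threshold > 0, p_threshold <= 1,
    alpha > 0, alpha < 1, null_reps >= 2
  )
  structure(
    list(counts_path = counts_path, metadata_path = metadata_path,
         tree_path = tree_path, preset = preset, n_otus = n_otus,
         n_samples_per_group = n_samples_per_group, depth = depth,
         rare_cut = rare_cut, abundant_cut = abundant_cut,
         r_threshold = r_threshold, p_threshold = p_threshold,
         min_total = min_total, alpha = alpha, null_reps = null_reps,
         subcommunities = subcommunities,
         robustness_reps = robustness_reps, env_var = env_var,
         seed = seed, outdir = outdir),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file of [pipeline_config()] fields.
#' @param ... overrides taking precedence over the file.
#' @return a [pipeline_config()].
#' @export
read_pipeline_config <- function(path, ...) {
  vals <- yaml::read_yaml(path)
  overrides <- list(...)
  vals[names(overrides)] <- overrides
  do.call(pipeline_config, vals)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Executes the stages in fixed order and writes a TSV/JSON report bundle
#' plus a manifest into `config$outdir`. Identical config and seed produce
#' byte-identical outputs.
#'
#' @param config a [pipeline_config()].
#' @param quiet suppress stage messages.
#' @return invisibly, a list with the in-memory stage results and
#'   `manifest` (named file paths).
#' @export
run_full_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (!quiet) message("[microassembly] ", sprintf(...))
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  manifest <- character(0)

  # -- ingest or simulate ---------------------------------------------------
  if (!is.null(config$preset)) {
    say("simulating preset '%s'", config$preset)
    sim <- simulate_survey(regime_preset(
      config$preset, n_otus = config$n_otus,
      n_samples_per_group = config$n_samples_per_group,
      seed = stage_seed(config$seed, 10)
    ))
    table <- sim$table
    tree <- sim$tree
  } else {
    say("reading %s", config$counts_path)
    table <- read_community_table(config$counts_path, config$metadata_path)
    tree <- read_newick(config$tree_path)
  }

  # -- rarefy + relative abundance -----------------------------------------
  depth <- config$depth %||% min(colSums(table$counts))
  say("rarefying to %d reads/sample", depth)
  table <- rarefy_counts(table, depth, seed = stage_seed(config$seed, 11))
  ra <- relative_abundance(table)

  # -- classification -------------------------------------------------------
  cls <- classify_all(ra, config$rare_cut, config$abundant_cut)
  manifest["classification"] <- write_tsv(
    cls$otus, file.path(outdir, "classification.tsv"))
  manifest["classification_summary"] <- write_tsv(
    data.frame(category = names(cls$summary),
               count = as.integer(cls$summary)),
    file.path(outdir, "classification_summary.tsv"))

  # -- alpha diversity ------------------------------------------------------
  alpha <- alpha_diversity_table(table)
  manifest["alpha_diversity"] <- write_tsv(
    alpha, file.path(outdir, "alpha_diversity.tsv"))

  # -- assembly nulls: total community -------------------------------------
  say("betaNTI (%d reps) for the total community", config$null_reps)
  bnti <- beta_nti_matrix(table, tree, reps = config$null_reps,
                          seed = stage_seed(config$seed, 12))
  say("RC-Bray (%d reps)", config$null_reps)
  rc <- rc_bray_matrix(table, reps = config$null_reps,
                       seed = stage_seed(config$seed, 13))
  part <- partition_processes(bnti, rc)
  manifest["pairwise_assembly"] <- write_tsv(
    part$pairs, file.path(outdir, "pairwise_assembly.tsv"))
  fractions <- cbind(community = "total", part$fractions)

  # -- assembly nulls: CRT / ART / AT subcommunities -----------------------
  if (isTRUE(config$subcommunities)) {
    for (sub in c("CRT", "ART", "AT")) {
      sub_tab <- tryCatch(subset_by_class(table, cls, sub),
                          error = function(e) NULL)
      if (is.null(sub_tab) || nrow(sub_tab$counts) < 3) {
        say("subcommunity %s empty or too small; skipped", sub)
        next
      }
      # samples with no reads in the subcommunity have no betaMNTD; their
      # pairs are excluded from this subcommunity's summary
      occupied <- colSums(sub_tab$counts) > 0
      if (sum(occupied) < 2) {
        say("subcommunity %s present in < 2 samples; skipped", sub)
        next
      }
      if (!all(occupied)) {
        sub_tab <- community_table(
          sub_tab$counts[, occupied, drop = FALSE],
          sub_tab$sample_groups[occupied],
          if (!is.null(sub_tab$env)) sub_tab$env[occupied, , drop = FALSE]
        )
      }
      say("betaNTI for subcommunity %s (%d OTUs)", sub,
          nrow(sub_tab$counts))
      sub_bnti <- suppressWarnings(
        beta_nti_matrix(sub_tab, tree, reps = config$null_reps,
                        seed = stage_seed(config$seed, 12))
      )
      sub_part <- partition_processes(sub_bnti, NULL)
      fractions <- rbind(fractions,
                         cbind(community = sub, sub_part$fractions))
    }
  }
  manifest["process_fractions"] <- write_tsv(
    fractions, file.path(outdir, "process_fractions.tsv"))

  # -- niche optima + phylogenetic signal ----------------------------------
  correlogram <- NULL
  if (!is.null(table$env) && config$env_var %in% colnames(table$env)) {
    optima <- suppressWarnings(niche_optima(table, config$env_var))
    al <- align_tree_table(table, tree)
    D <- cophenetic_matrix(al$tree)
    correlogram <- phylo_signal_correlogram(
      optima, D, permutations = 199, seed = stage_seed(config$seed, 14))
    manifest["phylo_signal"] <- write_tsv(
      correlogram, file.path(outdir, "phylo_signal.tsv"))
  }

  # -- network --------------------------------------------------------------
  say("building co-occurrence network")
  net_tab <- filter_min_sequences(table, config$min_total)
  labels <- enrichment_labels(net_tab, config$alpha)
  classes <- stats::setNames(as.character(cls$otus$category),
                             cls$otus$otu_id)
  net <- build_network(relative_abundance(net_tab),
                       r_threshold = config$r_threshold,
                       p_threshold = config$p_threshold,
                       node_labels = labels, node_classes = classes)
  manifest["network_edges"] <- write_tsv(
    net$edges, file.path(outdir, "network_edges.tsv"))
  nm <- node_metrics(net)
  nodes <- merge(net$nodes, nm, by.x = "otu_id", by.y = "node", sort = TRUE)
  if (igraph::ecount(net$graph) > 0) {
    mod <- modularity_partition(net, seed = stage_seed(config$seed, 15))
    nodes$module <- mod$membership[nodes$otu_id]
  } else {
    mod <- list(modularity = NA_real_, n_modules = 0L)
    nodes$module <- NA_integer_
  }
  manifest["network_nodes"] <- write_tsv(
    nodes, file.path(outdir, "network_nodes.tsv"))

  met <- network_metrics(net)
  pl <- powerlaw_fit_r2(nm$degree)
  er <- if (met$n_edges > 0) {
    erdos_renyi_baseline(met$n_nodes, met$n_edges, reps = 50,
                         seed = stage_seed(config$seed, 16))
  } else {
    list(apl_mean = NA, apl_sd = NA, clustering_mean = NA,
         clustering_sd = NA)
  }
  summary_df <- data.frame(
    metric = c("n_tested", "n_isolated", "n_nodes", "n_edges",
               "average_degree", "connectance", "diameter",
               "average_path_length", "clustering", "powerlaw_r2",
               "powerlaw_slope", "modularity_Q", "n_modules",
               "random_apl_mean", "random_clustering_mean",
               "natural_connectivity"),
    value = c(net$n_tested, net$n_isolated, met$n_nodes, met$n_edges,
              met$average_degree, met$connectance, met$diameter,
              met$average_path_length, met$clustering, pl$r_squared,
              pl$slope, mod$modularity, mod$n_modules, er$apl_mean,
              er$clustering_mean, natural_connectivity(net))
  )
  manifest["network_summary"] <- write_tsv(
    summary_df, file.path(outdir, "network_summary.tsv"))

  census <- edge_census(net, labels)
  manifest["edge_census"] <- write_tsv(
    census, file.path(outdir, "edge_census.tsv"))

  if (igraph::ecount(net$graph) > 0) {
    say("robustness curve (%d reps)", config$robustness_reps)
    rob <- robustness_curve(net, "random", reps = config$robustness_reps,
                            seed = stage_seed(config$seed, 17))
    manifest["robustness"] <- write_tsv(
      rob, file.path(outdir, "robustness.tsv"))
  } else {
    rob <- NULL
  }

  # -- manifest -------------------------------------------------------------
  manifest_path <- file.path(outdir, "manifest.json")
  jsonlite::write_json(
    list(package = "microassembly",
         config = unclass(config),
         seed = config$seed,
         files = as.list(manifest)),
    manifest_path, auto_unbox = TRUE, digits = NA, null = "null"
  )
  say("done: %d files in %s", length(manifest) + 1, outdir)
  invisible(list(
    table = table, tree = tree, classification = cls, alpha = alpha,
    bnti = bnti, rc = rc, partition = part, fractions = fractions,
    correlogram = correlogram, network = net, node_metrics = nm,
    network_summary = summary_df, modularity = mod, robustness = rob,
    census = census,
    manifest = c(manifest, manifest = manifest_path)
  ))
}
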