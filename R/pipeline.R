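#' Configuration for a full pipeline run
#'
#' Collects every tunable of the end-to-end analysis. Either point
#' `table_path`/`metadata_path` at TSV inputs ([read_taxa_table()] dialect)
#' or leave them `NULL` to generate synthetic data from `synth` (arguments
#' for [synth_spec()]). Unknown keys are rejected.
#'
#' @param out_dir Output directory (created if missing).
#' @param table_path,metadata_path Optional input TSV paths.
#' @param synth Named list of [synth_spec()] arguments (used when no input
#'   paths are given).
#' @param contaminant_threshold Prevalence-score threshold (default 0.5).
#' @param remove_contaminants Remove flagged taxa before analysis? Default
#'   `TRUE`.
#' @param sparcc Named list of [sparcc_infer()] settings.
#' @param edge_cutoff Correlation threshold for edges (default 0.5).
#' @param centrality_percentile Percentile for most-central sets (default
#'   75).
#' @param addition_grid Node counts for the addition analysis (default
#'   `c(100, 300, 500, 700, 1000)`).
#' @param addition_reps Replicates per grid size (default 2).
#' @param knockout_taxa Taxa to knock out; `NULL` picks the first four
#'   shared (present-in-every-group) taxa alphabetically.
#' @param seed Master seed; all stage seeds are derived from it by fixed
#'   offsets.
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(out_dir,
                       table_path = NULL, metadata_path = NULL,
                       synth = list(),
                       contaminant_threshold = 0.5,
                       remove_contaminants = TRUE,
                       sparcc = list(),
                       edge_cutoff = 0.5,
                       centrality_percentile = 75,
                       addition_grid = c(100, 300, 500, 700, 1000),
                       addition_reps = 2,
                       knockout_taxa = NULL,
                       seed = 1L) {
  check_number(contaminant_threshold, "contaminant_threshold", 0, 1)
  check_number(edge_cutoff, "edge_cutoff", 1e-12, 1)
  check_number(centrality_percentile, "centrality_percentile", 0, 100)
  stopifnot(all(addition_grid >= 1))
  check_number(addition_reps, "addition_reps", 1, Inf, TRUE)
  check_number(seed, "seed", -2^31, 2^31, TRUE)
  allowed_sparcc <- c("n_iter", "exclusion_threshold", "n_resamples",
                      "pseudocount")
  bad <- setdiff(names(sparcc), allowed_sparcc)
  if (length(bad) > 0) {
    stopf("unknown sparcc setting(s): %s", paste(bad, collapse = ", "))
  }
  structure(list(
    out_dir = out_dir, table_path = table_path,
    metadata_path = metadata_path, synth = synth,
    contaminant_threshold = contaminant_threshold,
    remove_contaminants = remove_contaminants,
    sparcc = sparcc, edge_cutoff = edge_cutoff,
    centrality_percentile = centrality_percentile,
    addition_grid = as.integer(sort(addition_grid)),
    addition_reps = as.integer(addition_reps),
    knockout_taxa = knockout_taxa, seed = as.integer(seed)
  ), class = "run_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys mirror the arguments of [run_config()]; unknown keys are rejected.
#'
#' @param path YAML file path.
#' @param seed Optional seed override.
#' @param out_dir Optional output-directory override.
#' @return A `run_config`.
#' @export
read_run_config <- function(path, seed = NULL, out_dir = NULL) {
  raw <- yaml::read_yaml(path)
  allowed <- setdiff(names(formals(run_config)), "")
  bad <- setdiff(names(raw), allowed)
  if (length(bad) > 0) {
    stopf("unknown config key(s) in '%s': %s", path,
          paste(bad, collapse = ", "))
  }
  if (!is.null(seed)) raw$seed <- seed
  if (!is.null(out_dir)) raw$out_dir <- out_dir
  if (is.null(raw$out_dir)) stopf("config must set out_dir")
  do.call(run_config, raw)
}

write_stage <- function(x, dir, name) {
  path <- file.path(dir, name)
  readr::write_tsv(x, path, progress = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Executes, in order: data loading or synthesis, contaminant filtering,
#' alpha/beta diversity (including PERMANOVA, dispersion, UPGMA tree and
#' Venn partition), SparCC network inference per group, topology summaries,
#' cross-network comparison, robustness (four attack strategies per
#' network plus the node-addition grid), and single-taxon knockouts with
#' re-inference and re-attack. Every output file is listed in a manifest
#' with an MD5 checksum; an identical config and seed reproduces identical
#' checksums.
#'
#' @param config A [run_config()].
#' @return The manifest tibble (`path`, `md5`), invisibly; also written to
#'   `manifest.tsv` in `out_dir`.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- config$out_dir
  paths <- character(0)
  seed <- config$seed

  # --- data ---
  if (!is.null(config$table_path)) {
    tab <- read_taxa_table(config$table_path, config$metadata_path)
  } else {
    spec <- do.call(synth_spec, modifyList(list(seed = seed), config$synth))
    tab <- generate_table(spec)
  }
  paths <- c(paths, file.path(out, c("table.tsv", "metadata.tsv")))
  write_taxa_table(tab, file.path(out, "table.tsv"),
                   file.path(out, "metadata.tsv"))

  # --- contaminant filter ---
  if (sum(tab$is_control) > 0) {
    rep <- find_contaminants(tab, config$contaminant_threshold)
    paths <- c(paths, write_stage(tidy(rep), out, "contaminants.tsv"))
    filtered <- if (config$remove_contaminants) rep$filtered else tab
  } else {
    filtered <- tab
  }
  bio <- biological_samples(filtered)
  groups <- sort(unique(bio$group))

  # --- diversity ---
  alpha <- alpha_diversity(bio)
  paths <- c(paths, write_stage(tidy(alpha), out, "alpha_samples.tsv"),
             write_stage(alpha$tests, out, "alpha_tests.tsv"))
  bray <- beta_distance(bio, "bray_curtis")
  jac <- beta_distance(bio, "jaccard")
  for (d in list(list(bray, "bray_curtis"), list(jac, "jaccard"))) {
    dm_tbl <- dplyr::bind_cols(tibble(sample_id = rownames(d[[1]])),
                               as_tibble(unclass(d[[1]])))
    paths <- c(paths, write_stage(dm_tbl, out,
                                  sprintf("dist_%s.tsv", d[[2]])))
  }
  pc <- pcoa_ordination(bray)
  paths <- c(paths, write_stage(tidy(pc), out, "pcoa_coordinates.tsv"))
  pn <- permanova_test(bray, bio$group, seed = derive_seed(seed, 11))
  bd <- beta_dispersion(bray, bio$group)
  paths <- c(paths, write_stage(
    bind_rows(mutate(tidy(pn)[, c("statistic", "p_value")], test = "permanova"),
              mutate(glance(bd), test = "betadisper_anova")),
    out, "beta_tests.tsv"))
  tree <- hclust_tree(jac)
  tree_path <- file.path(out, "jaccard_upgma.nwk")
  write_newick(tree, tree_path)
  paths <- c(paths, tree_path)
  sets <- group_taxa_sets(bio)
  venn <- venn_partition(sets[[1]], sets[[2]])
  paths <- c(paths, write_stage(tidy(venn), out, "venn_counts.tsv"))

  # --- networks per group ---
  sparcc_seed <- derive_seed(seed, 21)
  nets <- list()
  for (g in groups) {
    sub <- bio[bio$group == g, ]
    class(sub) <- c("taxa_table", setdiff(class(sub), "taxa_table"))
    fit <- do.call(sparcc_infer, c(list(table = sub, seed = sparcc_seed),
                                   config$sparcc))
    edges <- threshold_edges(fit, config$edge_cutoff)
    nets[[g]] <- build_network(edges)
    paths <- c(paths,
               write_stage(edges, out, sprintf("edges_%s.tsv", g)),
               write_stage(centralities_or_empty(nets[[g]]), out,
                           sprintf("centralities_%s.tsv", g)))
    gml <- file.path(out, sprintf("network_%s.graphml", g))
    write_graphml(nets[[g]], gml, seed = derive_seed(seed, 31))
    gexf <- file.path(out, sprintf("network_%s.gexf", g))
    write_gexf(nets[[g]], gexf, seed = derive_seed(seed, 31))
    paths <- c(paths, gml, gexf)
  }
  topo <- imap(nets, function(net, g) {
    mutate(topology_summary(net, seed = derive_seed(seed, 31)),
           network = g, .before = 1)
  }) |> list_rbind()
  paths <- c(paths, write_stage(topo, out, "topology_baseline.tsv"))

  # --- comparison ---
  cmp <- compare_networks(nets[[1]], nets[[2]],
                          percentile = config$centrality_percentile)
  paths <- c(paths, write_stage(tidy(cmp), out, "comparison_jaccard.tsv"),
             write_stage(differential_edges(nets[[1]], nets[[2]]), out,
                         "differential_edges.tsv"))

  # --- robustness ---
  atk_seed <- derive_seed(seed, 41)
  atk <- imap(nets, function(net, g) {
    mutate(attack_all(net, seed = atk_seed), network = g, .before = 1)
  }) |> list_rbind()
  paths <- c(paths, write_stage(atk, out, "attack_curves.tsv"))
  d80 <- atk |>
    group_by(.data$network, .data$strategy) |>
    summarise(disconnect_80 = pct_disconnection_point(
      dplyr::pick("fraction_removed", "connectivity_loss")),
      .groups = "drop")
  paths <- c(paths, write_stage(d80, out, "disconnection_points.tsv"))

  add_seed <- derive_seed(seed, 51)
  adds <- purrr::map(groups, function(g) {
    purrr::map(config$addition_grid, function(n_add) {
      mutate(add_nodes(nets[[g]], n_add, reps = config$addition_reps,
                       seed = derive_seed(add_seed, n_add)),
             network = g, n_add = n_add, .before = 1)
    }) |> list_rbind()
  }) |> list_rbind()
  paths <- c(paths, write_stage(adds, out, "addition_curves.tsv"))
  add_cmp <- purrr::map(config$addition_grid, function(n_add) {
    ca <- adds[adds$network == groups[1] & adds$n_add == n_add, ]
    cb <- adds[adds$network == groups[2] & adds$n_add == n_add, ]
    mutate(compare_addition(ca, cb, seed = derive_seed(add_seed, 7)),
           n_add = n_add, .before = 1)
  }) |> list_rbind() |>
    mutate(p_adjusted = p.adjust(.data$p_value, method = "BH"))
  paths <- c(paths, write_stage(add_cmp, out, "addition_comparison.tsv"))

  # --- knockouts ---
  ko_taxa <- config$knockout_taxa
  if (is.null(ko_taxa)) {
    # default: four shared taxa, skipping the single most abundant one
    # (dominant endosymbionts are excluded from inferred networks anyway)
    shared <- Reduce(intersect, group_taxa_sets(bio))
    ab <- colSums(tt_counts(bio))[shared]
    shared <- setdiff(shared, names(ab)[which.max(ab)])
    ko_taxa <- head(sort(shared, method = "radix"), 4)
  }
  ko <- knockout_experiment(bio, ko_taxa, cutoff = config$edge_cutoff,
                            sparcc_args = config$sparcc, seed = sparcc_seed)
  paths <- c(paths, write_stage(tidy(ko), out, "topology_knockouts.tsv"),
             write_stage(emergent_summary(ko), out, "emergent_summary.tsv"))
  for (tx in names(ko$reports)) {
    for (g in ko$groups) {
      pg <- ko$reports[[tx]]$per_group[[g]]
      paths <- c(paths, write_stage(
        mutate(pg$attacks, network = sprintf("%s_wo_%s", g, tx),
               .before = 1),
        out, sprintf("attack_%s_wo_%s.tsv", g, tx)))
      gml <- file.path(out, sprintf("network_%s_wo_%s.graphml", g, tx))
      write_graphml(pg$network, gml, seed = derive_seed(seed, 31))
      paths <- c(paths, gml)
    }
  }

  manifest <- tibble(
    path = sort(unique(basename(paths))),
    md5 = unname(tools::md5sum(file.path(out, sort(unique(basename(paths))))))
  )
  readr::write_tsv(manifest, file.path(out, "manifest.tsv"),
                   progress = FALSE)
  invisible(manifest)
}

# centralities() errors on empty networks; the pipeline writes an empty
# table instead so a degenerate group still yields a complete manifest.
centralities_or_empty <- function(net) {
  if (igraph::vcount(net$graph) == 0) {
    tibble(taxon = character(), degree = integer(),
           weighted_degree = numeric(), betweenness = numeric(),
           closeness = numeric(), eigenvector = numeric())
  } else {
    centralities(net)
  }
}
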