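#' Zero out one taxon's read counts
#'
#' The in-silico knockout: every sample's count for the taxon is set to
#' zero. The column is retained (the taxon then drops out of SparCC input
#' via the zero-variance guard and so vanishes from re-inferred networks).
#' Idempotent.
#'
#' @param table A `taxa_table`.
#' @param taxon Taxon name present in the table.
#' @return The modified `taxa_table`.
#' @export
remove_taxon <- function(table, taxon) {
  validate_taxa_table(table)
  taxa <- taxon_names(table)
  if (!taxon %in% taxa) {
    near <- agrep(taxon, taxa, max.distance = 0.3, value = TRUE)
    stopf("unknown taxon '%s'%s", taxon,
          if (length(near) > 0) {
            sprintf(" (did you mean: %s?)",
                    paste(head(near, 3), collapse = ", "))
          } else "")
  }
  table[[taxon]] <- rep(0L, nrow(table))
  table
}

# shared inference chain: counts table -> network, under one config
infer_network <- function(table, cutoff = 0.5, sparcc_args = list(),
                          seed = 1L) {
  fit <- do.call(sparcc_infer,
                 c(list(table = table, seed = seed), sparcc_args))
  build_network(threshold_edges(fit, cutoff = cutoff))
}

#' Emergent edges and nodes after a perturbation
#'
#' Set differences over unordered taxon-name pairs and node names: edges
#' present only after, split by sign, and taxa appearing only in the post
#' network.
#'
#' @param pre,post `co_network` objects (before/after).
#' @return List with `edges` (tibble with `sign`), `nodes` (character),
#'   `lost_edges` (tibble).
#' @export
emergent_interactions <- function(pre, post) {
  key <- function(e) paste(pmin(e$taxon_a, e$taxon_b),
                           pmax(e$taxon_a, e$taxon_b), sep = "\r")
  pre_keys <- key(pre$edges)
  post_keys <- key(post$edges)
  list(
    edges = post$edges[!post_keys %in% pre_keys, , drop = FALSE],
    lost_edges = pre$edges[!pre_keys %in% post_keys, , drop = FALSE],
    nodes = setdiff(network_nodes(post), network_nodes(pre))
  )
}

#' In-silico knockout experiment over shared taxa
#'
#' For each taxon in `taxa`, independently (never cumulatively): zero its
#' counts in all samples ([remove_taxon()]), re-run the full inference
#' chain (SparCC with the same seed and settings as the baseline,
#' thresholding, network construction) per group, and assemble a report
#' comparing topology before/after, listing emergent edges (split by sign)
#' and emergent taxa, and — when `run_attacks` — the four attack-strategy
#' robustness curves on both baseline and depleted networks.
#'
#' @param table A `taxa_table` containing both groups (controls, if any,
#'   are ignored by the inference chain).
#' @param taxa Character vector of taxa to knock out; each must be present
#'   (count > 0 somewhere) in every group.
#' @param cutoff Edge threshold on `|r|` (default 0.5).
#' @param sparcc_args List of extra arguments for [sparcc_infer()].
#' @param seed Seed shared by the baseline and every knockout run, so
#'   topology differences are attributable to the knockout.
#' @param run_attacks Also compute attack curves? Default `TRUE`.
#' @return Object of class `knockout_experiment`: `$baseline` (per-group
#'   `co_network`), `$reports` (one `knockout_report` per taxon).
#' @export
knockout_experiment <- function(table, taxa, cutoff = 0.5,
                                sparcc_args = list(), seed = 1L,
                                run_attacks = TRUE) {
  validate_taxa_table(table)
  bio <- biological_samples(table)
  groups <- sort(unique(bio$group))
  for (tx in taxa) {
    if (!tx %in% taxon_names(table)) stopf("unknown taxon '%s'", tx)
    for (g in groups) {
      sub <- bio[bio$group == g, ]
      if (sum(sub[[tx]]) == 0) {
        stopf("taxon '%s' is absent from group '%s'", tx, g)
      }
    }
  }

  group_tables <- lapply(groups, function(g) {
    out <- bio[bio$group == g, ]
    class(out) <- c("taxa_table", setdiff(class(out), "taxa_table"))
    out
  })
  names(group_tables) <- groups

  baseline <- lapply(group_tables, infer_network, cutoff = cutoff,
                     sparcc_args = sparcc_args, seed = seed)
  baseline_attacks <- if (run_attacks) {
    lapply(baseline, attack_all, seed = derive_seed(seed, 5))
  }

  reports <- lapply(taxa, function(tx) {
    per_group <- lapply(groups, function(g) {
      depleted_tab <- remove_taxon(group_tables[[g]], tx)
      net <- infer_network(depleted_tab, cutoff = cutoff,
                           sparcc_args = sparcc_args, seed = seed)
      list(
        network = net,
        topology = topology_summary(net, seed = derive_seed(seed, 9)),
        emergent = emergent_interactions(baseline[[g]], net),
        attacks = if (run_attacks) {
          attack_all(net, seed = derive_seed(seed, 5))
        }
      )
    })
    names(per_group) <- groups
    structure(list(taxon = tx, groups = groups, per_group = per_group),
              class = "knockout_report")
  })
  names(reports) <- taxa

  structure(list(
    baseline = baseline,
    baseline_topology = lapply(baseline, topology_summary,
                               seed = derive_seed(seed, 9)),
    baseline_attacks = baseline_attacks,
    reports = reports,
    groups = groups,
    cutoff = cutoff,
    seed = as.integer(seed)
  ), class = "knockout_experiment")
}

#' @export
print.knockout_experiment <- function(x, ...) {
  cat(sprintf("<knockout_experiment> %d knockouts x %d groups\n",
              length(x$reports), length(x$groups)))
  print(tidy(x))
  invisible(x)
}

#' @export
tidy.knockout_experiment <- function(x, ...) {
  base_rows <- imap(x$baseline_topology, function(topo, g) {
    mutate(topo, group = g, knockout = "baseline", .before = 1)
  }) |> list_rbind()
  ko_rows <- purrr::map(x$reports, function(rep) {
    imap(rep$per_group, function(pg, g) {
      mutate(pg$topology, group = g, knockout = rep$taxon, .before = 1)
    }) |> list_rbind()
  }) |> list_rbind()
  bind_rows(base_rows, ko_rows)
}

#' @export
tidy.knockout_report <- function(x, ...) {
  imap(x$per_group, function(pg, g) {
    mutate(pg$topology, group = g, knockout = x$taxon, .before = 1)
  }) |> list_rbind()
}

#' Emergent-edge summary of a knockout experiment
#'
#' @param x A `knockout_experiment`.
#' @return Tibble: per knockout and group, counts of emergent positive and
#'   negative edges and emergent taxa.
#' @export
emergent_summary <- function(x) {
  purrr::map(x$reports, function(rep) {
    imap(rep$per_group, function(pg, g) {
      tibble(knockout = rep$taxon, group = g,
             emergent_positive = sum(pg$emergent$edges$sign == 1),
             emergent_negative = sum(pg$emergent$edges$sign == -1),
             emergent_nodes = length(pg$emergent$nodes))
    }) |> list_rbind()
  }) |> list_rbind()
}
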