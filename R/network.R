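#' Build a signed co-occurrence network from a thresholded edge list
#'
#' Nodes are the taxa appearing in at least one edge (isolated taxa are
#' dropped, matching the "connected nodes" convention of topology tables);
#' edges carry the correlation `r` and its `sign`. Both signs are retained
#' in the data structure — visual exports may drop negative edges, the
#' analysis never does.
#'
#' @param edges Tibble from [threshold_edges()] (columns `taxon_a`,
#'   `taxon_b`, `r`, `sign`); each unordered pair at most once.
#' @return Object of class `co_network` wrapping an igraph graph and the
#'   edge tibble.
#' @export
build_network <- function(edges) {
  edges <- as_tibble(edges)
  needed <- c("taxon_a", "taxon_b", "r", "sign")
  if (!all(needed %in% names(edges))) {
    stopf("edge list must have columns %s", paste(needed, collapse = ", "))
  }
  if (nrow(edges) > 0) {
    if (any(edges$taxon_a == edges$taxon_b)) stopf("self-loop in edge list")
    key <- paste(pmin(edges$taxon_a, edges$taxon_b),
                 pmax(edges$taxon_a, edges$taxon_b))
    if (anyDuplicated(key)) {
      stopf("duplicate pair(s) in edge list: %s",
            paste(unique(key[duplicated(key)]), collapse = "; "))
    }
  }
  g <- if (nrow(edges) == 0) {
    igraph::make_empty_graph(0, directed = FALSE)
  } else {
    igraph::graph_from_data_frame(
      edges[, c("taxon_a", "taxon_b", "r", "sign")], directed = FALSE)
  }
  structure(list(graph = g, edges = edges), class = "co_network")
}

network_nodes <- function(net) igraph::V(net$graph)$name

#' @export
print.co_network <- function(x, ...) {
  cat(sprintf("<co_network> %d nodes, %d edges (%d positive, %d negative)\n",
              igraph::vcount(x$graph), igraph::ecount(x$graph),
              sum(x$edges$sign == 1), sum(x$edges$sign == -1)))
  invisible(x)
}

#' @export
tidy.co_network <- function(x, ...) x$edges

#' @export
glance.co_network <- function(x, seed = 1L, ...) topology_summary(x, seed = seed)

# Eigenvector centrality by power iteration on the |r|-weighted adjacency,
# normalized to max 1. Deterministic (uniform start). Iterates on A + cI
# (same eigenvectors): the shift breaks the +/- eigenvalue symmetry of
# bipartite graphs that would otherwise make the iteration oscillate.
eigenvector_power <- function(g, w, tol = 1e-8, max_iter = 10000) {
  n <- igraph::vcount(g)
  el <- igraph::as_edgelist(g, names = FALSE)
  adj <- matrix(0, n, n)
  adj[el] <- w
  adj[el[, 2:1, drop = FALSE]] <- w
  shift <- max(rowSums(adj))
  if (shift == 0) return(rep(0, n))
  x <- rep(1 / sqrt(n), n)
  for (i in seq_len(max_iter)) {
    x_new <- drop(adj %*% x) + shift * x
    nrm <- sqrt(sum(x_new^2))
    if (nrm == 0) return(rep(0, n))
    x_new <- x_new / nrm
    if (max(abs(x_new - x)) < tol) {
      x <- x_new
      break
    }
    x <- x_new
  }
  x / max(x)
}

# mean local clustering coefficient, unweighted, degree < 2 counts as 0
local_clustering_mean <- function(g) {
  if (igraph::vcount(g) == 0) return(NA_real_)
  cc <- igraph::transitivity(g, type = "local", isolates = "zero")
  mean(cc)
}

#' Topology summary of a co-occurrence network
#'
#' The full metric bundle used in the ecoregion comparison tables: node and
#' edge counts, positive/negative edge counts and percentages (1 decimal),
#' Louvain modularity and module count on `|r|` weights (fixed seed for
#' reproducibility), diameter of the largest connected component
#' (unweighted — these networks are fragmented, so the global diameter
#' would be undefined), average degree `2E/N` (3 decimals), mean weighted
#' degree (per-node sum of incident `|r|`), and the mean local clustering
#' coefficient (nodes of degree < 2 contribute 0; the global transitivity
#' is also reported for reference).
#'
#' @param net A `co_network`.
#' @param seed Seed for the Louvain pass.
#' @return One-row tibble of class rows; all-`NA` for an empty network.
#' @export
topology_summary <- function(net, seed = 1L) {
  g <- net$graph
  n <- igraph::vcount(g)
  e <- igraph::ecount(g)
  if (n == 0) {
    return(tibble(
      n_nodes = 0L, n_edges = 0L, n_positive = 0L, n_negative = 0L,
      pct_positive = NA_real_, pct_negative = NA_real_,
      modularity = NA_real_, n_modules = NA_integer_,
      diameter = NA_real_, average_degree = NA_real_,
      weighted_degree = NA_real_, clustering_coefficient = NA_real_,
      global_transitivity = NA_real_
    ))
  }
  w <- abs(igraph::E(g)$r)
  comm <- with_seed(seed, igraph::cluster_louvain(g, weights = w))
  comp <- igraph::components(g)
  lcc <- igraph::induced_subgraph(
    g, which(comp$membership == which.max(comp$csize)))
  n_pos <- sum(igraph::E(g)$sign == 1)
  n_neg <- e - n_pos
  tibble(
    n_nodes = n,
    n_edges = e,
    n_positive = as.integer(n_pos),
    n_negative = as.integer(n_neg),
    pct_positive = round1(100 * n_pos / e),
    pct_negative = round1(100 * n_neg / e),
    modularity = igraph::modularity(comm),
    n_modules = length(unique(igraph::membership(comm))),
    diameter = igraph::diameter(lcc, weights = NA),
    average_degree = round3(2 * e / n),
    weighted_degree = mean(igraph::strength(g, weights = w)),
    clustering_coefficient = local_clustering_mean(g),
    global_transitivity = igraph::transitivity(g, type = "global")
  )
}

#' Node centralities of a co-occurrence network
#'
#' Degree (edge count), weighted degree (sum of incident `|r|`),
#' betweenness (normalized, unweighted shortest paths), closeness
#' (normalized within each node's component), and eigenvector centrality on
#' `|r|` weights by power iteration (tolerance 1e-8, max normalized to 1).
#'
#' @param net A non-empty `co_network`.
#' @return Tibble with one row per node.
#' @export
centralities <- function(net) {
  g <- net$graph
  if (igraph::vcount(g) == 0) stopf("network is empty")
  w <- abs(igraph::E(g)$r)
  suppressWarnings(cl <- igraph::closeness(g, weights = NA, normalized = TRUE))
  cl[is.nan(cl)] <- 0  # isolated-in-component convention
  tibble(
    taxon = igraph::V(g)$name,
    degree = as.integer(igraph::degree(g)),
    weighted_degree = unname(igraph::strength(g, weights = w)),
    betweenness = unname(igraph::betweenness(g, weights = NA,
                                             normalized = TRUE)),
    closeness = unname(cl),
    eigenvector = eigenvector_power(g, w)
  )
}

#' Ego subnetwork of a focal taxon
#'
#' Induced subgraph on the closed neighborhood (radius 1 by default) of a
#' focal taxon — the local-connectivity view used for shared genera. When
#' the focal taxon is absent from the network (as dominant, low-variance
#' endosymbionts typically are), an empty subnetwork is returned with
#' `focal_absent = TRUE`.
#'
#' @param net A `co_network`.
#' @param focal_taxon Taxon name.
#' @param radius Neighborhood order (default 1).
#' @return A `co_network` with extra fields `focal_taxon`, `focal_absent`.
#' @export
ego_subnetwork <- function(net, focal_taxon, radius = 1) {
  g <- net$graph
  if (!focal_taxon %in% network_nodes(net)) {
    out <- build_network(net$edges[0, ])
    out$focal_taxon <- focal_taxon
    out$focal_absent <- TRUE
    return(out)
  }
  nb <- igraph::ego(g, order = radius, nodes = focal_taxon)[[1]]
  sub <- igraph::induced_subgraph(g, nb)
  keep_names <- igraph::V(sub)$name
  edges <- net$edges[net$edges$taxon_a %in% keep_names &
                       net$edges$taxon_b %in% keep_names, ]
  out <- structure(list(graph = sub, edges = edges), class = "co_network")
  out$focal_taxon <- focal_taxon
  out$focal_absent <- FALSE
  out
}

#' Export a co-occurrence network to GraphML
#'
#' Node attributes (module, centralities) and edge attributes (`r`, `sign`)
#' are attached before writing, so the file opens ready-annotated in Gephi.
#'
#' @param net A `co_network`.
#' @param path Output path.
#' @param positive_only Drop negative edges (the convention used for
#'   network figures)? Default `FALSE`.
#' @param seed Seed for the Louvain module assignment.
#' @return `net`, invisibly.
#' @export
write_graphml <- function(net, path, positive_only = FALSE, seed = 1L) {
  g <- annotate_graph(net, seed, positive_only)
  igraph::write_graph(g, path, format = "graphml")
  invisible(net)
}

annotate_graph <- function(net, seed = 1L, positive_only = FALSE) {
  g <- net$graph
  if (igraph::vcount(g) > 0) {
    cent <- centralities(net)
    w <- abs(igraph::E(g)$r)
    comm <- with_seed(seed, igraph::cluster_louvain(g, weights = w))
    igraph::V(g)$module <- as.integer(igraph::membership(comm))
    for (col in c("degree", "weighted_degree", "betweenness", "closeness",
                  "eigenvector")) {
      g <- igraph::set_vertex_attr(g, col, value = cent[[col]])
    }
    if (positive_only) {
      g <- igraph::delete_edges(g, which(igraph::E(g)$sign < 0))
    }
  }
  g
}

#' Export a co-occurrence network to GEXF
#'
#' Minimal GEXF 1.2 writer (no R package on hand emits GEXF): nodes with
#' module and eigenvector-centrality attributes, edges with weight `|r|`
#' and sign.
#'
#' @inheritParams write_graphml
#' @return `net`, invisibly.
#' @export
write_gexf <- function(net, path, positive_only = FALSE, seed = 1L) {
  g <- annotate_graph(net, seed, positive_only)
  nodes <- igraph::V(g)$name
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<gexf xmlns="http://gexf.net/1.2" version="1.2">',
    '  <graph defaultedgetype="undirected">',
    '    <attributes class="node">',
    '      <attribute id="0" title="module" type="integer"/>',
    '      <attribute id="1" title="eigenvector" type="double"/>',
    '    </attributes>',
    '    <attributes class="edge">',
    '      <attribute id="0" title="r" type="double"/>',
    '      <attribute id="1" title="sign" type="integer"/>',
    '    </attributes>',
    '    <nodes>'
  )
  if (length(nodes) > 0) {
    mod <- igraph::V(g)$module
    eig <- igraph::V(g)$eigenvector
    lines <- c(lines, sprintf(
      '      <node id="%s" label="%s"><attvalues><attvalue for="0" value="%d"/><attvalue for="1" value="%.10g"/></attvalues></node>',
      esc(nodes), esc(nodes), mod, eig))
  }
  lines <- c(lines, '    </nodes>', '    <edges>')
  if (igraph::ecount(g) > 0) {
    el <- igraph::as_edgelist(g)
    lines <- c(lines, sprintf(
      '      <edge id="%d" source="%s" target="%s" weight="%.10g"><attvalues><attvalue for="0" value="%.10g"/><attvalue for="1" value="%d"/></attvalues></edge>',
      seq_len(nrow(el)) - 1L, esc(el[, 1]), esc(el[, 2]),
      abs(igraph::E(g)$r), igraph::E(g)$r, igraph::E(g)$sign))
  }
  lines <- c(lines, '    </edges>', '  </graph>', '</gexf>')
  writeLines(lines, path)
  invisible(net)
}

#' @param object A `co_network`.
#' @param seed Layout seed.
#' @param ... Unused.
#' @rdname build_network
#' @export
autoplot.co_network <- function(object, seed = 1L, ...) {
  g <- object$graph
  if (igraph::vcount(g) == 0) {
    return(ggplot2::ggplot() + ggplot2::theme_void() +
             ggplot2::annotate("text", 0, 0, label = "empty network"))
  }
  xy <- with_seed(seed, igraph::layout_with_fr(g))
  nodes <- tibble(taxon = igraph::V(g)$name, x = xy[, 1], y = xy[, 2])
  el <- igraph::as_edgelist(g)
  segs <- tibble(
    x = nodes$x[match(el[, 1], nodes$taxon)],
    y = nodes$y[match(el[, 1], nodes$taxon)],
    xend = nodes$x[match(el[, 2], nodes$taxon)],
    yend = nodes$y[match(el[, 2], nodes$taxon)],
    sign = factor(ifelse(igraph::E(g)$sign > 0, "positive", "negative"),
                  levels = c("positive", "negative"))
  )
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = segs,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend,
                   yend = .data$yend, colour = .data$sign),
      linewidth = 0.4, alpha = 0.7) +
    ggplot2::scale_colour_manual(
      values = c(positive = "steelblue", negative = "firebrick"),
      drop = FALSE) +
    ggplot2::geom_point(data = nodes,
                        ggplot2::aes(x = .data$x, y = .data$y), size = 2) +
    ggplot2::theme_void()
}
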