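# Fixtures built in code: tiny specs, tables and graphs shared by tests.

tiny_spec <- function(seed = 1, ...) {
  args <- list(
    n_samples_per_group = 5, n_core_taxa = 5,
    n_accessory_taxa_per_group = c(3, 3), sequencing_depth = 2000,
    n_controls = 3, seed = seed
  )
  do.call(synth_spec, modifyList(args, list(...)))
}

# the SparCC calibration fixture: 20 biological samples, mostly-shared taxa
calib_spec <- function(seed, planted = NULL) {
  synth_spec(
    n_samples_per_group = 10, n_core_taxa = 18,
    n_accessory_taxa_per_group = c(1, 1),
    planted_graph = planted %||%
      tibble::tibble(taxon_a = character(), taxon_b = character(),
                     sign = integer()),
    log_effect_size = 0.8, sequencing_depth = 50000,
    n_controls = 0, contaminant_taxa = character(), seed = seed
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# hand-built taxa table: 4 biological (2 groups) + 2 controls
hand_table <- function() {
  m <- matrix(c(
    10, 5, 0, 7,
    8, 6, 1, 9,
    0, 12, 3, 5,
    1, 10, 4, 6,
    0, 0, 50, 0,
    0, 0, 40, 1
  ), nrow = 6, byrow = TRUE,
  dimnames = list(NULL, c("gA", "gB", "gC", "gD")))
  taxa_table(m, group = c("X", "X", "Y", "Y", "control", "control"),
             is_control = c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE),
             sample_ids = sprintf("s%d", 1:6))
}

# co_network from a plain edge matrix/data.frame (taxon_a, taxon_b[, r])
make_net <- function(pairs, r = NULL) {
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  names(pairs)[1:2] <- c("taxon_a", "taxon_b")
  if (is.null(pairs$r)) pairs$r <- if (is.null(r)) 1 else r
  pairs$sign <- ifelse(pairs$r >= 0, 1L, -1L)
  build_network(tibble::as_tibble(pairs))
}

star_net <- function(k) {
  make_net(data.frame(taxon_a = "hub", taxon_b = sprintf("leaf%02d", 1:k)))
}

ring_net <- function(k) {
  v <- sprintf("n%02d", 1:k)
  make_net(data.frame(taxon_a = v, taxon_b = v[c(2:k, 1)]))
}

path_net <- function(labels) {
  make_net(data.frame(taxon_a = labels[-length(labels)],
                      taxon_b = labels[-1]))
}

# seeded random connected-ish graph as a co_network; edges get random signs
random_net <- function(n, p = 0.4, seed = 1, signed = FALSE) {
  set.seed(seed)
  repeat {
    pairs <- t(combn(sprintf("v%02d", 1:n), 2))
    keep <- runif(nrow(pairs)) < p
    if (sum(keep) >= 1) {
      el <- as.data.frame(pairs[keep, , drop = FALSE])
      names(el) <- c("taxon_a", "taxon_b")
      el$r <- if (signed) {
        sample(c(-1, 1), nrow(el), TRUE) * runif(nrow(el), 0.5, 1)
      } else {
        rep(1, nrow(el))
      }
      net <- make_net(el)
      # only accept graphs covering all n vertices (no isolated dropped)
      if (igraph::vcount(net$graph) == n) return(net)
    }
  }
}

# seeded G(n, m) graph with no isolated vertices, as a co_network
gnm_net <- function(n, m, seed = 1) {
  set.seed(seed)
  labels <- sprintf("t%03d", 1:n)
  pairs <- t(combn(labels, 2))
  repeat {
    pick <- sample(nrow(pairs), m)
    el <- data.frame(taxon_a = pairs[pick, 1], taxon_b = pairs[pick, 2])
    net <- make_net(el)
    if (igraph::vcount(net$graph) == n) return(net)
  }
}

# adjacency matrix (0/1) of a co_network, ordered by node name
net_adjacency <- function(net) {
  g <- net$graph
  ord <- order(igraph::V(g)$name)
  a <- as.matrix(igraph::as_adjacency_matrix(g))
  a[ord, ord]
}
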