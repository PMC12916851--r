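#' Most-central node set above a percentile
#'
#' Nodes whose centrality value is strictly greater than the empirical
#' percentile (linear-interpolation quantile, default 75th); ties at the
#' threshold are excluded, so a constant centrality yields an empty set.
#'
#' @param values Named numeric vector of centrality values (names = taxa).
#' @param percentile Percentile in `[0, 100)`; default 75.
#' @return Character vector of node names.
#' @export
top_central_set <- function(values, percentile = 75) {
  stopifnot(length(values) > 0, !is.null(names(values)))
  q <- quantile(values, probs = percentile / 100, type = 7, names = FALSE)
  names(values)[values > q]
}

#' Jaccard index of two node sets with an exact hypergeometric null
#'
#' `J = |A∩B| / |A∪B|` over taxon names. The null model draws both sets
#' uniformly without replacement from the common universe (the union of the
#' two networks' node names), with the observed sizes fixed; the overlap is
#' then hypergeometric, and since `J` is monotone in the overlap, the
#' two-tailed quantities `P(J <= j)` and `P(J >= j)` (each including the
#' observed value) follow by exact summation of the hypergeometric pmf.
#'
#' @param set_a,set_b Character vectors (subsets of the universe).
#' @param universe Character vector: the common name universe.
#' @return One-row tibble: sizes, `jaccard`, `p_le`, `p_ge`.
#' @export
jaccard_with_null <- function(set_a, set_b, universe) {
  set_a <- unique(as.character(set_a))
  set_b <- unique(as.character(set_b))
  universe <- unique(as.character(universe))
  stopifnot(all(set_a %in% universe), all(set_b %in% universe))
  n <- length(universe)
  a <- length(set_a)
  b <- length(set_b)
  k <- length(intersect(set_a, set_b))
  u <- length(union(set_a, set_b))
  if (u == 0) {
    return(tibble(size_a = a, size_b = b, overlap = k,
                  jaccard = NA_real_, p_le = NA_real_, p_ge = NA_real_))
  }
  j <- k / u
  # overlap ~ Hypergeometric(n, a, b); J = k/(a+b-k) is increasing in k
  p_le <- stats::phyper(k, a, n - a, b)
  p_ge <- 1 - stats::phyper(k - 1, a, n - a, b)
  tibble(size_a = a, size_b = b, overlap = k,
         jaccard = j, p_le = p_le, p_ge = p_ge)
}

#' Hub taxa of a network
#'
#' Nodes simultaneously above the percentile threshold for each of the
#' chosen centrality measures (default: degree, betweenness, eigenvector —
#' the multi-criterion hub rule).
#'
#' @param net A non-empty `co_network`.
#' @param measures Centrality columns to intersect over.
#' @param percentile Percentile threshold (default 75).
#' @return Character vector of hub taxon names.
#' @export
hub_taxa <- function(net, measures = c("degree", "betweenness", "eigenvector"),
                     percentile = 75) {
  cent <- centralities(net)
  sets <- lapply(measures, function(mname) {
    top_central_set(setNames(cent[[mname]], cent$taxon), percentile)
  })
  Reduce(intersect, sets)
}

#' Compare two networks by Jaccard indices of most-central node sets
#'
#' For each centrality measure (degree, betweenness, closeness,
#' eigenvector) and for the hub-taxa rule, takes the above-percentile node
#' sets of the two networks and computes the Jaccard index with exact
#' two-tailed null p-values over the shared name universe
#' ([jaccard_with_null()]).
#'
#' @param net_a,net_b `co_network` objects.
#' @param percentile Percentile for the central sets (default 75).
#' @return Object of class `network_comparison`; `tidy()` yields the
#'   measure-by-measure report.
#' @export
compare_networks <- function(net_a, net_b, percentile = 75) {
  cent_a <- centralities(net_a)
  cent_b <- centralities(net_b)
  universe <- union(cent_a$taxon, cent_b$taxon)
  measures <- c("degree", "betweenness", "closeness", "eigenvector")
  rows <- purrr::map(measures, function(mname) {
    sa <- top_central_set(setNames(cent_a[[mname]], cent_a$taxon), percentile)
    sb <- top_central_set(setNames(cent_b[[mname]], cent_b$taxon), percentile)
    mutate(jaccard_with_null(sa, sb, universe), measure = mname, .before = 1)
  }) |> list_rbind()
  hubs <- jaccard_with_null(hub_taxa(net_a, percentile = percentile),
                            hub_taxa(net_b, percentile = percentile),
                            universe)
  rows <- bind_rows(rows, mutate(hubs, measure = "hub_taxa", .before = 1))
  structure(list(report = rows, percentile = percentile,
                 universe_size = length(universe)),
            class = "network_comparison")
}

#' @export
print.network_comparison <- function(x, ...) {
  cat(sprintf("<network_comparison> %d-name universe, top-%g%% sets\n",
              x$universe_size, x$percentile))
  print(x$report)
  invisible(x)
}

#' @export
tidy.network_comparison <- function(x, ...) x$report

#' @export
glance.network_comparison <- function(x, ...) {
  tibble(universe_size = x$universe_size, percentile = x$percentile,
         min_jaccard = min(x$report$jaccard, na.rm = TRUE),
         max_jaccard = max(x$report$jaccard, na.rm = TRUE))
}

#' Differential edge partition of two networks
#'
#' Exact set algebra over unordered taxon-name pairs: edges only in A, only
#' in B, shared with the same sign, and shared with flipped sign.
#'
#' @param net_a,net_b `co_network` objects.
#' @return Tibble with columns `taxon_a`, `taxon_b`, `category`, `r_a`,
#'   `r_b`.
#' @export
differential_edges <- function(net_a, net_b) {
  key <- function(e) paste(pmin(e$taxon_a, e$taxon_b),
                           pmax(e$taxon_a, e$taxon_b), sep = "\r")
  ea <- mutate(net_a$edges, .key = key(net_a$edges))
  eb <- mutate(net_b$edges, .key = key(net_b$edges))
  merged <- dplyr::full_join(
    select(ea, ".key", taxon_a = "taxon_a", taxon_b = "taxon_b",
           r_a = "r", sign_a = "sign"),
    select(eb, ".key", taxon_a2 = "taxon_a", taxon_b2 = "taxon_b",
           r_b = "r", sign_b = "sign"),
    by = ".key"
  )
  merged |>
    mutate(
      taxon_a = dplyr::coalesce(.data$taxon_a, .data$taxon_a2),
      taxon_b = dplyr::coalesce(.data$taxon_b, .data$taxon_b2),
      category = dplyr::case_when(
        is.na(r_b) ~ "a_only",
        is.na(r_a) ~ "b_only",
        sign_a == sign_b ~ "shared_same_sign",
        TRUE ~ "shared_sign_flip"
      )
    ) |>
    select("taxon_a", "taxon_b", "category", "r_a", "r_b") |>
    arrange(.data$category, .data$taxon_a, .data$taxon_b)
}
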