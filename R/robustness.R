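# Attack-based robustness and node-addition analysis.

pair_connectivity <- function(g) {
  if (igraph::vcount(g) == 0) return(0)
  comp <- igraph::components(g)
  sum(choose(comp$csize, 2))
}

# deterministic tie-break: rank by -value, then lexicographic node name
order_by_value <- function(names, values) {
  names[order(-values, names)]
}

#' Attack a network by sequential node removal
#'
#' Removes nodes one at a time and tracks connectivity loss, defined as
#' `1 - (connected node pairs remaining) / (connected node pairs
#' initially)` — well-defined and monotone on fragmented graphs. The
#' LCC-based alternative (`1 - LCC/LCC0`) is reported alongside.
#' Strategies: `random` (uniform order, seeded), `degree` and `betweenness`
#' (precomputed ranking, ties broken by node name), and `cascading`
#' (betweenness recomputed after every removal).
#'
#' @param net A non-empty `co_network`.
#' @param strategy One of `"random"`, `"degree"`, `"betweenness"`,
#'   `"cascading"`.
#' @param seed Seed (used by the random strategy).
#' @return Tibble of class `attack_curve`: `strategy`, `step`,
#'   `fraction_removed`, `connectivity_loss`, `lcc_loss`, `removed`.
#' @export
attack <- function(net, strategy = c("random", "degree", "betweenness",
                                     "cascading"), seed = 1L) {
  strategy <- match.arg(strategy)
  g <- net$graph
  n0 <- igraph::vcount(g)
  if (n0 == 0 || igraph::ecount(g) == 0) {
    stopf("attack curves are undefined on an empty network")
  }
  pairs0 <- pair_connectivity(g)
  lcc0 <- max(igraph::components(g)$csize)

  order_names <- switch(
    strategy,
    random = with_seed(seed, sample(igraph::V(g)$name)),
    degree = order_by_value(igraph::V(g)$name, igraph::degree(g)),
    betweenness = order_by_value(igraph::V(g)$name,
                                 igraph::betweenness(g, weights = NA)),
    cascading = NULL
  )

  steps <- vector("list", n0 + 1)
  steps[[1]] <- tibble(step = 0L, fraction_removed = 0,
                       connectivity_loss = 0, lcc_loss = 0,
                       removed = NA_character_)
  cur <- g
  for (k in seq_len(n0)) {
    victim <- if (strategy == "cascading") {
      order_by_value(igraph::V(cur)$name,
                     igraph::betweenness(cur, weights = NA))[1]
    } else {
      order_names[k]
    }
    cur <- igraph::delete_vertices(cur, victim)
    comp_sizes <- if (igraph::vcount(cur) > 0) {
      igraph::components(cur)$csize
    } else 0
    steps[[k + 1]] <- tibble(
      step = k,
      fraction_removed = k / n0,
      connectivity_loss = 1 - sum(choose(comp_sizes, 2)) / pairs0,
      lcc_loss = 1 - max(comp_sizes) / lcc0,
      removed = victim
    )
  }
  out <- mutate(list_rbind(steps), strategy = strategy, .before = 1)
  class(out) <- c("attack_curve", class(out))
  out
}

#' Fraction of nodes removed at which a disconnection level is first reached
#'
#' @param curve An `attack_curve`.
#' @param level Connectivity-loss level (default 0.8, i.e., 80%
#'   disconnection).
#' @return Smallest `fraction_removed` with `connectivity_loss >= level`;
#'   1.0 if the level is only reached at exhaustion (or never).
#' @export
pct_disconnection_point <- function(curve, level = 0.8) {
  check_number(level, "level", 0, 1)
  hit <- which(curve$connectivity_loss >= level - 1e-12)
  if (length(hit) == 0) return(1.0)
  curve$fraction_removed[hit[1]]
}

#' Run all four attack strategies on a network
#'
#' @param net A `co_network`.
#' @param seed Seed for the random strategy.
#' @return A single long tibble of class `attack_curve`.
#' @export
attack_all <- function(net, seed = 1L) {
  out <- list_rbind(lapply(
    c("random", "degree", "betweenness", "cascading"),
    function(s) attack(net, s, seed = seed)))
  class(out) <- c("attack_curve", class(out))
  out
}

#' @param object An `attack_curve` tibble.
#' @param ... Unused.
#' @rdname attack
#' @export
autoplot.attack_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$fraction_removed,
                                       y = .data$connectivity_loss,
                                       colour = .data$strategy)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "fraction of nodes removed",
                  y = "connectivity loss") +
    ggplot2::theme_minimal()
}

#' Node-addition robustness analysis
#'
#' Adds `n_add` nodes one at a time, each attached by `m` edges to
#' uniformly chosen distinct existing nodes (default `m = 1`), recording
#' the largest-connected-component size and the average path length within
#' the LCC after every addition. With `m = 1` a new node can only ever
#' extend existing components; `m >= 2` additionally allows additions to
#' bridge components. Replicated `reps` times with derived seeds.
#'
#' @param net A non-empty `co_network`.
#' @param n_add Number of nodes to add (>= 0).
#' @param reps Number of replicates.
#' @param m Edges per added node (capped at the current node count).
#' @param seed Master seed.
#' @return Tibble of class `addition_curve`: `replicate`, `step`,
#'   `lcc_size`, `apl`.
#' @export
add_nodes <- function(net, n_add, reps = 1, m = 1, seed = 1L) {
  g0 <- net$graph
  if (igraph::vcount(g0) == 0) stopf("network is empty")
  check_number(n_add, "n_add", 0, Inf, TRUE)
  check_number(reps, "reps", 1, Inf, TRUE)

  lcc_stats <- function(g) {
    comp <- igraph::components(g)
    lcc <- igraph::induced_subgraph(g, which(comp$membership ==
                                               which.max(comp$csize)))
    c(lcc_size = max(comp$csize),
      apl = if (igraph::vcount(lcc) > 1) {
        igraph::mean_distance(lcc, directed = FALSE)
      } else 0)
  }

  out <- purrr::map(seq_len(reps), function(rep_i) {
    with_seed(derive_seed(seed, rep_i), {
      g <- g0
      base <- lcc_stats(g)
      rows <- vector("list", n_add + 1)
      rows[[1]] <- tibble(replicate = rep_i, step = 0L,
                          lcc_size = base[["lcc_size"]],
                          apl = base[["apl"]])
      if (n_add > 0) {
        for (k in seq_len(n_add)) {
          targets <- sample(igraph::V(g)$name,
                            min(m, igraph::vcount(g)))
          new_name <- sprintf("added_%04d", k)
          g <- igraph::add_vertices(g, 1, name = new_name)
          g <- igraph::add_edges(g, rbind(new_name, targets))
          st <- lcc_stats(g)
          rows[[k + 1]] <- tibble(replicate = rep_i, step = k,
                                  lcc_size = st[["lcc_size"]],
                                  apl = st[["apl"]])
        }
      }
      list_rbind(rows)
    })
  }) |> list_rbind()
  class(out) <- c("addition_curve", class(out))
  out
}

#' @param object An `addition_curve` tibble.
#' @param ... Unused.
#' @rdname add_nodes
#' @export
autoplot.addition_curve <- function(object, ...) {
  long <- tidyr::pivot_longer(object, c("lcc_size", "apl"),
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$step, y = .data$value,
                                     group = .data$replicate)) +
    ggplot2::geom_line(alpha = 0.6) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "nodes added", y = NULL) +
    ggplot2::theme_minimal()
}

# Exact two-sided Wilcoxon signed-rank p for nonzero differences, valid
# under ties: average ranks are doubled to integers and the exact null
# distribution of W+ is built by dynamic-programming convolution over the
# 2^n equiprobable sign assignments. Both tails include the observed value.
wilcoxon_signed_exact <- function(d) {
  n <- length(d)
  r2 <- as.integer(round(2 * rank(abs(d))))
  w_obs <- sum(r2[d > 0])
  total <- sum(r2)
  prob <- c(1, numeric(total))  # P(W2 = s), s = 0..total
  for (v in r2) {
    shifted <- c(numeric(v), prob[seq_len(total + 1 - v)])
    prob <- (prob + shifted) / 2
  }
  p_ge <- sum(prob[(w_obs + 1):(total + 1)])
  p_le <- sum(prob[1:(w_obs + 1)])
  list(statistic = w_obs / 2, p_value = min(1, 2 * min(p_ge, p_le)))
}

#' Compare paired addition curves between two networks
#'
#' Averages each network's curves over replicates, pairs the two step
#' series, and tests the per-step differences in LCC size and APL with the
#' Wilcoxon signed-rank test (zero differences dropped; exact distribution
#' for up to 25 informative pairs, normal approximation beyond).
#' Benjamini-Hochberg adjustment is applied across the tested metrics, and
#' a seeded percentile bootstrap (2.5/97.5) gives a confidence interval for
#' the mean difference.
#'
#' @param curves_a,curves_b `addition_curve` tibbles over the same step
#'   grid.
#' @param n_boot Bootstrap resamples (default 1000).
#' @param seed Bootstrap seed.
#' @return Tibble: one row per metric with `p_value`, `p_adjusted`,
#'   `mean_difference`, `ci_lower`, `ci_upper`.
#' @export
compare_addition <- function(curves_a, curves_b, n_boot = 1000, seed = 1L) {
  mean_by_step <- function(curves) {
    curves |>
      group_by(.data$step) |>
      summarise(lcc_size = mean(.data$lcc_size), apl = mean(.data$apl),
                .groups = "drop") |>
      arrange(.data$step)
  }
  a <- mean_by_step(curves_a)
  b <- mean_by_step(curves_b)
  if (!identical(a$step, b$step)) {
    stopf("addition curves have different step grids")
  }

  one_metric <- function(metric) {
    d <- a[[metric]] - b[[metric]]
    nz <- d[d != 0]
    if (length(nz) == 0) {
      p <- 1
      stat <- 0
    } else if (length(nz) <= 25) {
      ex <- wilcoxon_signed_exact(nz)
      p <- ex$p_value
      stat <- ex$statistic
    } else {
      wt <- suppressWarnings(
        wilcox.test(a[[metric]], b[[metric]], paired = TRUE, exact = FALSE))
      p <- wt$p.value
      stat <- unname(wt$statistic)
    }
    ci <- with_seed(derive_seed(seed, match(metric, c("lcc_size", "apl"))), {
      boots <- vapply(seq_len(n_boot), function(i) {
        mean(sample(d, length(d), replace = TRUE))
      }, numeric(1))
      quantile(boots, c(0.025, 0.975), names = FALSE)
    })
    tibble(metric = metric, n_pairs = length(d),
           n_nonzero_pairs = length(nz), statistic = stat, p_value = p,
           mean_difference = mean(d), ci_lower = ci[1], ci_upper = ci[2])
  }
  out <- list_rbind(lapply(c("lcc_size", "apl"), one_metric))
  mutate(out, p_adjusted = p.adjust(.data$p_value, method = "BH"),
         .after = "p_value")
}
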