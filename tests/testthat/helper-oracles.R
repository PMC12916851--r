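# Naive brute-force oracles, written independently of the implementation
# path they check: dense-matrix algorithms, exhaustive enumeration, closed
# forms.

# all-pairs shortest paths by Floyd-Warshall on a 0/1 adjacency matrix
oracle_distances <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  d[adj > 0] <- 1
  diag(d) <- 0
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
      }
    }
  }
  d
}

# number of shortest s-t paths, by dynamic programming over distances
oracle_path_counts <- function(adj, d, s) {
  n <- nrow(adj)
  cnt <- numeric(n)
  cnt[s] <- 1
  for (t in order(d[s, ])) {
    if (t == s || is.infinite(d[s, t])) next
    preds <- which(adj[, t] > 0 & d[s, ] == d[s, t] - 1)
    cnt[t] <- sum(cnt[preds])
  }
  cnt
}

# normalized betweenness centrality by explicit pair/path counting
oracle_betweenness <- function(adj) {
  n <- nrow(adj)
  d <- oracle_distances(adj)
  cnt <- t(sapply(seq_len(n), function(s) oracle_path_counts(adj, d, s)))
  bw <- numeric(n)
  for (v in seq_len(n)) {
    for (s in seq_len(n - 1)) {
      for (t in (s + 1):n) {
        if (s == v || t == v || is.infinite(d[s, t])) next
        # paths through v: shortest s-v and v-t segments must concatenate
        if (d[s, v] + d[v, t] == d[s, t]) {
          bw[v] <- bw[v] + cnt[s, v] * cnt[v, t] / cnt[s, t]
        }
      }
    }
  }
  bw / (choose(n - 1, 2))
}

# per-component normalized closeness: (|C|-1) / sum of distances in C
oracle_closeness <- function(adj) {
  d <- oracle_distances(adj)
  sapply(seq_len(nrow(adj)), function(v) {
    reach <- which(is.finite(d[v, ]) & seq_len(ncol(d)) != v)
    if (length(reach) == 0) return(0)
    length(reach) / sum(d[v, reach])
  })
}

# mean local clustering coefficient; degree < 2 contributes 0
oracle_clustering <- function(adj) {
  n <- nrow(adj)
  cc <- sapply(seq_len(n), function(v) {
    nb <- which(adj[v, ] > 0)
    k <- length(nb)
    if (k < 2) return(0)
    links <- sum(adj[nb, nb]) / 2
    links / choose(k, 2)
  })
  mean(cc)
}

oracle_diameter_lcc <- function(adj) {
  d <- oracle_distances(adj)
  n <- nrow(adj)
  # component membership by reachability
  comp <- rep(NA_integer_, n)
  cid <- 0
  for (v in seq_len(n)) {
    if (is.na(comp[v])) {
      cid <- cid + 1
      comp[is.finite(d[v, ])] <- cid
    }
  }
  big <- which(comp == which.max(tabulate(comp)))
  max(d[big, big])
}

# principal eigenvector of the weighted adjacency, max-normalized
oracle_eigencent <- function(w_adj) {
  e <- eigen(w_adj, symmetric = TRUE)
  v <- e$vectors[, which.max(e$values)]
  v <- v * sign(sum(v))
  v / max(v)
}

# unweighted Newman modularity of a partition (membership vector)
oracle_modularity_q <- function(adj, membership) {
  m <- sum(adj) / 2
  deg <- rowSums(adj)
  same <- outer(membership, membership, `==`)
  sum((adj - outer(deg, deg) / (2 * m)) * same) / (2 * m)
}

# maximum modularity by exhaustive search over all set partitions (n <= 8)
oracle_modularity_max <- function(adj) {
  n <- nrow(adj)
  best <- -Inf
  # enumerate restricted-growth strings
  rec <- function(i, memb, kmax) {
    if (i > n) {
      q <- oracle_modularity_q(adj, memb)
      if (q > best) best <<- q
      return(invisible())
    }
    for (g in seq_len(kmax + 1)) {
      memb[i] <- g
      rec(i + 1, memb, max(kmax, g))
    }
  }
  rec(1, integer(n), 0)
  best
}

# O(n^3) UPGMA returning the cophenetic distance matrix
oracle_upgma_cophenetic <- function(dm) {
  n <- nrow(dm)
  clusters <- as.list(seq_len(n))
  d <- dm
  coph <- matrix(0, n, n)
  active <- rep(TRUE, n)
  dwork <- d
  diag(dwork) <- Inf
  members <- clusters
  while (sum(active) > 1) {
    idx <- which(active)
    sub <- dwork[idx, idx, drop = FALSE]
    best <- which(sub == min(sub), arr.ind = TRUE)[1, ]
    a <- idx[best[1]]; b <- idx[best[2]]
    h <- dwork[a, b]
    for (x in members[[a]]) for (y in members[[b]]) {
      coph[x, y] <- coph[y, x] <- h
    }
    # average linkage update, sizes weighted
    na <- length(members[[a]]); nb <- length(members[[b]])
    for (c in idx) {
      if (c %in% c(a, b)) next
      dwork[a, c] <- dwork[c, a] <- (na * dwork[a, c] + nb * dwork[b, c]) /
        (na + nb)
    }
    members[[a]] <- c(members[[a]], members[[b]])
    active[b] <- FALSE
    dwork[b, ] <- dwork[, b] <- Inf
  }
  coph
}

# classical scaling by direct eigen-decomposition of the Gram matrix
oracle_pcoa <- function(dm) {
  n <- nrow(dm)
  j <- diag(n) - matrix(1 / n, n, n)
  b <- -0.5 * j %*% (dm^2) %*% j
  e <- eigen((b + t(b)) / 2, symmetric = TRUE)
  list(eigenvalues = e$values,
       points = e$vectors %*% diag(sqrt(pmax(e$values, 0))))
}

# connected node pairs by BFS reachability
oracle_pair_connectivity <- function(adj) {
  if (nrow(adj) == 0) return(0)
  d <- oracle_distances(adj)
  sum(is.finite(d[upper.tri(d)]))
}

# exact two-sided signed-rank p by enumeration over all sign vectors
oracle_wilcoxon_exact <- function(diffs) {
  d <- diffs[diffs != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- expand.grid(rep(list(c(0, 1)), n))
  w_all <- as.matrix(signs) %*% r
  p_ge <- mean(w_all >= w_obs)
  p_le <- mean(w_all <= w_obs)
  min(1, 2 * min(p_ge, p_le))
}

# Monte-Carlo null of the Jaccard index of two random fixed-size subsets
oracle_jaccard_null_mc <- function(n_universe, a, b, n_draws = 1e5,
                                   seed = 1) {
  set.seed(seed)
  u <- seq_len(n_universe)
  replicate(n_draws, {
    sa <- sample(u, a)
    sb <- sample(u, b)
    length(intersect(sa, sb)) / length(union(sa, sb))
  })
}

# pseudo-F for PERMANOVA by direct group-sum formula (independent impl)
oracle_permanova_f <- function(dm, groups) {
  d2 <- as.matrix(dm)^2
  n <- nrow(d2)
  lev <- unique(groups)
  sst <- sum(d2[upper.tri(d2)]) / n
  ssw <- 0
  for (g in lev) {
    idx <- which(groups == g)
    ssw <- ssw + sum(d2[idx, idx][upper.tri(d2[idx, idx])]) / length(idx)
  }
  ((sst - ssw) / (length(lev) - 1)) / (ssw / (n - length(lev)))
}
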