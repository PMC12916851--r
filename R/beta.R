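#' Between-sample distance matrix
#'
#' Bray-Curtis dissimilarity on raw counts, or Jaccard distance
#' (1 - shared/union) on presence/absence (count >= 1). Pairs of all-zero
#' samples are defined to have distance 0, with a warning.
#'
#' @param table A `taxa_table`; control samples are dropped.
#' @param metric `"bray_curtis"` or `"jaccard"`.
#' @return A square symmetric matrix of class `beta_dist` with zero
#'   diagonal, entries in `[0, 1]`, and sample ids as dimnames.
#' @export
beta_distance <- function(table, metric = c("bray_curtis", "jaccard")) {
  validate_taxa_table(table)
  metric <- match.arg(metric)
  table <- biological_samples(table)
  if (nrow(table) < 2) stopf("need at least 2 biological samples")
  m <- tt_counts(table)
  d <- if (metric == "bray_curtis") {
    vegan::vegdist(m, method = "bray")
  } else {
    vegan::vegdist(m, method = "jaccard", binary = TRUE)
  }
  dm <- as.matrix(d)
  if (anyNA(dm)) {
    warn("all-zero sample pair(s); defining their distance as 0")
    dm[is.na(dm)] <- 0
  }
  diag(dm) <- 0
  structure(dm, metric = metric, class = c("beta_dist", "matrix", "array"))
}

#' @export
tidy.beta_dist <- function(x, ...) {
  m <- unclass(x)
  idx <- which(upper.tri(m), arr.ind = TRUE)
  tibble(sample_a = rownames(m)[idx[, 1]],
         sample_b = colnames(m)[idx[, 2]],
         distance = m[idx])
}

#' Principal coordinates analysis (classical multidimensional scaling)
#'
#' Double-centers the squared distance matrix and eigen-decomposes it.
#' Coordinates are returned for axes with positive eigenvalues, ordered by
#' eigenvalue; negative eigenvalues (non-Euclidean input) are reported in
#' `$eigenvalues`. When the input distances are Euclidean the pairwise
#' coordinate distances reproduce the input exactly.
#'
#' @param dm A `beta_dist` (or any square symmetric distance matrix).
#' @return Object of class `pcoa_result` with `$coordinates` (tibble:
#'   `sample_id`, `axis_1`, `axis_2`, ...) and `$eigenvalues`.
#' @export
pcoa_ordination <- function(dm) {
  m <- as.matrix(dm)
  n <- nrow(m)
  fit <- suppressWarnings(cmdscale(as.dist(m), k = max(1, n - 1), eig = TRUE))
  pts <- fit$points
  coords <- as_tibble(pts, .name_repair = "minimal")
  names(coords) <- sprintf("axis_%d", seq_len(ncol(pts)))
  coords <- dplyr::bind_cols(tibble(sample_id = rownames(m)), coords)
  structure(list(coordinates = coords, eigenvalues = fit$eig),
            class = "pcoa_result")
}

#' @export
tidy.pcoa_result <- function(x, ...) x$coordinates

#' @export
glance.pcoa_result <- function(x, ...) {
  pos <- x$eigenvalues[x$eigenvalues > 0]
  tibble(n_axes = length(pos),
         n_negative_eigenvalues = sum(x$eigenvalues < -1e-8),
         pct_axis_1 = 100 * pos[1] / sum(pos),
         pct_axis_2 = if (length(pos) > 1) 100 * pos[2] / sum(pos) else NA_real_)
}

#' @param object A `pcoa_result`.
#' @param groups Optional named vector (names = sample ids) of group labels
#'   to color by.
#' @param ... Unused.
#' @rdname pcoa_ordination
#' @export
autoplot.pcoa_result <- function(object, groups = NULL, ...) {
  dat <- object$coordinates
  if (!is.null(groups)) dat$group <- unname(groups[dat$sample_id])
  p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$axis_1, y = .data$axis_2))
  p <- if (is.null(groups)) {
    p + ggplot2::geom_point(size = 2)
  } else {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$group), size = 2) +
      ggplot2::stat_ellipse(ggplot2::aes(colour = .data$group))
  }
  gl <- glance(object)
  p + ggplot2::labs(
    x = sprintf("PCo1 (%.1f%%)", gl$pct_axis_1),
    y = sprintf("PCo2 (%.1f%%)", gl$pct_axis_2)
  ) + ggplot2::theme_minimal()
}

# Sums of squares for the distance-based pseudo-F. `g` is an integer group
# index vector; d2 the squared distance matrix.
permanova_f <- function(d2, g, sizes) {
  n <- nrow(d2)
  k <- length(sizes)
  ss_total <- sum(d2[upper.tri(d2)]) / n
  ss_within <- 0
  for (lev in seq_len(k)) {
    idx <- which(g == lev)
    if (length(idx) > 1) {
      sub <- d2[idx, idx]
      ss_within <- ss_within + sum(sub[upper.tri(sub)]) / length(idx)
    }
  }
  ((ss_total - ss_within) / (k - 1)) / (ss_within / (n - k))
}

#' PERMANOVA: permutational multivariate analysis of variance
#'
#' Distance-based pseudo-F with a permutation p-value computed with the
#' `(1 + x) / (1 + N)` estimator over label permutations. For two groups,
#' when the number of distinct label assignments (complements identified
#' when group sizes are equal) does not exceed `n_perm`, the exact
#' enumeration over all distinct splits is used instead of sampling.
#'
#' @param dm A `beta_dist` or square symmetric distance matrix.
#' @param groups Group labels, one per row of `dm` (>= 2 groups, each of
#'   size >= 2).
#' @param n_perm Number of permutations (default 999).
#' @param seed Seed for the Monte-Carlo permutations.
#' @return Object of class `permanova_test`.
#' @export
permanova_test <- function(dm, groups, n_perm = 999, seed = 1L) {
  m <- as.matrix(dm)
  groups <- as.character(groups)
  stopifnot(length(groups) == nrow(m))
  f <- factor(groups)
  sizes <- table(f)
  if (nlevels(f) < 2) stopf("need at least 2 groups")
  if (any(sizes < 2)) {
    stopf("group(s) of size 1: %s",
          paste(names(sizes)[sizes < 2], collapse = ", "))
  }
  d2 <- m^2
  g <- as.integer(f)
  f_obs <- permanova_f(d2, g, sizes)

  n <- nrow(m)
  exhaustive <- FALSE
  if (nlevels(f) == 2) {
    n1 <- sizes[[1]]
    n_splits <- choose(n, n1)
    if (sizes[[1]] == sizes[[2]]) n_splits <- n_splits / 2
    if (n_splits <= n_perm) exhaustive <- TRUE
  }

  if (exhaustive) {
    n1 <- sizes[[1]]
    splits <- combn(n, n1)
    if (sizes[[1]] == sizes[[2]]) {
      splits <- splits[, splits[1, ] == 1, drop = FALSE]
    }
    obs_set <- sort(which(g == 1L))
    if (sizes[[1]] == sizes[[2]] && !(1L %in% obs_set)) {
      obs_set <- sort(which(g == 2L))
    }
    f_perm <- numeric(0)
    for (j in seq_len(ncol(splits))) {
      idx <- splits[, j]
      if (identical(idx, obs_set)) next  # identity split
      gp <- rep(2L, n)
      gp[idx] <- 1L
      f_perm <- c(f_perm, permanova_f(d2, gp, sizes))
    }
    n_used <- length(f_perm)
  } else {
    f_perm <- with_seed(seed, {
      vapply(seq_len(n_perm), function(i) {
        permanova_f(d2, sample(g), sizes)
      }, numeric(1))
    })
    n_used <- n_perm
  }
  p <- (1 + sum(f_perm >= f_obs - 1e-12)) / (1 + n_used)

  structure(list(statistic = f_obs, p_value = p, n_perm = n_used,
                 exhaustive = exhaustive, sizes = as.integer(sizes),
                 groups = levels(f)),
            class = "permanova_test")
}

#' @export
print.permanova_test <- function(x, ...) {
  cat(sprintf("PERMANOVA pseudo-F = %.4f, p = %.4g (%s, %d permutations)\n",
              x$statistic, x$p_value,
              if (x$exhaustive) "exhaustive" else "Monte-Carlo", x$n_perm))
  invisible(x)
}

#' @export
tidy.permanova_test <- function(x, ...) {
  tibble(statistic = x$statistic, p_value = x$p_value,
         n_perm = x$n_perm, exhaustive = x$exhaustive)
}

#' @export
glance.permanova_test <- tidy.permanova_test

#' Multivariate homogeneity of group dispersions
#'
#' Embeds the samples by PCoA (with the standard imaginary-axis correction
#' for negative eigenvalues), measures each sample's distance to its group
#' centroid, and compares dispersions across groups with a one-way ANOVA.
#' Backed by `vegan::betadisper`.
#'
#' @inheritParams permanova_test
#' @return Object of class `beta_dispersion` with `$distances` (per-sample
#'   tibble) and `$anova` (one-row tibble with F and p).
#' @export
beta_dispersion <- function(dm, groups) {
  m <- as.matrix(dm)
  groups <- as.character(groups)
  f <- factor(groups)
  sizes <- table(f)
  if (nlevels(f) < 2) stopf("need at least 2 groups")
  if (any(sizes < 2)) {
    stopf("group(s) of size 1: %s",
          paste(names(sizes)[sizes < 2], collapse = ", "))
  }
  bd <- vegan::betadisper(as.dist(m), f, type = "centroid")
  av <- anova(bd)
  structure(list(
    distances = tibble(sample_id = rownames(m), group = groups,
                       dist_to_centroid = unname(bd$distances)),
    anova = tibble(statistic = av$`F value`[1], p_value = av$`Pr(>F)`[1])
  ), class = "beta_dispersion")
}

#' @export
tidy.beta_dispersion <- function(x, ...) x$distances

#' @export
glance.beta_dispersion <- function(x, ...) x$anova

#' UPGMA (average-linkage) clustering of samples
#'
#' @param dm A `beta_dist` or square symmetric distance matrix.
#' @param linkage Only `"average"` (UPGMA) is offered; merge heights are
#'   non-decreasing.
#' @return Object of class `upgma_tree` wrapping the `hclust` fit and its
#'   `ape::phylo` conversion (for Newick export via [write_newick()]).
#' @export
hclust_tree <- function(dm, linkage = "average") {
  linkage <- match.arg(linkage, "average")
  m <- as.matrix(dm)
  fit <- hclust(as.dist(m), method = linkage)
  structure(list(hclust = fit, phylo = ape::as.phylo(fit)),
            class = "upgma_tree")
}

#' @export
tidy.upgma_tree <- function(x, ...) {
  tibble(merge_a = x$hclust$merge[, 1], merge_b = x$hclust$merge[, 2],
         height = x$hclust$height)
}

#' Write an UPGMA tree to a Newick file
#'
#' @param tree An `upgma_tree`.
#' @param path Output path.
#' @return `tree`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree$phylo, file = path)
  invisible(tree)
}

#' Two-set Venn partition of taxa
#'
#' @param set_a,set_b Character vectors of taxon names.
#' @return Object of class `venn_partition`: `$counts` is a tibble with
#'   regions `unique_a`, `shared`, `unique_b`; `$members` holds the name
#'   lists.
#' @export
venn_partition <- function(set_a, set_b) {
  set_a <- unique(as.character(set_a))
  set_b <- unique(as.character(set_b))
  members <- list(
    unique_a = setdiff(set_a, set_b),
    shared = intersect(set_a, set_b),
    unique_b = setdiff(set_b, set_a)
  )
  structure(list(
    counts = tibble(region = names(members),
                    n = unname(vapply(members, length, integer(1)))),
    members = members
  ), class = "venn_partition")
}

#' @export
print.venn_partition <- function(x, ...) {
  with(x$counts, cat(sprintf(
    "<venn_partition> unique A: %d | shared: %d | unique B: %d\n",
    n[1], n[2], n[3])))
  invisible(x)
}

#' @export
tidy.venn_partition <- function(x, ...) x$counts

#' Per-group sets of present taxa
#'
#' A taxon is present in a group if its count is > 0 in at least one
#' biological sample of that group (apply contaminant filtering first).
#'
#' @param table A `taxa_table`.
#' @return Named list of character vectors, one per group.
#' @export
group_taxa_sets <- function(table) {
  validate_taxa_table(table)
  table <- biological_samples(table)
  m <- tt_counts(table)
  lapply(split(seq_len(nrow(m)), table$group), function(idx) {
    colnames(m)[colSums(m[idx, , drop = FALSE] > 0) > 0]
  })
}
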