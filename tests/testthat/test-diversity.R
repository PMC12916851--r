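mk_tab <- function(m, groups) {
  taxa_table(m, group = groups, sample_ids = sprintf("s%02d", seq_len(nrow(m))))
}

test_that("alpha diversity matches closed forms on degenerate samples", {
  m <- rbind(c(10L, 10L, 10L, 10L),
             c(100L, 0L, 0L, 0L),
             c(8L, 8L, 8L, 8L),
             c(50L, 25L, 0L, 0L))
  colnames(m) <- c("a", "b", "c", "d")
  a <- alpha_diversity(mk_tab(m, c("X", "X", "Y", "Y")))
  s <- a$samples
  expect_equal(s$observed_features, c(4L, 1L, 4L, 2L))
  expect_equal(s$shannon[1], 2)       # uniform over 4 taxa, bits
  expect_equal(s$pielou[1], 1)
  expect_equal(s$shannon[2], 0)       # single taxon
  expect_true(is.na(s$pielou[2]))     # evenness undefined at richness 1
  expect_equal(s$shannon[4], -sum(c(2, 1) / 3 * log2(c(2, 1) / 3)))
})

test_that("fully tied alpha values give Kruskal-Wallis p = 1", {
  m <- rbind(c(5L, 5L), c(7L, 7L), c(3L, 3L), c(9L, 9L))
  colnames(m) <- c("a", "b")
  a <- alpha_diversity(mk_tab(m, c("X", "X", "Y", "Y")))
  row <- a$tests[a$tests$metric == "observed_features", ]
  expect_equal(row$p_value, 1)
  expect_equal(row$statistic, 0)
})

test_that("empty samples are reported by name", {
  m <- rbind(c(5L, 1L), c(0L, 0L))
  colnames(m) <- c("a", "b")
  expect_error(alpha_diversity(mk_tab(m, c("X", "Y"))), "s02")
})

test_that("Bray-Curtis and Jaccard distances match hand computation", {
  m <- rbind(c(1L, 2L, 3L), c(3L, 2L, 1L), c(1L, 2L, 3L), c(0L, 0L, 7L))
  colnames(m) <- c("a", "b", "c")
  tab <- mk_tab(m, rep("X", 4))
  bc <- beta_distance(tab, "bray_curtis")
  expect_equal(bc["s01", "s02"], 4 / 12)
  expect_equal(bc["s01", "s03"], 0)          # identical samples
  jc <- beta_distance(tab, "jaccard")
  expect_equal(jc["s01", "s03"], 0)
  expect_equal(jc["s01", "s04"], 1 - 1 / 3)  # one shared of three in union
  # symmetry, zero diagonal, bounds
  for (d in list(bc, jc)) {
    expect_equal(unclass(d), t(unclass(d)), ignore_attr = TRUE)
    expect_true(all(diag(d) == 0))
    expect_true(all(d >= 0 & d <= 1))
  }
  # disjoint supports give distance 1 under both metrics
  m2 <- rbind(c(5L, 4L, 0L), c(0L, 0L, 7L))
  d2 <- beta_distance(mk_tab(m2, c("X", "X")), "bray_curtis")
  expect_equal(d2[1, 2], 1)
})

test_that("distances are invariant to taxa permutation", {
  tab <- biological_samples(generate_table(tiny_spec(seed = 13)))
  taxa <- mosqnet:::taxon_names(tab)
  tab2 <- tab[, c("sample_id", "group", "is_control",
                  withr::with_seed(5, sample(taxa)))]
  class(tab2) <- class(tab)
  expect_equal(unclass(beta_distance(tab, "bray_curtis")),
               unclass(beta_distance(tab2, "bray_curtis")))
})

test_that("PCoA reproduces closed-form spectra and Euclidean isometry", {
  # equilateral triangle: two equal positive eigenvalues of 1/2
  dm <- matrix(1, 3, 3) - diag(3)
  dimnames(dm) <- list(letters[1:3], letters[1:3])
  p <- pcoa_ordination(dm)
  pos <- sort(p$eigenvalues[p$eigenvalues > 1e-8], decreasing = TRUE)
  expect_equal(pos, c(0.5, 0.5))
  # identical samples collapse to the origin
  dm0 <- matrix(0, 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  p0 <- pcoa_ordination(dm0)
  expect_true(all(abs(as.matrix(p0$coordinates[, -1])) < 1e-12))
  # Euclidean input: coordinate distances reproduce the input
  pts <- withr::with_seed(3, matrix(rnorm(15), 5, 3))
  dm2 <- as.matrix(dist(pts))
  p2 <- pcoa_ordination(dm2)
  rec <- as.matrix(dist(as.matrix(p2$coordinates[, -1])))
  expect_equal(unname(rec), unname(dm2), tolerance = 1e-8)
  # eigenvalues agree with the direct Gram-matrix oracle
  o <- oracle_pcoa(dm2)
  expect_equal(sort(p2$eigenvalues, decreasing = TRUE)[1:3],
               o$eigenvalues[1:3], tolerance = 1e-8)
})

test_that("PERMANOVA exhaustive mode equals brute-force enumeration at 2v2", {
  pts <- withr::with_seed(7, matrix(rnorm(8), 4, 2))
  dm <- as.matrix(dist(pts))
  dimnames(dm) <- list(sprintf("s%d", 1:4), sprintf("s%d", 1:4))
  groups <- c("A", "A", "B", "B")
  fit <- permanova_test(dm, groups)
  expect_true(fit$exhaustive)
  # brute force over all C(4,2)=6 assignments; F is invariant to
  # relabeling, so the 3 distinct splits carry 2 non-identity values
  f_all <- apply(combn(4, 2), 2, function(idx) {
    g <- rep("B", 4); g[idx] <- "A"
    oracle_permanova_f(dm, g)
  })
  f_obs <- oracle_permanova_f(dm, groups)
  expect_equal(fit$statistic, f_obs, tolerance = 1e-12)
  distinct <- f_all[combn(4, 2)[1, ] == 1]  # splits containing s1
  n_exceed <- sum(distinct[-1] >= f_obs - 1e-12)  # first is the identity
  expect_equal(fit$p_value, (1 + n_exceed) / 3)
  expect_true(fit$p_value %in% c(1 / 3, 2 / 3, 1))
})

test_that("PERMANOVA pseudo-F agrees with vegan::adonis2", {
  tab <- biological_samples(generate_table(tiny_spec(seed = 21)))
  dm <- beta_distance(tab, "bray_curtis")
  fit <- permanova_test(dm, tab$group, n_perm = 199, seed = 4)
  ad <- vegan::adonis2(as.dist(unclass(dm)) ~ g,
                       data = data.frame(g = tab$group), permutations = 99)
  expect_equal(fit$statistic, ad$F[1], tolerance = 1e-10)
})

test_that("identical group clouds give F near 0 and p = 1", {
  pts <- withr::with_seed(2, matrix(rnorm(6), 3, 2))
  pts <- rbind(pts, pts)  # group B duplicates group A exactly
  dm <- as.matrix(dist(pts))
  dimnames(dm) <- list(sprintf("s%d", 1:6), sprintf("s%d", 1:6))
  fit <- permanova_test(dm, rep(c("A", "B"), each = 3), n_perm = 999, seed = 1)
  expect_lt(fit$statistic, 1e-10)
  expect_equal(fit$p_value, 1)
})

test_that("groups of size one are rejected", {
  dm <- as.matrix(dist(matrix(rnorm(6), 3, 2)))
  dimnames(dm) <- list(sprintf("s%d", 1:3), sprintf("s%d", 1:3))
  expect_error(permanova_test(dm, c("A", "A", "B")), "size 1")
  expect_error(beta_dispersion(dm, c("A", "A", "B")), "size 1")
})

test_that("beta dispersion distances match hand calculation on one axis", {
  # 1-D points: group A at {0, 1, 5} (centroid 2), B at {10, 11, 18}
  # (centroid 13); distances to centroid follow by hand
  x <- c(0, 1, 5, 10, 11, 18)
  g <- rep(c("A", "B"), each = 3)
  dm <- as.matrix(dist(x))
  dimnames(dm) <- list(sprintf("s%d", 1:6), sprintf("s%d", 1:6))
  bd <- beta_dispersion(dm, g)
  expect_equal(bd$distances$dist_to_centroid, c(2, 1, 3, 3, 2, 5))
  # ANOVA on those distances, computed independently
  av <- anova(aov(d ~ g, data = data.frame(d = c(2, 1, 3, 3, 2, 5), g = g)))
  expect_equal(bd$anova$statistic, av$`F value`[1], tolerance = 1e-8)
  expect_equal(bd$anova$p_value, av$`Pr(>F)`[1], tolerance = 1e-8)
})

test_that("mirror-image groups have equal dispersion; concentrated vs spread differ", {
  pts <- withr::with_seed(11, matrix(rnorm(10), 5, 2))
  mirrored <- rbind(pts, -pts)
  dm <- as.matrix(dist(mirrored))
  dimnames(dm) <- list(sprintf("s%d", 1:10), sprintf("s%d", 1:10))
  bd <- beta_dispersion(dm, rep(c("A", "B"), each = 5))
  expect_gt(bd$anova$p_value, 0.99)
  # one tight group, one spread group
  spread <- rbind(matrix(0.01 * rnorm(10), 5, 2),
                  matrix(5 * rnorm(10), 5, 2))
  dm2 <- as.matrix(dist(spread))
  dimnames(dm2) <- dimnames(dm)
  bd2 <- beta_dispersion(dm2, rep(c("A", "B"), each = 5))
  expect_lt(bd2$anova$p_value, 0.05)
})

test_that("UPGMA matches a naive average-linkage oracle", {
  # two samples: a single merge at their distance
  dm2 <- matrix(c(0, 0.4, 0.4, 0), 2, 2,
                dimnames = list(c("a", "b"), c("a", "b")))
  tr2 <- hclust_tree(dm2)
  expect_equal(tr2$hclust$height, 0.4)
  # three samples: closest pair merges first
  dm3 <- matrix(0.9, 3, 3) - diag(0.9, 3)
  dm3[1, 2] <- dm3[2, 1] <- 0.1
  dimnames(dm3) <- list(letters[1:3], letters[1:3])
  tr3 <- hclust_tree(dm3)
  expect_equal(tr3$hclust$height[1], 0.1)
  expect_setequal(abs(tr3$hclust$merge[1, ]), c(1, 2))
  # random matrices: cophenetic distances equal the O(n^3) oracle
  for (s in 1:5) {
    n <- 6
    d <- withr::with_seed(s, {
      x <- matrix(runif(n * n), n, n)
      d <- (x + t(x)) / 2; diag(d) <- 0; d
    })
    dimnames(d) <- list(sprintf("s%d", 1:n), sprintf("s%d", 1:n))
    tr <- hclust_tree(d)
    coph <- as.matrix(stats::cophenetic(tr$hclust))
    expect_equal(unname(coph), unname(oracle_upgma_cophenetic(d)),
                 tolerance = 1e-10)
    expect_true(all(diff(tr$hclust$height) >= -1e-12))
  }
})

test_that("Newick export round-trips through ape", {
  tab <- biological_samples(generate_table(tiny_spec(seed = 17)))
  tr <- hclust_tree(beta_distance(tab, "jaccard"))
  tmp <- withr::local_tempfile(fileext = ".nwk")
  write_newick(tr, tmp)
  back <- ape::read.tree(tmp)
  expect_setequal(back$tip.label, tab$sample_id)
})

test_that("venn partition is exact set algebra", {
  v <- venn_partition(c("a", "b", "c"), c("b", "c", "d"))
  expect_equal(v$counts$n, c(1L, 2L, 1L))
  expect_equal(v$members$shared, c("b", "c"))
  same <- venn_partition(letters[1:5], letters[1:5])
  expect_equal(same$counts$n, c(0L, 5L, 0L))
  disj <- venn_partition(letters[1:3], letters[10:15])
  expect_equal(disj$counts$n, c(3L, 0L, 6L))
})

test_that("adding an all-zero taxon changes no diversity result", {
  tab <- biological_samples(generate_table(tiny_spec(seed = 19)))
  a1 <- alpha_diversity(tab)
  tab2 <- tab
  tab2$zzz_empty <- rep(0L, nrow(tab2))
  class(tab2) <- class(tab)
  a2 <- alpha_diversity(tab2)
  expect_equal(a1$samples, a2$samples)
  expect_equal(unclass(beta_distance(tab, "bray_curtis")),
               unclass(beta_distance(tab2, "bray_curtis")))
})
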