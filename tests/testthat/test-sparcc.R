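rand_fracs <- function(n, d, seed = 1) {
  withr::with_seed(seed, {
    x <- matrix(rexp(n * d), n, d)
    x <- x / rowSums(x)
    colnames(x) <- sprintf("t%d", 1:d)
    x
  })
}

test_that("variation matrix matches direct per-pair variance computation", {
  f <- rand_fracs(8, 4, seed = 2)
  t_mat <- variation_matrix(f)
  for (i in 1:3) for (j in (i + 1):4) {
    expect_equal(t_mat[i, j], var(log(f[, i] / f[, j])), tolerance = 1e-12)
  }
  expect_equal(t_mat, t(t_mat))
  expect_true(all(diag(t_mat) == 0))
  # proportional columns have zero log-ratio variance
  f2 <- cbind(f[, 1], 3 * f[, 1], f[, 2])
  colnames(f2) <- c("a", "b", "c")
  expect_equal(variation_matrix(f2)["a", "b"], 0, tolerance = 1e-12)
  # invariant to sample order
  expect_equal(variation_matrix(f[8:1, ]), t_mat)
})

test_that("independent unit-variance taxa give omega = 1 and r = 0", {
  t_mat <- 2 * (matrix(1, 3, 3) - diag(3))
  dimnames(t_mat) <- list(letters[1:3], letters[1:3])
  fit <- basis_correlations(t_mat)
  expect_equal(unname(fit$omega), c(1, 1, 1), tolerance = 1e-12)
  off <- fit$r[upper.tri(fit$r)]
  expect_true(all(abs(off) < 1e-12))
  expect_equal(diag(fit$r), c(a = 1, b = 1, c = 1))
})

test_that("D=3 closed-form basis variances match the linear solve to 1e-10", {
  for (s in 1:50) {
    t_mat <- withr::with_seed(s, {
      v <- runif(3, 0.5, 2)
      r12 <- runif(1, -0.5, 0.5)
      m <- matrix(0, 3, 3)
      m[1, 2] <- m[2, 1] <- v[1] + v[2] - 2 * r12 * sqrt(v[1] * v[2])
      m[1, 3] <- m[3, 1] <- v[1] + v[3]
      m[2, 3] <- m[3, 2] <- v[2] + v[3]
      m
    })
    fit <- basis_correlations(t_mat)
    w1 <- (t_mat[1, 2] + t_mat[1, 3] - t_mat[2, 3]) / 2
    w2 <- (t_mat[1, 2] + t_mat[2, 3] - t_mat[1, 3]) / 2
    w3 <- (t_mat[1, 3] + t_mat[2, 3] - t_mat[1, 2]) / 2
    expect_equal(unname(fit$omega), c(w1, w2, w3), tolerance = 1e-10)
  }
})

test_that("r is symmetric with unit diagonal and clipped on random input", {
  f <- rand_fracs(10, 6, seed = 9)
  fit <- basis_correlations(variation_matrix(f))
  expect_equal(fit$r, t(fit$r))
  expect_equal(unname(diag(fit$r)), rep(1, 6))
  expect_true(all(fit$r >= -1 & fit$r <= 1))
})

test_that("SparCC r is invariant to per-sample count scaling", {
  counts <- withr::with_seed(4, matrix(rpois(60, 200) + 1, 10, 6))
  colnames(counts) <- sprintf("t%d", 1:6)
  # pseudocount-free fractions isolate the compositional invariance
  f1 <- sparcc_infer(counts, n_resamples = 0, pseudocount = 0)
  scaled <- counts
  scaled[3, ] <- scaled[3, ] * 50L
  scaled[7, ] <- scaled[7, ] * 9L
  f2 <- sparcc_infer(scaled, n_resamples = 0, pseudocount = 0)
  expect_equal(f1$r, f2$r, tolerance = 1e-10)
})

test_that("SparCC r is equivariant under taxa reordering", {
  counts <- withr::with_seed(6, matrix(rpois(80, 100) + 1, 10, 8))
  colnames(counts) <- sprintf("t%d", 1:8)
  f1 <- sparcc_infer(counts, n_resamples = 0)
  perm <- withr::with_seed(7, sample(8))
  f2 <- sparcc_infer(counts[, perm], n_resamples = 0)
  expect_equal(f2$r[colnames(counts), colnames(counts)], f1$r,
               tolerance = 1e-12)
})

test_that("resampled inference is deterministic given the seed", {
  counts <- withr::with_seed(8, matrix(rpois(60, 150) + 1, 10, 6))
  colnames(counts) <- sprintf("t%d", 1:6)
  f1 <- sparcc_infer(counts, n_resamples = 1, seed = 33)
  f2 <- sparcc_infer(counts, n_resamples = 1, seed = 33)
  expect_identical(f1$r, f2$r)
  f3 <- sparcc_infer(counts, n_resamples = 1, seed = 34)
  expect_false(identical(f1$r, f3$r))
})

test_that("near-constant taxa are dropped before inference", {
  tab <- generate_table(tiny_spec(seed = 14, sequencing_depth = 50000))
  fit <- sparcc_infer(biological_samples(tab, group = "siteA"),
                      n_resamples = 2, seed = 1)
  expect_true("Wolbachia" %in% fit$dropped_taxa)
  expect_false("Wolbachia" %in% fit$taxa)
})

test_that("a strongly planted pair is recovered at a fixed seed", {
  planted <- tibble::tibble(taxon_a = "core_01", taxon_b = "core_02",
                            sign = 1L)
  tab <- generate_table(calib_spec(5, planted), include_controls = FALSE)
  fit <- sparcc_infer(tab, seed = 101)
  expect_gte(fit$r["core_01", "core_02"], 0.5)
})

test_that("edge thresholding respects the inclusive 0.5 bound", {
  r <- diag(3)
  dimnames(r) <- list(letters[1:3], letters[1:3])
  r["a", "b"] <- r["b", "a"] <- 0.5
  r["a", "c"] <- r["c", "a"] <- 0.49
  r["b", "c"] <- r["c", "b"] <- -0.51
  e <- threshold_edges(r, cutoff = 0.5)
  expect_equal(nrow(e), 2)
  expect_true(any(e$taxon_a == "a" & e$taxon_b == "b" & e$sign == 1))
  expect_true(any(e$taxon_a == "b" & e$taxon_b == "c" & e$sign == -1))
  expect_false(any(e$taxon_b == "c" & e$taxon_a == "a"))
  # all-zero off-diagonal: empty edge list
  expect_equal(nrow(threshold_edges(diag(3) |>
                                      `dimnames<-`(list(letters[1:3],
                                                        letters[1:3])),
                                    0.5)), 0)
  expect_error(threshold_edges(r, cutoff = 0), "cutoff")
})

test_that("fewer than 3 informative taxa is an error", {
  counts <- cbind(a = rep(5L, 4), b = c(1L, 2L, 3L, 4L))
  expect_error(sparcc_infer(counts), "3")
  expect_error(variation_matrix(rand_fracs(5, 2)), "3")
})
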