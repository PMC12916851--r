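# SparCC: basis correlations from compositional counts.
#
# Read counts only carry relative information, so Pearson correlations on
# proportions are biased by the closure. SparCC estimates the correlations
# of the unobserved ("basis") absolute abundances from the variation matrix
# t_ij = Var(log(f_i/f_j)) under a sparsity assumption: for most pairs
# t_ij ~ w_i + w_j, where w_i is the basis log-variance of taxon i. Strongly
# correlated pairs violate the assumption and are excluded iteratively.

# Fraction estimates. Point estimate: Dirichlet posterior mean
# (x + pseudocount) / sum. Resample: one Dirichlet(x + pseudocount) draw per
# sample (gamma normalization).
sparcc_fractions <- function(counts, pseudocount = 1, resample = FALSE) {
  a <- counts + pseudocount
  if (resample) {
    g <- matrix(rgamma(length(a), shape = a, rate = 1),
                nrow = nrow(a), dimnames = dimnames(a))
    g / rowSums(g)
  } else {
    a / rowSums(a)
  }
}

#' Variation matrix of log-ratio variances
#'
#' For fractions `f` (samples by taxa), entry (i, j) is the variance across
#' samples of `log(f_i / f_j)`: symmetric, non-negative, zero diagonal.
#' Computed from the covariance of the log fractions as
#' `Var(a - b) = Var(a) + Var(b) - 2 Cov(a, b)`.
#'
#' @param fractions Matrix of positive fractions, rows = samples (>= 2),
#'   columns = taxa (>= 3).
#' @return Symmetric taxa-by-taxa matrix.
#' @export
variation_matrix <- function(fractions) {
  if (nrow(fractions) < 2) stopf("need >= 2 samples")
  if (ncol(fractions) < 3) stopf("SparCC needs >= 3 taxa (basis solve)")
  lf <- log(fractions)
  cv <- stats::cov(lf)
  v <- diag(cv)
  t_mat <- outer(v, v, `+`) - 2 * cv
  t_mat[t_mat < 0] <- 0  # numerical guard
  diag(t_mat) <- 0
  dimnames(t_mat) <- list(colnames(fractions), colnames(fractions))
  t_mat
}

# Floor for non-positive basis-variance estimates (standard practical fix).
OMEGA_FLOOR <- 1e-6

#' Solve the SparCC linear system for basis variances and correlations
#'
#' Under sparsity, row sums of the variation matrix over unexcluded pairs
#' satisfy a D-by-D linear system in the basis variances `omega` (diagonal
#' D-1, off-diagonal 1 when nothing is excluded). Correlations follow as
#' `r_ij = (omega_i + omega_j - t_ij) / (2 sqrt(omega_i omega_j))`, clipped
#' to `[-1, 1]`. Non-positive `omega` estimates are floored at `1e-6`
#' (recorded in the `floored` attribute).
#'
#' @param t_mat Variation matrix from [variation_matrix()].
#' @param excluded Optional 2-column integer matrix of excluded pair
#'   indices.
#' @return List with `omega` (basis variances) and `r` (correlation matrix,
#'   unit diagonal).
#' @export
basis_correlations <- function(t_mat, excluded = NULL) {
  d <- ncol(t_mat)
  if (d < 3) stopf("SparCC needs >= 3 taxa")
  adj <- matrix(1, d, d) - diag(d)  # 1 where pair is unexcluded
  if (!is.null(excluded) && nrow(excluded) > 0) {
    for (k in seq_len(nrow(excluded))) {
      i <- excluded[k, 1]; j <- excluded[k, 2]
      adj[i, j] <- adj[j, i] <- 0
    }
  }
  m <- adj + diag(rowSums(adj))
  rhs <- rowSums(t_mat * adj)
  omega <- solve(m, rhs)
  floored <- omega < OMEGA_FLOOR
  omega[floored] <- OMEGA_FLOOR
  s <- sqrt(omega)
  r <- (outer(omega, omega, `+`) - t_mat) / (2 * outer(s, s))
  r[r > 1] <- 1
  r[r < -1] <- -1
  diag(r) <- 1
  dimnames(r) <- dimnames(t_mat)
  names(omega) <- colnames(t_mat)
  structure(list(omega = omega, r = r), floored = sum(floored))
}

# One full SparCC pass on a fraction matrix: iterative strongest-pair
# exclusion, then the final solve over the remaining pairs.
sparcc_one_pass <- function(fractions, n_iter, exclusion_threshold) {
  t_mat <- variation_matrix(fractions)
  d <- ncol(t_mat)
  excluded <- matrix(integer(0), ncol = 2)
  partner_count <- rep(d - 1L, d)
  fit <- basis_correlations(t_mat, excluded)
  for (iter in seq_len(n_iter)) {
    r_abs <- abs(fit$r)
    diag(r_abs) <- 0
    if (nrow(excluded) > 0) {
      r_abs[excluded] <- 0
      r_abs[excluded[, 2:1, drop = FALSE]] <- 0
    }
    top <- which.max(r_abs)
    if (r_abs[top] <= exclusion_threshold) break
    ij <- arrayInd(top, dim(r_abs))
    i <- ij[1]; j <- ij[2]
    # keep the solve well posed: stop rather than strip a taxon bare or
    # make the system singular
    new_pc <- partner_count
    new_pc[c(i, j)] <- new_pc[c(i, j)] - 1L
    if (any(new_pc[c(i, j)] < 1) || sum(new_pc > 0) < 4) break
    new_fit <- tryCatch(
      basis_correlations(t_mat, rbind(excluded, c(i, j))),
      error = function(e) NULL)
    if (is.null(new_fit)) break
    partner_count <- new_pc
    excluded <- rbind(excluded, c(i, j))
    fit <- new_fit
  }
  list(r = fit$r, omega = fit$omega, excluded = excluded)
}

#' Infer SparCC correlations from a taxa table
#'
#' Runs the full SparCC procedure: taxa that are all-zero, have zero count
#' variance, or whose log-fraction variance falls below `min_variance` are
#' dropped first (the dropped names are recorded). The variance guard is a
#' degenerate-input rule: the correlation normalization divides by the
#' square root of the estimated basis variance, so a taxon whose
#' log-abundance is essentially constant across samples — the signature of
#' a dominant endosymbiont — has no identifiable basis variance at these
#' sample sizes and would only contribute numerically unstable, clipped
#' correlations. Such taxa therefore never enter inferred networks.
#' Then, for each of `n_resamples`
#' Dirichlet-resampled fraction matrices, the iterative
#' strongest-pair-exclusion loop is run and the final correlation matrix is
#' the elementwise median over resamples. With `n_resamples = 0` a single
#' deterministic pass on the posterior-mean fractions is used.
#' Deterministic given `seed`.
#'
#' @param table A `taxa_table` (control samples are dropped); or a bare
#'   counts matrix, samples by taxa.
#' @param n_iter Maximum number of pair exclusions per pass (default 10).
#' @param exclusion_threshold Exclude the strongest pair only while its
#'   `|r|` exceeds this (default 0.1).
#' @param n_resamples Dirichlet resamples to aggregate over (default 20).
#' @param pseudocount Added to counts for the Dirichlet fractions
#'   (default 1).
#' @param min_variance Absolute floor on the variance of a taxon's log
#'   point-estimate fraction for it to enter inference (default 1e-3); the
#'   effective floor is the larger of this and 5% of the community's
#'   median log-fraction variance.
#' @param seed Integer seed.
#' @return Object of class `sparcc_fit` with `$r` (symmetric correlation
#'   matrix, unit diagonal), `$taxa`, `$dropped_taxa`, `$params`.
#' @export
#' @examples
#' sp <- synth_spec(n_samples_per_group = 8, n_core_taxa = 5,
#'                  n_accessory_taxa_per_group = c(2, 2), seed = 3)
#' fit <- sparcc_infer(generate_table(sp, include_controls = FALSE),
#'                     n_resamples = 5, seed = 1)
#' head(tidy(fit))
sparcc_infer <- function(table, n_iter = 10, exclusion_threshold = 0.1,
                         n_resamples = 20, pseudocount = 1,
                         min_variance = 1e-3, seed = 1L) {
  if (inherits(table, "taxa_table")) {
    counts <- tt_counts(biological_samples(table))
  } else {
    counts <- as.matrix(table)
  }
  lf <- log(sparcc_fractions(counts, pseudocount))
  lf_var <- apply(lf, 2, var)
  # scale-free component: a taxon an order of magnitude (and more) less
  # variable than the community median is treated as near-constant
  var_floor <- max(min_variance, 0.05 * median(lf_var))
  keep <- apply(counts, 2, function(x) sum(x) > 0 && var(x) > 0) &
    lf_var >= var_floor
  dropped <- colnames(counts)[!keep]
  counts <- counts[, keep, drop = FALSE]
  if (ncol(counts) < 3) stopf("fewer than 3 informative taxa after dropping")

  run_pass <- function(resample) {
    fr <- sparcc_fractions(counts, pseudocount, resample = resample)
    sparcc_one_pass(fr, n_iter, exclusion_threshold)
  }

  if (n_resamples == 0) {
    pass <- run_pass(FALSE)
    r <- pass$r
    n_excluded <- nrow(pass$excluded)
  } else {
    passes <- with_seed(seed, {
      lapply(seq_len(n_resamples), function(b) run_pass(TRUE))
    })
    arr <- simplify2array(lapply(passes, `[[`, "r"))
    r <- apply(arr, c(1, 2), median)
    dimnames(r) <- dimnames(passes[[1]]$r)
    n_excluded <- mean(vapply(passes, function(p) nrow(p$excluded), numeric(1)))
  }
  r <- (r + t(r)) / 2
  diag(r) <- 1

  structure(list(
    r = r,
    taxa = colnames(counts),
    dropped_taxa = dropped,
    n_excluded_pairs = n_excluded,
    params = list(n_iter = n_iter, exclusion_threshold = exclusion_threshold,
                  n_resamples = n_resamples, pseudocount = pseudocount,
                  min_variance = min_variance, seed = as.integer(seed))
  ), class = "sparcc_fit")
}

#' @export
print.sparcc_fit <- function(x, ...) {
  cat(sprintf("<sparcc_fit> %d taxa (%d dropped), %d resamples\n",
              length(x$taxa), length(x$dropped_taxa),
              x$params$n_resamples))
  invisible(x)
}

#' @export
tidy.sparcc_fit <- function(x, ...) {
  idx <- which(upper.tri(x$r), arr.ind = TRUE)
  tibble(taxon_a = rownames(x$r)[idx[, 1]],
         taxon_b = colnames(x$r)[idx[, 2]],
         r = x$r[idx]) |>
    arrange(dplyr::desc(abs(.data$r)))
}

#' @export
glance.sparcc_fit <- function(x, ...) {
  off <- x$r[upper.tri(x$r)]
  tibble(n_taxa = length(x$taxa), n_dropped = length(x$dropped_taxa),
         n_resamples = x$params$n_resamples,
         max_abs_r = max(abs(off)), mean_excluded_pairs = x$n_excluded_pairs)
}

#' Threshold a correlation matrix into a signed edge list
#'
#' Keeps every unordered taxon pair with `r >= cutoff` or `r <= -cutoff`
#' (bounds inclusive on both sides).
#'
#' @param fit A `sparcc_fit` (or bare symmetric correlation matrix with
#'   dimnames).
#' @param cutoff Absolute-correlation threshold in `(0, 1]`; default 0.5.
#' @return Tibble with columns `taxon_a`, `taxon_b`, `r`, `sign` (+1/-1).
#' @export
threshold_edges <- function(fit, cutoff = 0.5) {
  check_number(cutoff, "cutoff", 0, 1, strict = FALSE)
  if (cutoff <= 0) stopf("`cutoff` must be in (0, 1]")
  rmat <- if (inherits(fit, "sparcc_fit")) fit$r else as.matrix(fit)
  idx <- which(upper.tri(rmat) & abs(rmat) >= cutoff, arr.ind = TRUE)
  vals <- rmat[idx]
  tibble(
    taxon_a = rownames(rmat)[idx[, 1]],
    taxon_b = colnames(rmat)[idx[, 2]],
    r = vals,
    sign = ifelse(vals >= 0, 1L, -1L)
  ) |> arrange(.data$taxon_a, .data$taxon_b)
}
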