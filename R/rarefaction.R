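#' Rarefaction curves of observed taxa versus subsampled depth
#'
#' For each sample and each depth `d` not exceeding the sample's total read
#' count, computes the expected number of distinct taxa in a uniform
#' without-replacement subsample of `d` reads. The default is the exact
#' hypergeometric expectation
#' \deqn{E[S_d] = \sum_t \left(1 - \binom{N - n_t}{d} / \binom{N}{d}\right),}
#' which removes any dependence on a Monte-Carlo replicate count; a seeded
#' Monte-Carlo estimator is available for cross-checking. Depths above a
#' sample's total yield `NA`.
#'
#' @param table A `taxa_table`.
#' @param depths Integer vector of subsampling depths.
#' @param reps Monte-Carlo replicates (used only for `method = "montecarlo"`).
#' @param seed Seed for the Monte-Carlo path.
#' @param method `"exact"` (default) or `"montecarlo"`.
#' @return A tibble with columns `sample_id`, `depth`, `richness`.
#' @export
rarefaction_curve <- function(table, depths, reps = 100, seed = 1L,
                              method = c("exact", "montecarlo")) {
  validate_taxa_table(table)
  method <- match.arg(method)
  stopifnot(all(depths >= 1), reps >= 1)
  depths <- as.integer(depths)
  m <- tt_counts(table)

  one_sample <- function(counts, d) {
    total <- sum(counts)
    if (d > total) return(NA_real_)
    nz <- counts[counts > 0]
    if (method == "exact") {
      sum(1 - exp(lchoose(total - nz, d) - lchoose(total, d)))
    } else {
      pool <- rep(seq_along(nz), nz)
      mean(vapply(seq_len(reps), function(i) {
        length(unique(sample(pool, d)))
      }, numeric(1)))
    }
  }

  run <- function() {
    tidyr::expand_grid(sample_id = rownames(m), depth = depths) |>
      mutate(richness = purrr::map2_dbl(
        .data$sample_id, .data$depth,
        function(s, d) one_sample(m[s, ], d)
      ))
  }
  if (method == "montecarlo") with_seed(seed, run()) else run()
}
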