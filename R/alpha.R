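#' Alpha diversity with Kruskal-Wallis group comparisons
#'
#' Computes, per biological sample: observed features (taxa with count > 0),
#' Shannon entropy in bits (base-2 log, the QIIME2 convention; configurable),
#' and Pielou's evenness (Shannon divided by log of observed richness;
#' undefined and reported `NA` when only one taxon is observed). Each metric
#' is compared between groups with the tie-corrected Kruskal-Wallis test.
#'
#' @param table A `taxa_table`; control samples are dropped before
#'   computation.
#' @param base Logarithm base for Shannon entropy (default 2, i.e., bits).
#' @return An object of class `alpha_diversity`: `$samples` a per-sample
#'   tibble, `$tests` a per-metric tibble of H statistics and p-values.
#' @export
#' @examples
#' sp <- synth_spec(n_samples_per_group = 5, n_core_taxa = 4,
#'                  n_accessory_taxa_per_group = c(3, 3), seed = 1)
#' a <- alpha_diversity(generate_table(sp))
#' tidy(a)
#' glance(a)
alpha_diversity <- function(table, base = 2) {
  validate_taxa_table(table)
  table <- biological_samples(table)
  m <- tt_counts(table)
  totals <- rowSums(m)
  if (any(totals == 0)) {
    stopf("sample(s) with zero reads: %s",
          paste(rownames(m)[totals == 0], collapse = ", "))
  }

  shannon_of <- function(x) {
    p <- x[x > 0] / sum(x)
    -sum(p * log(p, base = base))
  }
  samples <- tibble(
    sample_id = rownames(m),
    group = table$group,
    observed_features = unname(as.integer(rowSums(m > 0))),
    shannon = unname(apply(m, 1, shannon_of))
  ) |>
    mutate(pielou = ifelse(.data$observed_features > 1,
                           .data$shannon / log(.data$observed_features, base = base),
                           NA_real_))

  tests <- purrr::map(c("observed_features", "shannon", "pielou"), function(metric) {
    v <- samples[[metric]]
    keep <- !is.na(v)
    if (length(unique(v[keep])) == 1) {
      # fully tied data: H = 0 under the tie correction, no evidence
      return(tibble(metric = metric, statistic = 0, p_value = 1))
    }
    kt <- kruskal.test(v[keep], factor(samples$group[keep]))
    tibble(metric = metric,
           statistic = unname(kt$statistic),
           p_value = kt$p.value)
  }) |> list_rbind()

  structure(list(samples = samples, tests = tests, base = base),
            class = "alpha_diversity")
}

#' @export
print.alpha_diversity <- function(x, ...) {
  cat(sprintf("<alpha_diversity> %d samples, Shannon base %g\n",
              nrow(x$samples), x$base))
  print(x$tests)
  invisible(x)
}

#' @export
tidy.alpha_diversity <- function(x, ...) x$samples

#' @export
glance.alpha_diversity <- function(x, ...) {
  tidyr::pivot_wider(x$tests, names_from = "metric",
                     values_from = c("statistic", "p_value"))
}

#' @export
autoplot.alpha_diversity <- function(object, ...) {
  long <- tidyr::pivot_longer(object$samples,
                              cols = c("observed_features", "shannon", "pielou"),
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$group, y = .data$value,
                                     fill = .data$group)) +
    ggplot2::geom_boxplot(alpha = 0.6, outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.15, size = 1) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}
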