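#' Identify contaminant taxa by the prevalence method
#'
#' Compares each taxon's presence/absence (count >= 1) in negative-control
#' samples versus biological samples. The score is the one-sided Fisher
#' exact probability of observing control enrichment at least as extreme as
#' the data under the hypergeometric null — an exact realization of the
#' prevalence-based contaminant test, appropriate at the handful-of-samples
#' scale of extraction controls. A taxon is flagged when its score falls
#' below `threshold` (default 0.5).
#'
#' @param table A `taxa_table` containing at least one control and one
#'   biological sample.
#' @param threshold Probability threshold below which a taxon is called a
#'   contaminant.
#' @return An object of class `contaminant_report`: `$report` is a tibble
#'   with per-taxon prevalences, score and flag; `$filtered` is a copy of
#'   `table` with flagged taxa removed from the biological samples.
#' @export
#' @examples
#' sp <- synth_spec(n_samples_per_group = 5, n_core_taxa = 4,
#'                  n_accessory_taxa_per_group = c(3, 3), seed = 1)
#' rep <- find_contaminants(generate_table(sp))
#' tidy(rep)
find_contaminants <- function(table, threshold = 0.5) {
  validate_taxa_table(table)
  check_number(threshold, "threshold", 0, 1)
  n_ctl <- sum(table$is_control)
  n_bio <- sum(!table$is_control)
  if (n_ctl < 1) {
    stopf("no control samples in the table; skip contaminant filtering")
  }
  if (n_bio < 1) stopf("no biological samples in the table")

  m <- tt_counts(table) >= 1
  ctl <- table$is_control
  report <- purrr::map(taxon_names(table), function(tx) {
    in_ctl <- sum(m[ctl, tx])
    in_bio <- sum(m[!ctl, tx])
    # one-sided exact test for enrichment of presence in controls
    tab2 <- matrix(c(in_ctl, n_ctl - in_ctl, in_bio, n_bio - in_bio), 2, 2)
    score <- fisher.test(tab2, alternative = "greater")$p.value
    tibble(
      taxon = tx,
      prevalence_in_samples = in_bio / n_bio,
      prevalence_in_controls = in_ctl / n_ctl,
      score = score,
      is_contaminant = score < threshold
    )
  }) |> list_rbind()

  flagged <- report$taxon[report$is_contaminant]
  filtered <- table
  if (length(flagged) > 0) {
    filtered <- filtered[, setdiff(names(filtered), flagged)]
    class(filtered) <- c("taxa_table", setdiff(class(filtered), "taxa_table"))
  }
  structure(list(report = report, filtered = filtered,
                 threshold = threshold),
            class = "contaminant_report")
}

#' @export
print.contaminant_report <- function(x, ...) {
  cat(sprintf("<contaminant_report> %d/%d taxa flagged at threshold %g\n",
              sum(x$report$is_contaminant), nrow(x$report), x$threshold))
  print(x$report[x$report$is_contaminant, ])
  invisible(x)
}

#' @export
tidy.contaminant_report <- function(x, ...) x$report

#' @export
glance.contaminant_report <- function(x, ...) {
  tibble(n_taxa = nrow(x$report),
         n_contaminants = sum(x$report$is_contaminant),
         threshold = x$threshold)
}

#' Remove contaminant taxa from a taxa table
#'
#' Convenience wrapper: runs [find_contaminants()] and returns the filtered
#' table (contaminants dropped, all other counts untouched).
#'
#' @inheritParams find_contaminants
#' @param drop_controls Also drop the control samples from the result?
#' @return A filtered `taxa_table`.
#' @export
filter_contaminants <- function(table, threshold = 0.5, drop_controls = TRUE) {
  out <- find_contaminants(table, threshold)$filtered
  if (drop_controls) out <- biological_samples(out)
  out
}
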