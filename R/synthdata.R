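#' Specify a synthetic two-site microbiome study
#'
#' Describes the generative model used throughout the package's tests and
#' demos: two groups of samples whose genus-level log-abundances are drawn
#' from a multivariate normal with a *planted* correlation structure, closed
#' to proportions and read out by multinomial sequencing. The community has
#' a single dominant, near-constant taxon (a *Wolbachia*-like endosymbiont),
#' a small shared core, group-specific accessory genera, and negative
#' controls carrying contaminant taxa only.
#'
#' The defaults encode the study conditions the package emulates: 2 groups
#' of 10 mosquito-sized samples, a core of 15 shared genera plus the
#' dominant taxon, 100 vs 61 accessory genera, 4 negative controls, 2
#' contaminant taxa, 50,000 reads per sample.
#'
#' @param n_samples_per_group Biological samples per group.
#' @param n_core_taxa Number of shared core genera (the dominant taxon is
#'   counted separately).
#' @param n_accessory_taxa_per_group Length-2 integer vector: accessory
#'   genera unique to group 1 and group 2.
#' @param dominant_fraction Target relative abundance of the dominant taxon,
#'   strictly in (0, 1).
#' @param planted_graph Tibble/data frame with columns `taxon_a`, `taxon_b`,
#'   `sign` (+1/-1) giving the planted log-scale correlation pairs, or
#'   `NULL` to plant a default sparse modular structure derived from `seed`.
#' @param log_effect_size Magnitude of the planted log-scale correlation,
#'   in (0, 1); unit log-variance taxa make this the correlation itself.
#' @param sequencing_depth Reads per biological sample.
#' @param n_controls Number of negative-control samples.
#' @param contaminant_taxa Character vector of contaminant taxon names
#'   (present in controls, absent from biological samples).
#' @param group_labels Length-2 character vector of group names.
#' @param seed Integer seed; all randomness of the generator flows from it.
#'
#' @return A list of class `synth_spec`.
#' @export
#' @examples
#' sp <- synth_spec(n_samples_per_group = 5, n_core_taxa = 4,
#'                  n_accessory_taxa_per_group = c(3, 3), seed = 1)
#' tab <- generate_table(sp)
synth_spec <- function(n_samples_per_group = 10,
                       n_core_taxa = 15,
                       n_accessory_taxa_per_group = c(100, 61),
                       dominant_fraction = 0.9,
                       planted_graph = NULL,
                       log_effect_size = 0.8,
                       sequencing_depth = 50000,
                       n_controls = 4,
                       contaminant_taxa = c("contam_1", "contam_2"),
                       group_labels = c("siteA", "siteB"),
                       seed = 1L) {
  check_number(n_samples_per_group, "n_samples_per_group", 1, Inf, TRUE)
  check_number(n_core_taxa, "n_core_taxa", 1, Inf, TRUE)
  stopifnot(length(n_accessory_taxa_per_group) == 2)
  check_number(n_accessory_taxa_per_group[1], "n_accessory_taxa_per_group[1]", 1, Inf, TRUE)
  check_number(n_accessory_taxa_per_group[2], "n_accessory_taxa_per_group[2]", 1, Inf, TRUE)
  check_number(dominant_fraction, "dominant_fraction", 0, 1, strict = TRUE)
  check_number(log_effect_size, "log_effect_size", 0, 1, strict = TRUE)
  check_number(sequencing_depth, "sequencing_depth", 1, Inf, TRUE)
  check_number(n_controls, "n_controls", 0, Inf, TRUE)
  stopifnot(length(group_labels) == 2, !anyDuplicated(group_labels))
  check_number(seed, "seed", -2^31, 2^31, TRUE)

  spec <- structure(list(
    n_samples_per_group = as.integer(n_samples_per_group),
    n_core_taxa = as.integer(n_core_taxa),
    n_accessory_taxa_per_group = as.integer(n_accessory_taxa_per_group),
    dominant_fraction = dominant_fraction,
    planted_graph = planted_graph,
    log_effect_size = log_effect_size,
    sequencing_depth = as.integer(sequencing_depth),
    n_controls = as.integer(n_controls),
    contaminant_taxa = as.character(contaminant_taxa),
    group_labels = as.character(group_labels),
    seed = as.integer(seed)
  ), class = "synth_spec")

  if (is.null(spec$planted_graph)) {
    spec$planted_graph <- default_planted_graph(spec)
  } else {
    spec$planted_graph <- as_tibble(planted_graph)
  }
  validate_synth_spec(spec)
}

# Taxon name layout shared by the generator and its validation.
synth_taxa <- function(spec) {
  list(
    dominant = "Wolbachia",
    core = sprintf("core_%02d", seq_len(spec$n_core_taxa)),
    acc = list(
      sprintf("acc%s_%03d", spec$group_labels[1],
              seq_len(spec$n_accessory_taxa_per_group[1])),
      sprintf("acc%s_%03d", spec$group_labels[2],
              seq_len(spec$n_accessory_taxa_per_group[2]))
    )
  )
}

# Default planted structure: a sparse, mostly-positive random pairing within
# the core and within each group's accessory block (so each group's network
# has both shared and group-specific planted edges), about 0.6 edges per
# taxon, 85% positive.
default_planted_graph <- function(spec) {
  tx <- synth_taxa(spec)
  with_seed(derive_seed(spec$seed, 77), {
    plant_block <- function(taxa, n_edges) {
      if (length(taxa) < 2 || n_edges < 1) {
        return(tibble(taxon_a = character(), taxon_b = character(),
                      sign = integer()))
      }
      all_pairs <- t(combn(taxa, 2))
      k <- min(n_edges, nrow(all_pairs))
      pick <- sample(nrow(all_pairs), k)
      tibble(taxon_a = all_pairs[pick, 1], taxon_b = all_pairs[pick, 2],
             sign = ifelse(runif(k) < 0.85, 1L, -1L))
    }
    bind_rows(
      plant_block(tx$core, round(0.6 * length(tx$core))),
      plant_block(tx$acc[[1]], round(0.6 * length(tx$acc[[1]]))),
      plant_block(tx$acc[[2]], round(0.6 * length(tx$acc[[2]])))
    )
  })
}

validate_synth_spec <- function(spec) {
  tx <- synth_taxa(spec)
  declared <- c(tx$dominant, tx$core, unlist(tx$acc))
  if (anyDuplicated(c(declared, spec$contaminant_taxa))) {
    stopf("taxon name clash in synthetic spec")
  }
  pg <- spec$planted_graph
  needed <- c("taxon_a", "taxon_b", "sign")
  if (!all(needed %in% names(pg))) {
    stopf("planted_graph must have columns taxon_a, taxon_b, sign")
  }
  if (nrow(pg) > 0) {
    unknown <- setdiff(c(pg$taxon_a, pg$taxon_b), declared)
    if (length(unknown) > 0) {
      stopf("planted_graph references undeclared taxa: %s",
            paste(unique(unknown), collapse = ", "))
    }
    if (any(pg$taxon_a == pg$taxon_b)) stopf("planted_graph contains a self-pair")
    if (!all(pg$sign %in% c(-1, 1))) stopf("planted_graph sign must be +1 or -1")
    key <- paste(pmin(pg$taxon_a, pg$taxon_b), pmax(pg$taxon_a, pg$taxon_b))
    if (anyDuplicated(key)) stopf("planted_graph lists a pair twice")
  }
  spec
}

# Log-normal variances: ordinary taxa have unit log-variance; the dominant
# taxon is near-constant so it cannot form significant correlations and
# drops out of inferred networks, as dominant endosymbionts do.
DOMINANT_LOG_VAR <- 1e-4

# Covariance of log-abundances for one group's active taxa, with planted
# pairs as signed off-diagonal entries. A small ridge is added if planting
# makes the matrix non-positive-definite.
synth_sigma <- function(active, spec) {
  d <- length(active)
  sigma <- diag(rep(1, d))
  rownames(sigma) <- colnames(sigma) <- active
  pg <- spec$planted_graph
  keep <- pg$taxon_a %in% active & pg$taxon_b %in% active
  pg <- pg[keep, , drop = FALSE]
  if (nrow(pg) > 0) {
    for (k in seq_len(nrow(pg))) {
      v <- pg$sign[k] * spec$log_effect_size
      sigma[pg$taxon_a[k], pg$taxon_b[k]] <- v
      sigma[pg$taxon_b[k], pg$taxon_a[k]] <- v
    }
  }
  i_dom <- match(synth_taxa(spec)$dominant, active)
  if (!is.na(i_dom)) {
    sigma[i_dom, ] <- sigma[i_dom, ] * sqrt(DOMINANT_LOG_VAR)
    sigma[, i_dom] <- sigma[, i_dom] * sqrt(DOMINANT_LOG_VAR)
    sigma[i_dom, i_dom] <- DOMINANT_LOG_VAR
  }
  ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-8) {
    sigma <- sigma + diag(rep(1e-8 - min(ev), d))
  }
  sigma
}

#' Generate a synthetic taxa table
#'
#' Draws per-sample genus log-abundances from the multivariate normal
#' encoded by the spec (unit log-variances, planted signed correlations of
#' magnitude `log_effect_size`, near-zero variance for the dominant taxon),
#' closes them to proportions with the dominant taxon pinned near
#' `dominant_fraction`, and samples reads by multinomial at
#' `sequencing_depth`. Negative controls from [generate_controls()] are
#' appended when `n_controls > 0`. Deterministic given `spec$seed`.
#'
#' @param spec A [synth_spec()].
#' @param include_controls Append negative-control samples? Default `TRUE`.
#' @return A `taxa_table` with `2 * n_samples_per_group` biological samples
#'   (row sums exactly `sequencing_depth`) plus `n_controls` controls.
#' @export
generate_table <- function(spec, include_controls = TRUE) {
  stopifnot(inherits(spec, "synth_spec"))
  validate_synth_spec(spec)
  tx <- synth_taxa(spec)
  all_taxa <- c(tx$dominant, tx$core, unlist(tx$acc), spec$contaminant_taxa)
  n <- spec$n_samples_per_group

  counts <- with_seed(spec$seed, {
    rows <- list()
    for (g in 1:2) {
      active <- c(tx$dominant, tx$core, tx$acc[[g]])
      sigma <- synth_sigma(active, spec)
      # Pin the dominant taxon's expected share: non-dominant taxa have
      # E[abundance] = exp(1/2) under unit log-variance.
      k_other <- length(active) - 1
      mu <- rep(0, length(active))
      mu[match(tx$dominant, active)] <-
        log(spec$dominant_fraction / (1 - spec$dominant_fraction) *
              k_other * exp(0.5))
      z <- MASS::mvrnorm(n, mu = mu, Sigma = sigma)
      if (n == 1) z <- matrix(z, nrow = 1)
      ab <- exp(z)
      m <- matrix(0L, nrow = n, ncol = length(all_taxa),
                  dimnames = list(NULL, all_taxa))
      for (i in seq_len(n)) {
        p <- ab[i, ] / sum(ab[i, ])
        m[i, active] <- rmultinom(1, spec$sequencing_depth, p)[, 1]
      }
      rows[[g]] <- m
    }
    do.call(rbind, rows)
  })

  tab <- taxa_table(
    counts,
    group = rep(spec$group_labels, each = n),
    is_control = rep(FALSE, 2L * n),
    sample_ids = c(sprintf("%s_%02d", spec$group_labels[1], seq_len(n)),
                   sprintf("%s_%02d", spec$group_labels[2], seq_len(n))),
    taxon_ids = all_taxa
  )
  if (include_controls && spec$n_controls > 0) {
    tab <- bind_rows(tab, generate_controls(spec))
    class(tab) <- c("taxa_table", setdiff(class(tab), "taxa_table"))
  }
  validate_taxa_table(tab)
}

#' Generate negative-control samples
#'
#' Controls carry the spec's contaminant taxa at high prevalence (every
#' contaminant present in every control) and biological taxa at zero,
#' emulating sterile-water extraction controls processed alongside the
#' samples. With no contaminant taxa declared the controls are all-zero
#' rows.
#'
#' @param spec A [synth_spec()] with `n_controls >= 1`.
#' @return A `taxa_table` of control samples over the full taxon universe.
#' @export
generate_controls <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  if (spec$n_controls < 1) stopf("spec declares no control samples")
  tx <- synth_taxa(spec)
  all_taxa <- c(tx$dominant, tx$core, unlist(tx$acc), spec$contaminant_taxa)
  m <- matrix(0L, nrow = spec$n_controls, ncol = length(all_taxa),
              dimnames = list(NULL, all_taxa))
  if (length(spec$contaminant_taxa) > 0) {
    m[, spec$contaminant_taxa] <- with_seed(derive_seed(spec$seed, 101), {
      # high, variable contaminant loads; +1 guarantees presence
      matrix(rpois(spec$n_controls * length(spec$contaminant_taxa), 500) + 1L,
             nrow = spec$n_controls)
    })
  }
  taxa_table(
    m,
    group = rep("control", spec$n_controls),
    is_control = rep(TRUE, spec$n_controls),
    sample_ids = sprintf("control_%02d", seq_len(spec$n_controls)),
    taxon_ids = all_taxa
  )
}

#' @importFrom stats rpois
NULL
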