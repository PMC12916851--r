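#' Build a taxa table from a count matrix and sample metadata
#'
#' A taxa table is the central data structure of the pipeline: a tibble with
#' one row per sample, the metadata columns `sample_id`, `group` and
#' `is_control`, and one non-negative integer count column per taxon
#' (genus). All downstream functions take this tibble as their first
#' argument.
#'
#' @param counts Numeric matrix of non-negative integer read counts, rows =
#'   samples, columns = taxa. Row and column names are used as sample and
#'   taxon identifiers when `sample_ids`/`taxon_ids` are not given.
#' @param group Character vector of group labels, one per sample.
#' @param is_control Logical vector flagging negative-control samples.
#' @param sample_ids,taxon_ids Optional identifier vectors overriding the
#'   matrix dimnames. Must be unique.
#'
#' @return A tibble of class `taxa_table`.
#' @export
#' @examples
#' m <- matrix(c(5L, 0L, 3L, 2L), 2, 2,
#'             dimnames = list(c("s1", "s2"), c("gA", "gB")))
#' taxa_table(m, group = c("X", "Y"), is_control = c(FALSE, FALSE))
taxa_table <- function(counts, group, is_control = rep(FALSE, nrow(counts)),
                       sample_ids = rownames(counts),
                       taxon_ids = colnames(counts)) {
  counts <- as.matrix(counts)
  if (is.null(sample_ids)) sample_ids <- paste0("sample_", seq_len(nrow(counts)))
  if (is.null(taxon_ids)) taxon_ids <- paste0("taxon_", seq_len(ncol(counts)))
  if (anyDuplicated(taxon_ids)) {
    stopf("duplicate taxon_id: %s",
          paste(unique(taxon_ids[duplicated(taxon_ids)]), collapse = ", "))
  }
  tbl <- tibble(
    sample_id = as.character(sample_ids),
    group = as.character(group),
    is_control = as.logical(is_control)
  )
  cnt <- as_tibble(counts, .name_repair = "minimal")
  names(cnt) <- as.character(taxon_ids)
  out <- dplyr::bind_cols(tbl, cnt)
  class(out) <- c("taxa_table", class(out))
  validate_taxa_table(out)
}

#' Validate a taxa table
#'
#' Checks the structural invariants: metadata columns present, unique sample
#' and taxon identifiers, and non-negative integer counts.
#'
#' @param x A `taxa_table` (or a tibble with the same layout).
#' @return `x`, invisibly classed as `taxa_table`.
#' @export
validate_taxa_table <- function(x) {
  meta_cols <- c("sample_id", "group", "is_control")
  missing <- setdiff(meta_cols, names(x))
  if (length(missing) > 0) {
    stopf("taxa table is missing metadata column(s): %s",
          paste(missing, collapse = ", "))
  }
  if (anyDuplicated(x$sample_id)) {
    stopf("duplicate sample_id: %s",
          paste(unique(x$sample_id[duplicated(x$sample_id)]), collapse = ", "))
  }
  taxa <- setdiff(names(x), meta_cols)
  if (anyDuplicated(taxa)) {
    stopf("duplicate taxon_id: %s",
          paste(unique(taxa[duplicated(taxa)]), collapse = ", "))
  }
  for (tx in taxa) {
    v <- x[[tx]]
    if (!is.numeric(v)) stopf("counts for taxon '%s' are not numeric", tx)
    if (anyNA(v)) stopf("counts for taxon '%s' contain NA", tx)
    if (any(v < 0)) stopf("negative count for taxon '%s'", tx)
    if (any(abs(v - round(v)) > 1e-8)) {
      stopf("non-integer count for taxon '%s'", tx)
    }
  }
  if (!inherits(x, "taxa_table")) class(x) <- c("taxa_table", class(x))
  invisible(x)
}

taxon_names <- function(x) {
  setdiff(names(x), c("sample_id", "group", "is_control"))
}

# samples x taxa integer matrix with sample_id rownames
tt_counts <- function(x) {
  taxa <- taxon_names(x)
  m <- as.matrix(x[, taxa, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- x$sample_id
  m
}

tt_meta <- function(x) {
  as_tibble(x[, c("sample_id", "group", "is_control")])
}

#' Keep only biological (non-control) samples
#'
#' @param x A `taxa_table`.
#' @param group Optional group label to additionally filter on.
#' @return A `taxa_table` with control samples removed.
#' @export
biological_samples <- function(x, group = NULL) {
  out <- x[!x$is_control, , drop = FALSE]
  if (!is.null(group)) out <- out[out$group %in% group, , drop = FALSE]
  class(out) <- c("taxa_table", setdiff(class(out), "taxa_table"))
  out
}

#' Read a taxa table and its sample metadata from TSV files
#'
#' The count file is taxon-major (first column `taxon_id`, one column per
#' sample, integer cells, tab-separated) and is transposed on read to the
#' samples-by-taxa layout. The metadata file has columns `sample_id`,
#' `group`, `is_control`.
#'
#' @param path Path to the count TSV.
#' @param metadata_path Path to the metadata TSV.
#' @return A validated `taxa_table`.
#' @export
read_taxa_table <- function(path, metadata_path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(
    taxon_id = readr::col_character(),
    .default = readr::col_double()
  ), progress = FALSE)
  if (!"taxon_id" %in% names(raw)) {
    stopf("count file '%s' has no `taxon_id` column", path)
  }
  meta <- readr::read_tsv(metadata_path, col_types = readr::cols(
    sample_id = readr::col_character(),
    group = readr::col_character(),
    is_control = readr::col_logical()
  ), progress = FALSE)
  samples <- setdiff(names(raw), "taxon_id")
  unknown <- setdiff(samples, meta$sample_id)
  if (length(unknown) > 0) {
    stopf("metadata file '%s' is missing sample(s): %s", metadata_path,
          paste(unknown, collapse = ", "))
  }
  extra <- setdiff(meta$sample_id, samples)
  if (length(extra) > 0) {
    stopf("metadata lists sample(s) absent from the count file: %s",
          paste(extra, collapse = ", "))
  }
  m <- t(as.matrix(raw[, samples, drop = FALSE]))
  colnames(m) <- raw$taxon_id
  meta <- meta[match(samples, meta$sample_id), ]
  taxa_table(m, group = meta$group, is_control = meta$is_control,
             sample_ids = samples, taxon_ids = raw$taxon_id)
}

#' Write a taxa table (and optionally its metadata) to TSV
#'
#' Inverse of [read_taxa_table()]: counts are written taxon-major with a
#' leading `taxon_id` column.
#'
#' @param x A `taxa_table`.
#' @param path Output path for the count TSV.
#' @param metadata_path Optional output path for the metadata TSV.
#' @return `x`, invisibly.
#' @export
write_taxa_table <- function(x, path, metadata_path = NULL) {
  validate_taxa_table(x)
  m <- t(tt_counts(x))
  out <- dplyr::bind_cols(
    tibble(taxon_id = rownames(m)),
    as_tibble(m, .name_repair = "minimal")
  )
  readr::write_tsv(out, path, progress = FALSE)
  if (!is.null(metadata_path)) {
    readr::write_tsv(tt_meta(x), metadata_path, progress = FALSE)
  }
  invisible(x)
}

#' @export
print.taxa_table <- function(x, ...) {
  nb <- sum(!x$is_control)
  cat(sprintf("<taxa_table> %d samples (%d biological, %d controls), %d taxa\n",
              nrow(x), nb, nrow(x) - nb, length(taxon_names(x))))
  NextMethod()
}
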