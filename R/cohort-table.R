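#' Health-status vocabulary
#'
#' Closed set of per-sample status labels accepted by [cohort_table()]:
#' healthy controls, pooled IBS, the Rome subtypes, and the paired
#' before/after labels of the rifaximin treatment arm.
#'
#' @export
status_levels <- c("HC", "IBS", "IBS-C", "IBS-D", "IBS-M", "IBS-U",
                   "IBSD_before", "IBSD_after")

#' Construct a per-cohort abundance table
#'
#' The central container of the pipeline: one cohort's species-by-sample
#' abundance matrix plus per-sample metadata. The matrix is always oriented
#' species in rows, samples in columns; a `scale` tag records whether entries
#' are read counts or relative abundances (proportions summing to 1 per
#' sample).
#'
#' @param counts Non-negative numeric matrix, species x samples, with unique
#'   rownames (species ids) and colnames (sample ids).
#' @param metadata Data frame with one row per sample: a `sample_id` column
#'   matching `colnames(counts)` and a `status` column drawn from
#'   [status_levels]. Any further columns are carried along as covariates;
#'   missing covariate values are explicit `NA`.
#' @param cohort_id Single string identifying the cohort.
#' @param scale `"counts"` (default) or `"proportions"`.
#' @return An object of class `cohort_table`.
#' @export
cohort_table <- function(counts, metadata, cohort_id, scale = c("counts", "proportions")) {
  scale <- match.arg(scale)
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  metadata <- tibble::as_tibble(metadata)

  if (!is.character(cohort_id) || length(cohort_id) != 1L)
    abort("`cohort_id` must be a single string")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    abort("`counts` must have species rownames and sample colnames")
  if (anyDuplicated(rownames(counts)))
    abort(sprintf("duplicated species ids: %s",
                  paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", ")))
  if (anyDuplicated(colnames(counts)))
    abort(sprintf("duplicated sample ids: %s",
                  paste(unique(colnames(counts)[duplicated(colnames(counts))]), collapse = ", ")))
  if (any(counts < 0)) abort("`counts` has negative entries")
  if (!"sample_id" %in% names(metadata)) abort("metadata needs a `sample_id` column")
  if (!"status" %in% names(metadata)) abort("metadata needs a `status` column")

  orphans_tab <- setdiff(colnames(counts), metadata$sample_id)
  orphans_meta <- setdiff(metadata$sample_id, colnames(counts))
  if (length(orphans_tab) || length(orphans_meta)) {
    abort(sprintf(
      "sample sets differ between table and metadata (table-only: %s; metadata-only: %s)",
      paste(orphans_tab, collapse = ", ") %|empty|% "none",
      paste(orphans_meta, collapse = ", ") %|empty|% "none"))
  }
  bad_status <- setdiff(unique(metadata$status), status_levels)
  if (length(bad_status))
    abort(sprintf("unknown status labels: %s", paste(bad_status, collapse = ", ")))

  # align metadata rows to column order
  metadata <- metadata[match(colnames(counts), metadata$sample_id), , drop = FALSE]

  if (scale == "proportions") {
    cs <- colSums(counts)
    if (any(abs(cs - 1) > 1e-8))
      abort(sprintf("proportions-scale columns must sum to 1; offenders: %s",
                    paste(colnames(counts)[abs(cs - 1) > 1e-8], collapse = ", ")))
  }

  structure(
    list(cohort_id = cohort_id, counts = counts, metadata = metadata, scale = scale),
    class = "cohort_table")
}

`%|empty|%` <- function(x, alt) if (nzchar(x)) x else alt

#' @export
print.cohort_table <- function(x, ...) {
  cat(sprintf("<cohort_table> %s: %d species x %d samples (%s)\n",
              x$cohort_id, nrow(x$counts), ncol(x$counts), x$scale))
  st <- table(x$metadata$status)
  cat("  status:", paste(sprintf("%s=%d", names(st), st), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.cohort_table <- function(x) dim(x$counts)

#' Read one cohort from TSV files
#'
#' The abundance TSV carries feature ids in its first column and sample ids in
#' the header; the metadata TSV is keyed by `sample_id`. Unknown metadata
#' columns are preserved as covariates.
#'
#' @param table_path Path to the species x samples abundance TSV.
#' @param metadata_path Path to the per-sample metadata TSV.
#' @param cohort_id Cohort identifier; defaults to the table file stem.
#' @param scale Scale tag of the abundance values, `"counts"` or
#'   `"proportions"`.
#' @return A [cohort_table()].
#' @export
read_cohort <- function(table_path, metadata_path, cohort_id = NULL,
                        scale = c("counts", "proportions")) {
  scale <- match.arg(scale)
  header <- strsplit(readLines(table_path, n = 1L), "\t", fixed = TRUE)[[1]]
  sample_ids <- header[-1]
  if (anyDuplicated(sample_ids))
    abort(sprintf("duplicated sample id in header: %s",
                  paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", ")))
  tab <- readr::read_tsv(table_path, show_col_types = FALSE, progress = FALSE)
  counts <- as.matrix(tab[, -1, drop = FALSE])
  rownames(counts) <- as.character(tab[[1]])
  colnames(counts) <- sample_ids
  meta <- readr::read_tsv(metadata_path, show_col_types = FALSE, progress = FALSE)
  cohort_table(counts, meta,
               cohort_id = cohort_id %||% sub("\\.[^.]*$", "", basename(table_path)),
               scale = scale)
}

#' Write one cohort to TSV files
#'
#' Emits the canonical orientation (species rows, sample columns) and the
#' metadata keyed by `sample_id`; [read_cohort()] round-trips the result
#' exactly.
#'
#' @param table A [cohort_table()].
#' @param table_path,metadata_path Output TSV paths.
#' @return `table`, invisibly.
#' @export
write_cohort <- function(table, table_path, metadata_path) {
  stopifnot(inherits(table, "cohort_table"))
  out <- tibble::as_tibble(table$counts, .name_repair = "minimal")
  out <- dplyr::bind_cols(tibble::tibble(species_id = rownames(table$counts)), out)
  readr::write_tsv(out, table_path, progress = FALSE)
  readr::write_tsv(table$metadata, metadata_path, progress = FALSE)
  invisible(table)
}

#' Drop shallow samples
#'
#' Removes samples whose total read count falls below `min_reads`, the
#' depth-exclusion rule applied before any analysis (2000 reads for 16S
#' libraries, 0.5 million for shotgun libraries). Acts on column sums of the
#' annotated count table and is idempotent.
#'
#' @param table A counts-scale [cohort_table()].
#' @param min_reads Minimum per-sample read count to retain.
#' @return The filtered [cohort_table()] (possibly with zero samples).
#' @export
filter_samples <- function(table, min_reads) {
  stopifnot(inherits(table, "cohort_table"))
  if (table$scale != "counts")
    abort("filter_samples needs counts-scale input; proportions carry no depth")
  keep <- colSums(table$counts) >= min_reads
  if (!any(keep)) ibs_log("WARN", sprintf(
    "all %d samples of %s below min_reads=%g", ncol(table$counts), table$cohort_id, min_reads))
  out <- table
  out$counts <- table$counts[, keep, drop = FALSE]
  out$metadata <- table$metadata[keep, , drop = FALSE]
  out
}

#' Read a bacterial phenotype annotation table
#'
#' Static per-species annotation (habitat, aerotolerance, notable
#' characteristic, bacteremia reports) consumed for network interpretation,
#' never computed. Values must come from the supplied closed vocabularies.
#'
#' @param path TSV with columns `species_id`, `habitat`, `aerotolerance`,
#'   `characteristic`, `bacteremia_reported`.
#' @param species_ids Optional character vector of known species; annotation
#'   keys must be a subset.
#' @param habitat_levels,aerotolerance_levels Closed vocabularies.
#' @return A tibble.
#' @export
read_annotation <- function(path, species_ids = NULL,
                            habitat_levels = c("gut", "oral cavity", "vagina", "skin",
                                               "respiratory tract", "environment", "unknown"),
                            aerotolerance_levels = c("obligate anaerobe", "facultative anaerobe",
                                                     "aerotolerant anaerobe", "aerobe", "unknown")) {
  ann <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("species_id", "habitat", "aerotolerance", "characteristic", "bacteremia_reported")
  missing_cols <- setdiff(need, names(ann))
  if (length(missing_cols))
    abort(sprintf("annotation missing columns: %s", paste(missing_cols, collapse = ", ")))
  if (!is.null(species_ids)) {
    extra <- setdiff(ann$species_id, species_ids)
    if (length(extra))
      abort(sprintf("annotation keys not among known species: %s", paste(extra, collapse = ", ")))
  }
  bad_hab <- setdiff(unique(ann$habitat), habitat_levels)
  bad_aer <- setdiff(unique(ann$aerotolerance), aerotolerance_levels)
  if (length(bad_hab) || length(bad_aer))
    abort(sprintf("annotation values outside vocabulary: %s",
                  paste(c(bad_hab, bad_aer), collapse = ", ")))
  ann$bacteremia_reported <- as.logical(ann$bacteremia_reported)
  ann
}

# group column matrix for a contrast; errors on absent labels
contrast_columns <- function(table, contrast) {
  if (length(contrast) != 2L) abort("`contrast` must be c(control_label, case_label)")
  st <- table$metadata$status
  for (lab in contrast) {
    if (!any(st == lab))
      abort(sprintf("contrast label '%s' absent from cohort %s", lab, table$cohort_id))
  }
  list(control = which(st == contrast[1]), case = which(st == contrast[2]))
}
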