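#' Sample dissimilarity matrices
#'
#' `bray_curtis()` computes the abundance-weighted Bray-Curtis dissimilarity
#' `d(x, y) = sum |x_i - y_i| / sum (x_i + y_i)` on relative abundances;
#' `binary_jaccard()` computes the presence/absence Jaccard dissimilarity
#' `1 - |A n B| / |A u B|`. Both delegate to [vegan::vegdist()].
#'
#' @param table A [cohort_table()]; `bray_curtis()` requires proportions
#'   scale (use [relative_abundance()] first).
#' @return A `dist_matrix`: list with `values` (symmetric matrix, zero
#'   diagonal, entries in `[0, 1]`), `sample_ids`, `metric`.
#' @export
bray_curtis <- function(table) {
  stopifnot(inherits(table, "cohort_table"))
  if (table$scale != "proportions")
    abort("bray_curtis expects proportions scale; apply relative_abundance() first")
  dist_matrix_from(table, "bray_curtis",
                   vegan::vegdist(t(table$counts), method = "bray"))
}

#' @rdname bray_curtis
#' @export
binary_jaccard <- function(table) {
  stopifnot(inherits(table, "cohort_table"))
  empty <- colSums(table$counts > 0) == 0
  if (sum(empty) >= 2)
    abort(sprintf("presence sets undefined: empty samples %s",
                  paste(colnames(table$counts)[empty], collapse = ", ")))
  dist_matrix_from(table, "binary_jaccard",
                   vegan::vegdist(t(table$counts), method = "jaccard", binary = TRUE))
}

dist_matrix_from <- function(table, metric, d) {
  vals <- as.matrix(d)
  if (any(!is.finite(vals)))
    abort(sprintf("%s undefined for some sample pair (all-zero samples?)", metric))
  structure(list(values = vals, sample_ids = colnames(table$counts), metric = metric),
            class = "dist_matrix")
}

#' @export
print.dist_matrix <- function(x, ...) {
  cat(sprintf("<dist_matrix> %s over %d samples\n", x$metric, length(x$sample_ids)))
  invisible(x)
}

#' PERMANOVA with marginal sums of squares
#'
#' Covariate-adjusted permutational multivariate ANOVA on a dissimilarity
#' matrix, testing every term given all others (marginal / type-III-like
#' sums of squares via full-vs-reduced model comparison), as implemented by
#' [vegan::adonis2()] with `by = "margin"`. Permutations shuffle observations
#' freely; samples with `NA` in any model term are dropped and the count
#' logged.
#'
#' @param dist A `dist_matrix` from [bray_curtis()] or [binary_jaccard()].
#' @param metadata Data frame with `sample_id` and the model terms.
#' @param terms Character vector of metadata columns (categorical terms are
#'   dummy-coded, numeric terms enter as-is).
#' @param n_permutations Number of permutations (default 999).
#' @param seed Integer seed for the permutation stream.
#' @return A tibble with one row per term plus `Residual` and `Total`:
#'   `term`, `df`, `ss`, `r2`, `f`, `p`; attributes record the formula,
#'   permutation count, seed, and dropped-sample count.
#' @export
permanova_marginal <- function(dist, metadata, terms, n_permutations = 999, seed = 1L) {
  stopifnot(inherits(dist, "dist_matrix"))
  missing_terms <- setdiff(terms, names(metadata))
  if (length(missing_terms))
    abort(sprintf("terms absent from metadata: %s", paste(missing_terms, collapse = ", ")))
  metadata <- as.data.frame(metadata)
  rownames(metadata) <- metadata$sample_id
  metadata <- metadata[dist$sample_ids, , drop = FALSE]

  keep <- complete.cases(metadata[, terms, drop = FALSE])
  n_dropped <- sum(!keep)
  if (n_dropped > 0)
    ibs_log("INFO", sprintf("permanova: dropping %d samples with NA in model terms", n_dropped))
  md <- metadata[keep, , drop = FALSE]
  md[] <- lapply(md, function(col) if (is.character(col)) factor(col) else col)
  dm <- as.dist(dist$values[keep, keep])

  fml <- as.formula(paste("dm ~", paste(terms, collapse = " + ")))
  mm <- stats::model.matrix(as.formula(paste("~", paste(terms, collapse = " + "))), data = md)
  qr_mm <- qr(mm)
  if (qr_mm$rank < ncol(mm)) {
    aliased <- colnames(mm)[setdiff(seq_len(ncol(mm)), qr_mm$pivot[seq_len(qr_mm$rank)])]
    abort(sprintf("rank-deficient design; aliased terms: %s", paste(aliased, collapse = ", ")))
  }

  set.seed(seed)
  fit <- vegan::adonis2(fml, data = md, permutations = n_permutations,
                        by = "margin")
  out <- tibble::tibble(
    term = rownames(fit), df = fit$Df, ss = fit$SumOfSqs,
    r2 = fit$R2, f = fit$F, p = fit$`Pr(>F)`)
  attr(out, "formula") <- paste("dist ~", paste(terms, collapse = " + "))
  attr(out, "n_permutations") <- n_permutations
  attr(out, "seed") <- seed
  attr(out, "n_dropped") <- n_dropped
  attr(out, "metric") <- dist$metric
  out
}

#' Export a PERMANOVA table to TSV
#'
#' @param result Tibble from [permanova_marginal()].
#' @param path Output TSV path.
#' @export
write_permanova <- function(result, path) {
  readr::write_tsv(result, path, progress = FALSE)
  invisible(result)
}
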