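#' Default 10-level FFQ frequency weights
#'
#' Monotone servings-per-week-style weights for the ten consumption-frequency
#' categories of a semi-quantitative food frequency questionnaire. Because
#' the downstream screen is Spearman (rank-based), results depend only on the
#' monotonicity of this map, not on the specific values; the map is fully
#' configurable.
#'
#' @return Named numeric vector, names `"1"` (never) through `"10"`.
#' @export
default_ffq_weights <- function() {
  setNames(c(0, 0.1, 0.5, 1, 2, 3.5, 5.5, 7, 10, 14), as.character(1:10))
}

#' Weight categorical FFQ responses
#'
#' Maps each ordinal frequency category to its numeric weight. `NA` responses
#' become 0 (with a logged count); categories outside the weight map are an
#' error.
#'
#' @param raw Data frame: `sample_id` column plus one column per food item
#'   holding category levels (matching `names(weights)`) or `NA`.
#' @param weights Named numeric category -> weight map (default
#'   [default_ffq_weights()]).
#' @return Tibble: `sample_id` plus numeric weighted-intake columns.
#' @export
weight_ffq <- function(raw, weights = default_ffq_weights()) {
  raw <- tibble::as_tibble(raw)
  if (!"sample_id" %in% names(raw)) abort("`raw` needs a sample_id column")
  items <- setdiff(names(raw), "sample_id")
  n_na <- 0L
  out <- raw
  for (it in items) {
    v <- as.character(raw[[it]])
    unknown <- setdiff(unique(v[!is.na(v)]), names(weights))
    if (length(unknown))
      abort(sprintf("unknown FFQ category in '%s': %s", it, paste(unknown, collapse = ", ")))
    n_na <- n_na + sum(is.na(v))
    if (all(is.na(v))) warn(sprintf("item '%s' is all-NA: weighted to zero", it))
    w <- unname(weights[v])
    w[is.na(w)] <- 0
    out[[it]] <- w
  }
  if (n_na > 0) ibs_log("INFO", sprintf("weight_ffq: %d NA responses set to 0", n_na))
  out
}

#' Diet-species Spearman association screen
#'
#' Correlates weighted food intakes with the relative abundance of signature
#' species over the samples both matrices share (optionally restricted to one
#' health-status group), using Spearman's rho with average ranks and a
#' t-approximation p-value, then applies one BH correction over the whole
#' item x species grid (a single testing family). Constant vectors give an
#' undefined rho, marked `NA` and excluded from the family.
#'
#' @param diet Tibble from [weight_ffq()] (or any `sample_id` + numeric item
#'   columns).
#' @param abundance A [cohort_table()] restricted to the species of interest.
#' @param subset Optional status label; only samples with that status enter.
#' @return Tibble of class `association_grid`: `item_id`, `species_id`,
#'   `rho`, `p`, `q`.
#' @export
diet_species_correlations <- function(diet, abundance, subset = NULL) {
  stopifnot(inherits(abundance, "cohort_table"))
  tab <- if (abundance$scale == "counts") relative_abundance(abundance) else abundance
  samp <- tab$metadata$sample_id
  if (!is.null(subset)) samp <- samp[tab$metadata$status == subset]
  shared <- intersect(diet$sample_id, samp)
  if (length(shared) < 10) abort("fewer than 10 overlapping samples")
  items <- setdiff(names(diet), "sample_id")
  dm <- as.matrix(diet[match(shared, diet$sample_id), items, drop = FALSE])
  am <- t(tab$counts[, shared, drop = FALSE])
  grid <- tidyr::expand_grid(item_id = items, species_id = colnames(am))
  res <- purrr::map2(grid$item_id, grid$species_id, function(it, sp) {
    spearman_test(dm[, it], am[, sp])
  })
  grid$rho <- purrr::map_dbl(res, "rho")
  grid$p <- purrr::map_dbl(res, "p")
  grid$q <- bh_fdr(grid$p)
  class(grid) <- c("association_grid", class(grid))
  attr(grid, "n_samples") <- length(shared)
  grid
}

#' Cluster food items by their species-association profiles
#'
#' Hierarchical clustering (Euclidean distance, complete linkage) of the item
#' rows of the association grid — each item represented by its vector of rho
#' across species. Undefined rho values enter as 0 (logged); all-NA items are
#' excluded with a warning.
#'
#' @param grid An `association_grid` from [diet_species_correlations()].
#' @param k Number of clusters to cut.
#' @return List: `clusters` tibble (`item_id`, `cluster_id`), `linkage`
#'   (the [stats::hclust()] object), `merges` tibble (merge order and
#'   heights).
#' @export
cluster_foods <- function(grid, k = 3) {
  wide <- tidyr::pivot_wider(grid[, c("item_id", "species_id", "rho")],
                             names_from = "species_id", values_from = "rho")
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$item_id
  all_na <- rowSums(!is.na(m)) == 0
  if (any(all_na)) {
    warn(sprintf("items with no defined rho excluded: %s",
                 paste(rownames(m)[all_na], collapse = ", ")))
    m <- m[!all_na, , drop = FALSE]
  }
  if (nrow(m) < 2) abort("need >= 2 items with defined associations")
  n_na <- sum(is.na(m))
  if (n_na > 0) {
    ibs_log("INFO", sprintf("cluster_foods: %d undefined rho set to 0", n_na))
    m[is.na(m)] <- 0
  }
  hc <- hclust(dist(m, method = "euclidean"), method = "complete")
  k <- min(k, nrow(m))
  cl <- cutree(hc, k = k)
  list(clusters = tibble::tibble(item_id = names(cl), cluster_id = unname(cl)),
       linkage = hc,
       merges = tibble::tibble(step = seq_len(nrow(hc$merge)),
                               left = hc$merge[, 1], right = hc$merge[, 2],
                               height = hc$height))
}

#' Compare alcohol consumption between status groups
#'
#' Continuous intake values get a two-sided Wilcoxon rank-sum test; a binary
#' drinking flag gets a two-sided Fisher's exact test on the 2x2 table.
#'
#' @param values Numeric intake vector, or logical/0-1 drinking flag.
#' @param status Status labels, two groups.
#' @param binary Force the binary treatment; by default inferred from
#'   `values` having at most two distinct non-NA levels in \{0, 1\}.
#' @return One-row tibble: `test`, `p`, plus `odds_ratio` for the Fisher
#'   branch.
#' @export
alcohol_contrast <- function(values, status, binary = NULL) {
  ok <- !is.na(values) & !is.na(status)
  values <- values[ok]; status <- as.character(status)[ok]
  groups <- unique(status)
  if (length(groups) != 2) abort("exactly two status groups required")
  if (!all(table(status) > 0)) abort("empty status group")
  if (is.null(binary))
    binary <- is.logical(values) || all(values %in% c(0, 1))
  if (binary) {
    ft <- fisher.test(table(factor(status, levels = groups),
                            factor(as.integer(values), levels = c(0, 1))))
    tibble::tibble(test = "fisher", p = ft$p.value, odds_ratio = unname(ft$estimate))
  } else {
    wt <- suppressWarnings(wilcox.test(values[status == groups[1]],
                                       values[status == groups[2]]))
    tibble::tibble(test = "wilcoxon", p = wt$p.value, odds_ratio = NA_real_)
  }
}

#' Export a diet association grid (and optional linkage) to TSV
#'
#' @param grid An `association_grid`.
#' @param path Output TSV path.
#' @param clusters Optional result of [cluster_foods()] joined onto items.
#' @export
write_associations <- function(grid, path, clusters = NULL) {
  out <- grid
  if (!is.null(clusters))
    out <- dplyr::left_join(out, clusters$clusters, by = "item_id")
  readr::write_tsv(out, path, progress = FALSE)
  invisible(grid)
}
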