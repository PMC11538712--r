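#' Hedges' G standardized mean difference
#'
#' Bias-corrected standardized mean difference between a control and a case
#' group. With group sizes n1, n2 and sample variances s1^2, s2^2:
#' `s_p^2 = ((n1-1)s1^2 + (n2-1)s2^2) / (n1+n2-2)`,
#' `d = (mean(control) - mean(case)) / s_p`, small-sample correction
#' `J = 1 - 3/(4(n1+n2-2) - 1)`, `g = J d`, and sampling variance
#' `var_g = (n1+n2)/(n1 n2) + g^2 / (2(n1+n2))`. The sign convention is fixed
#' pipeline-wide: positive g means higher abundance in controls, i.e. the
#' feature is depleted in cases.
#'
#' @param control_values,case_values Numeric vectors, each of length >= 2.
#' @return A list with elements `g` and `var_g`; both `NA` (undefined-effect
#'   marker) when the pooled standard deviation is zero.
#' @export
#' @examples
#' hedges_g(c(2, 4, 6, 8), c(1, 3, 5, 7))
hedges_g <- function(control_values, case_values) {
  n1 <- length(control_values); n2 <- length(case_values)
  if (n1 < 2 || n2 < 2) abort("both groups need length >= 2")
  sp2 <- ((n1 - 1) * var(control_values) + (n2 - 1) * var(case_values)) / (n1 + n2 - 2)
  if (sp2 == 0) {
    ibs_log("WARN", "zero pooled SD: undefined effect")
    return(list(g = NA_real_, var_g = NA_real_))
  }
  d <- (mean(control_values) - mean(case_values)) / sqrt(sp2)
  J <- 1 - 3 / (4 * (n1 + n2 - 2) - 1)
  g <- J * d
  list(g = g, var_g = (n1 + n2) / (n1 * n2) + g^2 / (2 * (n1 + n2)))
}

# row-wise Hedges' g for a species x samples matrix split into two groups
hedges_g_rows <- function(mat_control, mat_case) {
  n1 <- ncol(mat_control); n2 <- ncol(mat_case)
  m1 <- rowMeans(mat_control); m2 <- rowMeans(mat_case)
  v1 <- rowSums((mat_control - m1)^2) / (n1 - 1)
  v2 <- rowSums((mat_case - m2)^2) / (n2 - 1)
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  J <- 1 - 3 / (4 * (n1 + n2 - 2) - 1)
  g <- ifelse(sp2 > 0, J * (m1 - m2) / sqrt(sp2), NA_real_)
  tibble::tibble(
    g = g,
    var_g = ifelse(is.na(g), NA_real_, (n1 + n2) / (n1 * n2) + g^2 / (2 * (n1 + n2))))
}

#' Per-cohort effect sizes for every species
#'
#' Computes Hedges' G between the two contrast groups for each species of one
#' cohort, on relative abundance (the default analysis scale) or on
#' CLR-transformed counts (the concordance-check scale). Species never
#' observed in the cohort are flagged `detected = FALSE` and carry no effect.
#'
#' @param table A [cohort_table()].
#' @param contrast Length-2 character vector `c(control_label, case_label)`;
#'   positive g then means depleted in the case group.
#' @param scale `"proportions"` or `"clr"`.
#' @param pseudocount CLR pseudocount, used only when `scale = "clr"`.
#' @return A tibble with one row per species: `species_id`, `cohort_id`, `g`,
#'   `var_g`, `n_control`, `n_case`, `detected`.
#' @export
cohort_effect_sizes <- function(table, contrast = c("HC", "IBS"),
                                scale = c("proportions", "clr"), pseudocount = 1) {
  stopifnot(inherits(table, "cohort_table"))
  scale <- match.arg(scale)
  idx <- contrast_columns(table, contrast)
  if (length(idx$control) < 2 || length(idx$case) < 2)
    abort("both contrast groups need >= 2 samples")
  detected <- rowSums(table$counts) > 0
  vals <- switch(scale,
    proportions = {
      tab <- if (table$scale == "counts") relative_abundance(table) else table
      tab$counts
    },
    clr = unclass(clr_transform(table, pseudocount)))
  es <- hedges_g_rows(vals[, idx$control, drop = FALSE], vals[, idx$case, drop = FALSE])
  out <- tibble::tibble(
    species_id = rownames(table$counts),
    cohort_id = table$cohort_id,
    g = ifelse(detected, es$g, NA_real_),
    var_g = ifelse(detected, es$var_g, NA_real_),
    n_control = length(idx$control),
    n_case = length(idx$case),
    detected = detected)
  n_undef <- sum(detected & is.na(out$g))
  if (n_undef > 0)
    ibs_log("WARN", sprintf("%d detected species with zero pooled SD in %s",
                            n_undef, table$cohort_id))
  out
}

#' Per-species Wilcoxon rank-sum tests
#'
#' Two-sided Wilcoxon rank-sum test of abundance between the contrast groups
#' for every detected species (exact distribution for small untied groups,
#' normal approximation with tie and continuity correction otherwise).
#'
#' @inheritParams cohort_effect_sizes
#' @return A tibble: `species_id`, `cohort_id`, `p_wilcoxon` (`NA` for
#'   undetected species).
#' @export
wilcoxon_per_species <- function(table, contrast = c("HC", "IBS")) {
  stopifnot(inherits(table, "cohort_table"))
  idx <- contrast_columns(table, contrast)
  if (length(idx$control) == 0 || length(idx$case) == 0) abort("empty contrast group")
  tab <- if (table$scale == "counts") relative_abundance(table) else table
  detected <- rowSums(table$counts) > 0
  p <- rep(NA_real_, nrow(tab$counts))
  for (i in which(detected)) {
    p[i] <- suppressWarnings(
      wilcox.test(tab$counts[i, idx$control], tab$counts[i, idx$case],
                  alternative = "two.sided")$p.value)
    # fully tied groups have zero rank variance; no evidence against the null
    if (is.nan(p[i])) p[i] <- 1
  }
  tibble::tibble(species_id = rownames(tab$counts), cohort_id = table$cohort_id,
                 p_wilcoxon = p)
}

# Spearman rho with average ranks plus t-approximation p, used by the
# concordance checks and the diet screen
spearman_test <- function(x, y) {
  ok <- complete.cases(x, y)
  n <- sum(ok)
  if (n < 3) return(list(rho = NA_real_, p = NA_real_, n = n))
  if (sd(x[ok]) == 0 || sd(y[ok]) == 0) return(list(rho = NA_real_, p = NA_real_, n = n))
  rho <- cor(x[ok], y[ok], method = "spearman")
  if (abs(rho) >= 1) return(list(rho = rho, p = 0, n = n))
  tval <- rho * sqrt((n - 2) / (1 - rho^2))
  list(rho = rho, p = 2 * pt(-abs(tval), df = n - 2), n = n)
}

#' Concordance of two effect-size sets
#'
#' Spearman correlation of Hedges' G between two effect-size tables over the
#' species (and cohorts, when present in both) they share — e.g. relative
#' abundance vs CLR scale for the same cohorts.
#'
#' @param records_a,records_b Tibbles as returned by [cohort_effect_sizes()]
#'   (only `species_id`, optional `cohort_id`, and `g` are used).
#' @return A one-row tibble: `rho`, `p`, `n_shared`.
#' @export
effect_size_concordance <- function(records_a, records_b) {
  by <- intersect(c("species_id", "cohort_id"), intersect(names(records_a), names(records_b)))
  joined <- dplyr::inner_join(
    dplyr::select(records_a, dplyr::all_of(by), g_a = "g"),
    dplyr::select(records_b, dplyr::all_of(by), g_b = "g"),
    by = by)
  joined <- joined[complete.cases(joined$g_a, joined$g_b), , drop = FALSE]
  if (nrow(joined) < 3) abort("fewer than 3 shared species with defined g")
  st <- spearman_test(joined$g_a, joined$g_b)
  tibble::tibble(rho = st$rho, p = st$p, n_shared = st$n)
}

#' Export per-cohort effect sizes to TSV
#'
#' @param records Combined effect-size tibble (optionally joined with
#'   [wilcoxon_per_species()] output).
#' @param path Output TSV path.
#' @export
write_effects <- function(records, path) {
  readr::write_tsv(records, path, progress = FALSE)
  invisible(records)
}
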