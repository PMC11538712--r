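#' Signature-selection configuration
#'
#' Thresholds of the discovery chain. Defaults follow the study design this
#' pipeline reproduces: an effect is called supporting when |G| exceeds 0.1
#' (the conventional "small effect" floor), a candidate needs support in at
#' least 7 of the 14 discovery cohorts with at most 3 conflicting cohorts, and
#' signatures are retained at joint FDR < 0.1 with p < 0.05.
#'
#' @param g_thresh Hedges' G magnitude defining support/conflict.
#' @param min_support Minimum number of supporting cohorts.
#' @param max_conflict Maximum number of opposing cohorts.
#' @param n_cohorts_expected Cohorts in the design (sanity bound only).
#' @param fdr_thresh BH FDR gate for signature retention.
#' @param p_thresh Raw p gate for signature retention.
#' @param proportional_support If `TRUE`, scale `min_support`/`max_conflict`
#'   by the fraction of cohorts in which the species was detected (alternative
#'   reading of the consistency rule; default keeps absolute counts).
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(g_thresh = 0.1, min_support = 7, max_conflict = 3,
                          n_cohorts_expected = 14, fdr_thresh = 0.1, p_thresh = 0.05,
                          proportional_support = FALSE) {
  if (g_thresh <= 0) abort("g_thresh must be positive")
  if (min_support + max_conflict > n_cohorts_expected)
    abort("min_support + max_conflict exceeds n_cohorts_expected")
  structure(list(g_thresh = g_thresh, min_support = min_support,
                 max_conflict = max_conflict, n_cohorts_expected = n_cohorts_expected,
                 fdr_thresh = fdr_thresh, p_thresh = p_thresh,
                 proportional_support = proportional_support),
            class = "filter_config")
}

#' Cross-cohort consistency filter
#'
#' First stage of signature discovery: a species is a depleted candidate when
#' its per-cohort Hedges' G exceeds `g_thresh` in at least `min_support`
#' cohorts and falls below `-g_thresh` in at most `max_conflict` cohorts; an
#' enriched candidate is the mirror image. Cohorts where the species is
#' undetected or its effect undefined count toward neither tally.
#'
#' @param records Effect-size tibble spanning all cohorts
#'   (rows from [cohort_effect_sizes()]).
#' @param cfg A [filter_config()].
#' @return A tibble of candidates: `species_id`, `candidate_direction`
#'   (`"depleted"` or `"enriched"`), `n_support`, `n_conflict`, `k_defined`.
#' @export
consistency_filter <- function(records, cfg = filter_config()) {
  defined <- records[!is.na(records$g), , drop = FALSE]
  if (length(unique(defined$cohort_id)) < cfg$min_support)
    abort("records span fewer cohorts than min_support")
  tallies <- defined |>
    dplyr::group_by(.data$species_id) |>
    dplyr::summarise(
      n_pos = sum(.data$g > cfg$g_thresh),
      n_neg = sum(.data$g < -cfg$g_thresh),
      k_defined = dplyr::n(), .groups = "drop")
  if (cfg$proportional_support) {
    sup <- ceiling(cfg$min_support * tallies$k_defined / cfg$n_cohorts_expected)
    con <- floor(cfg$max_conflict * tallies$k_defined / cfg$n_cohorts_expected)
  } else {
    sup <- cfg$min_support
    con <- cfg$max_conflict
  }
  depleted <- tallies$n_pos >= sup & tallies$n_neg <= con
  enriched <- tallies$n_neg >= sup & tallies$n_pos <= con
  dplyr::bind_rows(
    tibble::tibble(species_id = tallies$species_id[depleted],
                   candidate_direction = "depleted",
                   n_support = tallies$n_pos[depleted],
                   n_conflict = tallies$n_neg[depleted],
                   k_defined = tallies$k_defined[depleted]),
    tibble::tibble(species_id = tallies$species_id[enriched],
                   candidate_direction = "enriched",
                   n_support = tallies$n_neg[enriched],
                   n_conflict = tallies$n_pos[enriched],
                   k_defined = tallies$k_defined[enriched]))
}

#' Random-effects pooling of one species' per-cohort effects
#'
#' Pools k per-cohort Hedges' G values under the random-effects model
#' `g_i ~ N(mu, var_i + tau2)`. The DerSimonian-Laird (`"DL"`) estimator is
#' closed-form: with fixed-effect weights `w_i = 1/var_i`,
#' `Q = sum w_i (g_i - g_FE)^2` and
#' `tau2 = max(0, (Q - (k-1)) / (sum w - sum w^2 / sum w))`. The default
#' `"REML"` estimator iterates the restricted-likelihood fixed point from the
#' DL start (convergence `|d tau2| < 1e-10`, at most 100 iterations, DL
#' fallback with a warning on non-convergence). `mu_hat` uses weights
#' `1/(var_i + tau2)`; `I2 = max(0, (Q - (k-1))/Q) * 100` (0 when Q = 0).
#'
#' @param records Tibble with columns `g` and `var_g` (one row per cohort;
#'   `species_id`/`cohort_id` carried through when present).
#' @param method `"REML"` (default) or `"DL"`.
#' @return An object of class `rem_fit`; see [tidy.rem_fit()] and
#'   [glance.rem_fit()].
#' @export
random_effects_fit <- function(records, method = c("REML", "DL")) {
  method <- match.arg(method)
  records <- records[!is.na(records$g), , drop = FALSE]
  k <- nrow(records)
  if (k < 2) abort("random_effects_fit needs k >= 2 defined effects")
  y <- records$g; v <- records$var_g
  if (any(is.na(v) | v <= 0)) abort("all var_g must be positive")

  w <- 1 / v
  fe <- sum(w * y) / sum(w)
  Q <- sum(w * (y - fe)^2)
  C <- sum(w) - sum(w^2) / sum(w)
  tau2_dl <- max(0, (Q - (k - 1)) / C)

  converged <- TRUE
  if (method == "REML") {
    tau2 <- tau2_dl
    ok <- FALSE
    for (it in seq_len(100)) {
      wi <- 1 / (v + tau2)
      mu <- sum(wi * y) / sum(wi)
      tau2_new <- max(0, sum(wi^2 * ((y - mu)^2 - v)) / sum(wi^2) + 1 / sum(wi))
      if (abs(tau2_new - tau2) < 1e-10) { tau2 <- tau2_new; ok <- TRUE; break }
      tau2 <- tau2_new
    }
    if (!ok) {
      ibs_log("WARN", "REML did not converge in 100 iterations; falling back to DL")
      tau2 <- tau2_dl
      converged <- FALSE
    }
  } else {
    tau2 <- tau2_dl
  }

  ws <- 1 / (v + tau2)
  mu_hat <- sum(ws * y) / sum(ws)
  se <- sum(ws)^(-0.5)
  z <- mu_hat / se
  I2 <- if (Q > 0) max(0, (Q - (k - 1)) / Q) * 100 else 0

  structure(list(
    species_id = if ("species_id" %in% names(records)) records$species_id[1] else NA_character_,
    k = k, mu_hat = mu_hat, se = se, z = z, p = 2 * pnorm(-abs(z)),
    tau2 = tau2, Q = Q, I2 = I2, method = method, converged = converged,
    cohorts = tibble::as_tibble(records)),
    class = "rem_fit")
}

#' @export
print.rem_fit <- function(x, ...) {
  cat(sprintf("<rem_fit %s> k=%d mu=%.4f (se %.4f) p=%.3g tau2=%.4f I2=%.1f%%\n",
              x$species_id, x$k, x$mu_hat, x$se, x$p, x$tau2, x$I2))
  invisible(x)
}

#' Tidy a random-effects fit
#'
#' One row per pooled cohort with the forest-plot quantities: the cohort
#' effect, its 95% CI, and the random-effects weight.
#'
#' @param x An [random_effects_fit()] object.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy rem_fit
#' @export
tidy.rem_fit <- function(x, ...) {
  co <- x$cohorts
  ws <- 1 / (co$var_g + x$tau2)
  tibble::tibble(
    species_id = x$species_id,
    cohort_id = if ("cohort_id" %in% names(co)) co$cohort_id else as.character(seq_len(x$k)),
    g = co$g,
    ci_low = co$g - 1.959964 * sqrt(co$var_g),
    ci_high = co$g + 1.959964 * sqrt(co$var_g),
    weight = ws / sum(ws))
}

#' One-row summary of a random-effects fit
#'
#' @inheritParams tidy.rem_fit
#' @return A one-row tibble with the pooled estimate, its uncertainty, and
#'   heterogeneity statistics.
#' @method glance rem_fit
#' @export
glance.rem_fit <- function(x, ...) {
  tibble::tibble(species_id = x$species_id, k = x$k, mu_hat = x$mu_hat, se = x$se,
                 z = x$z, p = x$p, tau2 = x$tau2, Q = x$Q, I2 = x$I2,
                 method = x$method, converged = x$converged)
}

#' Heterogeneity class from I-squared
#'
#' `low` below 25%, `moderate` from 25 to below 50%, `high` at or above 50%
#' (boundaries assigned upward).
#'
#' @param I2 Numeric vector of I-squared percentages in `[0, 100]`.
#' @return Character vector.
#' @export
heterogeneity_class <- function(I2) {
  if (any(is.na(I2) | I2 < 0 | I2 > 100)) abort("I2 must lie in [0, 100]")
  dplyr::case_when(I2 < 25 ~ "low", I2 < 50 ~ "moderate", TRUE ~ "high")
}

#' Pool all candidate species with random-effects models
#'
#' Fits one random-effects model per candidate species over the cohorts where
#' its effect is defined (k may be below the cohort count and is reported),
#' then applies one joint BH correction across all candidates — depleted and
#' enriched together form a single testing family.
#'
#' @param records Effect-size tibble spanning all cohorts.
#' @param candidates Tibble from [consistency_filter()] (or any tibble with a
#'   `species_id` column).
#' @param method Passed to [random_effects_fit()].
#' @return A tibble with one row per candidate: `species_id`, `k`, `mu_hat`,
#'   `se`, `z`, `p`, `q`, `tau2`, `Q`, `I2`, `direction`,
#'   `heterogeneity_class`.
#' @export
meta_analyse <- function(records, candidates, method = c("REML", "DL")) {
  method <- match.arg(method)
  fits <- purrr::map(candidates$species_id, function(sp) {
    rec <- records[records$species_id == sp & !is.na(records$g), , drop = FALSE]
    random_effects_fit(rec, method = method)
  })
  out <- purrr::list_rbind(purrr::map(fits, glance))
  out$q <- bh_fdr(out$p)
  out$direction <- ifelse(out$mu_hat >= 0, "depleted", "enriched")
  out$heterogeneity_class <- heterogeneity_class(out$I2)
  dplyr::select(out, "species_id", "k", "mu_hat", "se", "z", "p", "q",
                "tau2", "Q", "I2", "direction", "heterogeneity_class")
}

#' Retain significant signature species
#'
#' Keeps candidates passing both gates: BH FDR below `fdr_thresh` and raw p
#' below `p_thresh` (the second gate removes FDR-passing species whose
#' individual evidence is weak).
#'
#' @param meta_results Tibble from [meta_analyse()].
#' @param cfg A [filter_config()].
#' @return The retained subset, unchanged columns.
#' @export
select_signatures <- function(meta_results, cfg = filter_config()) {
  meta_results[meta_results$q < cfg$fdr_thresh & meta_results$p < cfg$p_thresh, , drop = FALSE]
}

#' Validate pooled estimates against an external cohort
#'
#' Spearman correlation between the pooled effects (`mu_hat`) of the
#' signatures and the Hedges' G observed in an independent cohort, over the
#' species both carry.
#'
#' @param signatures Tibble from [meta_analyse()] / [select_signatures()].
#' @param external_records Effect-size tibble of the validation cohort.
#' @return A one-row tibble: `rho`, `p`, `n_shared`.
#' @export
validate_against_cohort <- function(signatures, external_records) {
  joined <- dplyr::inner_join(
    dplyr::select(signatures, "species_id", "mu_hat"),
    dplyr::select(external_records, "species_id", g_external = "g"),
    by = "species_id")
  joined <- joined[complete.cases(joined$mu_hat, joined$g_external), , drop = FALSE]
  if (nrow(joined) < 3) abort("fewer than 3 shared species with defined effects")
  st <- spearman_test(joined$mu_hat, joined$g_external)
  tibble::tibble(rho = st$rho, p = st$p, n_shared = st$n)
}

#' Export meta-analysis results to TSV
#'
#' @param meta_results Tibble from [meta_analyse()].
#' @param path Output TSV path.
#' @export
write_meta <- function(meta_results, path) {
  readr::write_tsv(meta_results, path, progress = FALSE)
  invisible(meta_results)
}
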