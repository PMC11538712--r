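#' Per-cohort covariate-adjusted function regression
#'
#' For one cohort and one functional category (pathways, CAZymes, or EC
#' numbers): ordinary least squares of each function's relative abundance on
#' health status plus the cohort's available covariates. The reported
#' coefficient is the case-vs-control difference on the relative-abundance
#' scale (untransformed by default; an arcsin-sqrt switch is available), with
#' its two-sided p-value; BH correction is applied within the cohort x
#' category family. Functions with zero variance in the cohort are
#' unevaluated (`NA` coefficient); samples with missing covariates are
#' dropped per model with a logged count.
#'
#' @param values Functions x samples numeric matrix of relative abundances,
#'   with function rownames and sample colnames.
#' @param metadata Data frame with `sample_id`, `status`, and any covariate
#'   columns, covering all samples.
#' @param covariates Character vector of metadata columns to adjust for
#'   (cohort-specific, possibly empty).
#' @param contrast `c(control_label, case_label)`; the coefficient is
#'   case minus control.
#' @param cohort_id Identifier recorded on the output rows.
#' @param transform `"none"` (default) or `"arcsin_sqrt"`.
#' @return Tibble: `function_id`, `cohort_id`, `coefficient`, `p`, `q`,
#'   `evaluated`.
#' @export
function_regression <- function(values, metadata, covariates = character(),
                                contrast = c("HC", "IBS"), cohort_id = "cohort",
                                transform = c("none", "arcsin_sqrt")) {
  transform <- match.arg(transform)
  values <- as.matrix(values)
  metadata <- tibble::as_tibble(metadata)
  md <- metadata[match(colnames(values), metadata$sample_id), , drop = FALSE]
  if (anyNA(md$sample_id)) abort("metadata does not cover all samples")
  keep <- md$status %in% contrast
  if (length(covariates)) {
    missing_cov <- setdiff(covariates, names(md))
    if (length(missing_cov))
      abort(sprintf("covariates absent from metadata: %s", paste(missing_cov, collapse = ", ")))
    cc <- complete.cases(md[, covariates, drop = FALSE])
    n_drop <- sum(keep & !cc)
    if (n_drop > 0)
      ibs_log("INFO", sprintf("function_regression: dropping %d samples with NA covariates", n_drop))
    keep <- keep & cc
  }
  md <- md[keep, , drop = FALSE]
  vals <- values[, keep, drop = FALSE]
  if (transform == "arcsin_sqrt") vals <- asin(sqrt(vals))
  df <- as.data.frame(md[, covariates, drop = FALSE])
  df$..status <- factor(md$status, levels = contrast)
  rhs <- paste(c("..status", covariates), collapse = " + ")

  ids <- rownames(values) %||% paste0("fn", seq_len(nrow(values)))
  coefs <- p <- rep(NA_real_, length(ids))
  evaluated <- apply(vals, 1, sd) > 0
  for (i in which(evaluated)) {
    df$..y <- vals[i, ]
    fit <- tryCatch(lm(as.formula(paste("..y ~", rhs)), data = df),
                    error = function(e) NULL)
    if (is.null(fit) || any(is.na(coef(fit)))) {
      warn(sprintf("function %s skipped: rank-deficient design", ids[i]))
      evaluated[i] <- FALSE
      next
    }
    sm <- summary(fit)$coefficients
    row <- paste0("..status", contrast[2])
    coefs[i] <- sm[row, "Estimate"]
    p[i] <- sm[row, "Pr(>|t|)"]
  }
  q <- rep(NA_real_, length(ids))
  q[evaluated] <- bh_fdr(p[evaluated])
  tibble::tibble(function_id = ids, cohort_id = cohort_id,
                 coefficient = coefs, p = p, q = q, evaluated = evaluated)
}

#' Cross-cohort direction-consistency of functional shifts
#'
#' Two-tier rule over per-cohort regression results. A function evaluated in
#' all cohorts is `overlapping` when its status coefficient has the same sign
#' in every cohort, and `significant` when additionally it reaches FDR below
#' `fdr_thresh` or p below `p_thresh` in at least one cohort. Functions not
#' evaluated everywhere are excluded (logged).
#'
#' @param results Row-bound tibbles from [function_regression()] across
#'   cohorts.
#' @param n_cohorts Number of cohorts a function must be evaluated in.
#' @param fdr_thresh,p_thresh Significance gates for the `significant` tier.
#' @return Tibble: `function_id`, `direction` (`enriched`/`depleted` in
#'   cases), `n_cohorts`, `tier` (`"overlapping"` or `"significant"`;
#'   significant functions are a subset of overlapping ones).
#' @export
cross_cohort_consistency <- function(results, n_cohorts,
                                     fdr_thresh = 0.1, p_thresh = 0.05) {
  evaluated <- results[results$evaluated & !is.na(results$coefficient), , drop = FALSE]
  tallies <- evaluated |>
    dplyr::group_by(.data$function_id) |>
    dplyr::summarise(
      k = dplyr::n(),
      all_pos = all(.data$coefficient > 0),
      all_neg = all(.data$coefficient < 0),
      any_sig = any(.data$q < fdr_thresh | .data$p < p_thresh),
      .groups = "drop")
  n_excluded <- sum(tallies$k < n_cohorts)
  if (n_excluded > 0)
    ibs_log("INFO", sprintf(
      "cross_cohort_consistency: %d functions not evaluated in all %d cohorts excluded",
      n_excluded, n_cohorts))
  tallies <- tallies[tallies$k == n_cohorts & (tallies$all_pos | tallies$all_neg), , drop = FALSE]
  tibble::tibble(
    function_id = tallies$function_id,
    direction = ifelse(tallies$all_pos, "enriched", "depleted"),
    n_cohorts = tallies$k,
    tier = ifelse(tallies$any_sig, "significant", "overlapping"))
}
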