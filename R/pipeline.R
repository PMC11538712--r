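#' Run the signature-discovery stage end to end
#'
#' Orchestrates the discovery chain on a list of cohorts: depth filtering,
#' per-cohort Hedges' G, the cross-cohort consistency filter, random-effects
#' pooling with joint FDR, signature selection, the SparCC co-occurrence
#' network with Louvain modules over the signatures (samples pooled across
#' cohorts), and pooled-sample PERMANOVA. When `outdir` is given, every
#' stage's table is exported as TSV along with a run manifest.
#'
#' @param cohorts List of counts-scale [cohort_table()]s.
#' @param cfg A [filter_config()].
#' @param sparcc_cfg A [sparcc_config()].
#' @param min_reads Depth filter applied per cohort before analysis (0
#'   disables).
#' @param contrast `c(control_label, case_label)` for effect sizes.
#' @param method Random-effects estimator, `"REML"` or `"DL"`.
#' @param permanova_terms Metadata terms for the pooled PERMANOVA (a
#'   `cohort` column is added automatically); `NULL` skips the stage.
#' @param n_permutations PERMANOVA permutations.
#' @param seed Master seed.
#' @param outdir Optional output directory.
#' @return List: `effects`, `candidates`, `meta`, `signatures`, `network`,
#'   `permanova`.
#' @export
run_discovery <- function(cohorts, cfg = filter_config(),
                          sparcc_cfg = sparcc_config(), min_reads = 0,
                          contrast = c("HC", "IBS"), method = "REML",
                          permanova_terms = c("status", "cohort", "age", "sex"),
                          n_permutations = 999, seed = 1L, outdir = NULL) {
  stage <- "depth filter"
  res <- tryCatch({
    if (min_reads > 0) cohorts <- purrr::map(cohorts, filter_samples, min_reads = min_reads)

    stage <- "effect sizes"
    effects <- purrr::list_rbind(purrr::map(cohorts, cohort_effect_sizes,
                                            contrast = contrast))
    stage <- "consistency filter"
    candidates <- consistency_filter(effects, cfg)

    stage <- "random-effects pooling"
    meta <- meta_analyse(effects, candidates, method = method)
    signatures <- select_signatures(meta, cfg)

    stage <- "co-occurrence network"
    network <- NULL
    if (nrow(signatures) >= 4) {
      pooled <- do.call(cbind, purrr::map(cohorts, function(tb)
        tb$counts[signatures$species_id, , drop = FALSE]))
      sparcc_cfg$seed <- derive_seed(seed, 11L)
      rho <- sparcc_correlations(pooled, sparcc_cfg)
      pv <- permutation_pvalues(pooled, sparcc_cfg, rho = rho)
      network <- build_network(rho, pv, sparcc_cfg,
                               directions = signatures[, c("species_id", "direction")])
      network <- louvain_modules(network, seed = derive_seed(seed, 12L))
    } else {
      ibs_log("WARN", "fewer than 4 signatures: network stage skipped")
    }

    stage <- "permanova"
    permanova <- NULL
    if (!is.null(permanova_terms)) {
      pooled_counts <- do.call(cbind, purrr::map(cohorts, function(tb) tb$counts))
      md <- purrr::list_rbind(purrr::map(cohorts, function(tb)
        dplyr::mutate(tb$metadata, cohort = tb$cohort_id)))
      pooled_tab <- cohort_table(pooled_counts, md, "pooled")
      d <- bray_curtis(relative_abundance(pooled_tab))
      permanova <- permanova_marginal(d, dplyr::mutate(md, sample_id = md$sample_id),
                                      terms = permanova_terms,
                                      n_permutations = n_permutations,
                                      seed = derive_seed(seed, 13L))
    }

    list(effects = effects, candidates = candidates, meta = meta,
         signatures = signatures, network = network, permanova = permanova)
  }, error = function(e) {
    abort(sprintf("discovery aborted at stage '%s': %s", stage, conditionMessage(e)))
  })

  if (!is.null(outdir)) {
    if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
    write_effects(res$effects, file.path(outdir, "effects.tsv"))
    write_meta(res$meta, file.path(outdir, "meta.tsv"))
    readr::write_tsv(res$signatures, file.path(outdir, "signatures.tsv"), progress = FALSE)
    if (!is.null(res$network)) {
      write_edges(res$network, file.path(outdir, "network_edges.tsv"))
      write_graphml(res$network, file.path(outdir, "network.graphml"))
      readr::write_tsv(res$network$nodes, file.path(outdir, "network_nodes.tsv"),
                       progress = FALSE)
    }
    if (!is.null(res$permanova))
      write_permanova(res$permanova, file.path(outdir, "permanova.tsv"))
    write_manifest(res, outdir, seed)
  }
  res
}

write_manifest <- function(res, outdir, seed) {
  files <- list.files(outdir)
  lines <- c(
    sprintf("package_version\t%s", as.character(utils::packageVersion("ibsmeta"))),
    sprintf("seed\t%d", seed),
    sprintf("timestamp\t%s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
    sprintf("n_signatures\t%d", nrow(res$signatures)),
    sprintf("output\t%s", files))
  writeLines(lines, file.path(outdir, "manifest.tsv"))
}

#' Run the classifier-validation stage
#'
#' Trains and evaluates the three cross-validation schemes on the discovered
#' signature feature set: cross-cohort (train on each cohort, test on every
#' other), leave-one-cohort-out, and within-cohort 60/40 splits. Optionally
#' correlates the pooled estimates with an external cohort's effect sizes.
#'
#' @param cohorts List of [cohort_table()]s.
#' @param signatures Tibble from [select_signatures()].
#' @param grid An [rf_grid()].
#' @param external Optional external-cohort effect tibble for
#'   [validate_against_cohort()].
#' @param seed Master seed.
#' @return List: `cross_cohort`, `leave_one_cohort_out` (cv_reports),
#'   `within_cohort` (tibble of per-cohort AUCs), `concordance` (or `NULL`).
#' @export
run_validation <- function(cohorts, signatures, grid = rf_grid(),
                           external = NULL, seed = 1L) {
  feats <- signatures$species_id
  within <- purrr::list_rbind(purrr::imap(cohorts, function(tb, i)
    within_cohort_split(tb, feats, grid = grid, seed = derive_seed(seed, 100L + i))))
  list(
    cross_cohort = cross_cohort_cv(cohorts, feats, grid = grid, seed = derive_seed(seed, 1L)),
    leave_one_cohort_out = leave_one_cohort_out(cohorts, feats, grid = grid,
                                                seed = derive_seed(seed, 2L)),
    within_cohort = within,
    concordance = if (!is.null(external)) validate_against_cohort(signatures, external))
}

#' Run the treatment probability-shift stage
#'
#' Tunes a classifier on healthy controls vs pre-treatment patients in the
#' treatment arm, scores the probability shift after treatment
#' ([rifaximin_shift()]), and tabulates the per-signature before/after
#' Hedges' G with a toward-healthy direction summary.
#'
#' @param arm A [cohort_table()] with statuses `HC`, `IBSD_before`,
#'   `IBSD_after`.
#' @param signatures Tibble with `species_id` and `direction` (from
#'   [select_signatures()] or ground truth).
#' @param grid An [rf_grid()].
#' @param feature_set Species used as classifier features; defaults to all
#'   species in the arm.
#' @param seed Integer seed.
#' @return List: `shift` (a `shift_report`), `signature_shift` (per-signature
#'   tibble with `g_after_vs_before`, `p_wilcoxon`, `toward_hc`),
#'   `frac_toward_hc`.
#' @export
run_treatment <- function(arm, signatures, grid = rf_grid(),
                          feature_set = NULL, seed = 1L) {
  stopifnot(inherits(arm, "cohort_table"))
  feats <- feature_set %||% rownames(arm$counts)
  hc <- status_matrix(arm, "HC")[, feats, drop = FALSE]
  before <- status_matrix(arm, "IBSD_before")[, feats, drop = FALSE]
  after <- status_matrix(arm, "IBSD_after")[, feats, drop = FALSE]
  shift <- rifaximin_shift(hc, before, after, grid = grid, seed = seed)

  rel <- relative_abundance(arm)
  present <- intersect(signatures$species_id, rownames(rel$counts))
  detected <- present[rowSums(arm$counts[present, , drop = FALSE]) > 0]
  rows <- purrr::map(detected, function(sp) {
    bv <- rel$counts[sp, rel$metadata$status == "IBSD_before"]
    av <- rel$counts[sp, rel$metadata$status == "IBSD_after"]
    es <- hedges_g(av, bv)  # positive = higher after treatment
    pw <- suppressWarnings(wilcox.test(bv, av)$p.value)
    dir_s <- signatures$direction[signatures$species_id == sp][1]
    tibble::tibble(species_id = sp, direction = dir_s,
                   g_after_vs_before = es$g, p_wilcoxon = pw,
                   toward_hc = !is.na(es$g) &
                     ((dir_s == "depleted" & es$g > 0) |
                      (dir_s == "enriched" & es$g < 0)))
  })
  sig_shift <- purrr::list_rbind(rows)
  list(shift = shift, signature_shift = sig_shift,
       frac_toward_hc = mean(sig_shift$toward_hc))
}
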