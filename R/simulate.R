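#' Simulation configuration for synthetic multi-cohort data
#'
#' Defines the study conditions the generator emulates: K cohorts with
#' cohort-level composition offsets, case/control labels, planted signature
#' species with between-cohort heterogeneity, block-correlated species for
#' network tests, multinomial count sampling at variable depth, a
#' before/after treatment arm, diet variables monotonically coupled to a
#' subset of species, and functional tables with planted consistent effects.
#'
#' Species layout: block species first (network modules), then signature
#' species, then independent nulls; an error is raised when `S` cannot hold
#' blocks plus signatures.
#'
#' @param K Number of discovery cohorts.
#' @param n_control,n_case Samples per group per cohort.
#' @param S Total species.
#' @param n_signatures Planted signature species, split evenly between
#'   depleted and enriched in cases.
#' @param effect_mean True log-scale effect magnitude per signature
#'   (0.8 log-units keeps per-cohort |G| mostly in the small-effect regime
#'   0.2-0.6 that the consistency filter targets).
#' @param tau Between-cohort standard deviation of the true effect
#'   (random-effects heterogeneity).
#' @param cohort_offset_sd SD of per-cohort, per-species composition offsets.
#' @param depth_range Reads per sample, drawn uniformly.
#' @param module_spec List of `c(block_size, within_block_correlation)`
#'   pairs planting correlated species blocks.
#' @param treatment_lambda Mixing weight of post-treatment latent profiles
#'   toward the healthy profile (0 = unchanged, 1 = fully healthy).
#' @param n_foods,n_linked_foods Diet items simulated / monotonically coupled
#'   to species.
#' @param diet_rho Target latent correlation of linked food-species pairs.
#' @param n_functions,n_planted_functions Functional features simulated /
#'   planted with a consistent status effect.
#' @param function_effect Planted status coefficient for functions.
#' @param n_function_cohorts Cohorts carrying functional tables.
#' @param baseline_sd SD of global species log-baselines (variance 2 by
#'   default).
#' @param sample_sd Within-cohort per-sample latent noise SD (1.4 puts
#'   per-cohort planted |G| mostly in the 0.2-0.6 small-effect regime).
#' @param seed Master seed; everything downstream is deterministic given it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(K = 14, n_control = 50, n_case = 50, S = 300,
                       n_signatures = 30, effect_mean = 0.8, tau = 0.2,
                       cohort_offset_sd = 0.5, depth_range = c(5000, 50000),
                       module_spec = list(c(8, 0.7), c(8, 0.7), c(8, 0.7)),
                       treatment_lambda = 0.7,
                       n_foods = 30, n_linked_foods = 5, diet_rho = 0.4,
                       n_functions = 500, n_planted_functions = 20,
                       function_effect = 0.5, n_function_cohorts = 5,
                       baseline_sd = sqrt(2), sample_sd = 1.4, seed = 1L) {
  n_block <- sum(purrr::map_dbl(module_spec, 1))
  if (S < n_block + n_signatures)
    abort("S must be at least sum(block sizes) + n_signatures")
  if (tau < 0) abort("tau must be >= 0")
  if (treatment_lambda < 0 || treatment_lambda > 1)
    abort("treatment_lambda must lie in [0, 1]")
  if (any(purrr::map_dbl(module_spec, 2) <= -1) || any(purrr::map_dbl(module_spec, 2) >= 1))
    abort("block correlations must lie in (-1, 1)")
  structure(as.list(environment()), class = "sim_config")
}

# planted design shared by all generator stages
sim_truth <- function(cfg) {
  species_ids <- sprintf("sp%03d", seq_len(cfg$S))
  blocks <- integer(0)
  module <- integer(0)
  at <- 1L
  for (b in seq_along(cfg$module_spec)) {
    sz <- cfg$module_spec[[b]][1]
    blocks <- c(blocks, at:(at + sz - 1L))
    module <- c(module, rep(b, sz))
    at <- at + sz
  }
  sig_idx <- if (cfg$n_signatures > 0) at:(at + cfg$n_signatures - 1L) else integer(0)
  n_dep <- ceiling(cfg$n_signatures / 2)
  direction <- rep(c("depleted", "enriched"),
                   c(n_dep, cfg$n_signatures - n_dep))
  n_pf <- cfg$n_planted_functions
  fn_ids <- sprintf("fn%03d", seq_len(cfg$n_functions))
  planted_fn <- if (n_pf > 0) tibble::tibble(
    function_id = fn_ids[seq_len(n_pf)],
    effect = cfg$function_effect * rep(c(1, -1), length.out = n_pf)) else
    tibble::tibble(function_id = character(), effect = numeric())
  n_link <- min(cfg$n_linked_foods, length(sig_idx))
  linked <- tibble::tibble(
    item_id = sprintf("food%02d", seq_len(n_link)),
    species_id = species_ids[sig_idx[seq_len(n_link)]])
  list(
    species_ids = species_ids,
    signatures = tibble::tibble(species_id = species_ids[sig_idx],
                                delta = rep(cfg$effect_mean, cfg$n_signatures),
                                direction = direction),
    modules = tibble::tibble(species_id = species_ids[blocks], module = module),
    linked_foods = linked,
    planted_functions = planted_fn,
    function_ids = fn_ids,
    sig_idx = sig_idx, block_idx = blocks, block_module = module)
}

# latent log-abundance matrix for one group of samples in one cohort
latent_matrix <- function(cfg, truth, base, n, case_shift = NULL) {
  S <- cfg$S
  z <- matrix(rnorm(S * n, 0, cfg$sample_sd), S, n)
  for (b in seq_along(cfg$module_spec)) {
    r <- cfg$module_spec[[b]][2]
    rows <- truth$block_idx[truth$block_module == b]
    f <- rnorm(n)
    z[rows, ] <- sqrt(r) * cfg$sample_sd * matrix(f, length(rows), n, byrow = TRUE) +
      sqrt(1 - r) * z[rows, ]
  }
  z <- z + base
  if (!is.null(case_shift)) z <- z + case_shift
  z
}

counts_from_latent <- function(cfg, z, sample_ids) {
  p <- exp(sweep(z, 2, apply(z, 2, max), "-"))
  p <- sweep(p, 2, colSums(p), "/")
  depth <- floor(runif(ncol(z), cfg$depth_range[1], cfg$depth_range[2] + 1))
  counts <- vapply(seq_len(ncol(z)), function(j) rmultinom(1, depth[j], p[, j])[, 1],
                   numeric(nrow(z)))
  dimnames(counts) <- list(NULL, sample_ids)
  counts
}

sim_metadata <- function(sample_ids, status) {
  n <- length(sample_ids)
  tibble::tibble(
    sample_id = sample_ids, status = status,
    age = round(rnorm(n, 45, 12)),
    sex = sample(c("F", "M"), n, replace = TRUE),
    bmi = round(rnorm(n, 24, 3), 1))
}

#' Simulate a multi-cohort case-control study
#'
#' Per species, a global log-baseline is drawn from `N(0, baseline_sd^2)`;
#' each cohort adds a per-species composition offset `N(0, cohort_offset_sd^2)`;
#' each signature species' per-cohort effect is `N(delta, tau^2)` and shifts
#' the case group's log-mean down (depleted) or up (enriched); block species
#' share latent Gaussian factors producing the planted within-block
#' correlations; sample latent log-abundances pass through a softmax to
#' compositions and are sampled as multinomial counts at a uniformly drawn
#' depth. Deterministic under the config seed.
#'
#' @param cfg A [sim_config()].
#' @return List: `cohorts` (list of [cohort_table()]s) and `truth` (ground
#'   truth: `signatures`, `modules`, `linked_foods`, `planted_functions`).
#' @export
simulate_cohorts <- function(cfg = sim_config()) {
  set.seed(cfg$seed)
  truth <- sim_truth(cfg)
  b <- rnorm(cfg$S, 0, cfg$baseline_sd)
  # couple diet items to the most prevalent signature species: a link planted
  # on a species too rare to observe is undetectable by construction
  if (nrow(truth$linked_foods) > 0) {
    by_baseline <- truth$sig_idx[order(b[truth$sig_idx], decreasing = TRUE)]
    truth$linked_foods$species_id <-
      truth$species_ids[by_baseline[seq_len(nrow(truth$linked_foods))]]
  }
  sign_s <- ifelse(truth$signatures$direction == "depleted", -1, 1)
  cohorts <- vector("list", cfg$K)
  for (k in seq_len(cfg$K)) {
    cid <- sprintf("cohort%02d", k)
    offset <- rnorm(cfg$S, 0, cfg$cohort_offset_sd)
    delta_k <- rnorm(cfg$n_signatures, cfg$effect_mean, cfg$tau)
    case_shift <- rep(0, cfg$S)
    case_shift[truth$sig_idx] <- sign_s * delta_k
    n1 <- cfg$n_control; n2 <- cfg$n_case
    z_hc <- latent_matrix(cfg, truth, b + offset, n1)
    z_case <- latent_matrix(cfg, truth, b + offset + case_shift, n2)
    ids <- sprintf("%s_s%03d", cid, seq_len(n1 + n2))
    counts <- counts_from_latent(cfg, cbind(z_hc, z_case), ids)
    rownames(counts) <- truth$species_ids
    md <- sim_metadata(ids, rep(c("HC", "IBS"), c(n1, n2)))
    cohorts[[k]] <- cohort_table(counts, md, cid)
  }
  list(cohorts = cohorts, truth = truth[c("signatures", "modules",
                                          "linked_foods", "planted_functions")])
}

#' Simulate a rifaximin-style treatment arm
#'
#' One cohort with healthy controls, pre-treatment IBS-D patients, and
#' post-treatment samples drawn from the mixed group profile
#' `(1 - lambda) * before-profile + lambda * healthy-profile` before count
#' sampling (`lambda = 0` leaves the distribution unchanged; `lambda = 1`
#' matches the healthy distribution).
#'
#' @param cfg A [sim_config()] (`treatment_lambda` supplies lambda).
#' @param lambda Optional override of `cfg$treatment_lambda`.
#' @return A [cohort_table()] with statuses `HC`, `IBSD_before`,
#'   `IBSD_after`.
#' @export
simulate_treatment_arm <- function(cfg = sim_config(), lambda = NULL) {
  set.seed(derive_seed(cfg$seed, 900L))
  lambda <- lambda %||% cfg$treatment_lambda
  truth <- sim_truth(cfg)
  b <- rnorm(cfg$S, 0, cfg$baseline_sd)
  offset <- rnorm(cfg$S, 0, cfg$cohort_offset_sd)
  sign_s <- ifelse(truth$signatures$direction == "depleted", -1, 1)
  delta_k <- rnorm(cfg$n_signatures, cfg$effect_mean, cfg$tau)
  case_shift <- rep(0, cfg$S)
  case_shift[truth$sig_idx] <- sign_s * delta_k
  n1 <- cfg$n_control; n2 <- cfg$n_case
  z_hc <- latent_matrix(cfg, truth, b + offset, n1)
  z_before <- latent_matrix(cfg, truth, b + offset + case_shift, n2)
  # after-samples are independent draws from the mixed group profile; mixing
  # realised before-latents instead would make them near-copies of training
  # samples and bias full-model probabilities
  z_after <- latent_matrix(cfg, truth, b + offset + (1 - lambda) * case_shift, n2)
  ids <- c(sprintf("treat_hc%03d", seq_len(n1)),
           sprintf("treat_pre%03d", seq_len(n2)),
           sprintf("treat_post%03d", seq_len(n2)))
  counts <- counts_from_latent(cfg, cbind(z_hc, z_before, z_after), ids)
  rownames(counts) <- truth$species_ids
  md <- sim_metadata(ids, rep(c("HC", "IBSD_before", "IBSD_after"), c(n1, n2, n2)))
  cohort_table(counts, md, "treatment_arm")
}

#' Simulate food-frequency data coupled to species abundances
#'
#' Linked foods follow a monotone function of the linked species' observed
#' log relative abundance plus Gaussian noise calibrated so the latent
#' correlation is `diet_rho`; unlinked foods are independent noise. All foods
#' are then discretised into ten ordinal frequency categories (quantile
#' bins), mimicking a semi-quantitative FFQ.
#'
#' @param cfg A [sim_config()].
#' @param truth Ground truth from [simulate_cohorts()].
#' @param table The [cohort_table()] whose samples answer the FFQ.
#' @return List: `raw` (categorical responses for [weight_ffq()]) and
#'   `weighted` (the default-weighted intake matrix).
#' @export
simulate_diet <- function(cfg, truth, table) {
  set.seed(derive_seed(cfg$seed, 901L))
  stopifnot(inherits(table, "cohort_table"))
  rel <- if (table$scale == "counts") relative_abundance(table) else table
  n <- ncol(rel$counts)
  sigma <- sqrt(1 / cfg$diet_rho^2 - 1)
  vals <- matrix(rnorm(n * cfg$n_foods), n, cfg$n_foods,
                 dimnames = list(colnames(rel$counts),
                                 sprintf("food%02d", seq_len(cfg$n_foods))))
  for (i in seq_len(nrow(truth$linked_foods))) {
    sp <- truth$linked_foods$species_id[i]
    x <- as.numeric(scale(log(rel$counts[sp, ] + 1e-6)))
    vals[, truth$linked_foods$item_id[i]] <- x + sigma * rnorm(n)
  }
  raw <- tibble::as_tibble(vals)
  for (it in names(raw)) {
    br <- quantile(raw[[it]], probs = seq(0, 1, 0.1), names = FALSE)
    br[1] <- -Inf; br[11] <- Inf
    raw[[it]] <- as.character(cut(raw[[it]], breaks = unique(br),
                                  labels = FALSE, include.lowest = TRUE))
  }
  raw <- dplyr::bind_cols(tibble::tibble(sample_id = colnames(rel$counts)), raw)
  list(raw = raw, weighted = weight_ffq(raw))
}

#' Simulate per-cohort functional tables
#'
#' Planted functions carry a consistent status coefficient (magnitude
#' `function_effect`, fixed sign per function) across every cohort; null
#' functions are independent noise. Values mimic relative functional
#' abundances around a positive baseline with Gaussian noise (sd 0.5).
#'
#' @param cfg A [sim_config()].
#' @return List of `n_function_cohorts` elements, each
#'   `list(values, metadata, cohort_id)` suitable for
#'   [function_regression()].
#' @export
simulate_functions <- function(cfg = sim_config()) {
  set.seed(derive_seed(cfg$seed, 902L))
  truth <- sim_truth(cfg)
  planted <- setNames(rep(0, cfg$n_functions), truth$function_ids)
  planted[truth$planted_functions$function_id] <- truth$planted_functions$effect
  baseline <- runif(cfg$n_functions, 1, 5)
  out <- vector("list", cfg$n_function_cohorts)
  for (k in seq_len(cfg$n_function_cohorts)) {
    cid <- sprintf("fn_cohort%02d", k)
    n1 <- cfg$n_control; n2 <- cfg$n_case
    status <- rep(c("HC", "IBS"), c(n1, n2))
    ids <- sprintf("%s_s%03d", cid, seq_len(n1 + n2))
    vals <- baseline + outer(planted, as.numeric(status == "IBS")) +
      matrix(rnorm(cfg$n_functions * (n1 + n2), 0, 0.5), cfg$n_functions)
    dimnames(vals) <- list(truth$function_ids, ids)
    out[[k]] <- list(values = vals, metadata = sim_metadata(ids, status),
                     cohort_id = cid)
  }
  out
}

#' Write / read ground truth as TSV
#'
#' Lossless round trip of the generator's planted design (signatures with
#' effect and direction, module membership, linked food-species pairs,
#' planted function effects).
#'
#' @param truth `truth` element from [simulate_cohorts()].
#' @param dir Directory for the four TSV files.
#' @return `read_ground_truth()` returns the truth list.
#' @export
write_ground_truth <- function(truth, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_tsv(truth$signatures, file.path(dir, "truth_signatures.tsv"), progress = FALSE)
  readr::write_tsv(truth$modules, file.path(dir, "truth_modules.tsv"), progress = FALSE)
  readr::write_tsv(truth$linked_foods, file.path(dir, "truth_linked_foods.tsv"), progress = FALSE)
  readr::write_tsv(truth$planted_functions, file.path(dir, "truth_functions.tsv"), progress = FALSE)
  invisible(truth)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(dir) {
  list(
    signatures = readr::read_tsv(file.path(dir, "truth_signatures.tsv"),
                                 show_col_types = FALSE, progress = FALSE),
    modules = readr::read_tsv(file.path(dir, "truth_modules.tsv"),
                              show_col_types = FALSE, progress = FALSE),
    linked_foods = readr::read_tsv(file.path(dir, "truth_linked_foods.tsv"),
                                   show_col_types = FALSE, progress = FALSE),
    planted_functions = readr::read_tsv(file.path(dir, "truth_functions.tsv"),
                                        show_col_types = FALSE, progress = FALSE))
}
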