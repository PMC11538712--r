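#' Random-forest tuning grid
#'
#' Default grid mirrors the study's search: `mtry` from 6 to 60 in steps of 2
#' and `ntree` in \{100, 200, 300, 400, 500, 600, 800, 1000, 2000\}. Tests and
#' quick runs pass smaller grids.
#'
#' @param mtry,ntree Integer vectors of candidate values.
#' @return A list of class `rf_grid`.
#' @export
rf_grid <- function(mtry = seq(6, 60, by = 2),
                    ntree = c(100, 200, 300, 400, 500, 600, 800, 1000, 2000)) {
  structure(list(mtry = sort(unique(as.integer(mtry))),
                 ntree = sort(unique(as.integer(ntree)))), class = "rf_grid")
}

#' Tune a random-forest classifier by out-of-bag error
#'
#' Fits one forest per grid point and keeps the combination with the smallest
#' out-of-bag error; ties break toward smaller `ntree`, then smaller `mtry`.
#' `mtry` values exceeding the feature count are clipped with a warning.
#' Deterministic under a fixed seed.
#'
#' @param x Samples x features matrix or data frame.
#' @param y Two-level factor of class labels (second level = positive class).
#' @param grid An [rf_grid()].
#' @param seed Integer seed.
#' @return List of class `rf_tuned`: `model` (the refitted winner), `mtry`,
#'   `ntree`, `oob_error`.
#' @export
tune_classifier <- function(x, y, grid = rf_grid(), seed = 1L) {
  x <- as.data.frame(x)
  y <- droplevels(as.factor(y))
  if (nlevels(y) < 2) abort("training set has a single class")
  mtry <- grid$mtry
  if (any(mtry > ncol(x))) {
    warn(sprintf("grid mtry clipped to feature count %d", ncol(x)))
    mtry <- sort(unique(pmin(mtry, ncol(x))))
  }
  combos <- expand.grid(mtry = mtry, ntree = grid$ntree)  # ntree varies slowest
  combos <- combos[order(combos$ntree, combos$mtry), ]
  best <- NULL
  for (i in seq_len(nrow(combos))) {
    set.seed(derive_seed(seed, combos$ntree[i] * 1000L + combos$mtry[i]))
    fit <- randomForest::randomForest(x, y, ntree = combos$ntree[i], mtry = combos$mtry[i])
    err <- fit$err.rate[combos$ntree[i], "OOB"]
    if (is.null(best) || err < best$oob_error - 1e-12) {
      best <- list(model = fit, mtry = combos$mtry[i], ntree = combos$ntree[i],
                   oob_error = unname(err))
    }
  }
  structure(best, class = "rf_tuned")
}

#' Area under the ROC curve
#'
#' Mann-Whitney formulation: the probability that a randomly chosen positive
#' sample outscores a randomly chosen negative one, ties counted 1/2.
#'
#' @param scores Numeric classifier scores.
#' @param labels Logical/0-1/two-level factor; `TRUE`/1/second level =
#'   positive.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  if (is.factor(labels)) labels <- labels == levels(labels)[2]
  labels <- as.logical(labels)
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0) abort("both classes must be present")
  r <- rank(scores)
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

# samples x features relative-abundance matrix on a fixed feature set
# (missing species filled with 0), plus binary labels
feature_matrix <- function(table, feature_set, control_label = "HC",
                           case_labels = c("IBS", "IBS-C", "IBS-D", "IBS-M", "IBS-U")) {
  tab <- if (table$scale == "counts") relative_abundance(table) else table
  x <- matrix(0, ncol(tab$counts), length(feature_set),
              dimnames = list(colnames(tab$counts), feature_set))
  present <- intersect(feature_set, rownames(tab$counts))
  x[, present] <- t(tab$counts[present, , drop = FALSE])
  st <- tab$metadata$status
  keep <- st %in% c(control_label, case_labels)
  y <- factor(ifelse(st[keep] == control_label, "control", "case"),
              levels = c("control", "case"))
  list(x = as.data.frame(x[keep, , drop = FALSE]), y = y)
}

new_cv_report <- function(scheme, folds, seed) {
  structure(list(scheme = scheme, folds = folds,
                 mean_auc = mean(folds$auc), seed = seed),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report %s> %d folds, mean AUC %.3f\n",
              x$scheme, nrow(x$folds), x$mean_auc))
  invisible(x)
}

#' Tidy / summarise a cross-validation report
#'
#' @param x A `cv_report`.
#' @param ... Unused.
#' @return `tidy()`: the per-fold tibble; `glance()`: one row with the scheme
#'   and mean AUC.
#' @method tidy cv_report
#' @export
tidy.cv_report <- function(x, ...) x$folds

#' @rdname tidy.cv_report
#' @method glance cv_report
#' @export
glance.cv_report <- function(x, ...) {
  tibble::tibble(scheme = x$scheme, n_folds = nrow(x$folds), mean_auc = x$mean_auc)
}

#' Cross-cohort classifier validation
#'
#' `cross_cohort_cv()` trains on each cohort and evaluates on every other
#' cohort (one fold per ordered pair). `leave_one_cohort_out()` trains on the
#' concatenation of all but one cohort and evaluates on the hold-out (one
#' fold per cohort). Both operate on the shared feature space (union of
#' `feature_set`, absent species = 0 relative abundance); folds whose test
#' cohort carries a single class are skipped with a warning.
#'
#' @param cohorts List of [cohort_table()]s.
#' @param feature_set Character vector of species used as features (the
#'   discovered signatures).
#' @param grid An [rf_grid()].
#' @param control_label,case_labels Status labels defining the contrast.
#' @param seed Integer seed.
#' @return A `cv_report` with per-fold AUCs, tuned parameters, and the mean
#'   AUC.
#' @export
cross_cohort_cv <- function(cohorts, feature_set, grid = rf_grid(), seed = 1L,
                            control_label = "HC",
                            case_labels = c("IBS", "IBS-C", "IBS-D", "IBS-M", "IBS-U")) {
  if (length(cohorts) < 2) abort("cross_cohort_cv needs >= 2 cohorts")
  data <- purrr::map(cohorts, feature_matrix, feature_set = feature_set,
                     control_label = control_label, case_labels = case_labels)
  ids <- purrr::map_chr(cohorts, "cohort_id")
  folds <- list()
  for (i in seq_along(cohorts)) {
    tuned <- tune_classifier(data[[i]]$x, data[[i]]$y, grid = grid,
                             seed = derive_seed(seed, i))
    for (j in setdiff(seq_along(cohorts), i)) {
      if (nlevels(droplevels(data[[j]]$y)) < 2) {
        warn(sprintf("test cohort %s single-class: fold skipped", ids[j]))
        next
      }
      prob <- predict(tuned$model, data[[j]]$x, type = "prob")[, "case"]
      folds[[length(folds) + 1]] <- tibble::tibble(
        train_id = ids[i], test_id = ids[j],
        auc = roc_auc(prob, data[[j]]$y), n_test = length(prob),
        mtry = tuned$mtry, ntree = tuned$ntree)
    }
  }
  new_cv_report("cross_cohort", purrr::list_rbind(folds), seed)
}

#' @rdname cross_cohort_cv
#' @export
leave_one_cohort_out <- function(cohorts, feature_set, grid = rf_grid(), seed = 1L,
                                 control_label = "HC",
                                 case_labels = c("IBS", "IBS-C", "IBS-D", "IBS-M", "IBS-U")) {
  if (length(cohorts) < 3) abort("leave_one_cohort_out needs >= 3 cohorts")
  data <- purrr::map(cohorts, feature_matrix, feature_set = feature_set,
                     control_label = control_label, case_labels = case_labels)
  ids <- purrr::map_chr(cohorts, "cohort_id")
  folds <- list()
  for (k in seq_along(cohorts)) {
    if (nlevels(droplevels(data[[k]]$y)) < 2) {
      warn(sprintf("hold-out cohort %s single-class: fold skipped", ids[k]))
      next
    }
    train_x <- dplyr::bind_rows(purrr::map(data[-k], "x"))
    train_y <- factor(unlist(purrr::map(purrr::map(data[-k], "y"), as.character)),
                      levels = c("control", "case"))
    tuned <- tune_classifier(train_x, train_y, grid = grid, seed = derive_seed(seed, k))
    prob <- predict(tuned$model, data[[k]]$x, type = "prob")[, "case"]
    folds[[length(folds) + 1]] <- tibble::tibble(
      train_id = paste0("all_minus_", ids[k]), test_id = ids[k],
      auc = roc_auc(prob, data[[k]]$y), n_test = length(prob),
      mtry = tuned$mtry, ntree = tuned$ntree)
  }
  new_cv_report("leave_one_cohort_out", purrr::list_rbind(folds), seed)
}

#' Within-cohort train/test split
#'
#' Stratified split of one cohort by class (default 60% training, 40% test),
#' tuning on the training part and scoring AUC on the held-out part.
#'
#' @param cohort A [cohort_table()].
#' @param train_frac Training fraction per class.
#' @inheritParams cross_cohort_cv
#' @return One-row tibble: `cohort_id`, `auc`, `n_train`, `n_test`, `mtry`,
#'   `ntree`.
#' @export
within_cohort_split <- function(cohort, feature_set, train_frac = 0.6,
                                grid = rf_grid(), seed = 1L, control_label = "HC",
                                case_labels = c("IBS", "IBS-C", "IBS-D", "IBS-M", "IBS-U")) {
  dat <- feature_matrix(cohort, feature_set, control_label, case_labels)
  cls <- split(seq_along(dat$y), dat$y)
  if (any(lengths(cls) < 2)) abort("each class needs >= 2 samples to stratify")
  set.seed(derive_seed(seed, 7L))
  train_idx <- sort(unlist(lapply(cls, function(ix) {
    n_tr <- round(length(ix) * train_frac)
    n_tr <- min(max(n_tr, 1L), length(ix) - 1L)
    sample(ix, n_tr)
  })))
  test_idx <- setdiff(seq_along(dat$y), train_idx)
  tuned <- tune_classifier(dat$x[train_idx, , drop = FALSE], dat$y[train_idx],
                           grid = grid, seed = seed)
  prob <- predict(tuned$model, dat$x[test_idx, , drop = FALSE], type = "prob")[, "case"]
  tibble::tibble(cohort_id = cohort$cohort_id,
                 auc = roc_auc(prob, dat$y[test_idx]),
                 n_train = length(train_idx), n_test = length(test_idx),
                 mtry = tuned$mtry, ntree = tuned$ntree)
}

#' Top-ranked random-forest features
#'
#' Features ranked by mean impurity-decrease importance, descending; ties
#' break by original feature order.
#'
#' @param tuned An `rf_tuned` from [tune_classifier()].
#' @param k Number of features to return (clipped with a warning when it
#'   exceeds the feature count).
#' @return Tibble `rank`, `species_id`, `importance`.
#' @export
top_k_features <- function(tuned, k = 50) {
  imp <- randomForest::importance(tuned$model)[, 1]
  if (k > length(imp)) {
    warn(sprintf("k = %d exceeds feature count %d: returning all", k, length(imp)))
    k <- length(imp)
  }
  ord <- order(-imp, seq_along(imp))[seq_len(k)]
  tibble::tibble(rank = seq_len(k), species_id = names(imp)[ord],
                 importance = unname(imp[ord]))
}

#' Treatment probability-shift analysis
#'
#' Quantifies how far a treatment moved patients toward the healthy profile:
#' a classifier is tuned on healthy controls vs pre-treatment patients, each
#' pre-treatment sample gets its out-of-bag probability of being classified as
#' a patient (avoiding resubstitution optimism; set `oob_before = FALSE` to
#' score by refit prediction instead), each post-treatment sample gets the
#' full model's probability, and the before/after probability distributions
#' are compared by a two-sided Wilcoxon rank-sum test.
#'
#' @param hc,before,after Samples x features matrices (shared feature
#'   columns): healthy controls, patients pre-treatment, patients
#'   post-treatment.
#' @param grid An [rf_grid()].
#' @param seed Integer seed.
#' @param oob_before Score pre-treatment samples out-of-bag (default) or by
#'   refit prediction.
#' @param top_k Number of ranked features to report.
#' @return List of class `shift_report`: `probabilities` tibble (`sample_id`,
#'   `group`, `prob_case`), `wilcoxon_p`, `training_auc`, `top_features`,
#'   tuned parameters, `oob_before` flag.
#' @export
rifaximin_shift <- function(hc, before, after, grid = rf_grid(), seed = 1L,
                            oob_before = TRUE, top_k = 50) {
  if (nrow(hc) == 0 || nrow(before) == 0 || nrow(after) == 0)
    abort("hc, before, and after must all be non-empty")
  x <- as.data.frame(rbind(hc, before))
  y <- factor(rep(c("control", "case"), c(nrow(hc), nrow(before))),
              levels = c("control", "case"))
  tuned <- tune_classifier(x, y, grid = grid, seed = seed)
  oob_prob <- tuned$model$votes[, "case"]
  before_prob <- if (oob_before) {
    unname(oob_prob[nrow(hc) + seq_len(nrow(before))])
  } else {
    unname(predict(tuned$model, as.data.frame(before), type = "prob")[, "case"])
  }
  after_prob <- unname(predict(tuned$model, as.data.frame(after), type = "prob")[, "case"])
  probs <- tibble::tibble(
    sample_id = c(rownames(before) %||% paste0("before_", seq_len(nrow(before))),
                  rownames(after) %||% paste0("after_", seq_len(nrow(after)))),
    group = rep(c("before", "after"), c(nrow(before), nrow(after))),
    prob_case = c(before_prob, after_prob))
  structure(list(
    probabilities = probs,
    wilcoxon_p = suppressWarnings(
      wilcox.test(before_prob, after_prob, alternative = "two.sided")$p.value),
    training_auc = roc_auc(oob_prob, y),
    top_features = top_k_features(tuned, k = top_k),
    mtry = tuned$mtry, ntree = tuned$ntree, oob_before = oob_before, seed = seed),
    class = "shift_report")
}

#' @export
print.shift_report <- function(x, ...) {
  med <- tapply(x$probabilities$prob_case, x$probabilities$group, median)
  cat(sprintf("<shift_report> training AUC %.3f; median P(case) before %.3f -> after %.3f; Wilcoxon p = %.3g\n",
              x$training_auc, med[["before"]], med[["after"]], x$wilcoxon_p))
  invisible(x)
}

#' Tidy / summarise a shift report
#'
#' @param x A `shift_report`.
#' @param ... Unused.
#' @return `tidy()`: per-sample probability tibble; `glance()`: one-row
#'   summary.
#' @method tidy shift_report
#' @export
tidy.shift_report <- function(x, ...) x$probabilities

#' @rdname tidy.shift_report
#' @method glance shift_report
#' @export
glance.shift_report <- function(x, ...) {
  med <- tapply(x$probabilities$prob_case, x$probabilities$group, median)
  tibble::tibble(training_auc = x$training_auc,
                 median_before = unname(med[["before"]]),
                 median_after = unname(med[["after"]]),
                 wilcoxon_p = x$wilcoxon_p, oob_before = x$oob_before)
}

#' Extract one status group as a samples x features matrix
#'
#' Convenience accessor for the treatment-arm analysis: relative abundances
#' of all samples with the given status, samples in rows.
#'
#' @param table A [cohort_table()].
#' @param status One of [status_levels].
#' @return Numeric matrix, samples x species.
#' @export
status_matrix <- function(table, status) {
  stopifnot(inherits(table, "cohort_table"))
  tab <- if (table$scale == "counts") relative_abundance(table) else table
  idx <- which(tab$metadata$status == status)
  t(tab$counts[, idx, drop = FALSE])
}
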