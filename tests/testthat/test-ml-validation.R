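quick_grid <- rf_grid(mtry = c(4, 8), ntree = 200)

# brute-force pairwise AUC oracle
oracle_auc <- function(scores, labels) {
  pos <- scores[as.logical(labels)]; neg <- scores[!as.logical(labels)]
  tot <- 0
  for (a in pos) for (b in neg) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(pos) * length(neg))
}

test_that("roc_auc equals the pairwise Mann-Whitney oracle, ties included", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.4, 0.2), c(1, 1, 0, 0)), 1)
  expect_equal(roc_auc(c(0.9, 0.3, 0.5, 0.2), c(1, 1, 0, 0)), 0.75)
  expect_equal(roc_auc(rep(0.5, 10), rep(c(0, 1), 5)), 0.5)
  expect_error(roc_auc(1:4, rep(1, 4)), "both classes")

  skip_if_not_installed("pROC")
  set.seed(51)
  for (i in 1:200) {
    n <- sample(5:30, 1)
    labels <- c(0, 1, rbinom(n - 2, 1, 0.5))
    scores <- sample(seq(0, 1, 0.05), n, replace = TRUE)  # forces ties
    mine <- roc_auc(scores, labels)
    expect_equal(mine, oracle_auc(scores, labels), tolerance = 1e-12)
    pr <- suppressMessages(pROC::auc(pROC::roc(labels, scores, direction = "<")))
    expect_equal(mine, as.numeric(pr), tolerance = 1e-12)
  }
})

test_that("classifier tuning is deterministic, clips the grid, and learns planted signal", {
  set.seed(52)
  x <- matrix(rnorm(120 * 15), 120, 15, dimnames = list(NULL, paste0("f", 1:15)))
  y <- factor(rep(c("control", "case"), 60), levels = c("control", "case"))
  x[y == "case", 1:10] <- x[y == "case", 1:10] + 1.2  # strongly informative features

  expect_warning(tune_classifier(x, y, rf_grid(mtry = c(5, 40), ntree = 100), seed = 1),
                 "clipped")
  t1 <- tune_classifier(x, y, quick_grid, seed = 9)
  t2 <- tune_classifier(x, y, quick_grid, seed = 9)
  expect_identical(c(t1$mtry, t1$ntree), c(t2$mtry, t2$ntree))
  expect_identical(t1$oob_error, t2$oob_error)
  expect_lt(t1$oob_error, 0.2)

  expect_error(tune_classifier(x, rep("case", 120)), "single class")
})

test_that("top-k feature ranking is importance-ordered and deterministic", {
  set.seed(53)
  x <- matrix(rnorm(100 * 12), 100, 12, dimnames = list(NULL, paste0("f", 1:12)))
  y <- factor(rep(c("control", "case"), 50), levels = c("control", "case"))
  x[y == "case", 1:3] <- x[y == "case", 1:3] + 2
  tuned <- tune_classifier(x, y, quick_grid, seed = 2)
  top <- top_k_features(tuned, k = 12)
  expect_setequal(top$species_id, paste0("f", 1:12))
  expect_true(all(diff(top$importance) <= 1e-12))
  expect_true(all(paste0("f", 1:3) %in% top$species_id[1:4]))
  expect_warning(top_k_features(tuned, k = 50), "exceeds")
  tuned2 <- tune_classifier(x, y, quick_grid, seed = 2)
  expect_identical(top_k_features(tuned2, k = 12)$species_id, top$species_id)
})

test_that("cross-cohort CV makes one fold per ordered pair and finds shared signal", {
  sim <- small_sim()
  feats <- sim$truth$signatures$species_id
  cv <- cross_cohort_cv(sim$cohorts[1:3], feats, grid = quick_grid, seed = 4)
  expect_identical(nrow(cv$folds), 6L)           # 3 cohorts -> 6 ordered pairs
  expect_true(all(cv$folds$train_id != cv$folds$test_id))
  expect_equal(cv$mean_auc, mean(cv$folds$auc))
  expect_gt(cv$mean_auc, 0.8)                    # planted shared signal
  expect_identical(glance(cv)$scheme, "cross_cohort")
  expect_error(cross_cohort_cv(sim$cohorts[1], feats), ">= 2 cohorts")
})

test_that("leave-one-cohort-out yields K folds and pooling helps or matches", {
  sim <- small_sim()
  feats <- sim$truth$signatures$species_id
  loco <- leave_one_cohort_out(sim$cohorts[1:4], feats, grid = quick_grid, seed = 4)
  expect_identical(nrow(loco$folds), 4L)
  cv <- cross_cohort_cv(sim$cohorts[1:4], feats, grid = quick_grid, seed = 4)
  expect_gte(loco$mean_auc, cv$mean_auc - 0.05)
  expect_error(leave_one_cohort_out(sim$cohorts[1:2], feats), ">= 3 cohorts")
})

test_that("test-cohort labels cannot leak into training", {
  sim <- small_sim()
  feats <- sim$truth$signatures$species_id
  cohorts <- sim$cohorts[1:2]
  cv <- cross_cohort_cv(cohorts, feats, grid = quick_grid, seed = 11)
  # flip every test label in cohort 2: the trained model is untouched, so the
  # fold AUC must be exactly complemented
  flipped <- cohorts
  st <- flipped[[2]]$metadata$status
  flipped[[2]]$metadata$status <- ifelse(st == "HC", "IBS", "HC")
  cv_flip <- cross_cohort_cv(flipped, feats, grid = quick_grid, seed = 11)
  a <- cv$folds$auc[cv$folds$train_id == "cohort01"]
  b <- cv_flip$folds$auc[cv_flip$folds$train_id == "cohort01"]
  expect_equal(b, 1 - a, tolerance = 1e-12)
})

test_that("within-cohort split stratifies 60/40 and scores held-out samples", {
  sim <- small_sim()
  feats <- sim$truth$signatures$species_id
  res <- within_cohort_split(sim$cohorts[[1]], feats, grid = quick_grid, seed = 6)
  expect_identical(res$n_train, 36L)  # 60% of 30+30, stratified
  expect_identical(res$n_test, 24L)
  expect_gt(res$auc, 0.7)            # planted signal

  tiny <- sim$cohorts[[1]]
  keep <- c(which(tiny$metadata$status == "HC")[1],
            which(tiny$metadata$status == "IBS"))
  tiny$counts <- tiny$counts[, keep]; tiny$metadata <- tiny$metadata[keep, ]
  expect_error(within_cohort_split(tiny, feats, grid = quick_grid), "stratify")
})

test_that("null labels give chance-level AUC across schemes", {
  cfg <- sim_config(K = 3, n_control = 25, n_case = 25, S = 40, n_signatures = 0,
                    effect_mean = 0, module_spec = list(), seed = 60L)
  sim <- simulate_cohorts(cfg)
  feats <- rownames(sim$cohorts[[1]]$counts)
  cv <- cross_cohort_cv(sim$cohorts, feats, grid = quick_grid, seed = 1)
  loco <- leave_one_cohort_out(sim$cohorts, feats, grid = quick_grid, seed = 1)
  expect_gt(cv$mean_auc, 0.35); expect_lt(cv$mean_auc, 0.65)
  expect_gt(loco$mean_auc, 0.35); expect_lt(loco$mean_auc, 0.65)
})

test_that("probability-shift analysis flags a planted treatment response", {
  cfg <- sim_config(K = 1, n_control = 40, n_case = 40, S = 60, n_signatures = 20,
                    module_spec = list(), treatment_lambda = 0.7, seed = 61L)
  arm <- simulate_treatment_arm(cfg)
  hc <- status_matrix(arm, "HC")
  before <- status_matrix(arm, "IBSD_before")
  after <- status_matrix(arm, "IBSD_after")
  rep <- rifaximin_shift(hc, before, after, grid = quick_grid, seed = 2, top_k = 10)
  med <- tapply(rep$probabilities$prob_case, rep$probabilities$group, median)
  expect_lt(med[["after"]], med[["before"]])
  expect_lt(rep$wilcoxon_p, 0.01)
  expect_gt(rep$training_auc, 0.7)
  expect_identical(nrow(rep$top_features), 10L)
  expect_true(all(rep$probabilities$prob_case >= 0 & rep$probabilities$prob_case <= 1))
  g <- glance(rep)
  expect_identical(g$wilcoxon_p, rep$wilcoxon_p)

  # no-shift control: after == before scored by refit prediction
  rep0 <- rifaximin_shift(hc, before, before, grid = quick_grid, seed = 2,
                          oob_before = FALSE)
  pb <- rep0$probabilities$prob_case[rep0$probabilities$group == "before"]
  pa <- rep0$probabilities$prob_case[rep0$probabilities$group == "after"]
  expect_equal(pa, pb, tolerance = 1e-12)
  expect_gt(rep0$wilcoxon_p, 0.9)

  expect_error(rifaximin_shift(hc[0, ], before, after), "non-empty")
})
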