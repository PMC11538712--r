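make_records <- function(gs, species = "spX") {
  tibble::tibble(species_id = species,
                 cohort_id = sprintf("c%02d", seq_along(gs)),
                 g = gs, var_g = 0.05, n_control = 50, n_case = 50,
                 detected = TRUE)
}

test_that("consistency filter applies the support/conflict rule in both directions", {
  cfg <- filter_config()
  rec <- dplyr::bind_rows(
    make_records(c(rep(0.2, 8), rep(-0.05, 6)), "dep"),
    make_records(c(rep(0.2, 7), rep(-0.2, 4), rep(0, 3)), "conflict"),
    make_records(c(rep(-0.15, 10), rep(0.05, 4)), "enr"),
    make_records(rep(0.05, 14), "null"))
  out <- consistency_filter(rec, cfg)
  expect_setequal(out$species_id, c("dep", "enr"))
  expect_identical(out$candidate_direction[out$species_id == "dep"], "depleted")
  expect_identical(out$candidate_direction[out$species_id == "enr"], "enriched")

  # undetected cohorts count toward neither tally
  rec2 <- make_records(c(rep(0.2, 7), rep(NA, 7)), "na_rich")
  out2 <- consistency_filter(dplyr::bind_rows(rec, rec2), cfg)
  expect_true("na_rich" %in% out2$species_id)

  expect_error(consistency_filter(make_records(rep(0.2, 3)), cfg), "fewer cohorts")
})

test_that("random-effects fit reproduces closed-form worked examples", {
  # homogeneous: five identical records
  hom <- random_effects_fit(make_records(rep(0.5, 5))[, c("g", "cohort_id")] |>
                              dplyr::mutate(var_g = 0.04), method = "DL")
  expect_equal(hom$mu_hat, 0.5)
  expect_equal(hom$tau2, 0)
  expect_equal(hom$Q, 0)
  expect_equal(hom$I2, 0)
  expect_equal(hom$se, 0.089443, tolerance = 1e-5)
  # REML equals DL at homogeneity
  hom_reml <- random_effects_fit(tibble::tibble(g = rep(0.5, 5), var_g = 0.04), "REML")
  expect_equal(hom_reml$mu_hat, hom$mu_hat, tolerance = 1e-10)
  expect_equal(hom_reml$tau2, 0)

  # heterogeneous two-study DL example
  two <- random_effects_fit(tibble::tibble(g = c(0.2, 0.6), var_g = 0.01), "DL")
  expect_equal(two$Q, 8, tolerance = 1e-10)
  expect_equal(two$tau2, 0.07, tolerance = 1e-10)
  expect_equal(two$I2, 87.5, tolerance = 1e-10)
  expect_equal(two$mu_hat, 0.4, tolerance = 1e-10)

  # k = 2 equal effects: pooled estimate is that effect exactly
  eq <- random_effects_fit(tibble::tibble(g = c(0.3, 0.3), var_g = c(0.02, 0.05)))
  expect_equal(eq$mu_hat, 0.3, tolerance = 1e-12)

  expect_error(random_effects_fit(tibble::tibble(g = 0.5, var_g = 0.1)), "k >= 2")
  expect_error(random_effects_fit(tibble::tibble(g = c(0.1, 0.2), var_g = c(0.1, 0))),
               "positive")
})

test_that("DL and REML agree with the reference meta-analysis implementation", {
  skip_if_not_installed("metafor")
  set.seed(7)
  for (i in 1:50) {
    k <- sample(2:14, 1)
    y <- rnorm(k, 0.4, 0.4); v <- runif(k, 0.01, 0.2)
    mine_dl <- random_effects_fit(tibble::tibble(g = y, var_g = v), "DL")
    or_dl <- metafor::rma(yi = y, vi = v, method = "DL")
    expect_equal(mine_dl$mu_hat, as.numeric(or_dl$beta), tolerance = 1e-8)
    expect_equal(mine_dl$tau2, or_dl$tau2, tolerance = 1e-8)
    expect_equal(mine_dl$se, or_dl$se, tolerance = 1e-8)
    expect_equal(mine_dl$Q, or_dl$QE, tolerance = 1e-8)

    mine_reml <- suppressMessages(
      random_effects_fit(tibble::tibble(g = y, var_g = v), "REML"))
    if (mine_reml$converged) {  # DL fallback cases are compared above already
      or_reml <- metafor::rma(yi = y, vi = v, method = "REML")
      expect_lt(abs(mine_reml$tau2 - or_reml$tau2), 1e-4)
      expect_lt(abs(mine_reml$mu_hat - as.numeric(or_reml$beta)), 1e-4)
    }
  }
})

test_that("BH adjustment equals the hand step-up and preserves order", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(rep(0.2, 5)), rep(0.2, 5))
  expect_error(bh_fdr(c(0.5, 1.2)), "outside")

  step_up <- function(p) {  # independent oracle
    m <- length(p); o <- order(p); q <- numeric(m)
    running <- 1
    for (i in m:1) {
      running <- min(running, p[o[i]] * m / i)
      q[o[i]] <- running
    }
    q
  }
  set.seed(13)
  for (i in 1:200) {
    p <- runif(sample(1:40, 1))
    expect_equal(bh_fdr(p), step_up(p), tolerance = 1e-12)
  }
})

test_that("signature selection applies both the FDR and the raw-p gate", {
  meta <- tibble::tibble(species_id = c("a", "b", "c"),
                         k = 10, mu_hat = c(0.4, 0.3, -0.5), se = 0.1,
                         z = 3, p = c(0.01, 0.06, 0.01), q = c(0.05, 0.08, 0.2),
                         tau2 = 0, Q = 1, I2 = 0,
                         direction = c("depleted", "depleted", "enriched"),
                         heterogeneity_class = "low")
  kept <- select_signatures(meta, filter_config())
  expect_identical(kept$species_id, "a")
})

test_that("heterogeneity classes follow the I2 cut-points with upward boundaries", {
  expect_identical(heterogeneity_class(c(10, 25, 49.99, 50, 87.5)),
                   c("low", "moderate", "moderate", "high", "high"))
  expect_error(heterogeneity_class(101), "\\[0, 100\\]")
  expect_error(heterogeneity_class(-1), "\\[0, 100\\]")
})

test_that("meta_analyse pools candidates jointly and classifies heterogeneity", {
  sim <- small_sim()
  eff <- small_effects()
  cfg <- filter_config(min_support = 5, max_conflict = 2, n_cohorts_expected = 8)
  cand <- consistency_filter(eff, cfg)
  meta <- meta_analyse(eff, cand)
  expect_identical(nrow(meta), nrow(cand))
  expect_true(all(meta$q >= meta$p - 1e-12))
  expect_true(all(meta$tau2 >= 0))
  expect_true(all(meta$I2 >= 0 & meta$I2 <= 100))
  expect_true(all(meta$k >= 2))
  # planted signatures dominate the candidate list
  sig <- select_signatures(meta, cfg)
  truth <- sim$truth$signatures
  expect_gt(mean(sig$species_id %in% truth$species_id), 0.8)
  # directions match truth for the recovered planted species
  joined <- dplyr::inner_join(sig, truth, by = "species_id")
  expect_true(all(joined$direction.x == joined$direction.y))
})

test_that("external-cohort validation recovers planted concordance", {
  eff <- small_effects()
  cand <- consistency_filter(eff, filter_config(min_support = 5, max_conflict = 2,
                                                n_cohorts_expected = 8))
  meta <- meta_analyse(eff, cand)

  # external = the pooled estimates themselves
  self <- tibble::tibble(species_id = meta$species_id, g = meta$mu_hat)
  expect_equal(validate_against_cohort(meta, self)$rho, 1)

  # an extra well-powered cohort simulated from the same planted effects
  # associates strongly
  cfg2 <- small_sim()$cfg; cfg2$seed <- 777L; cfg2$K <- 1
  cfg2$n_control <- 100L; cfg2$n_case <- 100L
  ext <- cohort_effect_sizes(simulate_cohorts(cfg2)$cohorts[[1]])
  got <- validate_against_cohort(meta, ext)
  expect_gt(got$rho, 0.6)

  # shuffled external effects: no association
  set.seed(1)
  shuf <- ext; shuf$g <- sample(shuf$g)
  expect_lt(abs(validate_against_cohort(meta, shuf)$rho), 0.4)

  expect_error(validate_against_cohort(meta[0, ], ext), "3 shared")
})
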