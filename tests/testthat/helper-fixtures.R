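# shared fixtures, built in code at test time

# tiny hand-written cohort: 3 species x 4 samples
tiny_cohort <- function(status = c("HC", "HC", "IBS", "IBS")) {
  counts <- matrix(c(10, 5, 0, 20,
                     30, 15, 2, 40,
                     60, 30, 8, 140), nrow = 3, byrow = TRUE,
                   dimnames = list(c("spA", "spB", "spC"),
                                   c("s1", "s2", "s3", "s4")))
  md <- tibble::tibble(sample_id = colnames(counts), status = status,
                       age = c(30, 41, NA, 55), sex = c("F", "M", "F", "M"))
  cohort_table(counts, md, "tiny")
}

# memoised small simulation shared across test files
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(K = 8, n_control = 30, n_case = 30, S = 80,
                        n_signatures = 16, module_spec = list(c(6, 0.7), c(6, 0.7)),
                        seed = 42L)
      cache <<- c(simulate_cohorts(cfg), list(cfg = cfg))
    }
    cache
  }
})

# per-cohort effect sizes for the small simulation, memoised
small_effects <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- dplyr::bind_rows(lapply(small_sim()$cohorts, cohort_effect_sizes))
    cache
  }
})

expect_silent_log <- function(expr) suppressMessages(expr)
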