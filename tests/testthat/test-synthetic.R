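test_that("generation is deterministic given the seed", {
  spec <- cohort_spec("paper_like", n_subjects = 80, seed = 5)
  c1 <- generate_cohort(spec)
  c2 <- generate_cohort(spec)
  expect_identical(as.data.frame(c1), as.data.frame(c2))
  c3 <- generate_cohort(spec, seed = 6)
  expect_false(identical(as.data.frame(c1), as.data.frame(c3)))
})

test_that("generated values respect the design and instrument ranges", {
  spec <- cohort_spec("paper_like", n_subjects = 300, seed = 2)
  coh <- generate_cohort(spec)
  sch <- aud_schema()
  for (cv in intersect(names(sch), names(coh)))
    expect_true(all(coh[[cv]] >= sch[[cv]][1] & coh[[cv]] <= sch[[cv]][2]),
                label = paste("range of", cv))
  expect_true(all(coh$state %in% c(0, 1)))
  expect_true(all(coh$time >= 0))
  base_age <- coh$age[!duplicated(coh$subject_id)]
  expect_true(all(base_age >= 14 & base_age <= 24))
  # biannual design: mean observed gap near 6 months
  pairs <- build_transition_pairs(coh)
  expect_gt(mean(pairs$dt), 5.5)
})

test_that("a symmetric no-effect truth reaches 50% prevalence at stationarity", {
  # q01 = q10 = 0.02/month and many waves: state marginal approaches 1/2
  spec <- cohort_spec("null", n_subjects = 2500, n_waves = 12, p_miss = 0,
                      p_baseline_aud = 0.5, seed = 44)
  coh <- generate_cohort(spec)
  pairs <- build_transition_pairs(coh)
  tab <- tabulate_transitions(pairs)
  expect_lt(abs(mean(coh$state) - 0.5), 0.04)
  expect_equal(tab["NoAUD", "AUD"] / tab["AUD", "NoAUD"], 1, tolerance = 0.15)
})

test_that("empirical transition frequencies match the closed form at fixed z", {
  # large cohort, constant covariates: observed cell shares within 3
  # binomial SDs of P(dt)
  m <- intensity_model()
  spec <- cohort_spec(model = m, params = c(log(0.03), log(0.08)),
                      covariate_processes = list(),
                      n_subjects = 10000, n_waves = 3, p_miss = 0,
                      gap_sd = 0, p_baseline_aud = 0.4, seed = 77)
  coh <- generate_cohort(spec)
  pairs <- build_transition_pairs(coh)
  for (s in c(0, 1)) {
    sel <- pairs$pre_state == s
    phat <- mean(pairs$post_state[sel] == 1)
    ptrue <- oracle_p(0.03, 0.08, 6, s, 1)
    tol <- 3 * sqrt(ptrue * (1 - ptrue) / sum(sel))
    expect_lt(abs(phat - ptrue), tol)
  }
})

test_that("missingness removes follow-ups MCAR and never the baseline", {
  spec <- cohort_spec("null", n_subjects = 400, p_miss = 0, seed = 10)
  full <- generate_cohort(spec)
  expect_identical(nrow(full), 400L * 5L)
  same <- inject_missingness(full, 0)
  expect_identical(as.data.frame(same), as.data.frame(full))
  set.seed(3)
  thin <- inject_missingness(full, 0.3)
  expect_true(all(table(thin$subject_id) >= 1))
  expect_true(all(thin$time[!duplicated(thin$subject_id)] == 0))
  kept <- (nrow(thin) - 400) / (400 * 4)
  expect_equal(kept, 0.7, tolerance = 3 * sqrt(0.3 * 0.7 / 1600))
  expect_error(inject_missingness(full, 1), "p_miss")
  # a subject missing wave 1 but observed at 0 and 2 spans ~12 months
  pairs <- build_transition_pairs(thin)
  expect_true(any(pairs$dt > 10))
})

test_that("invalid specs are rejected before any sampling", {
  expect_error(cohort_spec("null", p_miss = 1.2), "probabilities")
  expect_error(cohort_spec("null", n_waves = 0))
  expect_error(cohort_spec(model = intensity_model(), params = NULL),
               "both 'model' and 'params'")
  bad <- default_covariate_processes()
  bad$cannabis$rho <- 1.2
  expect_error(cohort_spec("null", covariate_processes = bad), "rho")
})

test_that("generated cohorts round-trip through the CSV reader", {
  spec <- cohort_spec("paper_like", n_subjects = 50, seed = 13)
  coh <- generate_cohort(spec)
  path <- tempfile(fileext = ".csv")
  write_cohort(coh, path)
  back <- read_panel(path)
  expect_equal(nrow(back), nrow(coh))
  expect_equal(back$state, coh$state)
  expect_equal(back$cannabis, coh$cannabis, tolerance = 1e-12)
})
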