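test_that("covariate combination averages the sources element-wise", {
  coh <- toy_cohort()
  coh$anxiety <- c(0.4, 1, 2, 0, 1, 2, 3)
  coh$depression <- c(0.8, 1, 2, 4, 1, 0, 3)
  attr(coh, "covariates") <- c(attr(coh, "covariates"), "anxiety", "depression")
  attr(coh, "schema")$anxiety <- c(0, 4)
  attr(coh, "schema")$depression <- c(0, 4)
  out <- combine_covariates(coh, list(anx_dep = c("anxiety", "depression")))
  expect_equal(out$anx_dep[1], 0.6)
  expect_true(all(c("anxiety", "depression") %in% names(out)))  # retained
  # idempotence when sources agree
  expect_equal(out$anx_dep[2:3], out$anxiety[2:3])
  # three-source generalized mean
  out3 <- combine_covariates(out, list(m3 = c("anxiety", "depression", "cannabis")))
  expect_equal(out3$m3, rowMeans(cbind(out$anxiety, out$depression, out$cannabis)))
  expect_error(combine_covariates(coh, list(z = c("absent"))), "missing source")
})

test_that("unadjusted screening recovers per-covariate effects on synthetic data", {
  m <- intensity_model("x")
  truth <- c(-4.4, -2.4, 0.5, 0)  # onset log-HR 0.5, remission 0
  pr <- list(x = list(type = "ar1", mean = 0, sd = 1, rho = 0.5, clamp = c(-4, 4)))
  spec <- cohort_spec(model = m, params = truth, covariate_processes = pr,
                      n_subjects = 2000, p_miss = 0)
  pairs <- build_transition_pairs(generate_cohort(spec, seed = 8))
  tab <- screen_unadjusted(pairs, "x", starts = 1)
  expect_equal(tab$onset_hr, exp(0.5), tolerance = 0.15)
  expect_equal(tab$remission_hr, 1, tolerance = 0.15)
  expect_true(is.na(tab$error))
  # empty covariate list gives an empty table
  expect_equal(nrow(screen_unadjusted(pairs, character(0))), 0)
})

test_that("state-dependence LRT has the declared boundary behaviour", {
  # strong same-signed effect on both transitions: constrained fit misfits
  spec <- cohort_spec("state_dependent", n_subjects = 599, seed = 21,
                      covariate_processes = default_covariate_processes()["cannabis"])
  pairs <- build_transition_pairs(generate_cohort(spec))
  res <- test_state_dependence(pairs, "cannabis", starts = 1)
  expect_gte(res$statistic, 0)
  expect_lt(res$p_value, 0.05)
  expect_equal(res$decision, "keep free")
  expect_equal(res$statistic,
               2 * (res$loglik_unconstrained - res$loglik_constrained),
               tolerance = 1e-10)
})

test_that("constraint selection applies the p-threshold rule monotonically", {
  fake <- function(cv, p) structure(list(covariate = cv, p_value = p),
                                    class = "state_dependence")
  res <- list(fake("a", 0.02), fake("b", 0.16), fake("c", 0.91))
  expect_equal(select_constraints(res, 0.20), "c")
  expect_equal(select_constraints(res, 0), c("a", "b", "c"))
  expect_equal(select_constraints(res, 0.95), character(0))
  # monotone in the threshold: the constraint set shrinks (or stays) as the
  # evidence bar for constraining rises
  ths <- c(0.01, 0.1, 0.2, 0.5, 0.92)
  sets <- lapply(ths, function(t) select_constraints(res, t))
  for (i in seq_len(length(ths) - 1))
    expect_true(all(sets[[i + 1]] %in% sets[[i]]))
})

test_that("final model honours mixed constrained/free structure", {
  spec <- cohort_spec("paper_like", n_subjects = 599, seed = 31)
  coh <- combine_covariates(generate_cohort(spec),
                            list(anx_dep = c("anxiety", "depression")))
  pairs <- build_transition_pairs(coh)
  fit <- fit_final_model(pairs, spec$model$covariates,
                         constrained = spec$model$constrained, starts = 1)
  expect_true(fit$convergence)
  hr <- hazard_ratios(fit)
  con <- hr[hr$constrained, ]
  for (cv in unique(con$covariate)) {
    on <- con$hr[con$covariate == cv & con$transition == "onset"]
    re <- con$hr[con$covariate == cv & con$transition == "remission"]
    expect_equal(on * re, 1, tolerance = 1e-12)
  }
  # reduced demographics-only model still fits and reports 4 covariates
  fit2 <- fit_final_model(pairs, c("age", "male", "black", "public_assistance"),
                          starts = 1)
  expect_equal(nrow(format_hr_table(fit2)), 4)
  # constrained rows carry the dagger in the rendered table
  tab <- format_hr_table(fit)
  expect_true(all(grepl("†$",
                        tab$covariate[match(spec$model$constrained,
                                            sub("†$", "", tab$covariate))])))
})
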