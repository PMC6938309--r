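test_that("read_panel round-trips a small cohort and sorts rows", {
  df <- toy_cohort_df()
  path <- write_panel_csv(df[sample(nrow(df)), ])  # shuffled on disk
  coh <- read_panel(path, schema = list(cannabis = c(0, 6), male = c(0, 1)))
  expect_s3_class(coh, "panel_cohort")
  expect_equal(nrow(coh), 7)
  expect_equal(length(unique(coh$subject_id)), 3)
  expect_false(is.unsorted(coh$time[coh$subject_id == "A"], strictly = TRUE))
})

test_that("read_panel rejects invalid rows naming the offender", {
  df <- toy_cohort_df()
  df$state[4] <- 2
  expect_error(read_panel(write_panel_csv(df),
                          schema = list(cannabis = c(0, 6))),
               "state outside \\{0,1\\}.*4")
  df <- toy_cohort_df()
  df$time[2] <- 0  # duplicate (A, 0)
  expect_error(read_panel(write_panel_csv(df), schema = list()),
               "duplicate \\(subject, time\\)")
  df <- toy_cohort_df()
  df$cannabis[1] <- 9
  expect_error(read_panel(write_panel_csv(df),
                          schema = list(cannabis = c(0, 6))),
               "outside declared range.*9")
})

test_that("header-only file yields an empty cohort with a warning", {
  path <- write_panel_csv(toy_cohort_df()[0, ])
  expect_warning(coh <- read_panel(path, schema = list()), "header only")
  expect_equal(nrow(coh), 0)
  expect_equal(nrow(build_transition_pairs(coh)), 0)
})

test_that("transition pairs enumerate consecutive observed assessments", {
  pairs <- build_transition_pairs(toy_cohort())
  # observations minus subjects
  expect_equal(nrow(pairs), 7 - 3)
  a <- pairs[pairs$subject_id == "A", ]
  expect_equal(a$pre_state, c(0, 0, 1))
  expect_equal(a$post_state, c(0, 1, 0))
  expect_equal(a$dt, c(6, 6, 6))
  # a missed wave yields one pair with the actual elapsed gap
  b <- pairs[pairs$subject_id == "B", ]
  expect_equal(nrow(b), 1)
  expect_equal(b$dt, 12.7)
  # single-observation subject contributes no pairs
  expect_false("C" %in% pairs$subject_id)
})

test_that("pre-transition covariates come from the earlier observation", {
  coh <- toy_cohort()
  pairs <- build_transition_pairs(coh)
  df <- as.data.frame(coh)
  for (r in seq_len(nrow(pairs))) {
    src <- df[df$subject_id == pairs$subject_id[r] &
                abs((df$age - pairs$age_pre[r])) < 1e-12, ]
    expect_equal(pairs$cannabis[r], src$cannabis)
  }
})

test_that("pair construction is invariant to subject storage order", {
  df <- toy_cohort_df()
  sch <- list(cannabis = c(0, 6), male = c(0, 1))
  p1 <- build_transition_pairs(audmc:::as_panel_cohort(df, sch))
  p2 <- build_transition_pairs(
    audmc:::as_panel_cohort(df[rev(seq_len(nrow(df))), ], sch))
  key <- function(p) p[order(p$subject_id, p$dt, p$pre_state), ]
  expect_equal(key(p1), key(p2), ignore_attr = TRUE)
})

test_that("age stratification is an exhaustive disjoint partition at the cutoff", {
  pairs <- make_pairs(pre = rep(0, 10), post = rep(0, 10), dt = 6,
                      age_pre = c(20.9, 21.0, seq(14, 24, length.out = 8)))
  st <- stratify_by_age(pairs, cutoff = 21)
  expect_true(all(st$underage$age_pre < 21))
  expect_true(all(st$legal$age_pre >= 21))
  expect_true(20.9 %in% st$underage$age_pre)
  expect_true(21.0 %in% st$legal$age_pre)
  expect_equal(nrow(st$underage) + nrow(st$legal), 10)
  pairs$age_pre[3] <- NA
  expect_error(stratify_by_age(pairs), "missing age_pre")
})

test_that("pair count equals observations minus subjects for generated cohorts", {
  spec <- cohort_spec("null", n_subjects = 40, seed = 3)
  coh <- generate_cohort(spec)
  pairs <- build_transition_pairs(coh)
  expect_equal(nrow(pairs), nrow(coh) - length(unique(coh$subject_id)))
})
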