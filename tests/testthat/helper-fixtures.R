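# Fixtures built in code: tiny cohorts and pair tables for unit tests.

# A three-subject long-format cohort with a missed wave for subject B.
toy_cohort_df <- function() {
  data.frame(
    subject_id = c("A", "A", "A", "A", "B", "B", "C"),
    time = c(0, 6, 12, 18, 0, 12.7, 0),
    state = c(0, 0, 1, 0, 0, 1, 1),
    age = c(16, 16.5, 17, 17.5, 22, 23.06, 19),
    cannabis = c(1, 2, 3, 2, 0, 1, 4),
    male = c(1, 1, 1, 1, 0, 0, 1),
    stringsAsFactors = FALSE)
}

toy_cohort <- function() {
  audmc:::as_panel_cohort(toy_cohort_df(),
                          schema = list(cannabis = c(0, 6), male = c(0, 1)))
}

# Directly construct a transition-pair table (bypassing a cohort) with
# arbitrary covariate columns.
make_pairs <- function(pre, post, dt, age_pre = 20, ...) {
  n <- length(pre)
  out <- data.frame(subject_id = paste0("S", seq_len(n)),
                    pre_state = pre, post_state = post,
                    dt = rep_len(dt, n), age_pre = rep_len(age_pre, n),
                    stringsAsFactors = FALSE)
  out$age <- out$age_pre
  extra <- list(...)
  for (nm in names(extra)) out[[nm]] <- rep_len(extra[[nm]], n)
  class(out) <- c("transition_pairs", "data.frame")
  out
}

# Balanced pair table: k of each of the four pair types at a common gap.
balanced_pairs <- function(k = 2L, dt = 6) {
  make_pairs(pre = rep(c(0, 0, 1, 1), each = k),
             post = rep(c(0, 1, 0, 1), each = k),
             dt = dt)
}

# Write a CSV panel file and return its path.
write_panel_csv <- function(df, path = tempfile(fileext = ".csv")) {
  utils::write.csv(df, path, row.names = FALSE)
  path
}

# Closed-form two-state transition probability, written out independently
# of the package's implementation, for oracle checks.
oracle_p <- function(q01, q10, dt, from, to) {
  s <- q01 + q10
  p00 <- (q10 + q01 * exp(-s * dt)) / s
  p11 <- (q01 + q10 * exp(-s * dt)) / s
  if (from == 0) { if (to == 0) p00 else 1 - p00 }
  else { if (to == 1) p11 else 1 - p11 }
}
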