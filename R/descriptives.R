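#' Tabulate transition-pair counts
#'
#' Counts of the four consecutive-assessment pair types: persistence of
#' No-AUD (0 to 0), onset (0 to 1), remission (1 to 0) and persistence of
#' AUD (1 to 1).
#'
#' @param pairs A `transition_pairs` table.
#' @return A 2x2 contingency table, pre-state by post-state.
#' @export
tabulate_transitions <- function(pairs) {
  table(pre = factor(pairs$pre_state, levels = c(0, 1),
                     labels = c("NoAUD", "AUD")),
        post = factor(pairs$post_state, levels = c(0, 1),
                      labels = c("NoAUD", "AUD")))
}

#' Proportion of subjects with any AUD, by sex and age group
#'
#' Share of subjects diagnosed (state 1) at one or more assessments, in
#' cells of sex by baseline age band. A subject with AUD at several waves
#' counts once.
#'
#' @param cohort A `panel_cohort` with a `male` covariate column.
#' @param age_breaks Left-closed band edges for baseline age (default the
#'   14-17 / 18-20 / 21-24 bands).
#' @return Data frame with columns `sex`, `age_group`, `n_subjects`,
#'   `n_any_aud`, `proportion`; the overall proportion is attached as
#'   attribute `overall`.
#' @export
prevalence_any_aud <- function(cohort, age_breaks = c(14, 18, 21, 25)) {
  df <- as.data.frame(cohort)
  first <- !duplicated(df$subject_id)
  base <- df[first, c("subject_id", "age", "male")]
  ever <- tapply(df$state, df$subject_id, function(s) any(s == 1))
  base$ever_aud <- as.logical(ever[base$subject_id])
  labs <- paste(age_breaks[-length(age_breaks)],
                age_breaks[-1] - 1, sep = "-")
  base$age_group <- cut(base$age, breaks = age_breaks, labels = labs,
                        right = FALSE, include.lowest = TRUE)
  base$sex <- factor(ifelse(base$male == 1, "Male", "Female"),
                     levels = c("Female", "Male"))
  cells <- expand.grid(sex = levels(base$sex), age_group = labs,
                       stringsAsFactors = FALSE)
  cells$n_subjects <- NA_integer_
  cells$n_any_aud <- NA_integer_
  for (r in seq_len(nrow(cells))) {
    sel <- base$sex == cells$sex[r] &
      as.character(base$age_group) == cells$age_group[r]
    cells$n_subjects[r] <- sum(sel, na.rm = TRUE)
    cells$n_any_aud[r] <- sum(base$ever_aud[sel], na.rm = TRUE)
  }
  cells <- cells[cells$n_subjects > 0, , drop = FALSE]
  cells$proportion <- cells$n_any_aud / cells$n_subjects
  rownames(cells) <- NULL
  attr(cells, "overall") <- mean(base$ever_aud)
  cells
}

#' Grouped bar chart of any-AUD prevalence
#'
#' Renders the output of [prevalence_any_aud()] as a grouped bar chart
#' (base graphics), sexes side by side within age group.
#'
#' @param prev Output of [prevalence_any_aud()].
#' @param ... Passed to [graphics::barplot()].
#' @return The bar midpoints, invisibly.
#' @export
plot_prevalence <- function(prev, ...) {
  m <- tapply(prev$proportion, list(prev$sex, prev$age_group), identity)
  mid <- graphics::barplot(m, beside = TRUE, ylim = c(0, max(m, na.rm = TRUE) * 1.3),
                           legend.text = rownames(m),
                           ylab = "Proportion with any AUD",
                           xlab = "Baseline age group", ...)
  invisible(mid)
}

# Welch t-test p-value robust to degenerate groups: identical constant
# groups give p = 1, constant groups with different means give p ~ 0.
welch_p <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2L || length(y) < 2L) return(NA_real_)
  if (stats::sd(x) == 0 && stats::sd(y) == 0)
    return(if (isTRUE(all.equal(mean(x), mean(y)))) 1 else 0)
  tryCatch(stats::t.test(x, y)$p.value, error = function(e) NA_real_)
}

chisq_p <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (!length(x) || !length(y)) return(NA_real_)
  tab <- rbind(c(sum(x == 1), sum(x == 0)), c(sum(y == 1), sum(y == 0)))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) return(NA_real_)
  suppressWarnings(stats::chisq.test(tab, correct = TRUE)$p.value)
}

is_binary <- function(v) all(stats::na.omit(v) %in% c(0, 1))

#' Descriptive contrasts between transition types
#'
#' For each covariate, summarizes the four pair types (count and percent for
#' binary covariates, mean and SD for numeric ones) and tests two contrasts
#' on pre-transition values: the onset contrast (No-AUD pairs that did vs
#' did not transition to AUD) and the remission contrast (AUD pairs that did
#' vs did not transition to No-AUD). Numeric covariates use the Welch
#' unequal-variance t-test; binary covariates use the chi-square test with
#' continuity correction. Units are person-transition pairs, so a subject
#' can appear in several rows; no clustering adjustment is applied.
#'
#' @param pairs A `transition_pairs` table (typically one age stratum).
#' @param covariates Covariate names to contrast; defaults to every
#'   covariate column present.
#' @param alpha Flagging level for the `onset_sig`/`remission_sig` columns.
#' @return Data frame, one row per covariate, with per-group summaries,
#'   contrast p-values and significance flags.
#' @export
contrast_table <- function(pairs, covariates = NULL, alpha = 0.05) {
  if (is.null(covariates))
    covariates <- setdiff(names(pairs),
                          c("subject_id", "pre_state", "post_state", "dt",
                            "age_pre"))
  grp <- list(
    nn = pairs$pre_state == 0 & pairs$post_state == 0,
    na = pairs$pre_state == 0 & pairs$post_state == 1,
    an = pairs$pre_state == 1 & pairs$post_state == 0,
    aa = pairs$pre_state == 1 & pairs$post_state == 1)
  rows <- lapply(covariates, function(cv) {
    v <- pairs[[cv]]
    binary <- is_binary(v)
    summ <- vapply(grp, function(g) {
      x <- v[g]
      if (!length(x)) return("—")
      if (binary) sprintf("%d (%.1f%%)", sum(x == 1, na.rm = TRUE),
                          100 * mean(x == 1, na.rm = TRUE))
      else sprintf("%.2f (%.2f)", mean(x, na.rm = TRUE),
                   stats::sd(x, na.rm = TRUE))
    }, character(1))
    p_on <- if (binary) chisq_p(v[grp$na], v[grp$nn]) else welch_p(v[grp$na], v[grp$nn])
    p_re <- if (binary) chisq_p(v[grp$an], v[grp$aa]) else welch_p(v[grp$an], v[grp$aa])
    data.frame(covariate = cv, type = if (binary) "binary" else "numeric",
               no_to_no = summ[["nn"]], no_to_aud = summ[["na"]],
               aud_to_no = summ[["an"]], aud_to_aud = summ[["aa"]],
               onset_p = p_on, remission_p = p_re,
               onset_sig = !is.na(p_on) && p_on < alpha,
               remission_sig = !is.na(p_re) && p_re < alpha,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "group_n") <- vapply(grp, sum, integer(1))
  out
}
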