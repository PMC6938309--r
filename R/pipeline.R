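#' Run the full transition-modelling workflow on a cohort
#'
#' Orchestrates the whole procedure on one panel cohort: covariate
#' combination, transition-pair construction, age stratification,
#' descriptive contrasts, screening for model entry (a covariate enters a
#' stratum's model when either descriptive contrast is significant at the
#' screening level; demographic controls enter regardless), unadjusted
#' state-dependence tests per entered covariate, constraint selection at
#' the state-dependence threshold, the adjusted stratum fits, and
#' (optionally) the bootstrap lack-of-fit test. Every decision is recorded
#' in the returned manifest, and all randomness flows from one root seed
#' split per stage.
#'
#' @param cohort A `panel_cohort`.
#' @param config A [workflow_config()].
#' @param gof Run the lack-of-fit test per stratum?
#' @param gof_B Bootstrap iterations for the lack-of-fit test.
#' @param seed Root seed for the stochastic stages.
#' @param verbose Narrate each procedure decision via [message()].
#' @return Object of class `aud_analysis`: per-stratum descriptives,
#'   screening and state-dependence tables, final fits with hazard-ratio
#'   tables, optional `gof_result`s, cohort-level prevalence, and a run
#'   manifest (seeds, decisions, package version, timestamp).
#' @export
analyze_cohort <- function(cohort, config = workflow_config(), gof = TRUE,
                           gof_B = 1000L, seed = 1L, verbose = TRUE) {
  say <- function(...) if (verbose) message(...)
  stage_seed <- function(k) (as.integer(seed) * 113L + k) %% .Machine$integer.max

  if (length(config$combine)) {
    cohort <- combine_covariates(cohort, config$combine)
    say("combined covariates: ",
        paste(names(config$combine), vapply(config$combine, paste,
                                            character(1), collapse = "+"),
              sep = " = ", collapse = "; "))
  }
  pairs <- build_transition_pairs(cohort)
  strata <- stratify_by_age(pairs, cutoff = config$age_cutoff)
  say("built ", nrow(pairs), " transition pairs (",
      nrow(strata$underage), " underage, ", nrow(strata$legal), " legal)")

  candidates <- union("age", setdiff(attr(cohort, "covariates"),
                                     config$exclude))
  prevalence <- prevalence_any_aud(cohort)

  decisions <- list()
  strata_out <- list()
  for (snm in names(strata)) {
    sp <- strata[[snm]]
    out <- list(n_pairs = nrow(sp),
                transitions = tabulate_transitions(sp))
    n_trans <- sum(out$transitions[1, 2], out$transitions[2, 1])
    if (nrow(sp) < 10L || out$transitions[1, 2] == 0L ||
        out$transitions[2, 1] == 0L) {
      say(snm, ": insufficient transitions (", n_trans,
          "); descriptives only")
      out$insufficient <- TRUE
      out$contrasts <- if (nrow(sp)) contrast_table(sp, candidates,
                                                    config$screen_alpha)
      strata_out[[snm]] <- out
      decisions[[snm]] <- list(skipped = "insufficient transitions")
      next
    }
    out$insufficient <- FALSE
    out$contrasts <- contrast_table(sp, candidates, config$screen_alpha)

    ct <- out$contrasts
    screened_in <- ct$covariate[ct$onset_sig | ct$remission_sig]
    entered <- union(intersect(config$always_include, candidates),
                     screened_in)
    entered <- intersect(candidates, entered)  # stable order
    say(snm, ": screened in ", paste(screened_in, collapse = ", "),
        "; model covariates: ", paste(entered, collapse = ", "))

    sd_tests <- lapply(entered, function(cv)
      tryCatch(test_state_dependence(sp, cv, threshold = config$sd_threshold,
                                     starts = 1L),
               error = function(e) {
                 say(snm, ": state-dependence test failed for ", cv, ": ",
                     conditionMessage(e))
                 NULL
               }))
    sd_tests <- Filter(Negate(is.null), sd_tests)
    constrained <- select_constraints(sd_tests, config$sd_threshold)
    say(snm, ": constrained across states: ",
        if (length(constrained)) paste(constrained, collapse = ", ") else "(none)")

    out$screen <- screen_unadjusted(sp, entered, starts = 1L)
    out$screen$state_dependence_p <-
      vapply(out$screen$covariate, function(cv) {
        hit <- Filter(function(r) r$covariate == cv, sd_tests)
        if (length(hit)) hit[[1]]$p_value else NA_real_
      }, numeric(1))

    out$fit <- fit_final_model(sp, entered, constrained,
                               seed = stage_seed(match(snm, names(strata))))
    out$hr <- hazard_ratios(out$fit)
    out$hr_table <- format_hr_table(out$fit)

    if (gof) {
      out$gof <- bootstrap_pvalue(out$fit, sp, B = gof_B,
                                  seed = stage_seed(10L + match(snm, names(strata))))
      say(snm, ": lack-of-fit T = ", round(out$gof$statistic, 2),
          ", bootstrap p = ", round(out$gof$p_value, 3))
    }
    decisions[[snm]] <- list(
      screened_in = screened_in, entered = entered,
      constrained = constrained,
      state_dependence_p = stats::setNames(
        vapply(sd_tests, function(r) r$p_value, numeric(1)),
        vapply(sd_tests, function(r) r$covariate, character(1))))
    strata_out[[snm]] <- out
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("audmc")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    cohort_source = attr(cohort, "source"),
    cohort_seed = attr(cohort, "seed"),
    root_seed = seed,
    stage_seeds = list(fit = c(stage_seed(1L), stage_seed(2L)),
                       gof = c(stage_seed(11L), stage_seed(12L))),
    config = unclass(config),
    gof_B = if (gof) gof_B else NULL,
    decisions = decisions)

  structure(list(prevalence = prevalence, strata = strata_out,
                 pairs = pairs, manifest = manifest),
            class = "aud_analysis")
}

#' @export
print.aud_analysis <- function(x, ...) {
  cat("AUD transition analysis\n")
  cat(sprintf("  overall any-AUD prevalence: %.1f%%\n",
              100 * attr(x$prevalence, "overall")))
  for (snm in names(x$strata)) {
    s <- x$strata[[snm]]
    cat("\n== stratum:", snm, "(", s$n_pairs, "pairs ) ==\n")
    print(s$transitions)
    if (isTRUE(s$insufficient)) {
      cat("  insufficient transitions for modelling\n")
      next
    }
    cat("\nAdjusted hazard ratios († = constrained across states):\n")
    print(s$hr_table, row.names = FALSE)
    if (!is.null(s$gof))
      cat(sprintf("lack-of-fit: T = %.2f, bootstrap p = %.3f\n",
                  s$gof$statistic, s$gof$p_value))
  }
  invisible(x)
}

#' Write the analysis report to disk
#'
#' Emits, under `dir`: per-stratum descriptive-contrast CSVs (`table1_*`),
#' unadjusted screening/state-dependence CSVs (`table2_*`), adjusted
#' hazard-ratio CSVs (`table3_*`), a prevalence bar chart (PNG), lack-of-fit
#' JSONs, and the run manifest JSON.
#'
#' @param analysis An `aud_analysis`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_report <- function(analysis, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(analysis$prevalence,
                   file.path(dir, "prevalence_by_sex_age.csv"),
                   row.names = FALSE)
  grDevices::png(file.path(dir, "prevalence_by_sex_age.png"),
                 width = 800, height = 500)
  plot_prevalence(analysis$prevalence)
  grDevices::dev.off()
  for (snm in names(analysis$strata)) {
    s <- analysis$strata[[snm]]
    if (!is.null(s$contrasts))
      utils::write.csv(s$contrasts,
                       file.path(dir, paste0("table1_", snm, ".csv")),
                       row.names = FALSE)
    if (isTRUE(s$insufficient)) next
    utils::write.csv(s$screen,
                     file.path(dir, paste0("table2_", snm, ".csv")),
                     row.names = FALSE)
    utils::write.csv(s$hr_table,
                     file.path(dir, paste0("table3_", snm, ".csv")),
                     row.names = FALSE)
    jsonlite::write_json(
      list(estimate = as.list(s$fit$estimate),
           loglik = s$fit$loglik,
           vcov = s$fit$vcov),
      file.path(dir, paste0("fit_", snm, ".json")),
      auto_unbox = TRUE, digits = NA)
    if (!is.null(s$gof))
      jsonlite::write_json(
        list(statistic = s$gof$statistic, p_value = s$gof$p_value,
             B = s$gof$B, refit = s$gof$refit,
             cells = s$gof$cells),
        file.path(dir, paste0("gof_", snm, ".json")),
        auto_unbox = TRUE, digits = NA)
  }
  jsonlite::write_json(analysis$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  invisible(dir)
}
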