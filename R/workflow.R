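#' Combine covariates by averaging
#'
#' Adds a new covariate equal to the element-wise mean of the named source
#' covariates (used for collinear symptom scales, e.g. averaging the BSI
#' anxiety and depression means into one internalizing-symptoms score).
#' Sources are retained in the cohort for descriptives; the analysis
#' workflow excludes them from models once combined.
#'
#' @param cohort A `panel_cohort` (or `transition_pairs` table).
#' @param rule Named list: new covariate name mapped to a character vector
#'   of source covariate names, e.g. `list(anx_dep = c("anxiety", "depression"))`.
#' @return The input with the new column(s) added; the schema attribute is
#'   extended with the combined covariate's range (the widest source range).
#' @export
combine_covariates <- function(cohort, rule) {
  stopifnot(is.list(rule), !is.null(names(rule)))
  schema <- attr(cohort, "schema")
  covs <- attr(cohort, "covariates")
  for (new in names(rule)) {
    src <- rule[[new]]
    miss <- setdiff(src, names(cohort))
    if (length(miss))
      stop("combine_covariates: missing source covariate(s): ",
           paste(miss, collapse = ", "))
    cohort[[new]] <- rowMeans(as.data.frame(cohort)[, src, drop = FALSE])
    if (!is.null(schema)) {
      rngs <- do.call(rbind, schema[src])
      schema[[new]] <- c(min(rngs[, 1]), max(rngs[, 2]))
    }
    if (!is.null(covs)) covs <- union(covs, new)
  }
  attr(cohort, "schema") <- schema
  attr(cohort, "covariates") <- covs
  cohort
}

#' Workflow configuration
#'
#' Bundles the tunable thresholds and rules of the model-building procedure:
#' the descriptive screening level for model entry, the (deliberately
#' liberal) state-dependence threshold below which a covariate keeps
#' separate onset/remission effects, the demographic covariates included
#' regardless of significance, the covariate-combination rules, and the age
#' cutoff for stratification.
#'
#' @param screen_alpha Entry level for the descriptive contrasts (default
#'   0.05): a covariate enters a stratum's model if either its onset or its
#'   remission contrast is significant at this level.
#' @param sd_threshold State-dependence threshold (default 0.20): effects
#'   are constrained across states when the state-dependence p-value
#'   exceeds it.
#' @param always_include Covariates included regardless of screening
#'   (demographic controls).
#' @param combine Covariate-combination rules for [combine_covariates()].
#' @param exclude Covariates never offered to the models (e.g. sources of a
#'   combined score).
#' @param age_cutoff Stratification cutoff in years.
#' @return List of class `workflow_config`.
#' @export
workflow_config <- function(screen_alpha = 0.05,
                            sd_threshold = 0.20,
                            always_include = c("age", "male", "black",
                                               "public_assistance"),
                            combine = list(anx_dep = c("anxiety", "depression")),
                            exclude = c("anxiety", "depression"),
                            age_cutoff = 21) {
  stopifnot(screen_alpha > 0, screen_alpha < 1,
            sd_threshold > 0, sd_threshold < 1)
  structure(list(screen_alpha = screen_alpha, sd_threshold = sd_threshold,
                 always_include = always_include, combine = combine,
                 exclude = exclude, age_cutoff = age_cutoff),
            class = "workflow_config")
}

#' Unadjusted single-covariate screening fits
#'
#' Fits, for each covariate separately, the unconstrained model with
#' intercepts plus that covariate's two free coefficients, and reports the
#' onset and remission hazard ratios with confidence intervals (the
#' unadjusted columns of the state-dependence report). Per-covariate fit
#' failures are reported in the table without aborting the batch.
#'
#' @param pairs Stratum `transition_pairs`.
#' @param covariates Covariate names to screen.
#' @param level Confidence level.
#' @param ... Passed to [fit_mle()].
#' @return Data frame, one row per covariate: `onset_hr`, `onset_lower`,
#'   `onset_upper`, `remission_*`, `loglik`, `error` (NA when the fit
#'   succeeded).
#' @export
screen_unadjusted <- function(pairs, covariates, level = 0.95, ...) {
  rows <- lapply(covariates, function(cv) {
    res <- tryCatch({
      fit <- fit_mle(intensity_model(cv), pairs, ...)
      hr <- hazard_ratios(fit, level)
      on <- hr[hr$transition == "onset", ]
      re <- hr[hr$transition == "remission", ]
      data.frame(covariate = cv,
                 onset_hr = on$hr, onset_lower = on$lower,
                 onset_upper = on$upper,
                 remission_hr = re$hr, remission_lower = re$lower,
                 remission_upper = re$upper,
                 loglik = fit$loglik, error = NA_character_,
                 stringsAsFactors = FALSE)
    }, error = function(e) {
      data.frame(covariate = cv, onset_hr = NA_real_, onset_lower = NA_real_,
                 onset_upper = NA_real_, remission_hr = NA_real_,
                 remission_lower = NA_real_, remission_upper = NA_real_,
                 loglik = NA_real_, error = conditionMessage(e),
                 stringsAsFactors = FALSE)
    })
    res
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(covariate = character(0), onset_hr = numeric(0),
                      onset_lower = numeric(0), onset_upper = numeric(0),
                      remission_hr = numeric(0), remission_lower = numeric(0),
                      remission_upper = numeric(0), loglik = numeric(0),
                      error = character(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Likelihood-ratio test of covariate state-dependence
#'
#' Tests whether a covariate's effect on future AUD depends on the current
#' state: the null constrains the onset and remission coefficients to be
#' equal and opposite (`beta_onset = -beta_remission`), i.e. the hazard of
#' future AUD does not depend on the current state. Both the unconstrained
#' and the constrained single-covariate models are fit by maximum
#' likelihood; the statistic is twice the log-likelihood difference,
#' referred to chi-square with 1 degree of freedom.
#'
#' @param pairs Stratum `transition_pairs`.
#' @param covariate Covariate name.
#' @param threshold Decision threshold: the effect is constrained when
#'   `p > threshold` (default 0.20).
#' @param ... Passed to [fit_mle()].
#' @return List of class `state_dependence`: covariate, the two
#'   log-likelihoods, `statistic`, `df`, `p_value`, `decision`
#'   (`"constrain"`/`"keep free"`).
#' @export
test_state_dependence <- function(pairs, covariate, threshold = 0.20, ...) {
  fit_u <- tryCatch(fit_mle(intensity_model(covariate), pairs, ...),
                    error = function(e)
                      stop("unconstrained fit failed for '", covariate,
                           "': ", conditionMessage(e)))
  fit_c <- tryCatch(fit_mle(intensity_model(covariate, constrained = covariate),
                            pairs, ...),
                    error = function(e)
                      stop("constrained fit failed for '", covariate,
                           "': ", conditionMessage(e)))
  if (!isTRUE(fit_u$convergence))
    stop("unconstrained fit did not converge for '", covariate, "'")
  if (!isTRUE(fit_c$convergence))
    stop("constrained fit did not converge for '", covariate, "'")
  stat <- max(0, 2 * (fit_u$loglik - fit_c$loglik))
  p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  structure(list(covariate = covariate,
                 loglik_unconstrained = fit_u$loglik,
                 loglik_constrained = fit_c$loglik,
                 statistic = stat, df = 1L, p_value = p,
                 decision = if (p > threshold) "constrain" else "keep free",
                 threshold = threshold),
            class = "state_dependence")
}

#' @export
print.state_dependence <- function(x, ...) {
  cat("State-dependence LRT for '", x$covariate, "'\n", sep = "")
  cat(sprintf("  chi-square(1) = %.3f, p = %.3f -> %s (threshold %.2f)\n",
              x$statistic, x$p_value, x$decision, x$threshold))
  invisible(x)
}

#' Select the constraint set from state-dependence results
#'
#' Covariates with little evidence of state-dependence (`p > threshold`)
#' enter the constraint map of the adjusted model, borrowing information
#' across states; the rest keep free onset and remission coefficients.
#' Monotone in the threshold: raising it never removes a covariate from
#' the constraint set.
#'
#' @param results List of `state_dependence` objects.
#' @param threshold Constraint threshold (default 0.20).
#' @return Character vector of covariates to constrain.
#' @export
select_constraints <- function(results, threshold = 0.20) {
  p <- vapply(results, function(r) r$p_value, numeric(1))
  nm <- vapply(results, function(r) r$covariate, character(1))
  nm[p > threshold]
}

#' Fit the adjusted (final) stratum model
#'
#' One joint fit with all entered covariates, those in the constraint set
#' sharing a single coefficient with opposite signs across states.
#'
#' @param pairs Stratum `transition_pairs`.
#' @param covariates All covariates in the model (screened-in plus
#'   demographic controls).
#' @param constrained Subset to constrain across states.
#' @param ... Passed to [fit_mle()].
#' @return An `aud_fit`; its hazard-ratio table flags constrained rows, and
#'   [format_hr_table()] renders them with a dagger.
#' @export
fit_final_model <- function(pairs, covariates, constrained = character(), ...) {
  fit_mle(intensity_model(covariates, constrained = constrained), pairs, ...)
}
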