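#' Default time-varying covariate processes for the synthetic cohort
#'
#' Each numeric covariate follows a clamped stationary AR(1) on its
#' instrument scale: initial draw N(mean, sd), then
#' `x_{t+1} = mean + rho (x_t - mean) + N(0, sd sqrt(1 - rho^2))`, clamped
#' to the instrument range. Wave-level binary covariates (victimization
#' indicators) persist with probability `rho` and are otherwise redrawn
#' Bernoulli(mean). Means and SDs are set to the magnitudes typical of the
#' emulated instruments (BSI symptom means near 0.5 with SD near 0.8,
#' ASSIST cannabis severity near 1.7 with SD 1.4, drinking and support
#' scales between 1 and 5, community violence near 1.5).
#'
#' @return Named list of process descriptions.
#' @export
default_covariate_processes <- function() {
  num <- function(mean, sd, rho, clamp)
    list(type = "ar1", mean = mean, sd = sd, rho = rho, clamp = clamp)
  bin <- function(p, rho) list(type = "binary_markov", p = p, rho = rho)
  list(
    anxiety = num(0.55, 0.80, 0.6, c(0, 4)),
    depression = num(0.70, 0.85, 0.6, c(0, 4)),
    cannabis = num(1.70, 1.40, 0.7, c(0, 6)),
    parental_drinking = num(1.50, 0.75, 0.6, c(1, 5)),
    parental_support = num(3.10, 1.30, 0.7, c(1, 5)),
    friend_drinking = num(2.40, 1.10, 0.6, c(1, 5)),
    positive_peer = num(2.15, 0.72, 0.6, c(1, 4)),
    community_violence = num(1.50, 0.90, 0.7, c(1, 4)),
    partner_victimization = bin(0.45, 0.5),
    nonpartner_victimization = bin(0.40, 0.5)
  )
}

# Reference covariate profile at which the preset baseline intensities are
# anchored (process means plus the cohort's demographic mix and mid age).
reference_profile <- function() {
  c(age = 20.5, male = 0.588, black = 0.583, public_assistance = 0.730,
    anx_dep = 0.625, parental_drinking = 1.50, friend_drinking = 2.40,
    community_violence = 1.50, cannabis = 1.70)
}

# Preset truths. Baseline intensities at the reference profile are anchored
# to the crude rates implied by the emulated study's transition tallies
# (events over person-months at risk): ~0.0117 onsets and ~0.093
# remissions per person-month.
preset_truth <- function(preset) {
  q01_ref <- 0.0117
  q10_ref <- 0.093
  zref <- reference_profile()
  switch(preset,
    null = {
      list(model = intensity_model(), params = c(log(0.02), log(0.02)))
    },
    paper_like = {
      covs <- c("age", "male", "anx_dep", "parental_drinking",
                "friend_drinking", "black", "public_assistance",
                "community_violence", "cannabis")
      constrained <- c("black", "public_assistance", "community_violence",
                       "cannabis")
      model <- intensity_model(covs, constrained = constrained)
      b_on <- c(age = log(0.83), male = log(2.28), anx_dep = log(0.95),
                parental_drinking = log(0.62), friend_drinking = log(1.70))
      b_re <- c(age = log(0.71), male = log(1.57), anx_dep = log(0.76),
                parental_drinking = log(0.53), friend_drinking = log(1.26))
      g <- c(black = log(0.73), public_assistance = log(0.87),
             community_violence = log(1.04), cannabis = log(1.18))
      free <- model$free
      a01 <- log(q01_ref) - sum(b_on[free] * zref[free]) -
        sum(g * zref[names(g)])
      a10 <- log(q10_ref) - sum(b_re[free] * zref[free]) +
        sum(g * zref[names(g)])
      list(model = model,
           params = stats::setNames(c(a01, a10, b_on[free], b_re[free], g),
                                    model$par_names))
    },
    state_dependent = {
      model <- intensity_model("cannabis")
      b <- 0.5  # same-signed effect on both transitions: strong state-dependence
      a01 <- log(q01_ref) - b * zref[["cannabis"]]
      a10 <- log(q10_ref) - b * zref[["cannabis"]]
      list(model = model,
           params = stats::setNames(c(a01, a10, b, b), model$par_names))
    },
    stop("unknown preset: ", preset)
  )
}

#' Describe a synthetic panel cohort
#'
#' Full generative description of a cohort emulating the study design the
#' package targets: baseline plus four biannual follow-ups (waves ~6 months
#' apart with small jitter), per-wave missingness, the observed demographic
#' mix (58.8% male, 58.3% Black, 73.0% on public assistance), baseline age
#' uniform over 14-24, AR(1) time-varying covariates on their instrument
#' scales, and AUD state paths generated from a log-linear intensity model.
#'
#' Presets for the true model: `"paper_like"` (the adjusted-model hazard
#' ratios of the emulated study as generating coefficients, with the same
#' four covariates constrained across states), `"null"` (no covariate
#' effects, symmetric intensities log 0.02), and `"state_dependent"`
#' (a cannabis effect of +0.5 on both transitions, violating the
#' no-state-dependence null).
#'
#' @param preset Truth preset name (ignored when `model`/`params` given).
#' @param n_subjects Number of subjects (default 599).
#' @param n_waves Assessments per subject including baseline (default 5).
#' @param gap_mean,gap_sd Mean and jitter SD of inter-wave gaps, months.
#' @param p_miss Per-follow-up-wave missingness probability (default 0.163,
#'   the complement of the emulated design's 83.7% retention floor).
#' @param p_male,p_black,p_assist Baseline demographic probabilities.
#' @param age_range Baseline age range in years.
#' @param p_baseline_aud Probability of the AUD state at baseline.
#' @param model,params Optional explicit true [intensity_model()] and
#'   parameter vector, overriding the preset.
#' @param covariate_processes Optional override of
#'   [default_covariate_processes()] (only listed processes are generated).
#' @param seed Default seed used by [generate_cohort()].
#' @return List of class `cohort_spec`.
#' @export
cohort_spec <- function(preset = c("paper_like", "null", "state_dependent"),
                        n_subjects = 599L, n_waves = 5L,
                        gap_mean = 6, gap_sd = 0.4, p_miss = 0.163,
                        p_male = 0.588, p_black = 0.583, p_assist = 0.730,
                        age_range = c(14, 24), p_baseline_aud = 0.12,
                        model = NULL, params = NULL,
                        covariate_processes = default_covariate_processes(),
                        seed = NULL) {
  preset <- match.arg(preset)
  if (is.null(model) != is.null(params))
    stop("supply both 'model' and 'params', or neither")
  truth <- if (is.null(model)) preset_truth(preset) else
    list(model = model, params = stats::setNames(as.numeric(params),
                                                 model$par_names))
  probs <- c(p_miss = p_miss, p_male = p_male, p_black = p_black,
             p_assist = p_assist, p_baseline_aud = p_baseline_aud)
  if (any(probs < 0 | probs >= 1 + 1e-12) || p_miss >= 1)
    stop("probabilities must lie in [0, 1): ",
         paste(names(probs)[probs < 0 | probs >= 1], collapse = ", "))
  stopifnot(n_subjects >= 1, n_waves >= 1, gap_mean > 0, gap_sd >= 0,
            length(age_range) == 2, age_range[1] < age_range[2])
  for (pr in covariate_processes) {
    if (pr$type == "ar1" && (pr$rho < 0 || pr$rho >= 1))
      stop("AR(1) persistence rho must lie in [0, 1)")
  }
  structure(list(preset = preset, n_subjects = as.integer(n_subjects),
                 n_waves = as.integer(n_waves), gap_mean = gap_mean,
                 gap_sd = gap_sd, p_miss = p_miss, p_male = p_male,
                 p_black = p_black, p_assist = p_assist,
                 age_range = age_range, p_baseline_aud = p_baseline_aud,
                 model = truth$model, params = truth$params,
                 covariate_processes = covariate_processes, seed = seed),
            class = "cohort_spec")
}

clamp <- function(x, rng) pmin(pmax(x, rng[1]), rng[2])

#' Generate a synthetic panel cohort
#'
#' Draws demographics, baseline ages and jittered wave times, evolves
#' time-varying covariates by clamped AR(1) (binary indicators by a sticky
#' Bernoulli), and evolves the AUD state wave to wave by sampling directly
#' from the closed-form transition probability `P(dt)` at the earlier
#' wave's covariates under the spec's true intensity model — the exact
#' marginal at the observation times, which is all the panel likelihood
#' sees. Follow-up waves are then removed independently with the spec's
#' missingness probability (covariates measured at a missed wave are
#' removed with it). Deterministic given the seed.
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer seed (defaults to `spec$seed`).
#' @return A `panel_cohort` in the same long format as [read_panel()]
#'   ingests, with the spec and seed attached as attributes.
#' @export
generate_cohort <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (!is.null(seed)) set.seed(seed)
  n <- spec$n_subjects
  W <- spec$n_waves
  ids <- sprintf("S%0*d", nchar(n) + 1L, seq_len(n))

  male <- stats::rbinom(n, 1, spec$p_male)
  black <- stats::rbinom(n, 1, spec$p_black)
  assist <- stats::rbinom(n, 1, spec$p_assist)
  age0 <- stats::runif(n, spec$age_range[1], spec$age_range[2])

  times <- matrix(0, n, W)
  if (W > 1) {
    gaps <- matrix(stats::rnorm(n * (W - 1), spec$gap_mean, spec$gap_sd),
                   n, W - 1)
    gaps <- pmax(gaps, 0.5)  # gaps are positive by design; guard the tail
    times[, -1] <- t(apply(gaps, 1, cumsum))
  }

  # time-varying covariates, one n x W matrix each
  covmats <- list()
  for (nm in names(spec$covariate_processes)) {
    pr <- spec$covariate_processes[[nm]]
    X <- matrix(NA_real_, n, W)
    if (pr$type == "ar1") {
      X[, 1] <- clamp(stats::rnorm(n, pr$mean, pr$sd), pr$clamp)
      innov_sd <- pr$sd * sqrt(1 - pr$rho^2)
      for (w in seq_len(W - 1L))
        X[, w + 1L] <- clamp(pr$mean + pr$rho * (X[, w] - pr$mean) +
                               stats::rnorm(n, 0, innov_sd), pr$clamp)
    } else if (pr$type == "binary_markov") {
      X[, 1] <- stats::rbinom(n, 1, pr$p)
      for (w in seq_len(W - 1L)) {
        stay <- stats::rbinom(n, 1, pr$rho)
        X[, w + 1L] <- ifelse(stay == 1, X[, w], stats::rbinom(n, 1, pr$p))
      }
    } else stop("unknown covariate process type: ", pr$type)
    covmats[[nm]] <- X
  }

  model_covs <- spec$model$covariates
  wave_design <- function(w) {
    Z <- matrix(0, n, length(model_covs),
                dimnames = list(NULL, model_covs))
    for (cv in model_covs) {
      Z[, cv] <- switch(cv,
        age = age0 + times[, w] / 12,
        male = male, black = black, public_assistance = assist,
        anx_dep = (covmats[["anxiety"]][, w] + covmats[["depression"]][, w]) / 2,
        {
          if (is.null(covmats[[cv]]))
            stop("true model covariate '", cv, "' has no generating process")
          covmats[[cv]][, w]
        })
    }
    Z
  }

  states <- matrix(NA_integer_, n, W)
  states[, 1] <- stats::rbinom(n, 1, spec$p_baseline_aud)
  if (W > 1) {
    for (w in seq_len(W - 1L)) {
      Z <- wave_design(w)
      lp <- linear_predictors(spec$model, spec$params, Z)
      dt <- times[, w + 1L] - times[, w]
      pr <- pair_probs(exp(lp$eta01), exp(lp$eta10), dt,
                       pre = states[, w], post = rep(1L, n), deriv = FALSE)
      states[, w + 1L] <- stats::rbinom(n, 1, pr$p)
    }
  }

  df <- data.frame(
    subject_id = rep(ids, each = W),
    time = as.vector(t(times)),
    state = as.integer(t(states)),
    age = rep(age0, each = W) + as.vector(t(times)) / 12,
    male = rep(male, each = W),
    black = rep(black, each = W),
    public_assistance = rep(assist, each = W),
    stringsAsFactors = FALSE)
  for (nm in names(covmats)) df[[nm]] <- as.vector(t(covmats[[nm]]))

  cohort <- as_panel_cohort(df, schema = aud_schema(),
                            source = paste0("synthetic:", spec$preset),
                            seed = seed, validate = FALSE)
  attr(cohort, "spec") <- spec
  if (spec$p_miss > 0)
    cohort <- inject_missingness(cohort, spec$p_miss)
  cohort
}

#' Remove follow-up assessments at random
#'
#' Independently removes each non-baseline observation with probability
#' `p_miss` (missing completely at random), emulating per-wave panel
#' attrition; baseline observations are never removed, and covariates
#' measured at a missed wave are removed with it. Downstream,
#' [build_transition_pairs()] spans missed waves with longer gaps.
#'
#' @param cohort A `panel_cohort`.
#' @param p_miss Missingness probability in `[0, 1)`.
#' @param seed Optional seed (omit to continue the current RNG stream).
#' @return The thinned `panel_cohort`.
#' @export
inject_missingness <- function(cohort, p_miss, seed = NULL) {
  if (p_miss < 0 || p_miss >= 1)
    stop("p_miss must lie in [0, 1), got ", p_miss)
  if (!is.null(seed)) set.seed(seed)
  if (p_miss == 0) return(cohort)
  baseline <- !duplicated(cohort$subject_id)
  drop <- stats::rbinom(nrow(cohort), 1, p_miss) == 1 & !baseline
  out <- cohort[!drop, , drop = FALSE]
  for (a in c("schema", "source", "seed", "covariates", "spec"))
    attr(out, a) <- attr(cohort, a)
  out
}

#' Write a cohort to CSV
#'
#' Long-format CSV identical in schema to what [read_panel()] ingests.
#'
#' @param cohort A `panel_cohort`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE)
  invisible(path)
}
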