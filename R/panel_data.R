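#' Default covariate schema for an AUD panel cohort
#'
#' Names and admissible ranges for the covariates used in the
#' emergency-department cohort design this package emulates: demographic
#' indicators (male, Black race, public assistance), Brief Symptom Inventory
#' anxiety/depression means (0-4), ASSIST cannabis-use severity, peer and
#' parental drinking and support scales, community violence exposure, and
#' the two victimization indicators.
#'
#' @return Named list mapping covariate name to `c(min, max)`.
#' @export
aud_schema <- function() {
  list(
    male = c(0, 1),
    black = c(0, 1),
    public_assistance = c(0, 1),
    anxiety = c(0, 4),
    depression = c(0, 4),
    cannabis = c(0, 6),
    parental_drinking = c(1, 5),
    parental_support = c(1, 5),
    friend_drinking = c(1, 5),
    positive_peer = c(1, 4),
    community_violence = c(1, 4),
    partner_victimization = c(0, 1),
    nonpartner_victimization = c(0, 1)
  )
}

# Internal constructor + validator shared by read_panel() and the
# synthetic generator. `df` needs subject_id, time, state, age plus
# covariate columns.
as_panel_cohort <- function(df, schema = aud_schema(), source = "memory",
                            seed = NULL, validate = TRUE) {
  required <- c("subject_id", "time", "state", "age")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("cohort is missing required columns: ",
         paste(missing_cols, collapse = ", "))
  # every non-structural column is a covariate; the schema constrains the
  # ranges of those it declares
  covs <- setdiff(names(df), required)
  df <- df[order(df$subject_id, df$time), , drop = FALSE]
  rownames(df) <- NULL
  if (validate && nrow(df)) {
    dup <- duplicated(df[, c("subject_id", "time")])
    if (any(dup))
      stop("duplicate (subject, time) rows at row(s): ",
           paste(which(dup), collapse = ", "))
    bad_state <- which(!(df$state %in% c(0, 1)))
    if (length(bad_state))
      stop("state outside {0,1} at row(s): ",
           paste(bad_state, collapse = ", "),
           " (value ", df$state[bad_state[1L]], ")")
    bad_time <- which(df$time < 0)
    if (length(bad_time))
      stop("negative time at row(s): ", paste(bad_time, collapse = ", "))
    for (cv in intersect(covs, names(schema))) {
      rng <- schema[[cv]]
      v <- df[[cv]]
      bad <- which(!is.na(v) & (v < rng[1] | v > rng[2]))
      if (length(bad))
        stop("covariate '", cv, "' outside declared range [", rng[1], ", ",
             rng[2], "] at row ", bad[1L], " (value ", v[bad[1L]], ")")
    }
  }
  structure(df, class = c("panel_cohort", "data.frame"),
            schema = schema, source = source, seed = seed,
            covariates = covs)
}

#' Read a long-format panel cohort from CSV
#'
#' One row per subject-assessment with columns `subject_id`, `time` (months
#' since that subject's baseline), `state` (0 = No-AUD, 1 = AUD), `age`
#' (years at assessment), plus covariate columns declared in the schema.
#' Rows are sorted by subject then time and validated: duplicate
#' (subject, time) rows, states outside \{0, 1\}, and covariate values
#' outside their declared ranges are rejected with the offending row.
#'
#' @param path Path to a UTF-8 CSV file with a header.
#' @param schema Covariate schema: a named list of `c(min, max)` ranges (see
#'   [aud_schema()]), or a path to a YAML/JSON file declaring one.
#' @return A `panel_cohort` (a validated, ordered data frame with a schema
#'   attribute).
#' @export
read_panel <- function(path, schema = aud_schema()) {
  if (is.character(schema) && length(schema) == 1L)
    schema <- read_schema(schema)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) {
    warning("panel file ", path, " contains a header only; empty cohort")
  }
  as_panel_cohort(df, schema = schema, source = path)
}

# Schema files are flat maps name -> [min, max]; YAML (if available) or JSON.
read_schema <- function(path) {
  sch <- if (grepl("[.](ya?ml)$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML schemas requires the yaml package")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  lapply(sch, function(r) as.numeric(unlist(r)))
}

#' Build transition pairs from a panel cohort
#'
#' Forms one pair per consecutive pair of observed assessments within a
#' subject. The gap `dt` is the actual elapsed time, so a missed wave yields
#' a single pair with a roughly doubled gap rather than being dropped.
#' Covariates and age attach from the earlier (pre-transition) observation.
#' Subjects observed once contribute no pairs.
#'
#' @param cohort A `panel_cohort`.
#' @return Data frame of class `transition_pairs` with columns `subject_id`,
#'   `pre_state`, `post_state`, `dt`, `age_pre`, and one column per
#'   covariate holding its pre-transition value.
#' @export
build_transition_pairs <- function(cohort) {
  covs <- attr(cohort, "covariates")
  if (is.null(covs)) covs <- intersect(names(aud_schema()), names(cohort))
  df <- as.data.frame(cohort)
  if (nrow(df) < 2L)
    return(empty_pairs(covs))
  same_subject <- df$subject_id[-nrow(df)] == df$subject_id[-1L]
  i <- which(same_subject)          # index of the earlier observation
  if (!length(i)) return(empty_pairs(covs))
  out <- data.frame(subject_id = df$subject_id[i],
                    pre_state = df$state[i],
                    post_state = df$state[i + 1L],
                    dt = df$time[i + 1L] - df$time[i],
                    age_pre = df$age[i],
                    stringsAsFactors = FALSE)
  out$age <- df$age[i]  # pre-transition age, usable as a model covariate
  for (cv in covs) out[[cv]] <- df[[cv]][i]
  if (any(out$dt <= 0))
    stop("non-positive time gap between consecutive assessments of subject ",
         out$subject_id[which(out$dt <= 0)[1L]])
  class(out) <- c("transition_pairs", "data.frame")
  out
}

empty_pairs <- function(covs) {
  out <- data.frame(subject_id = character(0), pre_state = numeric(0),
                    post_state = numeric(0), dt = numeric(0),
                    age_pre = numeric(0), stringsAsFactors = FALSE)
  out$age <- numeric(0)
  for (cv in covs) out[[cv]] <- numeric(0)
  class(out) <- c("transition_pairs", "data.frame")
  out
}

#' Split transition pairs into age strata
#'
#' Assigns each pair to the underage or legal-drinking-age stratum by the
#' age at its pre-transition observation (`age_pre < cutoff` is underage),
#' so a pair straddling the cutoff birthday is classified by the state of
#' knowledge at the start of the interval, consistent with the use of
#' pre-transition covariates.
#'
#' @param pairs A `transition_pairs` table.
#' @param cutoff Age cutoff in years (default 21, the legal drinking age).
#' @return List with elements `underage` and `legal`, each a
#'   `transition_pairs` table; the two partition the input.
#' @export
stratify_by_age <- function(pairs, cutoff = 21) {
  if (anyNA(pairs$age_pre))
    stop("missing age_pre at pair(s): ",
         paste(which(is.na(pairs$age_pre)), collapse = ", "))
  under <- pairs$age_pre < cutoff
  list(underage = pairs[under, , drop = FALSE],
       legal = pairs[!under, , drop = FALSE])
}

#' Write transition pairs to CSV for audit
#'
#' @param pairs A `transition_pairs` table.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_pairs <- function(pairs, path) {
  utils::write.csv(as.data.frame(pairs), path, row.names = FALSE)
  invisible(path)
}
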