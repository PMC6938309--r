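#' Specify a two-state log-linear intensity model
#'
#' Defines the parameterization of a two-state continuous-time Markov chain
#' whose transition intensities depend log-linearly on covariates:
#' `log q_01 = alpha_onset + beta_onset . z` (No-AUD to AUD, "onset") and
#' `log q_10 = alpha_remission + beta_remission . z` (AUD to No-AUD,
#' "remission"). Covariates listed in `constrained` share a single
#' coefficient `gamma` with opposite signs across the two transitions
#' (`beta_onset = gamma`, `beta_remission = -gamma`), which makes their two
#' hazard ratios exact reciprocals.
#'
#' The free parameter vector is laid out as
#' `c(alpha_onset, alpha_remission, onset betas, remission betas, shared gammas)`,
#' with names returned in `$par_names`.
#'
#' @param covariates Character vector of covariate names entering the model.
#' @param constrained Subset of `covariates` whose effects are shared across
#'   states (one parameter, opposite signs).
#' @return An object of class `intensity_model`.
#' @examples
#' m <- intensity_model(c("cannabis", "male"), constrained = "cannabis")
#' m$par_names
#' @export
intensity_model <- function(covariates = character(), constrained = character()) {
  covariates <- as.character(covariates)
  constrained <- as.character(constrained)
  if (anyDuplicated(covariates))
    stop("duplicate covariate names: ",
         paste(unique(covariates[duplicated(covariates)]), collapse = ", "))
  missing_c <- setdiff(constrained, covariates)
  if (length(missing_c))
    stop("constrained covariates not in covariate list: ",
         paste(missing_c, collapse = ", "))
  free <- setdiff(covariates, constrained)
  par_names <- c("alpha_onset", "alpha_remission",
                 if (length(free)) paste0("onset_", free),
                 if (length(free)) paste0("remission_", free),
                 if (length(constrained)) paste0("shared_", constrained))
  structure(
    list(covariates = covariates, free = free, constrained = constrained,
         par_names = par_names, n_par = length(par_names)),
    class = "intensity_model"
  )
}

#' @export
print.intensity_model <- function(x, ...) {
  cat("Two-state log-linear intensity model\n")
  cat("  free covariates       :",
      if (length(x$free)) paste(x$free, collapse = ", ") else "(none)", "\n")
  cat("  constrained (b01=-b10):",
      if (length(x$constrained)) paste(x$constrained, collapse = ", ") else "(none)", "\n")
  cat("  parameters            :", x$n_par, "\n")
  invisible(x)
}

# Split a parameter vector into its blocks; returns named components.
split_params <- function(model, params) {
  if (length(params) != model$n_par)
    stop("expected ", model$n_par, " parameters, got ", length(params))
  nf <- length(model$free)
  nc <- length(model$constrained)
  list(
    alpha_onset = params[[1L]],
    alpha_remission = params[[2L]],
    beta_onset = if (nf) stats::setNames(params[3:(2 + nf)], model$free) else numeric(0),
    beta_remission = if (nf) stats::setNames(params[(3 + nf):(2 + 2 * nf)], model$free) else numeric(0),
    gamma = if (nc) stats::setNames(params[(3 + 2 * nf):model$n_par], model$constrained) else numeric(0)
  )
}

# Linear predictors for each transition given a covariate matrix Z
# (rows = pairs, columns named). Returns list(eta01, eta10).
linear_predictors <- function(model, params, Z) {
  sp <- split_params(model, params)
  eta01 <- rep(sp$alpha_onset, nrow(Z))
  eta10 <- rep(sp$alpha_remission, nrow(Z))
  if (length(model$free)) {
    Zf <- Z[, model$free, drop = FALSE]
    eta01 <- eta01 + drop(Zf %*% sp$beta_onset)
    eta10 <- eta10 + drop(Zf %*% sp$beta_remission)
  }
  if (length(model$constrained)) {
    Zc <- Z[, model$constrained, drop = FALSE]
    g <- drop(Zc %*% sp$gamma)
    eta01 <- eta01 + g
    eta10 <- eta10 - g
  }
  list(eta01 = eta01, eta10 = eta10)
}

#' Generator matrix for a covariate profile
#'
#' Evaluates the 2x2 intensity (generator) matrix `Q` at one covariate
#' vector: `q_01 = exp(alpha_onset + beta_onset . z)`,
#' `q_10 = exp(alpha_remission + beta_remission . z)`, diagonal entries the
#' negated row sums so rows sum to zero.
#'
#' @param model An [intensity_model()].
#' @param params Numeric parameter vector in the model's layout.
#' @param z Named numeric vector covering all model covariates.
#' @return A 2x2 generator matrix with dimnames `c("NoAUD", "AUD")`.
#' @export
build_generator <- function(model, params, z) {
  z <- z[model$covariates]
  if (length(model$covariates) && (anyNA(z) || is.null(names(z))))
    stop("covariate vector must name all model covariates: ",
         paste(model$covariates, collapse = ", "))
  Z <- matrix(as.numeric(z), nrow = 1,
              dimnames = list(NULL, model$covariates))
  lp <- linear_predictors(model, params, Z)
  if (abs(lp$eta01) > 50 || abs(lp$eta10) > 50)
    stop("linear predictor exceeds +/-50 (intensity would overflow) for ",
         "covariate configuration: ",
         paste(model$covariates, signif(z, 4), sep = "=", collapse = ", "))
  q01 <- exp(lp$eta01)
  q10 <- exp(lp$eta10)
  matrix(c(-q01, q10, q01, -q10), nrow = 2,
         dimnames = list(c("NoAUD", "AUD"), c("NoAUD", "AUD")))
}

#' Transition probability matrix over a time gap (closed form)
#'
#' For the two-state chain with onset intensity `q01` and remission
#' intensity `q10`, the transition probability matrix over a gap `dt` has
#' the closed form (with `s = q01 + q10`):
#' `P_00(dt) = (q10 + q01 e^{-s dt}) / s` when `s > 0`, identity otherwise;
#' remaining entries by complement and symmetry.
#'
#' @param Q 2x2 generator matrix (rows sum to zero, off-diagonals >= 0).
#' @param dt Non-negative time gap, in the same time unit as `Q` (months
#'   throughout this package).
#' @return A 2x2 stochastic matrix `P(dt)`.
#' @seealso [transition_matrix_expm()] for the general matrix-exponential
#'   evaluation used as a cross-check.
#' @export
transition_matrix <- function(Q, dt) {
  if (dt < 0) stop("dt must be non-negative, got ", dt)
  q01 <- Q[1, 2]
  q10 <- Q[2, 1]
  s <- q01 + q10
  if (s <= 0 || dt == 0) {
    P <- diag(2)
  } else {
    E <- exp(-s * dt)
    one_minus_E <- -expm1(-s * dt)
    P <- matrix(c((q10 + q01 * E) / s, q10 * one_minus_E / s,
                  q01 * one_minus_E / s, (q01 + q10 * E) / s),
                nrow = 2)
  }
  dimnames(P) <- dimnames(Q)
  P
}

#' Transition probability matrix via the matrix exponential
#'
#' General evaluation `P(dt) = expm(Q dt)` through [Matrix::expm()].
#' Used as an independent cross-check of the closed-form two-state solution;
#' works for any generator dimension.
#'
#' @inheritParams transition_matrix
#' @return A stochastic matrix of the same dimension as `Q`.
#' @export
transition_matrix_expm <- function(Q, dt) {
  if (dt < 0) stop("dt must be non-negative, got ", dt)
  P <- as.matrix(Matrix::expm(Matrix::Matrix(Q * dt)))
  dimnames(P) <- dimnames(Q)
  P
}

# Vectorized per-pair probability of the observed (pre, post) cell, with
# partial derivatives wrt q01 and q10. All arguments are equal-length
# vectors. Returns list(p, dp_dq01, dp_dq10).
pair_probs <- function(q01, q10, dt, pre, post, deriv = TRUE) {
  s <- q01 + q10
  E <- exp(-s * dt)
  one_minus_E <- -expm1(-s * dt)
  # cell probabilities
  P00 <- (q10 + q01 * E) / s
  P11 <- (q01 + q10 * E) / s
  p <- ifelse(pre == 0L,
              ifelse(post == 0L, P00, 1 - P00),
              ifelse(post == 1L, P11, 1 - P11))
  if (!deriv) return(list(p = p))
  # d/dq01, d/dq10 of P00 and P11 (dE/dq = -dt*E for either rate)
  dP00_d01 <- (E - q01 * dt * E) / s - P00 / s
  dP00_d10 <- (1 - q01 * dt * E) / s - P00 / s
  dP11_d01 <- (1 - q10 * dt * E) / s - P11 / s
  dP11_d10 <- (E - q10 * dt * E) / s - P11 / s
  dp01 <- ifelse(pre == 0L,
                 ifelse(post == 0L, dP00_d01, -dP00_d01),
                 ifelse(post == 1L, dP11_d01, -dP11_d01))
  dp10 <- ifelse(pre == 0L,
                 ifelse(post == 0L, dP00_d10, -dP00_d10),
                 ifelse(post == 1L, dP11_d10, -dP11_d10))
  list(p = p, dp_dq01 = dp01, dp_dq10 = dp10)
}

# Build the numeric design pieces the likelihood needs from a pair table.
# Drops pairs with missing covariate values (with a message when n > 0).
pair_design <- function(model, pairs, quiet = FALSE) {
  needed <- model$covariates
  missing_cols <- setdiff(needed, names(pairs))
  if (length(missing_cols))
    stop("pair table lacks model covariates: ",
         paste(missing_cols, collapse = ", "))
  Z <- if (length(needed)) {
    as.matrix(pairs[, needed, drop = FALSE])
  } else {
    matrix(numeric(0), nrow = nrow(pairs), ncol = 0)
  }
  keep <- if (ncol(Z)) stats::complete.cases(Z) else rep(TRUE, nrow(pairs))
  keep <- keep & !is.na(pairs$pre_state) & !is.na(pairs$post_state) &
    !is.na(pairs$dt)
  n_dropped <- sum(!keep)
  if (n_dropped > 0 && !quiet)
    message(n_dropped, " pair(s) dropped for missing covariate values")
  list(Z = Z[keep, , drop = FALSE],
       pre = as.integer(pairs$pre_state[keep]),
       post = as.integer(pairs$post_state[keep]),
       dt = as.numeric(pairs$dt[keep]),
       n_dropped = n_dropped)
}

#' Panel log-likelihood of a cohort of transition pairs
#'
#' Sums, over transition pairs, the log probability of the observed
#' post-state given the pre-state, the pair's time gap, and the generator
#' evaluated at the pair's pre-transition covariates (the Markov-assumption
#' panel likelihood). Summation is over the sorted log-probabilities so the
#' value is invariant to pair order.
#'
#' @param model An [intensity_model()].
#' @param params Parameter vector.
#' @param pairs Transition-pair table from [build_transition_pairs()].
#' @return The log-likelihood (scalar).
#' @export
cohort_loglik <- function(model, params, pairs) {
  if (nrow(pairs) == 0L) stop("no transition pairs supplied")
  d <- pair_design(model, pairs, quiet = TRUE)
  loglik_from_design(model, params, d, strict = TRUE)
}

# strict = TRUE enforces the user-facing error contract; the optimizer path
# instead clamps underflowed probabilities so line searches stay finite.
loglik_from_design <- function(model, params, d, strict = FALSE) {
  lp <- linear_predictors(model, params, d$Z)
  if (any(abs(lp$eta01) > 50) || any(abs(lp$eta10) > 50)) {
    if (strict) stop("linear predictor exceeds +/-50; intensities overflow")
    return(-1e10)
  }
  pr <- pair_probs(exp(lp$eta01), exp(lp$eta10), d$dt, d$pre, d$post,
                   deriv = FALSE)
  bad <- which(pr$p <= 0 | !is.finite(pr$p))
  if (length(bad)) {
    if (strict)
      stop("non-positive transition probability at pair index ", bad[1L])
    pr$p <- pmax(pr$p, 1e-300)
  }
  sum(sort(log(pr$p)))
}

# Analytic score of the panel log-likelihood in the model's layout.
score_from_design <- function(model, params, d) {
  lp <- linear_predictors(model, params, d$Z)
  q01 <- exp(lp$eta01)
  q10 <- exp(lp$eta10)
  pr <- pair_probs(q01, q10, d$dt, d$pre, d$post)
  p <- pmax(pr$p, 1e-300)
  # per-pair weight wrt each linear predictor (chain rule dq/deta = q)
  w01 <- pr$dp_dq01 * q01 / p
  w10 <- pr$dp_dq10 * q10 / p
  g <- numeric(model$n_par)
  g[1L] <- sum(w01)
  g[2L] <- sum(w10)
  nf <- length(model$free)
  if (nf) {
    Zf <- d$Z[, model$free, drop = FALSE]
    g[3:(2 + nf)] <- drop(crossprod(Zf, w01))
    g[(3 + nf):(2 + 2 * nf)] <- drop(crossprod(Zf, w10))
  }
  if (length(model$constrained)) {
    Zc <- d$Z[, model$constrained, drop = FALSE]
    g[(3 + 2 * nf):model$n_par] <- drop(crossprod(Zc, w01 - w10))
  }
  g
}
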