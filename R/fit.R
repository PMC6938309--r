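#' Maximum-likelihood fit of the two-state intensity model
#'
#' Maximizes the panel likelihood over the free parameter vector (any
#' constraints are respected by construction of the parameterization) with
#' BFGS using the analytic score. The default start is a method-of-moments
#' one: log crude transition rates (events over person-time at risk) for the
#' intercepts and zero coefficients; additional starts are seeded random
#' perturbations around it and the best converged solution is retained.
#' The covariance is the inverse of a finite-difference observed-information
#' matrix (numerical Hessian of the analytic score) at the optimum.
#'
#' @param model An [intensity_model()].
#' @param pairs Transition-pair table from [build_transition_pairs()]. Pairs
#'   with missing covariate values are dropped with a logged count.
#' @param starts Number of starting points (first is method-of-moments).
#' @param seed Optional integer seed for the random restarts.
#' @param start Optional explicit starting parameter vector; when supplied
#'   it replaces the method-of-moments start.
#' @param standardize If `TRUE`, covariates are centred and scaled before
#'   optimization and estimates are mapped back to the per-unit scale, so
#'   reported hazard ratios are always per instrument unit. Defaults off.
#' @param hessian If `FALSE`, skip the observed-information covariance
#'   (used by bootstrap refits, which only need point estimates).
#' @param control Passed to [stats::optim()] (sensible defaults applied).
#' @return An object of class `aud_fit`: list with `estimate` (named
#'   vector), `vcov`, `loglik`, `convergence` flag, `model`, counts and
#'   optimizer diagnostics.
#' @export
fit_mle <- function(model, pairs, starts = 3L, seed = NULL, start = NULL,
                    standardize = FALSE, hessian = TRUE, control = list()) {
  d <- pair_design(model, pairs)
  if (length(d$pre) == 0L) stop("no usable transition pairs")
  n01 <- sum(d$pre == 0L & d$post == 1L)
  n10 <- sum(d$pre == 1L & d$post == 0L)
  if (n01 == 0L || n10 == 0L)
    warning("no observed ", if (n01 == 0L) "onset" else "remission",
            " transitions; intercept weakly identified")
  sds <- if (ncol(d$Z)) apply(d$Z, 2, stats::sd) else numeric(0)
  degenerate <- names(sds)[sds == 0]
  if (length(degenerate))
    warning("covariate(s) constant across pairs, coefficient unidentifiable: ",
            paste(degenerate, collapse = ", "))

  # optional standardization (per-unit estimates recovered afterwards)
  ctr <- scl <- NULL
  if (standardize && ncol(d$Z)) {
    ctr <- colMeans(d$Z)
    scl <- ifelse(sds > 0, sds, 1)
    d$Z <- sweep(sweep(d$Z, 2, ctr), 2, scl, "/")
  }

  # method-of-moments start: crude rates = events / person-time at risk
  t0 <- sum(d$dt[d$pre == 0L])
  t1 <- sum(d$dt[d$pre == 1L])
  q01_crude <- max(n01, 0.5) / max(t0, 1e-8)
  q10_crude <- max(n10, 0.5) / max(t1, 1e-8)
  base_start <- c(log(q01_crude), log(q10_crude),
                  rep(0, model$n_par - 2L))
  if (!is.null(start)) {
    stopifnot(length(start) == model$n_par)
    base_start <- as.numeric(start)
  }

  if (!is.null(seed)) set.seed(seed)
  start_list <- list(base_start)
  if (starts > 1L)
    for (k in seq_len(starts - 1L))
      start_list[[k + 1L]] <- base_start + stats::rnorm(model$n_par, 0, 0.3)

  ctl <- utils::modifyList(list(maxit = 500L, reltol = 1e-12), control)
  negll <- function(p) -loglik_from_design(model, p, d)
  neggr <- function(p) -score_from_design(model, p, d)

  best <- NULL
  diagnostics <- list()
  for (k in seq_along(start_list)) {
    res <- tryCatch(
      stats::optim(start_list[[k]], negll, neggr, method = "BFGS",
                   control = ctl),
      error = function(e) NULL)
    diagnostics[[k]] <- if (is.null(res)) "error" else res$convergence
    if (is.null(res)) next
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best))
    stop("optimization failed at all ", starts, " starting points; ",
         "diagnostics: ", paste(unlist(diagnostics), collapse = ", "))
  converged <- best$convergence == 0L

  singular <- FALSE
  if (hessian) {
    H <- stats::optimHess(best$par, negll, neggr)
    V <- tryCatch(solve(H), error = function(e) NULL)
    if (is.null(V) || anyNA(V) || any(diag(V) < 0)) {
      warning("observed information singular or indefinite; ",
              "using pseudo-inverse covariance")
      V <- MASS::ginv(H)
      singular <- TRUE
    }
  } else {
    V <- matrix(NA_real_, model$n_par, model$n_par)
  }

  est <- best$par
  if (standardize && ncol(d$Z)) {
    # map back to per-unit scale: beta = beta'/s, alpha = alpha' - sum b' m/s
    A <- diag(model$n_par)
    nf <- length(model$free)
    idx_on <- if (nf) 3:(2 + nf) else integer(0)
    idx_re <- if (nf) (3 + nf):(2 + 2 * nf) else integer(0)
    idx_sh <- if (length(model$constrained)) (3 + 2 * nf):model$n_par else integer(0)
    m <- ctr; s <- scl
    for (j in seq_along(model$free)) {
      cv <- model$free[j]
      A[idx_on[j], idx_on[j]] <- 1 / s[cv]
      A[idx_re[j], idx_re[j]] <- 1 / s[cv]
      A[1L, idx_on[j]] <- -m[cv] / s[cv]
      A[2L, idx_re[j]] <- -m[cv] / s[cv]
    }
    for (j in seq_along(model$constrained)) {
      cv <- model$constrained[j]
      A[idx_sh[j], idx_sh[j]] <- 1 / s[cv]
      A[1L, idx_sh[j]] <- -m[cv] / s[cv]
      A[2L, idx_sh[j]] <- m[cv] / s[cv]
    }
    est <- drop(A %*% est)
    V <- A %*% V %*% t(A)
  }

  names(est) <- model$par_names
  dimnames(V) <- list(model$par_names, model$par_names)
  structure(
    list(model = model,
         estimate = est,
         vcov = V,
         loglik = -best$value,
         convergence = converged,
         singular_information = singular,
         degenerate_covariates = degenerate,
         n_pairs = length(d$pre),
         n_dropped = d$n_dropped,
         counts = c(onset = n01, remission = n10),
         optim_diagnostics = diagnostics),
    class = "aud_fit"
  )
}

#' @export
print.aud_fit <- function(x, ...) {
  cat("Two-state panel Markov model fit\n")
  cat("  pairs:", x$n_pairs,
      " (", x$counts["onset"], "onset,", x$counts["remission"], "remission )\n")
  cat("  log-likelihood:", format(x$loglik, digits = 7),
      " converged:", x$convergence, "\n")
  print(round(cbind(estimate = x$estimate,
                    se = sqrt(diag(x$vcov))), 4))
  invisible(x)
}

#' Hazard-ratio table with Wald confidence intervals
#'
#' Exponentiates each covariate's coefficient per transition into a hazard
#' ratio with a Wald interval on the log scale,
#' `exp(beta +/- z * SE)`. For covariates constrained across states the
#' remission hazard ratio is the exact reciprocal of the onset one (same
#' parameter, opposite sign), with the interval reversed accordingly.
#'
#' @param fit An `aud_fit` from [fit_mle()].
#' @param level Confidence level (default 0.95).
#' @return Data frame with columns `covariate`, `transition`
#'   (`"onset"`/`"remission"`), `hr`, `lower`, `upper`, `p_value` (Wald test
#'   of log-HR = 0), `constrained`.
#' @export
hazard_ratios <- function(fit, level = 0.95) {
  if (!inherits(fit, "aud_fit")) stop("fit must be an aud_fit")
  if (!isTRUE(fit$convergence)) warning("fit did not converge; HRs suspect")
  model <- fit$model
  zq <- stats::qnorm(1 - (1 - level) / 2)
  se <- sqrt(diag(fit$vcov))
  rows <- list()
  add <- function(cov, trans, b, s, constrained) {
    rows[[length(rows) + 1L]] <<- data.frame(
      covariate = cov, transition = trans,
      hr = exp(b), lower = exp(b - zq * s), upper = exp(b + zq * s),
      p_value = 2 * stats::pnorm(-abs(b / max(s, .Machine$double.eps))),
      constrained = constrained, stringsAsFactors = FALSE)
  }
  for (cv in model$free) {
    add(cv, "onset", fit$estimate[paste0("onset_", cv)],
        se[paste0("onset_", cv)], FALSE)
    add(cv, "remission", fit$estimate[paste0("remission_", cv)],
        se[paste0("remission_", cv)], FALSE)
  }
  for (cv in model$constrained) {
    g <- fit$estimate[paste0("shared_", cv)]
    s <- se[paste0("shared_", cv)]
    add(cv, "onset", g, s, TRUE)
    add(cv, "remission", -g, s, TRUE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Render a hazard-ratio table in the adjusted-model report layout
#'
#' One row per covariate, columns for the onset and remission hazard ratios
#' as `"HR (lower, upper)"`; covariates whose effects are constrained across
#' states are flagged with a dagger.
#'
#' @param fit An `aud_fit`.
#' @param level Confidence level for intervals.
#' @param digits Digits for rounding.
#' @return Data frame with columns `covariate`, `onset`, `remission`.
#' @export
format_hr_table <- function(fit, level = 0.95, digits = 2) {
  hr <- hazard_ratios(fit, level)
  fmt <- function(r) sprintf("%.*f (%.*f, %.*f)",
                             digits, r$hr, digits, r$lower, digits, r$upper)
  covs <- unique(hr$covariate)
  out <- data.frame(
    covariate = vapply(covs, function(cv) {
      con <- hr$constrained[hr$covariate == cv][1L]
      paste0(cv, if (con) "†" else "")
    }, character(1)),
    onset = vapply(covs, function(cv)
      fmt(hr[hr$covariate == cv & hr$transition == "onset", ]), character(1)),
    remission = vapply(covs, function(cv)
      fmt(hr[hr$covariate == cv & hr$transition == "remission", ]), character(1)),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
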