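# Per-pair probability of ending in state 1, plus the exit linear
# predictor (the fitted log-intensity out of the pair's pre-state), for a
# fitted model evaluated on a pair table.
pair_fitted <- function(fit, pairs) {
  d <- pair_design(fit$model, pairs, quiet = TRUE)
  lp <- linear_predictors(fit$model, fit$estimate, d$Z)
  q01 <- exp(lp$eta01)
  q10 <- exp(lp$eta10)
  pr <- pair_probs(q01, q10, d$dt, pre = d$pre, post = rep(1L, length(d$pre)),
                   deriv = FALSE)
  list(p1 = pr$p, pre = d$pre, post = d$post, dt = d$dt,
       lp_exit = ifelse(d$pre == 0L, lp$eta01, lp$eta10))
}

# Quantile-based grouping with guard against ties producing too few breaks.
cut_quantiles <- function(x, k) {
  if (k <= 1L || length(unique(x)) < 2L) return(rep(1L, length(x)))
  br <- unique(stats::quantile(x, probs = seq(0, 1, length.out = k + 1)))
  if (length(br) < 3L) return(rep(1L, length(x)))
  as.integer(cut(x, breaks = br, include.lowest = TRUE))
}

#' Pearson-type lack-of-fit statistic for a fitted panel model
#'
#' Contrasts observed with model-predicted transition counts. Pairs are
#' partitioned by pre-state, tertile of the time gap, and tertile of the
#' fitted exit linear predictor; within each group the expected count of
#' post-state `j` is the sum of fitted probabilities `P_ij(dt; z)` over the
#' group's pairs, and the statistic is `T = sum (o - e)^2 / e` over the
#' cells. Groups whose smallest expected cell falls below `min_expected`
#' are collapsed into a neighbouring group of the same pre-state before
#' computing `T`.
#'
#' @param fit A converged `aud_fit`.
#' @param pairs The `transition_pairs` the fit (or its replicate) applies to.
#' @param n_time_groups,n_lp_groups Numbers of quantile groups for the time
#'   gap and the linear predictor (default tertiles).
#' @param min_expected Collapse threshold for expected cell counts
#'   (default 5).
#' @return List of class `gof_cells`: `statistic`, `cells` (data frame of
#'   group, pre-state, post-state, observed, expected), `n_groups`.
#' @export
pearson_statistic <- function(fit, pairs, n_time_groups = 3L,
                              n_lp_groups = 3L, min_expected = 5) {
  if (!isTRUE(fit$convergence)) stop("fit did not converge")
  pf <- pair_fitted(fit, pairs)
  n <- length(pf$pre)
  if (!n) stop("no usable pairs")
  group <- integer(n)
  for (s in c(0L, 1L)) {
    sel <- pf$pre == s
    if (!any(sel)) next
    gt <- cut_quantiles(pf$dt[sel], n_time_groups)
    gl <- cut_quantiles(pf$lp_exit[sel], n_lp_groups)
    group[sel] <- (s * 10000L) + (gt - 1L) * n_lp_groups + gl
  }

  # vectorized per-group observed and expected counts for the two
  # post-state cells
  cell_stats <- function(group) {
    keys <- sort(unique(group))
    idx <- match(group, keys)
    n <- tabulate(idx, nbins = length(keys))
    o1 <- as.vector(rowsum(as.numeric(pf$post), idx))
    e1 <- as.vector(rowsum(pf$p1, idx))
    list(keys = keys, n = n, o1 = o1, o0 = n - o1, e1 = e1, e0 = n - e1)
  }

  # collapse under-populated groups into a neighbour with the same pre-state;
  # a pre-state reduced to a single group is left as is (frozen)
  frozen <- integer(0)
  repeat {
    cs <- cell_stats(group)
    mins <- pmin(cs$e0, cs$e1)
    cand <- setdiff(cs$keys[mins < min_expected], frozen)
    if (!length(cand)) break
    g <- cand[which.min(mins[match(cand, cs$keys)])]
    pre_s <- (g >= 10000L) * 1L
    same_pre <- sort(unique(group[pf$pre == pre_s]))
    if (length(same_pre) <= 1L) {
      frozen <- c(frozen, g)
      next
    }
    pos <- match(g, same_pre)
    neighbour <- if (pos > 1L) same_pre[pos - 1L] else same_pre[pos + 1L]
    group[group == g] <- neighbour
  }

  cs <- cell_stats(group)
  if (all(c(cs$e0, cs$e1) < min_expected))
    stop("all expected cell counts below ", min_expected,
         "; use a coarser grouping")
  statistic <- sum((cs$o0 - cs$e0)^2 / cs$e0 + (cs$o1 - cs$e1)^2 / cs$e1)
  k <- length(cs$keys)
  cells <- data.frame(
    group = rep(cs$keys, each = 2L),
    pre_state = rep((cs$keys >= 10000L) * 1L, each = 2L),
    post_state = rep(c(0L, 1L), k),
    observed = as.vector(rbind(cs$o0, cs$o1)),
    expected = as.vector(rbind(cs$e0, cs$e1)))
  structure(list(statistic = statistic, cells = cells, n_groups = k),
            class = "gof_cells")
}

#' Parametric-bootstrap p-value for the lack-of-fit statistic
#'
#' For each of `B` bootstrap iterations, simulates new post-states for every
#' pair from the fitted model conditional on the observed pre-state, time
#' gap and pre-transition covariates, refits the model (optionally), and
#' recomputes the Pearson-type statistic. The p-value uses the add-one rule
#' `p = (1 + #\{T_b >= T_obs\}) / (B + 1)` and is therefore never exactly
#' zero. Aborts if more than 5% of replicate refits fail.
#'
#' @inheritParams pearson_statistic
#' @param B Bootstrap iterations (default 1000).
#' @param seed Integer seed for the replicate streams.
#' @param refit If `TRUE` (default) the model is refit to each replicate
#'   dataset (one start, warm-started at the observed fit) before the
#'   statistic is recomputed; if `FALSE` the observed estimates are reused.
#' @return List of class `gof_result`: observed `statistic`, `cells`,
#'   `boot` (replicate statistics), `p_value`, `B`, `refit`.
#' @export
bootstrap_pvalue <- function(fit, pairs, B = 1000L, seed = NULL,
                             refit = TRUE, n_time_groups = 3L,
                             n_lp_groups = 3L, min_expected = 5) {
  obs <- pearson_statistic(fit, pairs, n_time_groups, n_lp_groups,
                           min_expected)
  pf <- pair_fitted(fit, pairs)
  if (!is.null(seed)) set.seed(seed)
  boot <- rep(NA_real_, B)
  failures <- character(0)
  pairs_b <- pairs
  for (b in seq_len(B)) {
    pairs_b$post_state <- stats::rbinom(length(pf$p1), 1, pf$p1)
    res <- tryCatch({
      fit_b <- if (refit)
        suppressWarnings(fit_mle(fit$model, pairs_b, starts = 1L,
                                 start = fit$estimate, hessian = FALSE))
      else fit
      pearson_statistic(fit_b, pairs_b, n_time_groups, n_lp_groups,
                        min_expected)$statistic
    }, error = function(e) conditionMessage(e))
    if (is.character(res)) failures <- c(failures, res) else boot[b] <- res
    if (length(failures) > 0.05 * B)
      stop("more than 5% of bootstrap refits failed; first errors: ",
           paste(utils::head(unique(failures), 3), collapse = " | "))
  }
  ok <- !is.na(boot)
  p <- (1 + sum(boot[ok] >= obs$statistic)) / (sum(ok) + 1)
  structure(list(statistic = obs$statistic, cells = obs$cells,
                 boot = boot[ok], p_value = p, B = B, refit = refit,
                 n_failed = sum(!ok), seed = seed),
            class = "gof_result")
}

#' @export
print.gof_result <- function(x, ...) {
  cat("Pearson-type lack-of-fit test (parametric bootstrap)\n")
  cat(sprintf("  T = %.3f over %d cells; p = %.3f (B = %d, refit = %s)\n",
              x$statistic, nrow(x$cells), x$p_value, x$B, x$refit))
  invisible(x)
}
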