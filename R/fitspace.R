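#' @title Confidence-contour (chi-square threshold) error analysis
#' @description Maps the normalized chi-square surface over pairs of
#'   parameters with re-optimization of all remaining free (nuisance)
#'   parameters at every grid node, and reads per-parameter confidence
#'   limits where the surface crosses a fixed fractional increase in
#'   chi-square (10% by default).  The display convention is
#'   chi2_min / chi2(node), so the surface lies in (0, 1] with its maximum
#'   of 1 at the best fit, and the 10%-increase threshold sits at
#'   1/1.1 ~ 0.909.
#' @name fitspace
NULL

# Re-optimize nuisance parameters at fixed profiled values.
# resid_given: named full-vector residual function; returns list(chisq, par).
.reopt_nuisance <- function(resid_given, fixed_par, nuisance_start,
                            lower, upper, thorough = FALSE) {
  if (!length(nuisance_start)) {
    r <- resid_given(fixed_par)
    return(list(chisq = sum(r^2), nuisance = numeric(0), ok = TRUE))
  }
  nms <- names(nuisance_start)
  fn <- function(lp) {
    full <- c(fixed_par, stats::setNames(10^lp, nms))
    r <- try(resid_given(full), silent = TRUE)
    if (inherits(r, "try-error") || any(!is.finite(r)))
      return(rep(1e8, .nres))
    .nres <<- length(r)
    r
  }
  .nres <- length(resid_given(c(fixed_par, nuisance_start)))
  lo <- log10(lower[nms]); hi <- log10(upper[nms])
  run_lm <- function(start_log) {
    fit <- try(minpack.lm::nls.lm(
      par = pmin(pmax(start_log, lo), hi), fn = fn, lower = lo, upper = hi,
      control = minpack.lm::nls.lm.control(maxiter = 60, ftol = 1e-9,
                                           ptol = 1e-9)), silent = TRUE)
    if (inherits(fit, "try-error")) NULL else fit
  }
  fit <- run_lm(log10(nuisance_start))
  if (thorough && length(nms) >= 2) {
    # NM interlude + LM refine escapes curved-valley stalls at far nodes
    from <- if (is.null(fit)) log10(nuisance_start) else stats::coef(fit)
    nm <- try(stats::optim(from, function(lp) sum(fn(lp)^2),
                           method = "Nelder-Mead",
                           control = list(maxit = 150, reltol = 1e-10)),
              silent = TRUE)
    if (!inherits(nm, "try-error")) {
      fit2 <- run_lm(nm$par)
      if (!is.null(fit2) && (is.null(fit) ||
                             stats::deviance(fit2) < stats::deviance(fit)))
        fit <- fit2
    }
  }
  if (is.null(fit))
    return(list(chisq = NA_real_, nuisance = nuisance_start, ok = FALSE))
  list(chisq = stats::deviance(fit),
       nuisance = stats::setNames(10^stats::coef(fit), nms),
       ok = fit$info %in% 1:4)
}

.log_axis <- function(center, span, n) {
  exp(seq(log(center / span), log(center * span), length.out = n))
}

#' Pairwise confidence contour
#'
#' Evaluates the chi-square surface over a log-spaced grid of two parameters,
#' re-optimizing every other free parameter at each node (warm-started from
#' the nearest solved neighbor).  If the threshold contour is not crossed on
#' some side of an axis, the grid is expanded twofold on that side (up to
#' `max_expand` times).
#'
#' @param data the [experiment_set()] (or list of sets) that was fit; only
#'   used for its description - the objective comes from `fit`.
#' @param fit a `fit_result` from [fit_global()] or [fit_processive()] whose
#'   free parameters include `p` and `q`.
#' @param p,q names of the two profiled parameters.
#' @param n_grid nodes per axis (default 21).
#' @param span initial half-decade span factor: axes run from value/span to
#'   value*span around the best fit (default 3).
#' @param threshold fractional chi-square increase defining the confidence
#'   region (default 0.10).
#' @param max_expand maximum number of twofold grid expansions per side.
#' @return An object of class `contour_grid`: axes, normalized chi-square
#'   matrix (chi2_min / chi2, in (0,1]), threshold level, per-parameter
#'   confidence limits and a matrix flagging non-converged nodes.
#' @export
profile_pair <- function(data, fit, p, q, n_grid = 21, span = 3,
                         threshold = 0.10, max_expand = 4) {
  stopifnot(inherits(fit, "fit_result"))
  if (!all(c(p, q) %in% fit$free))
    stop("both profiled parameters must have been free in the fit")
  if (p == q) stop("profile a pair of distinct parameters")
  lo <- fit$bounds$lower; hi <- fit$bounds$upper
  px <- .log_axis(fit$par[[p]], span, n_grid)
  qx <- .log_axis(fit$par[[q]], span, n_grid)
  crit <- (1 + threshold)  # chi2 <= crit * chi2_min inside the region
  for (round in 0:max_expand) {
    g <- .eval_pair_grid(fit, p, q, px, qx, lo, hi)
    chisq_min <- min(fit$chisq, min(g$chisq, na.rm = TRUE))
    lim <- crit * chisq_min
    prof_p <- apply(g$chisq, 1, min, na.rm = TRUE)
    prof_q <- apply(g$chisq, 2, min, na.rm = TRUE)
    if (round == max_expand) break
    px_new <- px; qx_new <- qx; expand <- FALSE
    if (prof_p[1] < lim && px[1] > lo[[p]]) {
      px_new <- .extend_axis(px_new, "low"); expand <- TRUE
    }
    if (prof_p[length(prof_p)] < lim && px[length(px)] < hi[[p]]) {
      px_new <- .extend_axis(px_new, "high"); expand <- TRUE
    }
    if (prof_q[1] < lim && qx[1] > lo[[q]]) {
      qx_new <- .extend_axis(qx_new, "low"); expand <- TRUE
    }
    if (prof_q[length(prof_q)] < lim && qx[length(qx)] < hi[[q]]) {
      qx_new <- .extend_axis(qx_new, "high"); expand <- TRUE
    }
    if (!expand) break
    px <- sort(unique(pmin(pmax(px_new, lo[[p]]), hi[[p]])))
    qx <- sort(unique(pmin(pmax(qx_new, lo[[q]]), hi[[q]])))
  }
  profile_p <- .refine_axis_profile(fit, p, q, px, qx, g$chisq, lo, hi,
                                    by_row = TRUE)
  profile_q <- .refine_axis_profile(fit, q, p, qx, px, g$chisq, lo, hi,
                                    by_row = FALSE)
  chisq_min <- min(chisq_min, profile_p, profile_q, na.rm = TRUE)
  normalized <- chisq_min / g$chisq
  grid <- structure(list(
    params = c(p, q), p_values = px, q_values = qx,
    normalized = normalized, chisq = g$chisq, chisq_min = chisq_min,
    profile_p = profile_p, profile_q = profile_q,
    threshold = threshold, failed = g$failed,
    best = fit$par[c(p, q)]), class = "contour_grid")
  grid$limits <- confidence_limits(grid, threshold)
  grid
}

.extend_axis <- function(x, side) {
  ratio <- x[2] / x[1]
  n_add <- max(1L, ceiling(log(2) / log(ratio)))
  if (side == "low") sort(unique(c(x[1] / ratio^seq_len(n_add), x)))
  else sort(unique(c(x, x[length(x)] * ratio^seq_len(n_add))))
}

# Evaluate the chi-square over the (px, qx) grid with warm-started nuisance
# re-optimization, sweeping rows outward from the node nearest the best fit.
.eval_pair_grid <- function(fit, p, q, px, qx, lo, hi) {
  nuis_names <- setdiff(fit$free, c(p, q))
  chisq <- matrix(NA_real_, length(px), length(qx))
  failed <- matrix(FALSE, length(px), length(qx))
  nuis <- vector("list", length(qx))  # warm start per column, updated per row
  start0 <- fit$par[nuis_names]
  i0 <- which.min(abs(log(px / fit$par[[p]])))
  row_order <- order(abs(seq_along(px) - i0))
  for (i in row_order) {
    j0 <- which.min(abs(log(qx / fit$par[[q]])))
    for (j in order(abs(seq_along(qx) - j0))) {
      fixed_pq <- stats::setNames(c(px[i], qx[j]), c(p, q))
      start <- if (!is.null(nuis[[j]])) nuis[[j]] else start0
      res <- .reopt_nuisance(fit$resid_given, fixed_pq, start, lo, hi)
      if (!is.finite(res$chisq) && length(start0) &&
          !isTRUE(all.equal(start, start0)))
        res <- .reopt_nuisance(fit$resid_given, fixed_pq, start0, lo, hi)
      chisq[i, j] <- res$chisq
      failed[i, j] <- !res$ok
      if (is.finite(res$chisq)) nuis[[j]] <- res$nuisance
    }
  }
  list(chisq = chisq, failed = failed)
}

# True 1-D profile along one axis of a pair grid: at each axis value the
# partner and all nuisance parameters are re-optimized continuously,
# warm-started from the best grid node of that row/column (removing the
# quantization of the partner axis).
.refine_axis_profile <- function(fit, p, q, px, qx, chisq_grid, lo, hi,
                                 by_row = TRUE) {
  nuis_names <- setdiff(fit$free, c(p, q))
  vapply(seq_along(px), function(i) {
    row <- if (by_row) chisq_grid[i, ] else chisq_grid[, i]
    if (all(!is.finite(row))) return(NA_real_)
    jbest <- which.min(row)
    fixed_p <- stats::setNames(px[i], p)
    start1 <- c(stats::setNames(qx[jbest], q), fit$par[nuis_names])
    res <- .reopt_nuisance(fit$resid_given, fixed_p, start1, lo, hi,
                           thorough = TRUE)
    best_i <- res$chisq
    if (!is.finite(best_i) || best_i > row[jbest]) {
      res2 <- .reopt_nuisance(fit$resid_given, fixed_p,
                              c(fit$par[q], fit$par[nuis_names]), lo, hi,
                              thorough = TRUE)
      best_i <- suppressWarnings(min(best_i, res2$chisq, na.rm = TRUE))
    }
    if (is.finite(best_i)) min(best_i, row[jbest]) else row[jbest]
  }, numeric(1))
}

#' One-dimensional chi-square profile of a parameter
#'
#' Re-optimizes all other free parameters at each value of the profiled
#' parameter along a log-spaced axis, auto-expanding until the threshold is
#' crossed (or the bounds are reached).
#'
#' @inheritParams profile_pair
#' @param n_grid number of profile points.
#' @return A data.frame with columns `value`, `chisq`, `normalized`, plus
#'   attributes `param`, `chisq_min` and `threshold`; suitable input for
#'   [confidence_limits()].
#' @export
profile_param <- function(fit, p, n_grid = 15, span = 3, threshold = 0.10,
                          max_expand = 4) {
  stopifnot(inherits(fit, "fit_result"), p %in% fit$free)
  lo <- fit$bounds$lower; hi <- fit$bounds$upper
  nuis_names <- setdiff(fit$free, p)
  px <- .log_axis(fit$par[[p]], span, n_grid)
  for (round in 0:max_expand) {
    px <- sort(unique(pmin(pmax(px, lo[[p]]), hi[[p]])))
    chisq <- rep(NA_real_, length(px))
    start <- fit$par[nuis_names]
    i0 <- which.min(abs(log(px / fit$par[[p]])))
    for (i in order(abs(seq_along(px) - i0))) {
      res <- .reopt_nuisance(fit$resid_given,
                             stats::setNames(px[i], p), start, lo, hi)
      chisq[i] <- res$chisq
      if (is.finite(res$chisq)) start <- res$nuisance
    }
    chisq_min <- min(fit$chisq, min(chisq, na.rm = TRUE))
    lim <- (1 + threshold) * chisq_min
    if (round == max_expand) break
    px_new <- px; expand <- FALSE
    if (chisq[1] < lim && px[1] > lo[[p]]) {
      px_new <- .extend_axis(px_new, "low"); expand <- TRUE
    }
    if (chisq[length(chisq)] < lim && px[length(px)] < hi[[p]]) {
      px_new <- .extend_axis(px_new, "high"); expand <- TRUE
    }
    if (!expand) break
    px <- px_new
  }
  out <- data.frame(value = px, chisq = chisq,
                    normalized = chisq_min / chisq)
  attr(out, "param") <- p
  attr(out, "chisq_min") <- chisq_min
  attr(out, "threshold") <- threshold
  attr(out, "best") <- fit$par[[p]]
  out
}

#' Confidence limits at a fractional chi-square threshold
#'
#' Extracts per-parameter lower and upper confidence limits where the
#' profiled chi-square crosses `(1 + threshold) * chi2_min` (the 10%
#' increase of the standard construction by default).  Crossings are
#' interpolated log-linearly between grid nodes; a profile that never
#' crosses the threshold within the grid is reported as an open (unbounded)
#' interval on that side.
#'
#' @param x a `contour_grid` from [profile_pair()], a 1-D profile
#'   data.frame from [profile_param()], or a data.frame with columns
#'   `value` and `chisq` (with attribute `param` optional).
#' @param threshold fractional chi-square increase (default 0.10).
#' @return Named list (one element per parameter) of lists with elements
#'   `low`, `high` (numeric, `NA` when open), `unbounded_low`,
#'   `unbounded_high` (logical).
#' @export
confidence_limits <- function(x, threshold = 0.10) {
  if (inherits(x, "contour_grid")) {
    prof_p <- if (!is.null(x$profile_p)) x$profile_p
              else apply(x$chisq, 1, min, na.rm = TRUE)
    prof_q <- if (!is.null(x$profile_q)) x$profile_q
              else apply(x$chisq, 2, min, na.rm = TRUE)
    mn <- x$chisq_min
    out <- list(
      .limits_1d(x$p_values, prof_p, mn, threshold, x$best[[1]]),
      .limits_1d(x$q_values, prof_q, mn, threshold, x$best[[2]]))
    names(out) <- x$params
    return(out)
  }
  stopifnot(is.data.frame(x), all(c("value", "chisq") %in% names(x)))
  mn <- if (!is.null(attr(x, "chisq_min"))) attr(x, "chisq_min")
        else min(x$chisq, na.rm = TRUE)
  best <- if (!is.null(attr(x, "best"))) attr(x, "best")
          else x$value[which.min(x$chisq)]
  out <- list(.limits_1d(x$value, x$chisq, mn, threshold, best))
  names(out) <- if (!is.null(attr(x, "param"))) attr(x, "param") else "param"
  out
}

# Interpolated threshold crossings of a 1-D profile.
.limits_1d <- function(values, chisq, chisq_min, threshold, best) {
  ok <- is.finite(chisq)
  values <- values[ok]; chisq <- chisq[ok]
  lim <- (1 + threshold) * chisq_min
  i_best <- which.min(abs(log(values / best)))
  cross <- function(idx_seq) {
    prev_v <- values[idx_seq[1]]; prev_c <- chisq[idx_seq[1]]
    for (i in idx_seq[-1]) {
      if (chisq[i] >= lim && prev_c < lim) {
        f <- (lim - prev_c) / (chisq[i] - prev_c)
        return(exp(log(prev_v) + f * (log(values[i]) - log(prev_v))))
      }
      prev_v <- values[i]; prev_c <- chisq[i]
    }
    NA_real_
  }
  low  <- cross(rev(seq_len(i_best)))
  high <- cross(seq(i_best, length(values)))
  list(low = low, high = high,
       unbounded_low = is.na(low), unbounded_high = is.na(high))
}

#' Wrap an arbitrary residual function as a fit result
#'
#' Builds a minimal `fit_result` around a user-supplied residual function so
#' the contour machinery ([profile_pair()], [profile_param()]) can be applied
#' to any least-squares objective - for example a closed-form test objective
#' with a known Hessian, or a model outside the built-in schemes.
#'
#' @param resid_given function taking a full named parameter vector (native
#'   units) and returning a residual vector (chi-square is its sum of
#'   squares).
#' @param par named numeric vector: the best-fit parameter values.
#' @param free names of the free parameters (default: all of `par`).
#' @param bounds optional list with named `lower`/`upper` vectors.
#' @return A `fit_result` usable with the profiling functions.
#' @export
as_fit_result <- function(resid_given, par, free = names(par), bounds = NULL) {
  b <- .default_bounds(free)
  if (!is.null(bounds)) {
    if (!is.null(bounds$lower)) b$lower[names(bounds$lower)] <- bounds$lower
    if (!is.null(bounds$upper)) b$upper[names(bounds$upper)] <- bounds$upper
  }
  r <- resid_given(par)
  structure(list(par = par, fixed = numeric(0), free = free,
                 chisq = sum(r^2), residuals = r, n_points = length(r),
                 derived = NULL, converged = TRUE, info = 1,
                 message = "user-supplied optimum", warnings = character(0),
                 rsstrace = sum(r^2), n_starts = 1, seed = NA,
                 guesses = par, bounds = b, resid_given = resid_given,
                 scheme_id = "custom"),
            class = "fit_result")
}

#' @export
print.contour_grid <- function(x, ...) {
  cat(sprintf("Confidence contour %s x %s: %d x %d nodes, threshold %.0f%% (normalized chi2 >= %.4g)\n",
              x$params[1], x$params[2], length(x$p_values), length(x$q_values),
              100 * x$threshold, 1 / (1 + x$threshold)))
  for (nm in x$params) {
    l <- x$limits[[nm]]
    cat(sprintf("  %-10s best %.5g, limits [%s, %s]%s\n", nm, x$best[[nm]],
                if (l$unbounded_low) "open" else signif(l$low, 5),
                if (l$unbounded_high) "open" else signif(l$high, 5),
                if (l$unbounded_low || l$unbounded_high) "  [OPEN]" else ""))
  }
  if (any(x$failed)) cat("  (", sum(x$failed), "non-converged nodes flagged )\n")
  invisible(x)
}
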