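#' @importFrom minpack.lm nls.lm nls.lm.control
NULL

# Levenberg-Marquardt minimization in log10 parameter space with seeded
# multi-start.  `resid_fun` maps a named native-unit vector over `free` to a
# residual vector.  Returns the best nls.lm fit plus the start used.
.lm_multistart <- function(resid_fun, guesses, lower, upper,
                           n_starts = 5, seed = NULL, maxiter = 100) {
  free <- names(guesses)
  wrap <- function(logp) {
    p <- stats::setNames(10^logp, free)
    r <- try(resid_fun(p), silent = TRUE)
    if (inherits(r, "try-error") || any(!is.finite(r)))
      return(rep(1e8, .lm_nres))
    .lm_nres <<- length(r)
    r
  }
  .lm_nres <- length(resid_fun(guesses))
  if (is.null(seed)) seed <- 1
  old <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv),
          add = TRUE)
  starts <- list(log10(guesses))
  if (n_starts > 1) {
    for (s in seq_len(n_starts - 1))
      starts[[s + 1L]] <- pmin(pmax(
        log10(guesses) + stats::runif(length(free), -1, 1),
        log10(lower)), log10(upper))
  }
  best <- NULL
  for (st in starts) {
    fit <- try(minpack.lm::nls.lm(
      par = st, fn = wrap, lower = log10(lower), upper = log10(upper),
      control = minpack.lm::nls.lm.control(maxiter = maxiter,
                                           ftol = 1e-10, ptol = 1e-10)),
      silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || stats::deviance(fit) < stats::deviance(best))
      best <- fit
  }
  if (is.null(best)) stop("all optimization starts failed")
  # Hybrid polish stage 1: a Nelder-Mead interlude crawls along the long
  # curved valleys where LM trust regions collapse, then LM refines from
  # its endpoint.
  obj <- function(lp) sum(wrap(lp)^2)
  nm <- if (length(free) < 2) NULL
  else try(stats::optim(stats::coef(best), obj, method = "Nelder-Mead",
                        control = list(maxit = 300, reltol = 1e-12)),
           silent = TRUE)
  if (!is.null(nm) && !inherits(nm, "try-error") &&
      nm$value < stats::deviance(best)) {
    refit <- try(minpack.lm::nls.lm(
      par = pmin(pmax(nm$par, log10(lower)), log10(upper)), fn = wrap,
      lower = log10(lower), upper = log10(upper),
      control = minpack.lm::nls.lm.control(maxiter = maxiter,
                                           ftol = 1e-10, ptol = 1e-10)),
      silent = TRUE)
    if (!inherits(refit, "try-error") &&
        stats::deviance(refit) < stats::deviance(best)) {
      refit$rsstrace <- c(best$rsstrace, refit$rsstrace)
      best <- refit
    }
  }
  # Stage 2: restarting LM (which resets the trust region) from the
  # current optimum and from small jittered neighbors escapes remaining
  # stalls.  Iterate while the best chi-square keeps improving.
  for (polish in 1:10) {
    cand <- list(stats::coef(best))
    for (scale in c(0.02, 0.05))
      cand[[length(cand) + 1L]] <- pmin(pmax(
        stats::coef(best) + scale * stats::runif(length(free), -1, 1),
        log10(lower)), log10(upper))
    prev <- stats::deviance(best)
    for (st in cand) {
      refit <- try(minpack.lm::nls.lm(
        par = st, fn = wrap,
        lower = log10(lower), upper = log10(upper),
        control = minpack.lm::nls.lm.control(maxiter = maxiter,
                                             ftol = 1e-10, ptol = 1e-10)),
        silent = TRUE)
      if (inherits(refit, "try-error")) next
      if (stats::deviance(refit) < stats::deviance(best)) {
        refit$rsstrace <- c(best$rsstrace, refit$rsstrace)
        best <- refit
      }
    }
    if ((prev - stats::deviance(best)) / max(prev, 1e-300) < 1e-5) break
  }
  best
}

# Identifiability diagnostics from the (approximate) Hessian J'J of the
# log-space fit: near-zero curvature flags a flat parameter; near-unit
# estimate correlation flags a correlated (unidentifiable) pair.
.identifiability_warnings <- function(hessian, free) {
  warnings <- character(0)
  d <- sqrt(pmax(diag(hessian), 0))
  flat <- d < 1e-6 * max(d, 1e-300)
  if (any(flat))
    warnings <- c(warnings, paste0("parameter '", free[flat],
                                   "' is unconstrained (flat chi-square)"))
  ok <- which(!flat)
  if (length(ok) >= 2) {
    cov <- try(solve(hessian[ok, ok, drop = FALSE]), silent = TRUE)
    if (inherits(cov, "try-error")) {
      warnings <- c(warnings,
                    "singular curvature matrix: parameters are not jointly identifiable")
    } else {
      dd <- sqrt(pmax(diag(cov), 0))
      corr <- cov / (dd %o% dd)
      for (i in seq_along(ok)) for (j in seq_along(ok)) {
        if (i < j && is.finite(corr[i, j]) && abs(corr[i, j]) > 0.95)
          warnings <- c(warnings, paste0("parameters '", free[ok[i]], "' and '",
                                         free[ok[j]], "' are strongly correlated (|r| = ",
                                         signif(abs(corr[i, j]), 3), ")"))
      }
    }
  }
  warnings
}

.default_bounds <- function(free) {
  list(lower = stats::setNames(rep(1e-6, length(free)), free),
       upper = stats::setNames(rep(1e6, length(free)), free))
}

# Rising-exponential fit y = A(1 - exp(-k t)) of one course; returns
# c(A, k) or NULL on failure.  Used only to seed global fits.
.rise_fit <- function(t, y) {
  A0 <- max(y, 1e-3)
  half <- t[which(y >= A0 / 2)[1]]
  k0 <- if (is.na(half) || half <= 0) 1 / max(t[1], 1e-3) else log(2) / half
  fit <- try(.lm_multistart(
    function(p) y - p[["A"]] * (1 - exp(-p[["k"]] * t)),
    c(A = A0, k = k0),
    c(A = 1e-6, k = 1e-6), c(A = 1e6, k = 1e6),
    n_starts = 1, seed = 1, maxiter = 50), silent = TRUE)
  if (inherits(fit, "try-error")) return(NULL)
  stats::setNames(10^stats::coef(fit), c("A", "k"))
}

# Data-driven starting values for scheme1 fits of nucleotide titrations,
# the standard kinetics workflow: fit each course to a rising exponential,
# then fit the observed-rate hyperbola k_obs = k3 N / (N + K_d,app) via its
# double-reciprocal form to seed k3 and k_minus2.  The chemistry/binding
# valley of the global objective is long and curved; starting on it is far
# more reliable than generic order-of-magnitude guesses.
.scheme1_auto_guesses <- function(sets, k2) {
  N <- c(); kobs <- c()
  for (s in sets) for (i in seq_along(s$courses)) {
    spec <- s$inits[[i]]
    if (!is.list(spec) || is.null(spec$N0) || spec$N0 <= 0) next
    tc <- s$courses[[i]]
    r <- .rise_fit(tc$times, tc$values)
    if (is.null(r)) next
    N <- c(N, spec$N0); kobs <- c(kobs, r[["k"]])
  }
  if (length(unique(N)) < 3) return(NULL)
  co <- try(stats::coef(stats::lm(I(1 / kobs) ~ I(1 / N))), silent = TRUE)
  if (inherits(co, "try-error") || any(!is.finite(co)) || co[1] <= 0)
    return(c(k3 = max(kobs) * 1.2,
             k_minus2 = stats::median(N) * k2))
  k3 <- 1 / co[1]
  Kd <- max(co[2] * k3, min(N) / 10)
  c(k3 = min(max(k3, 1e-3), 1e4), k_minus2 = min(max(Kd * k2, 1e-2), 1e5))
}

#' Global fit of a mechanism to one or more titration series
#'
#' Minimizes the weighted sum of squares [chi_square()] over the chosen free
#' rate constants, simulating the full mechanism for every course at each
#' objective evaluation.  Fitting is done in log10 parameter space by
#' trust-region Levenberg-Marquardt with seeded multi-start (restarts
#' perturb the guesses log-uniformly within one decade) to guard against the
#' local minima typical of ODE-model objectives.  The nucleotide association
#' rate k2 is diffusion-limited and fixed at 0.5 nM^-1 s^-1 unless the
#' caller frees or overrides it.
#'
#' @param data an [experiment_set()] or a list of them (fit jointly).
#' @param free character vector of free parameter names.
#' @param fixed named list of fixed parameter values (native units).
#' @param guesses named numeric initial guesses for the free parameters;
#'   order-of-magnitude defaults are supplied if omitted.
#' @param bounds optional list with named `lower` / `upper` vectors (native
#'   units); default `[1e-6, 1e6]`.
#' @param weights optional weights, as in [chi_square()].
#' @param n_starts number of multi-start optimizations (>= 1).
#' @param seed integer seed for the restart perturbations.
#' @param check_identifiability if `TRUE`, each free parameter is shifted
#'   by +/-50% with all other free parameters re-optimized; a parameter
#'   whose shifted chi-square stays within the 10% confidence region is
#'   flagged as poorly constrained.  More robust than the always-on local
#'   curvature check (which can miss long curved valleys), at the cost of
#'   extra re-optimizations.
#' @param rtol,atol ODE integration tolerances used inside the objective.
#' @return An object of class `fit_result`: best-fit parameters, fixed
#'   parameters, chi-square, per-course residuals, derived parameters,
#'   convergence status, identifiability warnings and the decreasing
#'   chi-square trace of the accepted optimizer iterations.
#' @export
fit_global <- function(data, free, fixed = list(), guesses = NULL,
                       bounds = NULL, weights = NULL, n_starts = 5,
                       seed = 1, check_identifiability = FALSE,
                       rtol = 1e-8, atol = 1e-6) {
  sets <- if (inherits(data, "experiment_set")) list(data) else data
  stopifnot(all(vapply(sets, inherits, TRUE, "experiment_set")))
  scheme_id <- sets[[1]]$scheme_id
  all_names <- if (scheme_id == "scheme1")
    c("k1", "k_minus1", "k2", "k_minus2", "k3")
  else stop("use fit_processive() for scheme2 experiment sets")
  free <- as.character(free)
  if (!all(free %in% all_names))
    stop("unknown free parameters: ",
         paste(setdiff(free, all_names), collapse = ", "))
  fixed <- as.list(fixed)
  if (!"k2" %in% c(free, names(fixed))) fixed$k2 <- 0.5
  missing <- setdiff(all_names, c(free, names(fixed)))
  if (length(missing))
    stop("parameters neither free nor fixed: ", paste(missing, collapse = ", "))

  default_guess <- c(k1 = 0.01, k_minus1 = 1, k2 = 0.5, k_minus2 = 100, k3 = 10)
  if (is.null(guesses)) {
    auto <- .scheme1_auto_guesses(sets, if ("k2" %in% names(fixed)) fixed$k2 else 0.5)
    if (!is.null(auto)) default_guess[names(auto)] <- auto
    guesses <- default_guess[free]
  }
  guesses <- stats::setNames(as.numeric(guesses[free]), free)
  if (anyNA(guesses)) stop("guesses must cover every free parameter")
  b <- .default_bounds(free)
  if (!is.null(bounds)) {
    if (!is.null(bounds$lower)) b$lower[names(bounds$lower)] <- bounds$lower
    if (!is.null(bounds$upper)) b$upper[names(bounds$upper)] <- bounds$upper
  }
  if (any(guesses < b$lower | guesses > b$upper))
    stop("guesses must lie within the bounds")
  n_points <- sum(vapply(sets, function(s)
    sum(vapply(s$courses, function(tc) length(tc$times), 0L)), 0L))
  if (length(free) >= n_points)
    stop("more free parameters than data points")

  # per-course weights in the caller's course order, then a canonical sort
  # by titrated value so the optimum does not depend on course order (the
  # objective is order-invariant mathematically; sorting removes
  # floating-point path sensitivity)
  sets_w <- list(); cursor <- 0
  for (si in seq_along(sets)) {
    n <- length(sets[[si]]$courses)
    sets_w[[si]] <- if (is.null(weights)) rep(list(1), n)
                    else if (is.list(weights)) weights[cursor + seq_len(n)]
                    else rep(list(weights), n)
    cursor <- cursor + n
  }
  for (si in seq_along(sets)) {
    sv <- vapply(sets[[si]]$courses, function(tc) {
      v <- tc$meta$series_value
      if (is.null(v)) NA_real_ else as.numeric(v)
    }, numeric(1))
    ord <- order(sv, na.last = TRUE)
    sets[[si]]$courses <- sets[[si]]$courses[ord]
    sets[[si]]$inits <- sets[[si]]$inits[ord]
    sets_w[[si]] <- sets_w[[si]][ord]
  }

  base_par <- unlist(fixed)
  resid_given <- function(par) {
    par_full <- base_par
    par_full[names(par)] <- par
    unlist(lapply(seq_along(sets), function(si) {
      s <- sets[[si]]
      curves <- eval_model_curves(s, par_full, rtol = rtol, atol = atol)
      unlist(lapply(seq_along(s$courses), function(i) {
        sqrt(sets_w[[si]][[i]]) * (s$courses[[i]]$values - curves[[i]])
      }))
    }), use.names = FALSE)
  }
  best <- .lm_multistart(resid_given, guesses, b$lower, b$upper,
                         n_starts = n_starts, seed = seed)
  par <- stats::setNames(10^stats::coef(best), free)
  full <- unlist(fixed); full[free] <- par
  derived <- if (all(c("k1", "k_minus1", "k2", "k_minus2", "k3") %in% names(full)))
    try(derived_parameters(rate_constants(full[["k1"]], full[["k_minus1"]],
                                          full[["k2"]], full[["k_minus2"]],
                                          full[["k3"]])), silent = TRUE)
  warn <- .identifiability_warnings(best$hessian, free)
  residuals <- resid_given(full)
  chisq <- sum(residuals^2)
  if (check_identifiability && length(free) >= 2) {
    for (p in free) {
      nuis <- par[setdiff(free, p)]
      d_up <- .reopt_nuisance(resid_given,
                              stats::setNames(par[[p]] * 1.5, p),
                              nuis, b$lower, b$upper)$chisq
      d_dn <- .reopt_nuisance(resid_given,
                              stats::setNames(par[[p]] / 1.5, p),
                              nuis, b$lower, b$upper)$chisq
      lim <- 1.1 * chisq + 1e-9 * n_points
      if (is.finite(d_up) && is.finite(d_dn) && min(d_up, d_dn) <= lim)
        warn <- c(warn, paste0(
          "parameter '", p, "' is poorly constrained: a 50% change stays ",
          "inside the 10% chi-square region after re-optimizing the others"))
    }
  }
  structure(list(
    par = par, fixed = unlist(fixed), free = free,
    chisq = chisq, residuals = residuals, n_points = n_points,
    derived = if (inherits(derived, "try-error")) NULL else derived,
    converged = best$info %in% 1:4, info = best$info, message = best$message,
    warnings = warn, rsstrace = best$rsstrace,
    n_starts = n_starts, seed = seed, guesses = guesses, bounds = b,
    resid_given = resid_given, scheme_id = scheme_id),
    class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("Global fit (%s): chi-square = %.6g over %d points%s\n",
              x$scheme_id, x$chisq, x$n_points,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  for (nm in names(x$par)) cat(sprintf("  %-10s = %.6g\n", nm, x$par[[nm]]))
  if (length(x$fixed))
    cat("fixed:", paste(names(x$fixed), signif(x$fixed, 4), sep = " = ",
                        collapse = ", "), "\n")
  if (!is.null(x$derived) && inherits(x$derived, "derived_params")) {
    cat("derived:\n"); print(x$derived)
  }
  for (w in x$warnings) cat("warning:", w, "\n")
  invisible(x)
}

#' Fit the burst equation to a multiple-turnover time course
#'
#' Least-squares fit of [burst_model()]; the DNA dissociation rate is
#' derived from the fitted amplitude and steady-state slope as
#' k_off = k_ss / A.  The amplitude (active enzyme-DNA complex) is free by
#' default; supply `active_E` to fix it to an independently titrated value.
#'
#' @param tc a [time_course()] spanning both the burst and linear phases
#'   (>= 5 points).
#' @param active_E optional fixed amplitude (nM).
#' @return List with elements `A` (nM), `k_obs` (s^-1), `k_ss` (nM s^-1),
#'   `k_off` (s^-1), `chisq` and `fitted`.
#' @export
fit_burst <- function(tc, active_E = NULL) {
  stopifnot(inherits(tc, "time_course"))
  t <- tc$times; y <- tc$values
  if (length(t) < 5) stop("need at least 5 points spanning burst and linear phases")
  tail_i <- which(t >= stats::quantile(t, 2 / 3))
  if (length(tail_i) < 2) tail_i <- utils::tail(seq_along(t), 3)
  lin <- stats::lm(y[tail_i] ~ t[tail_i])
  A0 <- max(stats::coef(lin)[1], max(y) / 4, 1e-6)
  kss0 <- max(stats::coef(lin)[2], 0)
  half <- t[which(y >= A0 / 2)[1]]
  k0 <- if (is.na(half) || half <= 0) 1 / max(t[1], 1e-3) else log(2) / half
  if (is.null(active_E)) {
    resid <- function(p) y - burst_model(t, p[["A"]], p[["k_obs"]], p[["k_ss"]])
    guesses <- c(A = A0, k_obs = k0, k_ss = max(kss0, 1e-6))
  } else {
    resid <- function(p) y - burst_model(t, active_E, p[["k_obs"]], p[["k_ss"]])
    guesses <- c(k_obs = k0, k_ss = max(kss0, 1e-6))
  }
  b <- .default_bounds(names(guesses))
  fit <- .lm_multistart(resid, guesses, b$lower, b$upper, n_starts = 3, seed = 1)
  p <- stats::setNames(10^stats::coef(fit), names(guesses))
  A <- if (is.null(active_E)) p[["A"]] else active_E
  k_ss <- p[["k_ss"]]
  if (k_ss <= 1.0001e-6) k_ss <- 0  # at the lower bound: no steady phase
  fitted <- burst_model(t, A, p[["k_obs"]], k_ss)
  # a burst model must beat a straight line; if not, the data carry no
  # exponential curvature and the amplitude/rate are meaningless
  lin_sse <- sum(stats::resid(stats::lm(y ~ t))^2)
  fit_sse <- sum((y - fitted)^2)
  if (fit_sse >= lin_sse * (1 - 1e-3) - 1e-12 ||
      p[["k_obs"]] <= 1.0001e-6 || A <= 1e-6 * max(abs(y), 1))
    stop("degenerate burst fit: no exponential curvature detectable")
  list(A = A, k_obs = p[["k_obs"]], k_ss = k_ss, k_off = k_ss / A,
       chisq = sum((y - fitted)^2), fitted = fitted)
}

#' Fit a single-exponential decay
#'
#' Least-squares fit of [exponential_decay()] (`A0 exp(-k t) + C`), used for
#' mismatch-excision time courses; the fitted rate is the excision rate
#' k_exo.  Data without detectable decay yield k_exo ~ 0 with a warning
#' rather than an error.
#'
#' @param tc a [time_course()] with >= 4 points.
#' @return List with `A0`, `k_exo`, `C`, `chisq`, `fitted` and a
#'   `warnings` character vector.
#' @export
fit_exponential <- function(tc) {
  stopifnot(inherits(tc, "time_course"))
  t <- tc$times; y <- tc$values
  if (length(t) < 4) stop("need at least 4 points")
  C0 <- min(y); A00 <- max(y[1] - C0, 1e-6)
  half_t <- t[which(y - C0 <= A00 / 2)[1]]
  k0 <- if (is.na(half_t) || half_t <= 0) 1 / max(t[length(t)], 1e-3)
        else log(2) / half_t
  # A0 and C are linear given k: profile them out and search k only.
  resid <- function(p) {
    k <- p[["k_exo"]]
    x <- exp(-k * t)
    co <- stats::coef(stats::lm(y ~ x))
    if (any(!is.finite(co))) co <- c(mean(y), 0)
    y - (co[2] * x + co[1])
  }
  b <- .default_bounds("k_exo")
  fit <- .lm_multistart(resid, c(k_exo = k0), b$lower, b$upper,
                        n_starts = 3, seed = 1)
  k <- 10^stats::coef(fit)[[1]]
  x <- exp(-k * t)
  co <- stats::coef(stats::lm(y ~ x))
  warnings <- character(0)
  if (k <= 1.0001e-6 || co[2] <= 1e-8 * max(abs(y), 1)) {
    warnings <- "no decay detected: k_exo is effectively 0"
    k <- 0; co <- c(mean(y), 0)
    fitted <- rep(mean(y), length(y))
  } else fitted <- co[2] * x + co[1]
  list(A0 = unname(co[2]), k_exo = k, C = unname(co[1]),
       chisq = sum((y - fitted)^2), fitted = fitted, warnings = warnings)
}

#' Global fit of the processive-incorporation model to gel-band ladders
#'
#' Jointly estimates the per-position incorporation rates kpol_1..n and the
#' DNA dissociation constant K_d,DNA from per-length band time courses
#' (fractional band intensity times total DNA concentration).  The DNA
#' association rate is fixed (see [processive_rates()]); K_d,DNA is the free
#' equilibrium parameter.
#'
#' @param data an [experiment_set()] with `scheme_id = "scheme2"` whose
#'   courses are the band time courses (observables `band_25`, `band_26`,
#'   ...).
#' @param n_steps number of incorporation steps; must be at most
#'   (number of bands - 1).
#' @param guesses optional named guesses for `kpol1..n` and `Kd_dna`.
#' @param weights optional per-band weights: a list of per-point vectors
#'   (or one numeric recycled per band).  Band courses span very different
#'   dynamic ranges, so 1/sigma^2 weighting is recommended when the noise
#'   scale is known.
#' @param n_starts,seed,rtol,atol as in [fit_global()].
#' @return A `fit_result` whose `par` holds the rate ladder and K_d,DNA and
#'   whose `processive` element is the fitted [processive_rates()] object.
#' @export
fit_processive <- function(data, n_steps, guesses = NULL, weights = NULL,
                           n_starts = 3, seed = 1, rtol = 1e-8,
                           atol = 1e-6) {
  stopifnot(inherits(data, "experiment_set"), data$scheme_id == "scheme2")
  n_bands <- length(data$courses)
  if (n_steps > n_bands - 1)
    stop("more incorporation steps (", n_steps, ") than band intervals (",
         n_bands - 1, ")")
  free <- c(paste0("kpol", seq_len(n_steps)), "Kd_dna")
  if (is.null(guesses))
    guesses <- stats::setNames(c(rep(30, n_steps), 20), free)
  b <- .default_bounds(free)
  w_list <- if (is.null(weights)) rep(list(1), n_bands)
            else if (is.list(weights)) weights else rep(list(weights), n_bands)
  resid_given <- function(par_full) {
    curves <- eval_model_curves(data, par_full, rtol = rtol, atol = atol)
    unlist(lapply(seq_along(data$courses), function(i)
      sqrt(w_list[[i]]) * (data$courses[[i]]$values - curves[[i]])),
      use.names = FALSE)
  }
  best <- .lm_multistart(function(p) resid_given(p), guesses,
                         b$lower, b$upper, n_starts = n_starts, seed = seed)
  par <- stats::setNames(10^stats::coef(best), free)
  residuals <- resid_given(par)
  k_on <- if (is.null(data$scheme_args$k_on)) 0.002 else data$scheme_args$k_on
  structure(list(
    par = par, fixed = c(k_on = k_on), free = free,
    chisq = sum(residuals^2), residuals = residuals,
    n_points = length(residuals),
    processive = processive_rates(unname(par[seq_len(n_steps)]),
                                  par[["Kd_dna"]], k_on = k_on),
    derived = NULL, converged = best$info %in% 1:4, info = best$info,
    message = best$message,
    warnings = .identifiability_warnings(best$hessian, free),
    rsstrace = best$rsstrace, n_starts = n_starts, seed = seed,
    guesses = guesses, bounds = b, resid_given = resid_given,
    scheme_id = "scheme2"),
    class = "fit_result")
}
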