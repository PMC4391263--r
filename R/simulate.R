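#' A single observed kinetic time course
#'
#' @param times sampling times (s), strictly increasing, all >= 0.
#' @param values observed concentrations (nM), same length as `times`.
#' @param observable name of the observed quantity (a scheme observable).
#' @param meta named list of metadata: typically the titrated concentration
#'   (`series_value`, `series_unit`) and an `experiment_id`.
#' @return Object of class `time_course`.
#' @export
time_course <- function(times, values, observable, meta = list()) {
  times <- as.numeric(times); values <- as.numeric(values)
  if (length(times) != length(values)) stop("times and values lengths differ")
  if (length(times) && times[1] < 0) stop("times must be >= 0")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (any(!is.finite(values))) stop("values must be finite")
  structure(list(times = times, values = values,
                 observable = as.character(observable), meta = meta),
            class = "time_course")
}

#' @export
print.time_course <- function(x, ...) {
  cat(sprintf("Time course '%s': %d points, t in [%g, %g] s\n",
              x$observable, length(x$times),
              if (length(x$times)) x$times[1] else NA,
              if (length(x$times)) x$times[length(x$times)] else NA))
  invisible(x)
}

#' Initial state for a scheme simulation
#'
#' @param scheme a `kinetic_scheme`.
#' @param ... named initial concentrations (nM); unnamed species start at 0.
#' @return Named numeric vector over all scheme species.
#' @export
initial_state <- function(scheme, ...) {
  conc <- c(...)
  y0 <- stats::setNames(numeric(length(scheme$species)), scheme$species)
  if (length(conc)) {
    bad <- setdiff(names(conc), scheme$species)
    if (length(bad)) stop("unknown species: ", paste(bad, collapse = ", "))
    if (any(conc < 0)) stop("initial concentrations must be >= 0")
    y0[names(conc)] <- conc
  }
  y0
}

#' Equilibrium partitioning of a pre-incubated binding mixture
#'
#' Solves the one-site binding equilibrium E + D <-> ED for the complex
#' concentration given totals and a dissociation constant; used to encode
#' the pre-incubation of enzyme with DNA before mixing (the equilibrium is
#' assumed reached during the pre-incubation).
#'
#' @param E_total total enzyme (nM).
#' @param D_total total DNA (nM).
#' @param Kd dissociation constant (nM).
#' @return List with free `E`, free `D` and complex `ED` (nM).
#' @export
preequilibrate_binding <- function(E_total, D_total, Kd) {
  stopifnot(E_total >= 0, D_total >= 0, Kd >= 0)
  b <- E_total + D_total + Kd
  ED <- (b - sqrt(b * b - 4 * E_total * D_total)) / 2
  ED <- min(ED, E_total, D_total)  # guard rounding at Kd ~ 0
  list(E = E_total - ED, D = D_total - ED, ED = ED)
}

# Flatten a scheme into the parameter vector understood by the compiled
# mass-action derivative (see src/massaction.c).
.scheme_parms <- function(scheme) {
  idx <- stats::setNames(seq_along(scheme$species) - 1L, scheme$species)
  p <- c(length(scheme$species), length(scheme$reactions))
  for (rx in scheme$reactions) {
    r <- idx[rx$reactants]; pr <- idx[rx$products]
    p <- c(p, rx$value,
           length(r),  if (length(r) >= 1) r[1] else -1, if (length(r) >= 2) r[2] else -1,
           length(pr), if (length(pr) >= 1) pr[1] else -1, if (length(pr) >= 2) pr[2] else -1)
  }
  if (length(p) > 1024L) stop("scheme too large for the compiled derivative")
  c(unname(p), numeric(1024L - length(p)))
}

#' Deterministic mass-action simulation of a kinetic scheme
#'
#' Integrates the scheme's mass-action ODE system with a stiff-capable
#' solver (`deSolve::lsoda` driving a compiled derivative) and returns one
#' [time_course()] per declared observable, evaluated at the requested times.
#'
#' @param scheme a `kinetic_scheme`.
#' @param init named numeric initial state (nM) over the scheme's species,
#'   e.g. from [initial_state()].
#' @param times strictly increasing sampling times (s), first >= 0.
#' @param rtol,atol relative / absolute integration tolerances (absolute in
#'   nM).
#' @return Named list of `time_course` objects, one per observable, with the
#'   full species trajectory matrix attached as attribute `"species"`.
#' @export
simulate_scheme <- function(scheme, init, times, rtol = 1e-8, atol = 1e-6) {
  stopifnot(inherits(scheme, "kinetic_scheme"))
  if (!all(scheme$species %in% names(init)))
    stop("init must name every species of the scheme")
  y0 <- as.numeric(init[scheme$species])
  if (any(y0 < 0)) stop("initial concentrations must be >= 0")
  times <- as.numeric(times)
  if (length(times) == 0 || times[1] < 0 || any(diff(times) <= 0))
    stop("times must be strictly increasing and start at >= 0")
  tt <- if (times[1] > 0) c(0, times) else times
  out <- try(suppressWarnings(deSolve::lsoda(
    y = stats::setNames(y0, scheme$species), times = tt,
    func = "polgkin_derivs", parms = .scheme_parms(scheme),
    dllname = "polgkin", initfunc = "polgkin_initmod",
    rtol = rtol, atol = atol, maxsteps = 20000)), silent = TRUE)
  if (inherits(out, "try-error") || nrow(out) < length(tt) ||
      anyNA(out[, -1, drop = FALSE]))
    stop("ODE integration failed for scheme '", scheme$id, "' with rates ",
         paste(vapply(scheme$reactions, function(r)
           paste0(r$rate, "=", signif(r$value, 4)), ""), collapse = ", "))
  if (times[1] > 0) out <- out[-1, , drop = FALSE]
  species <- out[, scheme$species, drop = FALSE]
  res <- lapply(names(scheme$observables), function(nm) {
    cols <- scheme$observables[[nm]]
    time_course(times, rowSums(species[, cols, drop = FALSE]), nm,
                meta = list(scheme = scheme$id))
  })
  names(res) <- names(scheme$observables)
  attr(res, "species") <- species
  attr(res, "times") <- times
  res
}

#' Closed-form burst equation
#'
#' Product formation under multiple-turnover conditions: a fast exponential
#' first turnover of amplitude `A` and observed rate `k_obs`, followed by a
#' linear steady-state phase of slope `k_ss` limited by product-DNA release,
#' so that `[product](t) = A (1 - exp(-k_obs t)) + k_ss t`.  The DNA
#' dissociation rate follows as k_off = k_ss / A.
#'
#' @param t time (s), vectorized; must be >= 0.
#' @param A burst amplitude, the active enzyme-DNA complex concentration (nM).
#' @param k_obs burst (first-turnover) rate (s^-1).
#' @param k_ss steady-state rate (nM s^-1).
#' @return Product concentration (nM).
#' @export
burst_model <- function(t, A, k_obs, k_ss) {
  if (any(t < 0)) stop("negative time")
  stopifnot(A >= 0, k_obs >= 0, k_ss >= 0)
  A * (1 - exp(-k_obs * t)) + k_ss * t
}

#' Single-exponential decay
#'
#' `A0 exp(-k t) + C`; used for mismatch-excision time courses, where `k` is
#' the excision rate k_exo.
#'
#' @param t time (s), vectorized.
#' @param A0 decaying amplitude (fraction or nM).
#' @param k first-order rate (s^-1), >= 0.
#' @param C offset.
#' @return Value at `t`.
#' @export
exponential_decay <- function(t, A0, k, C = 0) {
  if (k < 0) stop("decay rate must be >= 0")
  A0 * exp(-k * t) + C
}
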