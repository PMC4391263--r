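#' A titration series of time courses sharing one mechanism
#'
#' Groups time courses that are fit globally: all reference the same scheme
#' and differ in one titrated concentration (dNTP or DNA).  Each course
#' carries its own initial-state specification, which is either a fixed named
#' concentration vector or a pre-equilibration recipe resolved from the
#' current parameters at fit time (so DNA-binding information in the
#' pre-incubation is propagated into the fit).
#'
#' @param courses list of [time_course()] objects.
#' @param scheme_id `"scheme1"` or `"scheme2"`.
#' @param inits list (same length as `courses`) of initial-state specs: a
#'   named numeric vector of concentrations, or a list
#'   `list(preequilibrate = TRUE, E_total =, D_total =, N0 =)` resolved from
#'   the fitted K_d,DNA.
#' @param titration name of the titrated variable (e.g. `"dNTP"`, `"DNA"`);
#'   `NULL` for single-course sets.
#' @param scheme_args extra fixed arguments for the scheme builder (for
#'   scheme2: `k_on`, `trap`).
#' @return Object of class `experiment_set`.
#' @export
experiment_set <- function(courses, scheme_id = c("scheme1", "scheme2"),
                           inits, titration = NULL, scheme_args = list()) {
  scheme_id <- match.arg(scheme_id)
  if (!length(courses) || !all(vapply(courses, inherits, TRUE, "time_course")))
    stop("courses must be a non-empty list of time_course objects")
  if (length(inits) != length(courses))
    stop("one initial-state spec per course is required")
  if (!is.null(titration)) {
    sv <- vapply(courses, function(tc) {
      v <- tc$meta$series_value
      if (is.null(v)) NA_real_ else as.numeric(v)
    }, numeric(1))
    if (anyDuplicated(sv[!is.na(sv)]))
      stop("titrated variable '", titration, "' must differ across courses")
  }
  structure(list(courses = courses, scheme_id = scheme_id, inits = inits,
                 titration = titration, scheme_args = scheme_args),
            class = "experiment_set")
}

#' @export
print.experiment_set <- function(x, ...) {
  cat(sprintf("Experiment set (%s): %d courses, %d points%s\n",
              x$scheme_id, length(x$courses),
              sum(vapply(x$courses, function(tc) length(tc$times), 0L)),
              if (is.null(x$titration)) "" else paste0(", titrating ", x$titration)))
  invisible(x)
}

# Resolve an initial-state spec into a full species vector for a scheme.
# Kd is the current DNA dissociation constant (nM), used for pre-equilibrated
# binding mixtures.
.resolve_init <- function(scheme, spec, Kd) {
  if (is.numeric(spec)) return(initial_state(scheme, spec))
  if (isTRUE(spec$preequilibrate)) {
    eq <- preequilibrate_binding(spec$E_total, spec$D_total, Kd)
    if (scheme$id == "scheme1")
      return(initial_state(scheme,
                           c(E = eq$E, D25 = eq$D, ED25 = eq$ED,
                             N = if (is.null(spec$N0)) 0 else spec$N0)))
    if (scheme$id == "scheme2")
      return(initial_state(scheme, c(E = eq$E, D25 = eq$D, ED25 = eq$ED)))
  }
  stop("unrecognized initial-state specification")
}

# Build the scheme for an experiment set from a full named parameter vector.
.build_set_scheme <- function(set, par) {
  if (set$scheme_id == "scheme1") {
    rates <- rate_constants(k1 = par[["k1"]], k_minus1 = par[["k_minus1"]],
                            k2 = par[["k2"]], k_minus2 = par[["k_minus2"]],
                            k3 = par[["k3"]])
    list(scheme = build_scheme1(rates), Kd = par[["k_minus1"]] / par[["k1"]])
  } else {
    kp <- par[grep("^kpol", names(par))]
    kp <- kp[order(as.integer(sub("kpol", "", names(kp))))]
    k_on <- if (is.null(set$scheme_args$k_on)) 0.002 else set$scheme_args$k_on
    trap <- isTRUE(set$scheme_args$trap)
    p <- processive_rates(unname(kp), par[["Kd_dna"]], k_on = k_on)
    list(scheme = build_scheme2(p, trap = trap), Kd = par[["Kd_dna"]])
  }
}

#' Evaluate model curves for an experiment set
#'
#' Simulates the set's mechanism at a full named parameter vector and returns
#' the model-predicted values aligned with each course (same observable, same
#' times).  Courses sharing an identical initial state and time grid are
#' served by a single integration.
#'
#' @param set an [experiment_set()].
#' @param par named numeric vector of all mechanism parameters in native
#'   units (scheme1: k1, k_minus1, k2, k_minus2, k3; scheme2: kpol1..n,
#'   Kd_dna).
#' @param rtol,atol integration tolerances passed to [simulate_scheme()].
#' @return List of numeric vectors, one per course.
#' @export
eval_model_curves <- function(set, par, rtol = 1e-8, atol = 1e-6) {
  built <- .build_set_scheme(set, par)
  scheme <- built$scheme
  keys <- vapply(seq_along(set$courses), function(i)
    paste(c(format(.resolve_init(scheme, set$inits[[i]], built$Kd), digits = 15),
            format(set$courses[[i]]$times, digits = 15)), collapse = ","),
    character(1))
  sims <- new.env(parent = emptyenv())
  lapply(seq_along(set$courses), function(i) {
    tc <- set$courses[[i]]
    if (is.null(sims[[keys[i]]])) {
      init <- .resolve_init(scheme, set$inits[[i]], built$Kd)
      sims[[keys[i]]] <- simulate_scheme(scheme, init, tc$times,
                                         rtol = rtol, atol = atol)
    }
    out <- sims[[keys[i]]]
    if (!tc$observable %in% names(out))
      stop("observable '", tc$observable, "' not defined by ", scheme$id)
    out[[tc$observable]]$values
  })
}

#' Weighted sum-of-squares objective
#'
#' The global fitting objective: `sum_i w_i (y_i - yhat_i)^2` over every
#' point of every course.  Unit weights by default; with a perfect model the
#' value is 0.
#'
#' @param model_curves list of numeric vectors (model predictions), aligned
#'   one-to-one with `data$courses`; `time_course` objects are also accepted.
#' @param data an [experiment_set()].
#' @param weights optional list of per-point weight vectors (or a single
#'   numeric recycled per course).
#' @return The chi-square value (a single non-negative number).
#' @export
chi_square <- function(model_curves, data, weights = NULL) {
  stopifnot(inherits(data, "experiment_set"))
  if (length(model_curves) != length(data$courses))
    stop("model_curves and data have different numbers of courses")
  total <- 0
  for (i in seq_along(data$courses)) {
    m <- model_curves[[i]]
    if (inherits(m, "time_course")) m <- m$values
    y <- data$courses[[i]]$values
    if (length(m) != length(y))
      stop("course ", i, ": model and data lengths differ (",
           length(m), " vs ", length(y), ")")
    w <- if (is.null(weights)) 1
         else if (is.list(weights)) weights[[i]] else weights
    total <- total + sum(w * (y - m)^2)
  }
  total
}
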