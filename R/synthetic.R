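#' Noise model for synthetic rapid-quench data
#'
#' Gaussian noise with standard deviation `rel * max(|course|) + add`
#' applied pointwise to each simulated course: a relative component scaled
#' to the course's dynamic range plus an additive floor, emulating the
#' scatter of quantified gel bands.  The defaults (5% relative, 0.5 nM
#' additive) are the study conditions used throughout the recovery analyses.
#'
#' @param rel relative standard deviation (fraction of the per-course
#'   maximum).
#' @param add additive standard deviation (nM).
#' @return Object of class `noise_model`.
#' @export
noise_model <- function(rel = 0.05, add = 0.5) {
  stopifnot(rel >= 0, add >= 0)
  structure(list(rel = rel, add = add), class = "noise_model")
}

.apply_noise <- function(values, noise) {
  if (noise$rel == 0 && noise$add == 0) return(values)
  sigma <- noise$rel * max(abs(values)) + noise$add
  values + stats::rnorm(length(values), 0, sigma)
}

# Log-spaced sampling times from t_min to t_max (strictly increasing).
.log_times <- function(t_min, t_max, n) {
  exp(seq(log(t_min), log(t_max), length.out = n))
}

#' Experiment design for the synthetic-data generators
#'
#' Bundles everything a generator needs: the mechanism, the truth
#' parameters, initial concentrations, the titration grid, sampling times,
#' the noise model and the seed.  Class-specific constructors below fill in
#' the published concentration designs as defaults.
#'
#' @param scheme one of `"scheme1"`, `"scheme2"`, `"burst"`, `"exponential"`.
#' @param truth truth parameters (`rate_constants`, `processive_rates`, or a
#'   named list for the closed-form models).
#' @param init named list of initial concentrations (nM).
#' @param titration list with `values` (numeric, distinct) and `unit`.
#' @param times sampling times (s); `NULL` to derive from the truth rates.
#' @param n_times number of samples per course when `times` is derived.
#' @param replicates replicate count for recovery studies.
#' @param noise a [noise_model()].
#' @param seed integer; identical (design, seed) pairs regenerate identical
#'   datasets.
#' @return Object of class `experiment_design`.
#' @export
experiment_design <- function(scheme, truth, init = list(), titration = NULL,
                              times = NULL, n_times = 12, replicates = 1,
                              noise = noise_model(), seed = 1) {
  if (!is.null(times)) {
    if (any(times <= 0) || any(diff(times) <= 0))
      stop("sample times must be positive and strictly increasing")
  }
  if (!is.null(titration) && anyDuplicated(titration$values))
    stop("titration values must be distinct")
  structure(list(scheme = scheme, truth = truth, init = init,
                 titration = titration, times = times, n_times = n_times,
                 replicates = replicates, noise = noise, seed = seed),
            class = "experiment_design")
}

#' @rdname experiment_design
#' @param enzyme enzyme preset (`"S305R"`, `"WT"`, `"P1073L"`) supplying
#'   truth rates and the published dNTP grid.
#' @param dntp_uM nucleotide titration grid (uM).
#' @param E_total,D_total pre-incubated enzyme and DNA totals (nM).
#' @param ... passed on to [experiment_design()].
#' @export
design_single_turnover <- function(enzyme = "S305R",
                                   truth = polg_rates(enzyme),
                                   dntp_uM = NULL,
                                   E_total = 100, D_total = 75, ...) {
  if (is.null(dntp_uM))
    dntp_uM <- switch(enzyme,
                      S305R  = c(0.05, 0.2, 0.4, 1, 6, 17),
                      P1073L = c(0.2, 0.5, 1.5, 3, 5, 10),
                      WT     = c(0.1, 0.3, 0.7, 1.5, 5, 15))
  experiment_design("scheme1", truth,
                    init = list(E_total = E_total, D_total = D_total),
                    titration = list(name = "dNTP", values = dntp_uM,
                                     unit = "uM"), ...)
}

#' @rdname experiment_design
#' @param dna_nM DNA titration grid (nM).
#' @param dntp_uM_fixed fixed nucleotide concentration (uM).
#' @export
design_dna_titration <- function(enzyme = "S305R",
                                 truth = polg_rates(enzyme),
                                 dna_nM = c(10, 30, 50, 100, 200, 300),
                                 E_total = 55, dntp_uM_fixed = 100, ...) {
  experiment_design("scheme1", truth,
                    init = list(E_total = E_total,
                                N0 = dntp_uM_fixed * 1000),
                    titration = list(name = "DNA", values = dna_nM,
                                     unit = "nM"), ...)
}

#' @rdname experiment_design
#' @param dntp_uM_burst nucleotide concentration for the burst assay (uM).
#' @export
design_burst <- function(enzyme = "S305R", truth = polg_rates(enzyme),
                         E_total = 100, D_total = 350,
                         dntp_uM_burst = 50, ...) {
  experiment_design("burst", truth,
                    init = list(E_total = E_total, D_total = D_total,
                                N0 = dntp_uM_burst * 1000), ...)
}

#' @rdname experiment_design
#' @param k_exo excision-rate truth (s^-1); defaults to the preset enzyme's
#'   published rate.
#' @export
design_excision <- function(enzyme = "WT", truth = polg_rates(enzyme),
                            k_exo = attr(truth, "k_exo"),
                            D_total = 75, ...) {
  experiment_design("exponential",
                    list(A0 = D_total, k_exo = k_exo, C = 0),
                    init = list(D_total = D_total), ...)
}

#' @rdname experiment_design
#' @param kpol incorporation-rate ladder (s^-1).
#' @param Kd_dna DNA dissociation constant (nM).
#' @param k_on DNA association rate used to realize the equilibrium
#'   (nM^-1 s^-1).
#' @export
design_processive <- function(kpol = c(65, 36, 48, 28, 7), Kd_dna = 15,
                              k_on = 0.002, E_total = 150, D_total = 75,
                              n_times = 14, ...) {
  experiment_design("scheme2", processive_rates(kpol, Kd_dna, k_on = k_on),
                    init = list(E_total = E_total, D_total = D_total),
                    n_times = n_times, ...)
}

# Sampling-time default for scheme1 courses: log-spaced over a window
# spanning ~3 half-lives of the fast (burst) phase plus the slower
# enzyme-DNA re-equilibration phase, as a quench-flow series would.  The
# slow-phase extension is capped at ten fast half-lives: when dissociation
# is much slower than chemistry the product trace is flat there and a
# quench-flow series would not be extended further.
.scheme1_times <- function(truth, N0, n) {
  Kd_app <- truth$k_minus2 / truth$k2
  k_fast <- max(truth$k3 * N0 / (N0 + Kd_app), 1e-3)
  k_slow <- max(truth$k_minus1, k_fast / 10)
  t_max <- 3 * log(2) / k_fast + 3 * log(2) / k_slow
  .log_times(log(2) / k_fast / 20, t_max, n)
}

#' Synthetic single-turnover nucleotide titration
#'
#' Emulates the rapid-quench single-nucleotide incorporation titration: a
#' pre-incubated enzyme-DNA mixture (partitioned at the truth K_d,DNA) is
#' mixed with each nucleotide concentration of the design grid and product
#' formation (26-mer) is sampled over time, with gel-quantification noise.
#'
#' @param design a [design_single_turnover()] design.
#' @return An [experiment_set()]; the zero-noise model curves are attached
#'   as attribute `"truth_curves"` and the design as `"design"`.
#' @export
gen_single_turnover <- function(design) {
  stopifnot(inherits(design, "experiment_design"), design$scheme == "scheme1")
  truth <- design$truth
  E0 <- design$init$E_total; D0 <- design$init$D_total
  if (E0 < D0)
    warning("single-turnover design has [enzyme] < [DNA]; ",
            "multiple turnovers will contribute")
  set.seed(design$seed)
  nM <- design$titration$values *
    if (design$titration$unit == "uM") 1000 else 1
  courses <- list(); inits <- list(); truth_curves <- list()
  for (i in seq_along(nM)) {
    times <- if (is.null(design$times))
      .scheme1_times(truth, nM[i], design$n_times) else design$times
    spec <- list(preequilibrate = TRUE, E_total = E0, D_total = D0,
                 N0 = nM[i])
    par <- c(k1 = truth$k1, k_minus1 = truth$k_minus1, k2 = truth$k2,
             k_minus2 = truth$k_minus2, k3 = truth$k3)
    tmp_set <- experiment_set(
      list(time_course(times, numeric(length(times)), "product26",
                       meta = list(series_value = design$titration$values[i],
                                   series_unit = design$titration$unit,
                                   experiment_id = paste0("st_", i)))),
      "scheme1", list(spec))
    clean <- eval_model_curves(tmp_set, par)[[1]]
    truth_curves[[i]] <- clean
    courses[[i]] <- time_course(
      times, .apply_noise(clean, design$noise), "product26",
      meta = list(series_value = design$titration$values[i],
                  series_unit = design$titration$unit,
                  experiment_id = paste0("st_", i)))
    inits[[i]] <- spec
  }
  out <- experiment_set(courses, "scheme1", inits,
                        titration = design$titration$name)
  attr(out, "truth_curves") <- truth_curves
  attr(out, "design") <- design
  out
}

#' Synthetic DNA-concentration titration
#'
#' Emulates the DNA-titration incorporation assay: fixed enzyme is
#' pre-incubated with each DNA concentration (binding equilibrium applied
#' before t = 0) and mixed with a saturating fixed nucleotide concentration.
#'
#' @param design a [design_dna_titration()] design.
#' @return An [experiment_set()] with attributes as in
#'   [gen_single_turnover()].
#' @export
gen_dna_titration <- function(design) {
  stopifnot(inherits(design, "experiment_design"), design$scheme == "scheme1")
  truth <- design$truth
  set.seed(design$seed)
  E0 <- design$init$E_total; N0 <- design$init$N0
  courses <- list(); inits <- list(); truth_curves <- list()
  dna <- design$titration$values
  for (i in seq_along(dna)) {
    times <- if (is.null(design$times))
      .scheme1_times(truth, N0, design$n_times) else design$times
    spec <- list(preequilibrate = TRUE, E_total = E0, D_total = dna[i],
                 N0 = N0)
    par <- c(k1 = truth$k1, k_minus1 = truth$k_minus1, k2 = truth$k2,
             k_minus2 = truth$k_minus2, k3 = truth$k3)
    tmp_set <- experiment_set(
      list(time_course(times, numeric(length(times)), "product26",
                       meta = list(series_value = dna[i], series_unit = "nM",
                                   experiment_id = paste0("dna_", i)))),
      "scheme1", list(spec))
    clean <- eval_model_curves(tmp_set, par)[[1]]
    truth_curves[[i]] <- clean
    courses[[i]] <- time_course(
      times, .apply_noise(clean, design$noise), "product26",
      meta = list(series_value = dna[i], series_unit = "nM",
                  experiment_id = paste0("dna_", i)))
    inits[[i]] <- spec
  }
  out <- experiment_set(courses, "scheme1", inits, titration = "DNA")
  attr(out, "truth_curves") <- truth_curves
  attr(out, "design") <- design
  out
}

#' Synthetic multiple-turnover burst assay
#'
#' Emulates the pre-steady-state burst experiment with DNA in excess over
#' enzyme: the closed-form [burst_model()] with amplitude equal to the
#' pre-equilibrated active complex, burst rate k3 N/(N + K_d,app) and
#' steady-state slope k_off * A.
#'
#' @param design a [design_burst()] design.
#' @return A [time_course()] with truth parameters attached as attribute
#'   `"truth_burst"` and the clean curve as `"truth_curve"`.
#' @export
gen_burst <- function(design) {
  stopifnot(inherits(design, "experiment_design"), design$scheme == "burst")
  truth <- design$truth
  set.seed(design$seed)
  eq <- preequilibrate_binding(design$init$E_total, design$init$D_total,
                               truth$k_minus1 / truth$k1)
  N0 <- design$init$N0
  Kd_app <- truth$k_minus2 / truth$k2
  A <- eq$ED
  k_obs <- truth$k3 * N0 / (N0 + Kd_app)
  k_ss <- truth$k_minus1 * A
  times <- if (is.null(design$times))
    c(.log_times(0.01, 3 * log(2) / k_obs, 8), seq(1, 8, 1)) else design$times
  times <- sort(unique(times))
  clean <- burst_model(times, A, k_obs, k_ss)
  tc <- time_course(times, .apply_noise(clean, design$noise), "product26",
                    meta = list(experiment_id = "burst",
                                series_value = N0 / 1000,
                                series_unit = "uM"))
  attr(tc, "truth_burst") <- list(A = A, k_obs = k_obs, k_ss = k_ss,
                                  k_off = truth$k_minus1)
  attr(tc, "truth_curve") <- clean
  attr(tc, "design") <- design
  tc
}

#' Synthetic mismatch-excision decay
#'
#' Emulates the exonuclease excision assay: single-exponential loss of the
#' full-length mismatched primer at the truth excision rate.
#'
#' @param design a [design_excision()] design.
#' @return A [time_course()] with the clean curve attached as attribute
#'   `"truth_curve"`.
#' @export
gen_excision <- function(design) {
  stopifnot(inherits(design, "experiment_design"),
            design$scheme == "exponential")
  set.seed(design$seed)
  tr <- design$truth
  times <- if (is.null(design$times))
    .log_times(log(2) / tr$k_exo / 20, 4 * log(2) / tr$k_exo,
               design$n_times) else design$times
  clean <- exponential_decay(times, tr$A0, tr$k_exo, tr$C)
  tc <- time_course(times, .apply_noise(clean, design$noise), "primer25",
                    meta = list(experiment_id = "excision"))
  attr(tc, "truth_curve") <- clean
  attr(tc, "design") <- design
  tc
}

#' Synthetic processive-polymerization product ladder
#'
#' Emulates the multi-nucleotide extension assay quantified per gel band:
#' pre-incubated enzyme-DNA (partitioned at the truth K_d,DNA) extends
#' through the rate ladder; each band time course is the per-length DNA
#' total, so the bands sum to the total DNA at every time (the
#' gel-quantification convention of fractional intensity times DNA
#' concentration).
#'
#' @param design a [design_processive()] design.
#' @return An [experiment_set()] (`scheme_id = "scheme2"`) with one course
#'   per band and attributes as in [gen_single_turnover()].
#' @export
gen_processive <- function(design) {
  stopifnot(inherits(design, "experiment_design"), design$scheme == "scheme2")
  p <- design$truth
  set.seed(design$seed)
  n <- length(p$kpol)
  times <- if (is.null(design$times))
    .log_times(0.003, 3 * log(2) / min(p$kpol) + 1.5, design$n_times)
  else design$times
  spec <- list(preequilibrate = TRUE, E_total = design$init$E_total,
               D_total = design$init$D_total)
  scheme <- build_scheme2(p)
  init <- .resolve_init(scheme, spec, p$Kd_dna)
  sim <- simulate_scheme(scheme, init, times)
  bands <- paste0("band_", 25:(25 + n))
  courses <- list(); inits <- list(); truth_curves <- list()
  for (i in seq_along(bands)) {
    clean <- sim[[bands[i]]]$values
    truth_curves[[i]] <- clean
    courses[[i]] <- time_course(
      times, .apply_noise(clean, design$noise), bands[i],
      meta = list(experiment_id = paste0("band", 24 + i),
                  series_value = 24 + i, series_unit = "nt"))
    inits[[i]] <- spec
  }
  out <- experiment_set(courses, "scheme2", inits,
                        scheme_args = list(k_on = p$k_on))
  attr(out, "truth_curves") <- truth_curves
  attr(out, "design") <- design
  out
}
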