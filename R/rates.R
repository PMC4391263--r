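#' Rate constants for the single-nucleotide incorporation mechanism
#'
#' Container for the five elementary rate constants of the minimal
#' incorporation mechanism: DNA binding (`k1`, `k_minus1`), ground-state
#' nucleotide binding (`k2`, `k_minus2`) and the irreversible chemistry step
#' (`k3`, also written k_pol). Internal units are nM and seconds throughout:
#' second-order constants in nM^-1 s^-1, first-order constants in s^-1.
#'
#' Derived equilibrium constants follow from the ratios
#' K_d,app = k_minus2 / k2 (ground-state nucleotide affinity) and
#' K_d,DNA = k_minus1 / k1 (DNA affinity); the DNA dissociation rate k_off
#' equals k_minus1 and the association rate k_on equals k1.
#'
#' @param k1 DNA association rate (nM^-1 s^-1).
#' @param k_minus1 DNA dissociation rate k_off (s^-1).
#' @param k2 nucleotide association rate (nM^-1 s^-1); diffusion-limited,
#'   conventionally fixed at 0.5 nM^-1 s^-1 in global fits.
#' @param k_minus2 nucleotide dissociation rate (s^-1).
#' @param k3 maximum incorporation (chemistry) rate k_pol (s^-1).
#' @return An object of class `rate_constants` (a named list).
#' @export
rate_constants <- function(k1, k_minus1, k2 = 0.5, k_minus2, k3) {
  r <- list(k1 = k1, k_minus1 = k_minus1, k2 = k2,
            k_minus2 = k_minus2, k3 = k3)
  for (nm in names(r)) {
    v <- r[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("rate constant '", nm, "' must be a single finite number")
    if (v < 0)
      stop("rate constant '", nm, "' must be >= 0 (got ", v, ")")
  }
  structure(r, class = "rate_constants")
}

#' @export
print.rate_constants <- function(x, ...) {
  cat("Rate constants (nM, s units):\n")
  cat(sprintf("  k1  = %g nM^-1 s^-1   k-1 = %g s^-1  (K_d,DNA = %g nM)\n",
              x$k1, x$k_minus1, x$k_minus1 / x$k1))
  cat(sprintf("  k2  = %g nM^-1 s^-1   k-2 = %g s^-1  (K_d,app = %g uM)\n",
              x$k2, x$k_minus2, x$k_minus2 / x$k2 / 1000))
  cat(sprintf("  k3 (k_pol) = %g s^-1\n", x$k3))
  invisible(x)
}

#' Published rate constants for wild-type and mutant Pol-gamma
#'
#' Returns the elementary rate constants implied by the published kinetic
#' parameters for wild-type Pol-gamma and the S305R and P1073L Alpers
#' mutants.  k2 is the diffusion-limited value 0.5 nM^-1 s^-1; k_minus2
#' follows from K_d,app, and k1 from K_d,DNA together with k_off.
#' The mismatch-excision rate k_exo is attached as an attribute.
#'
#' @param enzyme one of `"WT"`, `"S305R"`, `"P1073L"`.
#' @return A `rate_constants` object with attribute `k_exo` (s^-1).
#' @export
polg_rates <- function(enzyme = c("S305R", "WT", "P1073L")) {
  enzyme <- match.arg(enzyme)
  # K_d,DNA (nM), k_off (s^-1), K_d,app (uM), k_pol (s^-1), k_exo (s^-1)
  tab <- list(
    WT     = c(Kd_dna = 9.9,  k_off = 0.02, Kd_app = 0.7, k_pol = 30,   k_exo = 0.34),
    S305R  = c(Kd_dna = 100,  k_off = 1.2,  Kd_app = 1.2, k_pol = 12.4, k_exo = 0.11),
    P1073L = c(Kd_dna = 10.2, k_off = 0.02, Kd_app = 1.5, k_pol = 54.2, k_exo = 0.28)
  )[[enzyme]]
  r <- rate_constants(
    k1       = tab[["k_off"]] / tab[["Kd_dna"]],
    k_minus1 = tab[["k_off"]],
    k2       = 0.5,
    k_minus2 = tab[["Kd_app"]] * 1000 * 0.5,  # uM -> nM, times k2
    k3       = tab[["k_pol"]]
  )
  attr(r, "k_exo") <- tab[["k_exo"]]
  attr(r, "enzyme") <- enzyme
  r
}

#' Derived kinetic parameters
#'
#' Computes the derived quantities reported for each enzyme: the apparent
#' nucleotide dissociation constant K_d,app = k_minus2/k2 (reported in uM),
#' the DNA dissociation constant K_d,DNA = k_minus1/k1 (nM), the specificity
#' constant k_pol/K_d,app (uM^-1 s^-1, equal to k_cat/K_m for processive
#' synthesis) and the processivity k_pol/k_off (nucleotides incorporated per
#' DNA binding event).  When a reference enzyme is supplied, fold changes are
#' reported as mutant/reference ratios (so a weaker-binding mutant has
#' fold_Kd_DNA > 1 and a faster-dissociating mutant has fold_k_off > 1).
#'
#' @param rates a `rate_constants` object (the enzyme of interest).
#' @param reference optional `rate_constants` object (e.g. wild type) for
#'   fold-change reporting.
#' @return A list of class `derived_params`.
#' @export
derived_parameters <- function(rates, reference = NULL) {
  stopifnot(inherits(rates, "rate_constants"))
  if (rates$k2 <= 0) stop("k2 must be > 0 to derive K_d,app")
  if (rates$k1 <= 0) stop("k1 must be > 0 to derive K_d,DNA")
  if (rates$k_minus1 <= 0) stop("k_off (k_minus1) must be > 0 to derive processivity")
  Kd_app_uM <- rates$k_minus2 / rates$k2 / 1000
  out <- list(
    Kd_app_uM     = Kd_app_uM,
    Kd_dna_nM     = rates$k_minus1 / rates$k1,
    specificity   = rates$k3 / Kd_app_uM,   # k_pol / K_d,app, uM^-1 s^-1
    processivity  = rates$k3 / rates$k_minus1,
    k_pol         = rates$k3,
    k_off         = rates$k_minus1
  )
  if (!is.null(reference)) {
    ref <- derived_parameters(reference)
    out$fold_k_off  <- out$k_off / ref$k_off
    out$fold_Kd_dna <- out$Kd_dna_nM / ref$Kd_dna_nM
    out$fold_specificity <- out$specificity / ref$specificity
  }
  structure(out, class = "derived_params")
}

#' @export
print.derived_params <- function(x, ...) {
  cat(sprintf("K_d,app       = %.3g uM\n", x$Kd_app_uM))
  cat(sprintf("K_d,DNA       = %.3g nM\n", x$Kd_dna_nM))
  cat(sprintf("k_pol/K_d,app = %.3g uM^-1 s^-1\n", x$specificity))
  cat(sprintf("processivity  = %.3g nt\n", x$processivity))
  if (!is.null(x$fold_k_off))
    cat(sprintf("fold changes vs reference: k_off %.3g, K_d,DNA %.3g\n",
                x$fold_k_off, x$fold_Kd_dna))
  invisible(x)
}
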