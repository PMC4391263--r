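#' Construct a mass-action kinetic scheme
#'
#' A scheme is an ordered species list plus elementary reactions, each with at
#' most two reactants and two products, and named observables defined as sums
#' of species (the quantities a gel assay actually reports).  Conservation
#' groups (which species contain enzyme, which contain DNA) are declared so
#' simulations can be checked for mass balance.
#'
#' @param species character vector of species names.
#' @param reactions list of reactions, each a list with elements `reactants`
#'   (character), `products` (character), `rate` (name of the rate constant)
#'   and `value` (numeric rate constant, nM/s units).
#' @param observables named list; each element a character vector of species
#'   whose concentrations are summed.
#' @param conserved named list of species groups expected to have constant
#'   total concentration (e.g. enzyme-containing, DNA-containing species).
#' @param id short identifier used in error messages and experiment sets.
#' @return An object of class `kinetic_scheme`.
#' @export
kinetic_scheme <- function(species, reactions, observables,
                           conserved = list(), id = "scheme") {
  species <- as.character(species)
  if (anyDuplicated(species)) stop("duplicate species names")
  for (rx in reactions) {
    for (s in c(rx$reactants, rx$products))
      if (!s %in% species)
        stop("reaction references undeclared species '", s, "'")
    if (length(rx$reactants) > 2L || length(rx$products) > 2L)
      stop("at most two reactants and two products per elementary step")
    if (is.null(rx$rate) || is.null(rx$value))
      stop("every reaction needs a named rate constant and its value")
    if (!is.finite(rx$value) || rx$value < 0)
      stop("rate constant '", rx$rate, "' must be finite and >= 0")
  }
  for (nm in names(observables))
    if (!all(observables[[nm]] %in% species))
      stop("observable '", nm, "' references undeclared species")
  for (grp in conserved) {
    counts <- vapply(reactions, function(rx) {
      sum(rx$products %in% grp) - sum(rx$reactants %in% grp)
    }, integer(1))
    if (any(counts != 0L))
      stop("a reaction does not conserve a declared conservation group")
  }
  structure(list(species = species, reactions = reactions,
                 observables = observables, conserved = conserved, id = id),
            class = "kinetic_scheme")
}

#' @export
print.kinetic_scheme <- function(x, ...) {
  cat("Kinetic scheme '", x$id, "': ", length(x$species), " species, ",
      length(x$reactions), " reactions\n", sep = "")
  for (rx in x$reactions)
    cat(sprintf("  %s -> %s   (%s = %g)\n",
                paste(rx$reactants, collapse = " + "),
                paste(rx$products, collapse = " + "), rx$rate, rx$value))
  cat("observables:", paste(names(x$observables), collapse = ", "), "\n")
  invisible(x)
}

#' Single-nucleotide incorporation scheme
#'
#' Builds the executable form of the minimal incorporation mechanism:
#' reversible binding of enzyme to the 25-mer primer/template
#' (E + D25 <-> ED25, k1/k_minus1), reversible ground-state nucleotide binding
#' (ED25 + N <-> ED25N, k2/k_minus2), irreversible chemistry
#' (ED25N -> ED26, k3) and reversible binding of the extended 26-mer product
#' (E + D26 <-> ED26, sharing k1/k_minus1).  Pyrophosphate is not tracked.
#' The observable `product26` = ED26 + D26 is the quantity a quench-flow gel
#' assay reports.
#'
#' @param rates a [rate_constants()] object.
#' @return A `kinetic_scheme` with species E, D25, ED25, N, ED25N, ED26, D26.
#' @export
build_scheme1 <- function(rates) {
  stopifnot(inherits(rates, "rate_constants"))
  rx <- function(reac, prod, rate) list(reactants = reac, products = prod,
                                        rate = rate, value = rates[[rate]])
  kinetic_scheme(
    species = c("E", "D25", "ED25", "N", "ED25N", "ED26", "D26"),
    reactions = list(
      rx(c("E", "D25"), "ED25", "k1"),
      rx("ED25", c("E", "D25"), "k_minus1"),
      rx(c("ED25", "N"), "ED25N", "k2"),
      rx("ED25N", c("ED25", "N"), "k_minus2"),
      rx("ED25N", "ED26", "k3"),
      rx(c("E", "D26"), "ED26", "k1"),
      rx("ED26", c("E", "D26"), "k_minus1")
    ),
    observables = list(product26 = c("ED26", "D26")),
    conserved = list(
      enzyme = c("E", "ED25", "ED25N", "ED26"),
      dna    = c("D25", "ED25", "ED25N", "ED26", "D26")
    ),
    id = "scheme1"
  )
}

#' Processive-polymerization rate ladder
#'
#' Per-position incorporation rates for sequential single-nucleotide
#' additions, plus the DNA dissociation constant governing exchange of every
#' enzyme-DNA species with free enzyme and free DNA.  The equilibrium
#' K_d,DNA is split into on/off rates by fixing the association rate `k_on`
#' (default 0.002 nM^-1 s^-1, the value implied by the wild-type K_d,DNA of
#' 9.9 nM and k_off of 0.02 s^-1) and deriving k_off = K_d * k_on, keeping
#' one free equilibrium parameter.
#'
#' @param kpol numeric vector of incorporation rates (s^-1), position 1 first.
#' @param Kd_dna DNA dissociation constant (nM).
#' @param k_on DNA association rate (nM^-1 s^-1) used to realize the
#'   equilibrium; set to 0 to disable binding entirely.
#' @return Object of class `processive_rates`.
#' @export
processive_rates <- function(kpol, Kd_dna, k_on = 0.002) {
  if (length(kpol) < 1L || any(!is.finite(kpol)) || any(kpol <= 0))
    stop("kpol ladder must contain positive finite rates")
  if (!is.finite(Kd_dna) || Kd_dna <= 0) stop("Kd_dna must be > 0")
  if (k_on < 0) stop("k_on must be >= 0")
  structure(list(kpol = as.numeric(kpol), Kd_dna = Kd_dna, k_on = k_on),
            class = "processive_rates")
}

#' Processive-incorporation scheme
#'
#' Builds the sequential-incorporation mechanism used to fit product-ladder
#' gels: ED25 -> ED26 -> ... -> ED(25+n) at per-position rates kpol_i, with
#' every enzyme-DNA species EDn exchanging with free E + Dn through the DNA
#' binding equilibrium.  Observables are the per-length DNA totals
#' (`band_25` = ED25 + D25, ...), matching the quantified gel bands.
#'
#' @param p a [processive_rates()] object.
#' @param n_products number of incorporation steps; must equal the ladder
#'   length.
#' @param trap if `TRUE`, rebinding of dissociated DNA is disabled (a DNA
#'   trap experiment): association reactions are omitted, dissociation kept.
#' @return A `kinetic_scheme` with bands 25-mer through (25+n)-mer.
#' @export
build_scheme2 <- function(p, n_products = length(p$kpol), trap = FALSE) {
  stopifnot(inherits(p, "processive_rates"))
  n <- length(p$kpol)
  if (n_products != n)
    stop("n_products (", n_products, ") does not match ladder length (", n, ")")
  lens <- 25:(25 + n)
  ed <- paste0("ED", lens)
  d  <- paste0("D", lens)
  k_off <- p$Kd_dna * p$k_on
  reactions <- list()
  for (i in seq_len(n))
    reactions[[length(reactions) + 1L]] <-
      list(reactants = ed[i], products = ed[i + 1L],
           rate = paste0("kpol", i), value = p$kpol[i])
  for (i in seq_along(lens)) {
    reactions[[length(reactions) + 1L]] <-
      list(reactants = ed[i], products = c("E", d[i]),
           rate = "k_off", value = k_off)
    if (!trap && p$k_on > 0)
      reactions[[length(reactions) + 1L]] <-
        list(reactants = c("E", d[i]), products = ed[i],
             rate = "k_on", value = p$k_on)
  }
  obs <- stats::setNames(
    lapply(seq_along(lens), function(i) c(ed[i], d[i])),
    paste0("band_", lens))
  kinetic_scheme(
    species = c("E", ed, d),
    reactions = reactions,
    observables = obs,
    conserved = list(enzyme = c("E", ed), dna = c(ed, d)),
    id = "scheme2"
  )
}
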