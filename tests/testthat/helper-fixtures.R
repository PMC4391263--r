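# Shared fixtures: truth parameter sets and small designs used across files.

s305r <- polg_rates("S305R")
p1073l <- polg_rates("P1073L")
wt <- polg_rates("WT")

# Fixed-parameter lists for reduced fits of nucleotide titrations, with the
# DNA-binding rates pinned at their independently determined values.
fixed_dna_s305r <- list(k2 = 0.5, k1 = s305r$k1, k_minus1 = s305r$k_minus1)
fixed_dna_p1073l <- list(k2 = 0.5, k1 = p1073l$k1, k_minus1 = p1073l$k_minus1)

full_par <- function(r) c(k1 = r$k1, k_minus1 = r$k_minus1, k2 = r$k2,
                          k_minus2 = r$k_minus2, k3 = r$k3)

# A reduced-size nucleotide titration used where many replicates are needed.
small_st_design <- function(seed, enzyme = "S305R",
                            noise = noise_model()) {
  design_single_turnover(enzyme, dntp_uM = c(0.2, 1, 6), n_times = 8,
                         noise = noise, seed = seed)
}

quiet <- function(expr) suppressWarnings(expr)
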