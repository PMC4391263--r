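#!/usr/bin/env Rscript
# Confidence-contour error analysis of the S305R joint fit: maps the
# normalized chi-square over the (k1, k-1) and (k-2, k3) pairs with
# nuisance re-optimization at every node, and reads 10%-threshold
# confidence limits for each rate constant.
# Output: results/contour_limits.json (+ grids).

suppressPackageStartupMessages(library(polgkin))
dir.create("results", showWarnings = FALSE)

read_set <- function(stem) {
  sidecar <- jsonlite::read_json(paste0(stem, ".json"),
                                 simplifyVector = TRUE)
  courses <- read_timecourse_csv(paste0(stem, ".csv"))
  inits <- sidecar$inits
  inits <- if (is.data.frame(inits))
    lapply(seq_len(nrow(inits)), function(i) as.list(inits[i, ]))
  else lapply(inits, as.list)
  experiment_set(courses, "scheme1", inits,
                 titration = sidecar$titration$name)
}

fit <- suppressWarnings(fit_global(
  list(read_set("results/data/s305r_dntp_titration"),
       read_set("results/data/s305r_dna_titration")),
  free = c("k1", "k_minus1", "k_minus2", "k3"), n_starts = 3, seed = 1))

g_bind <- suppressWarnings(profile_pair(NULL, fit, "k1", "k_minus1",
                                        n_grid = 11, span = 2.5))
g_chem <- suppressWarnings(profile_pair(NULL, fit, "k_minus2", "k3",
                                        n_grid = 11, span = 2.5))
print(g_bind); print(g_chem)

lims <- c(g_bind$limits, g_chem$limits)
jsonlite::write_json(
  list(best = as.list(fit$par), chisq_min = fit$chisq,
       threshold = 0.10,
       limits = lapply(lims, function(l)
         list(low = l$low, high = l$high,
              open = l$unbounded_low || l$unbounded_high))),
  "results/contour_limits.json", auto_unbox = TRUE, digits = NA,
  pretty = TRUE)
cat("wrote results/contour_limits.json\n")
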