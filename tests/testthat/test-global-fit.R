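make_set <- function(noise = noise_model(0, 0), seed = 1, enzyme = "S305R")
  gen_single_turnover(design_single_turnover(enzyme, noise = noise,
                                             seed = seed))

test_that("chi-square matches hand-computed values", {
  tc <- function(v) time_course(seq_along(v), v, "product26",
                                meta = list(series_value = v[1]))
  set <- experiment_set(list(tc(c(1, 2, 4))), "scheme1",
                        list(c(E = 1)), titration = NULL)
  expect_equal(chi_square(list(c(1, 2, 4)), set), 0)
  set1 <- experiment_set(list(tc(5)), "scheme1", list(c(E = 1)))
  expect_equal(chi_square(list(3), set1), 4)
  # 3-point weighted case: residuals (0.5, -0.5, 1), weights (1, 2, 0.5)
  expect_equal(chi_square(list(c(0.5, 2.5, 3)), set,
                          weights = list(c(1, 2, 0.5))),
               1 * 0.25 + 2 * 0.25 + 0.5 * 1)
  expect_error(chi_square(list(c(1, 2)), set), "lengths differ")
})

test_that("noiseless single-turnover data return the generating rates", {
  set <- make_set()
  fit <- quiet(fit_global(set, free = c("k1", "k_minus1", "k_minus2", "k3"),
                          n_starts = 2, seed = 1))
  expect_true(fit$converged)
  for (nm in names(fit$par)) {
    truth <- full_par(s305r)[[nm]]
    expect_lt(abs(fit$par[[nm]] - truth) / truth, 0.01)
  }
  # refitting from the optimum improves chi-square by at most 0.1%
  # (plus an absolute floor for optima at machine zero)
  refit <- quiet(fit_global(set, free = fit$free, guesses = fit$par,
                            n_starts = 1, seed = 1))
  expect_lt(fit$chisq - refit$chisq, 0.001 * fit$chisq + 1e-6)
})

test_that("noiseless DNA-titration data return the binding constants", {
  set <- gen_dna_titration(design_dna_titration("S305R",
                                                noise = noise_model(0, 0),
                                                seed = 2))
  fit <- quiet(fit_global(set, free = c("k1", "k_minus1"),
                          fixed = list(k2 = 0.5, k_minus2 = s305r$k_minus2,
                                       k3 = s305r$k3),
                          n_starts = 2, seed = 1))
  expect_lt(abs(fit$derived$Kd_dna_nM - 100) / 100, 0.05)
  expect_lt(abs(fit$par[["k_minus1"]] - 1.2) / 1.2, 0.05)
})

test_that("a single nucleotide concentration leaves the chemistry/binding pair unidentifiable", {
  d <- design_single_turnover("S305R", dntp_uM = 1,
                              noise = noise_model(0.02, 0.2), seed = 3)
  fit <- quiet(fit_global(gen_single_turnover(d), free = c("k_minus2", "k3"),
                          fixed = fixed_dna_s305r, n_starts = 2, seed = 1,
                          check_identifiability = TRUE))
  expect_true(length(fit$warnings) > 0)
  # the full titration grid is well determined under the same check
  d6 <- design_single_turnover("S305R", noise = noise_model(0.02, 0.2),
                               seed = 3)
  fit6 <- quiet(fit_global(gen_single_turnover(d6), free = c("k_minus2", "k3"),
                           fixed = fixed_dna_s305r, n_starts = 2, seed = 1,
                           check_identifiability = TRUE))
  expect_length(fit6$warnings, 0)
})

test_that("course order does not change the optimum", {
  set <- make_set(noise_model(0.05, 0.5), seed = 7)
  rev_set <- experiment_set(rev(set$courses), "scheme1", rev(set$inits),
                            titration = "dNTP")
  f1 <- quiet(fit_global(set, free = c("k_minus2", "k3"),
                         fixed = fixed_dna_s305r, n_starts = 2, seed = 1))
  f2 <- quiet(fit_global(rev_set, free = c("k_minus2", "k3"),
                         fixed = fixed_dna_s305r, n_starts = 2, seed = 1))
  expect_lt(abs(f1$chisq - f2$chisq) / f1$chisq, 1e-6)
})

test_that("the accepted chi-square trace is non-increasing", {
  set <- make_set(noise_model(0.05, 0.5), seed = 5)
  fit <- quiet(fit_global(set, free = c("k_minus2", "k3"),
                          fixed = fixed_dna_s305r, n_starts = 1, seed = 1))
  expect_true(all(diff(fit$rsstrace) <= 1e-6 * max(fit$rsstrace)))
})

test_that("burst fits recover amplitude, rates and the derived k_off", {
  tt <- c(seq(0.02, 1, length.out = 10), seq(1.5, 8, 0.5))
  tc <- time_course(tt, burst_model(tt, 75, 20, 90), "product26")
  fb <- fit_burst(tc)
  expect_equal(fb$A, 75, tolerance = 1e-4)
  expect_equal(fb$k_obs, 20, tolerance = 1e-4)
  expect_equal(fb$k_off, 1.2, tolerance = 1e-4)
  # no steady-state phase means no dissociation
  tc0 <- time_course(tt, burst_model(tt, 75, 20, 0), "product26")
  expect_equal(fit_burst(tc0)$k_off, 0)
  # fixing the active-site amplitude is supported
  fbA <- fit_burst(tc, active_E = 75)
  expect_equal(fbA$k_off, 1.2, tolerance = 1e-4)
  # purely linear data have no burst curvature
  lin <- time_course(tt, 2 * tt + 0.01, "product26")
  expect_error(fit_burst(lin), "degenerate")
  # wild-type vs mutant dissociation: 60-fold change
  tcw <- time_course(tt, burst_model(tt, 75, 25, 75 * 0.02), "product26")
  expect_equal(fit_burst(tc)$k_off / fit_burst(tcw)$k_off, 60,
               tolerance = 1e-3)
})

test_that("exponential fits recover the excision rate", {
  tt <- exp(seq(log(0.1), log(12), length.out = 12))
  fe <- fit_exponential(time_course(tt, exponential_decay(tt, 75, 0.34, 0),
                                    "primer25"))
  expect_lt(abs(fe$k_exo - 0.34) / 0.34, 0.001)
  fc <- fit_exponential(time_course(1:6, rep(5, 6), "primer25"))
  expect_equal(fc$k_exo, 0)
  expect_true(length(fc$warnings) > 0)
  # 5% noise, 20 replicates: mean recovered rate within the printed band
  set.seed(11)
  ks <- replicate(20, {
    y <- exponential_decay(tt, 75, 0.11, 0)
    fit_exponential(time_course(tt, y + rnorm(12, 0, 0.05 * 75), "primer25"))$k_exo
  })
  expect_lt(abs(mean(ks) - 0.11), 0.02)
})

test_that("processive fits recover the ladder and reduce to the exponential oracle", {
  set <- gen_processive(design_processive(noise = noise_model(0, 0), seed = 1))
  fit <- quiet(fit_processive(set, n_steps = 5, n_starts = 2, seed = 1))
  truth <- c(65, 36, 48, 28, 7, 15)
  for (i in seq_along(truth))
    expect_lt(abs(fit$par[[i]] - truth[i]) / truth[i], 0.02)
  expect_error(fit_processive(set, n_steps = 9), "more incorporation steps")
  # ten-step wild-type-like ladder: joint recovery of ten rates plus the
  # binding equilibrium from eleven noiseless bands
  wt_lad <- c(37, 75, 60, 65, 70, 37, 73, 58, 70, 46)
  s10 <- gen_processive(design_processive(kpol = wt_lad,
                                          noise = noise_model(0, 0),
                                          seed = 1))
  f10 <- quiet(fit_processive(s10, n_steps = 10, n_starts = 1, seed = 1))
  expect_lt(abs(f10$par[["Kd_dna"]] - 15) / 15, 0.01)
  for (i in 1:10)
    expect_lt(abs(f10$par[[i]] - wt_lad[i]) / wt_lad[i], 0.01)
  # one step without binding exchange: the 25-mer band is a pure decay
  d1 <- design_processive(kpol = 20, Kd_dna = 15, k_on = 0,
                          noise = noise_model(0, 0), seed = 1)
  s1 <- gen_processive(d1)
  fp <- quiet(fit_processive(s1, n_steps = 1, n_starts = 1, seed = 1))
  fe <- fit_exponential(s1$courses[[1]])
  expect_lt(abs(fp$par[["kpol1"]] - fe$k_exo) / fe$k_exo, 0.01)
})
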