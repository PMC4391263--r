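test_that("all rates zero leaves every species at its initial value", {
  r <- rate_constants(0, 0, 0, 0, 0)
  s <- build_scheme1(r)
  init <- initial_state(s, c(E = 30, D25 = 10, ED25 = 40, N = 500))
  sim <- simulate_scheme(s, init, c(0.1, 1, 10))
  sp <- attr(sim, "species")
  for (nm in s$species)
    expect_equal(sp[, nm], rep(unname(init[nm]), 3), tolerance = 1e-10)
})

test_that("no nucleotide means no product", {
  s <- build_scheme1(s305r)
  init <- initial_state(s, c(E = 25, D25 = 1.6, ED25 = 73.4))
  sim <- simulate_scheme(s, init, c(0.01, 0.1, 1))
  expect_true(all(abs(sim$product26$values) < 1e-8))
})

test_that("enzyme and DNA totals are conserved for random rate sets", {
  set.seed(42)
  for (i in 1:8) {
    r <- rate_constants(k1 = 10^runif(1, -4, -1), k_minus1 = 10^runif(1, -2, 1),
                        k2 = 0.5, k_minus2 = 10^runif(1, 1, 3),
                        k3 = 10^runif(1, 0, 2))
    s <- build_scheme1(r)
    eq <- preequilibrate_binding(100, 75, r$k_minus1 / max(r$k1, 1e-12))
    init <- initial_state(s, c(E = eq$E, D25 = eq$D, ED25 = eq$ED,
                               N = 10^runif(1, 2, 4)))
    sim <- simulate_scheme(s, init, 10^seq(-3, 0.7, length.out = 10))
    sp <- attr(sim, "species")
    enz <- rowSums(sp[, s$conserved$enzyme, drop = FALSE])
    dna <- rowSums(sp[, s$conserved$dna, drop = FALSE])
    expect_lt(max(abs(enz / enz[1] - 1)), 1e-6)
    expect_lt(max(abs(dna / dna[1] - 1)), 1e-6)
    expect_true(all(sp >= -1e-9))
  }
})

test_that("product formation is monotone when excision is absent", {
  s <- build_scheme1(s305r)
  eq <- preequilibrate_binding(100, 75, 100)
  init <- initial_state(s, c(E = eq$E, D25 = eq$D, ED25 = eq$ED, N = 2000))
  sim <- simulate_scheme(s, init, 10^seq(-3, 1, length.out = 30))
  expect_true(all(diff(sim$product26$values) >= -1e-8))
})

test_that("the ODE solution matches the closed-form rapid-equilibrium burst", {
  # With nucleotide binding much faster than chemistry and no DNA
  # dissociation, single-turnover product follows A (1 - exp(-k_obs t)),
  # k_obs = k3 N / (N + K_d,app).
  r <- rate_constants(k1 = 1, k_minus1 = 0, k2 = 10, k_minus2 = 5000, k3 = 2)
  s <- build_scheme1(r)
  N0 <- 1e4; D0 <- 10
  init <- initial_state(s, c(ED25 = D0, N = N0))
  tt <- seq(0.05, 2.5, length.out = 12)
  sim <- simulate_scheme(s, init, tt)
  k_obs <- r$k3 * N0 / (N0 + r$k_minus2 / r$k2)
  analytic <- D0 * (1 - exp(-k_obs * tt))
  expect_lt(max(abs(sim$product26$values - analytic) / analytic), 0.01)
})

test_that("a one-step ladder without binding exchange is a pure exponential", {
  p <- processive_rates(3, Kd_dna = 15, k_on = 0)
  s <- build_scheme2(p)
  init <- initial_state(s, c(ED25 = 60, D25 = 15, E = 90))
  tt <- seq(0.05, 1.5, length.out = 10)
  sim <- simulate_scheme(s, init, tt)
  expect_equal(sim$band_25$values,
               exponential_decay(tt, 60, 3, C = 15), tolerance = 1e-6)
})

test_that("an impossible integration is reported with the scheme name", {
  s <- build_scheme1(s305r)
  expect_error(simulate_scheme(s, stats::setNames(numeric(7), s$species),
                               c(0.1, 0.05)), "strictly increasing")
  expect_error(simulate_scheme(s, c(E = 1), c(0.1, 1)), "every species")
})
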