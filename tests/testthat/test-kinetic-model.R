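test_that("rate constants validate and expose the derived equilibria", {
  r <- rate_constants(k1 = 0.012, k_minus1 = 1.2, k2 = 0.5,
                      k_minus2 = 600, k3 = 12.4)
  expect_s3_class(r, "rate_constants")
  expect_error(rate_constants(-1, 1, 0.5, 1, 1), "must be >= 0")
  expect_error(rate_constants(0.01, NaN, 0.5, 1, 1), "finite")
})

test_that("the incorporation scheme has the expected species and reactions", {
  s <- build_scheme1(s305r)
  expect_setequal(s$species, c("E", "D25", "ED25", "N", "ED25N", "ED26", "D26"))
  expect_length(s$reactions, 7)  # 3 reversible pairs + irreversible chemistry
  expect_named(s$observables, "product26")
  # declared conservation groups are validated at construction
  expect_setequal(s$conserved$enzyme, c("E", "ED25", "ED25N", "ED26"))
})

test_that("a scheme referencing unknown species or negative rates is rejected", {
  expect_error(kinetic_scheme("A",
    list(list(reactants = "A", products = "B", rate = "k", value = 1)),
    list()), "undeclared species")
  expect_error(kinetic_scheme(c("A", "B"),
    list(list(reactants = "A", products = "B", rate = "k", value = -2)),
    list()), ">= 0")
})

test_that("chemistry off means no product", {
  r0 <- rate_constants(k1 = 0.012, k_minus1 = 1.2, k2 = 0.5,
                       k_minus2 = 600, k3 = 0)
  s <- build_scheme1(r0)
  init <- initial_state(s, c(ED25 = 75, E = 25, N = 5000))
  sim <- simulate_scheme(s, init, c(0.01, 0.1, 1, 5))
  expect_true(all(sim$product26$values < 1e-8))
})

test_that("the processive scheme builds the band ladder and checks its length", {
  p5 <- processive_rates(c(65, 36, 48, 28, 7), Kd_dna = 15)
  s5 <- build_scheme2(p5)
  expect_setequal(names(s5$observables), paste0("band_", 25:30))
  p10 <- processive_rates(c(37, 75, 60, 65, 70, 37, 73, 58, 70, 46), 15)
  s10 <- build_scheme2(p10)
  expect_setequal(names(s10$observables), paste0("band_", 25:35))
  expect_error(build_scheme2(p5, n_products = 4), "does not match")
  expect_error(processive_rates(c(65, -1), 15), "positive")
})

test_that("with dissociation dominant and no rebinding, extension stalls at the first-bound fraction", {
  # DNA trap limit: bound fraction either extends or falls off; free DNA
  # never re-engages, so total extended product is bounded by ED(0).
  p <- processive_rates(5, Kd_dna = 1000, k_on = 0.02)  # k_off = 20 s^-1 >> kpol
  s <- build_scheme2(p, trap = TRUE)
  init <- initial_state(s, c(ED25 = 50, D25 = 25, E = 100))
  sim <- simulate_scheme(s, init, c(0.01, 0.1, 1, 10))
  extended <- sim$band_26$values
  expect_true(all(diff(extended) >= -1e-9))
  # with k_off/( k_off + kpol ) = 0.8, only ~20% of the bound complex extends
  expect_lt(extended[4], 50 * 5 / 25 * 1.05)
  expect_gt(extended[4], 50 * 5 / 25 * 0.95)
})

test_that("burst equation limits and the k_off identity hold", {
  expect_equal(burst_model(0, 75, 20, 90), 0)
  expect_equal(burst_model(1e6, 75, 20, 0), 75)
  tt <- seq(0, 5, 0.5)
  expect_equal(burst_model(tt, 0, 20, 3), 3 * tt)
  expect_error(burst_model(-0.1, 1, 1, 1), "negative time")
  # steady-state slope over amplitude encodes the dissociation rate
  expect_equal(90 / 75, 1.2)
})

test_that("exponential decay obeys the half-life identity", {
  expect_equal(exponential_decay(log(2) / 0.34, 1, 0.34, 0), 0.5)
  expect_equal(exponential_decay(0, 2, 0.5, 1), 3)
  expect_equal(exponential_decay(c(1, 7), 4, 0, 1), c(5, 5))
  expect_error(exponential_decay(1, 1, -0.1), ">= 0")
})

test_that("derived parameters reproduce the published ratios", {
  d <- derived_parameters(s305r, reference = wt)
  expect_equal(d$Kd_app_uM, 1.2)
  expect_equal(d$Kd_dna_nM, 100)
  expect_equal(d$specificity, 12.4 / 1.2)
  expect_equal(d$processivity, 12.4 / 1.2, tolerance = 1e-12)
  expect_lt(abs(d$processivity - 10), 1)       # ~10 nt
  expect_equal(d$fold_k_off, 60)               # 1.2 / 0.02
  expect_equal(d$fold_Kd_dna, 100 / 9.9)       # ~10-fold weaker binding
  # equal chemistry and dissociation rates give processivity of one
  r1 <- rate_constants(0.01, 5, 0.5, 100, 5)
  expect_equal(derived_parameters(r1)$processivity, 1)
  bad <- rate_constants(0, 1, 0.5, 100, 5)
  expect_error(derived_parameters(bad), "k1 must be > 0")
})
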