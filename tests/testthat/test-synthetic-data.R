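test_that("identical seeds regenerate identical datasets, different seeds differ", {
  d <- design_single_turnover("S305R", seed = 4)
  a <- gen_single_turnover(d)
  b <- gen_single_turnover(d)
  for (i in seq_along(a$courses))
    expect_identical(a$courses[[i]]$values, b$courses[[i]]$values)
  d2 <- design_single_turnover("S305R", seed = 5)
  c2 <- gen_single_turnover(d2)
  expect_false(identical(a$courses[[1]]$values, c2$courses[[1]]$values))
})

test_that("zero-noise generators equal the deterministic forward models", {
  st <- gen_single_turnover(design_single_turnover(
    "S305R", noise = noise_model(0, 0), seed = 1))
  curves <- eval_model_curves(st, full_par(s305r))
  for (i in seq_along(st$courses))
    expect_equal(st$courses[[i]]$values, curves[[i]], tolerance = 1e-10)

  bt <- gen_burst(design_burst("S305R", noise = noise_model(0, 0), seed = 1))
  tb <- attr(bt, "truth_burst")
  expect_equal(bt$values,
               burst_model(bt$times, tb$A, tb$k_obs, tb$k_ss),
               tolerance = 1e-12)
  # the amplitude is the pre-equilibrated complex and k_ss/A = k_off
  eq <- preequilibrate_binding(100, 350, 100)
  expect_equal(tb$A, eq$ED)
  expect_equal(tb$k_ss / tb$A, 1.2)

  ex <- gen_excision(design_excision("WT", noise = noise_model(0, 0),
                                     seed = 1))
  expect_equal(ex$values, exponential_decay(ex$times, 75, 0.34, 0),
               tolerance = 1e-12)

  pr <- gen_processive(design_processive(noise = noise_model(0, 0), seed = 1))
  expect_equal(pr$courses[[1]]$values, attr(pr, "truth_curves")[[1]],
               tolerance = 1e-12)
})

test_that("gel bands sum to the total DNA at every time", {
  pr <- gen_processive(design_processive(noise = noise_model(0, 0), seed = 1))
  band_sum <- Reduce(`+`, lapply(pr$courses, `[[`, "values"))
  expect_equal(band_sum, rep(75, length(pr$courses[[1]]$times)),
               tolerance = 1e-6)
})

test_that("a single-turnover design with enzyme below DNA warns", {
  d <- design_single_turnover("S305R", E_total = 50, D_total = 75, seed = 1)
  expect_warning(gen_single_turnover(d), "\\[enzyme\\] < \\[DNA\\]")
})

test_that("empirical residual scatter matches the noise model", {
  # pool > 1000 points across seeded regenerations of one excision design
  resid <- unlist(lapply(1:30, function(s) {
    d <- design_excision("WT", n_times = 40, seed = s)
    tc <- gen_excision(d)
    tc$values - attr(tc, "truth_curve")
  }))
  expect_gte(length(resid), 1000)
  sigma_expected <- 0.05 * 75 + 0.5
  expect_lt(abs(sd(resid) / sigma_expected - 1), 0.1)
})

test_that("datasets round-trip through the CSV format byte-identically", {
  st <- gen_single_turnover(design_single_turnover("S305R", seed = 6))
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_timecourse_csv(st, f1)
  write_timecourse_csv(st, f2)
  expect_identical(readLines(f1), readLines(f2))
  back <- read_timecourse_csv(f1)
  expect_length(back, length(st$courses))
  expect_equal(back[[1]]$times, st$courses[[1]]$times, tolerance = 1e-10)
  expect_equal(back[[1]]$values, st$courses[[1]]$values, tolerance = 1e-10)
  unlink(c(f1, f2))
})

test_that("design validation rejects malformed inputs", {
  expect_error(experiment_design("scheme1", s305r,
                                 times = c(2, 1)), "strictly increasing")
  expect_error(experiment_design("scheme1", s305r,
                                 titration = list(values = c(1, 1))),
               "distinct")
})
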