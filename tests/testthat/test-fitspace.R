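# A quadratic least-squares toy objective with known geometry:
# chi2(a, b) = 1 + ((a - 2)/0.5)^2 + ((b - 10)/3)^2.
quad_fit <- function()
  as_fit_result(function(p) c(1, (p[["a"]] - 2) / 0.5, (p[["b"]] - 10) / 3),
                c(a = 2, b = 10))

test_that("the threshold contour of a quadratic objective matches the analytic ellipse", {
  fit <- quad_fit()
  g <- profile_pair(NULL, fit, "a", "b", n_grid = 17, span = 1.5)
  expect_equal(max(g$normalized, na.rm = TRUE), 1, tolerance = 1e-6)
  # profile limits: center +/- scale * sqrt(threshold * chi2_min), chi2_min = 1
  expect_equal(g$limits$a$low, 2 - 0.5 * sqrt(0.1), tolerance = 0.01)
  expect_equal(g$limits$a$high, 2 + 0.5 * sqrt(0.1), tolerance = 0.01)
  expect_equal(g$limits$b$low, 10 - 3 * sqrt(0.1), tolerance = 0.01)
  expect_equal(g$limits$b$high, 10 + 3 * sqrt(0.1), tolerance = 0.01)
  # every grid node obeys the normalized-scale invariants
  expect_true(all(g$normalized > 0 & g$normalized <= 1 + 1e-12, na.rm = TRUE))
})

test_that("confidence limits of a 1-D parabola are analytic", {
  p0 <- 5; s <- 2
  v <- exp(seq(log(1), log(25), length.out = 400))
  prof <- data.frame(value = v, chisq = 3 * (1 + ((v - p0) / s)^2))
  lims <- confidence_limits(prof)[[1]]
  expect_equal(lims$low, p0 - s * sqrt(0.1), tolerance = 1e-3)
  expect_equal(lims$high, p0 + s * sqrt(0.1), tolerance = 1e-3)
  expect_false(lims$unbounded_low || lims$unbounded_high)
})

test_that("a flat direction is reported as an open interval", {
  fit <- as_fit_result(function(p) c(1, (p[["a"]] - 2) / 0.5),
                       c(a = 2, b = 10))
  g <- profile_pair(NULL, fit, "a", "b", n_grid = 9, span = 2, max_expand = 1)
  expect_true(g$limits$b$unbounded_low)
  expect_true(g$limits$b$unbounded_high)
  expect_false(g$limits$a$unbounded_low || g$limits$a$unbounded_high)
})

test_that("confidence regions nest with the threshold", {
  fit <- quad_fit()
  g <- profile_pair(NULL, fit, "a", "b", n_grid = 17, span = 2)
  l05 <- confidence_limits(g, 0.05)
  l10 <- confidence_limits(g, 0.10)
  l20 <- confidence_limits(g, 0.20)
  for (p in c("a", "b")) {
    expect_gte(l05[[p]]$low, l10[[p]]$low)
    expect_lte(l05[[p]]$high, l10[[p]]$high)
    expect_gte(l10[[p]]$low, l20[[p]]$low)
    expect_lte(l10[[p]]$high, l20[[p]]$high)
  }
})

test_that("a parameter's profile does not depend on its contour partner", {
  set <- gen_single_turnover(design_single_turnover(
    "S305R", noise = noise_model(0.02, 0.2), seed = 9))
  fit <- quiet(fit_global(set, free = c("k_minus1", "k_minus2", "k3"),
                          fixed = list(k2 = 0.5, k1 = s305r$k1),
                          n_starts = 2, seed = 9))
  g1 <- quiet(profile_pair(set, fit, "k3", "k_minus2", n_grid = 7, span = 3,
                           max_expand = 0))
  g2 <- quiet(profile_pair(set, fit, "k3", "k_minus1", n_grid = 7, span = 3,
                           max_expand = 0))
  expect_equal(g1$p_values, g2$p_values, tolerance = 1e-12)
  # the refined axis profiles re-optimize partner + nuisance continuously,
  # so both pairings estimate the same 1-D profile of k3
  expect_lt(max(abs(g1$profile_p - g2$profile_p) / g1$profile_p), 0.01)
})

test_that("10% chi-square intervals for the chemistry rate cover the truth across replicates", {
  n_rep <- 50
  covered <- 0; widths <- numeric(0)
  for (r in seq_len(n_rep)) {
    set <- gen_single_turnover(small_st_design(seed = 2000 + r))
    fit <- quiet(fit_global(set, free = c("k_minus2", "k3"),
                            fixed = fixed_dna_s305r, n_starts = 1,
                            seed = r))
    pr <- quiet(profile_param(fit, "k3", n_grid = 9, span = 2.5,
                              max_expand = 2))
    lim <- confidence_limits(pr)[[1]]
    lo <- if (lim$unbounded_low) 0 else lim$low
    hi <- if (lim$unbounded_high) Inf else lim$high
    if (lo <= 12.4 && 12.4 <= hi) covered <- covered + 1
    widths <- c(widths, hi - lo)
  }
  coverage <- covered / n_rep
  cat(sprintf("\nempirical coverage of the 10%% interval for k3: %.2f\n",
              coverage))
  expect_gte(coverage, 0.6)  # a large majority of replicates
})
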