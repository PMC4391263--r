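test_that("run_simulate writes a reproducible dataset with the published design grid", {
  out_csv <- tempfile(fileext = ".csv")
  cfg <- list(class = "single_turnover", enzyme = "S305R", seed = 7,
              out_csv = out_csv)
  res <- run_simulate(cfg)
  expect_true(file.exists(out_csv))
  sidecar <- jsonlite::read_json(sub("\\.csv$", ".json", out_csv),
                                 simplifyVector = TRUE)
  expect_equal(sidecar$titration$values, c(0.05, 0.2, 0.4, 1, 6, 17))
  expect_equal(sidecar$seed, 7)
  expect_true(!is.null(sidecar$config_hash))
  first <- readLines(out_csv)
  run_simulate(cfg)
  expect_identical(readLines(out_csv), first)  # bit-for-bit reproducible
  expect_error(run_simulate(list(enzyme = "S305R")), "experiment class")
  unlink(out_csv); unlink(sub("\\.csv$", ".json", out_csv))
})

test_that("run_fit reproduces the chemistry rate from a noiseless dataset and reports the standard columns", {
  out_csv <- tempfile(fileext = ".csv")
  run_simulate(list(class = "single_turnover", enzyme = "S305R", seed = 1,
                    noise = list(rel = 0, add = 0), out_csv = out_csv))
  out_json <- tempfile(fileext = ".json")
  report_txt <- tempfile(fileext = ".txt")
  res <- quiet(run_fit(list(
    data_csv = out_csv, sidecar_json = sub("\\.csv$", ".json", out_csv),
    free = c("k_minus2", "k3"),
    fixed = list(k2 = 0.5, k1 = s305r$k1, k_minus1 = s305r$k_minus1),
    n_starts = 2, seed = 1, enzyme = "S305R",
    out_json = out_json, report_txt = report_txt)))
  fit <- res$fit
  expect_lt(abs(fit$par[["k3"]] - 12.4) / 12.4, 0.01)
  payload <- jsonlite::read_json(out_json, simplifyVector = TRUE)
  # the derived specificity column equals the ratio of the fitted columns
  expect_equal(payload$derived$specificity,
               payload$derived$k_pol / payload$derived$Kd_app_uM,
               tolerance = 1e-8)
  tab <- utils::read.table(report_txt, header = TRUE, sep = "\t")
  expect_true(all(c("Kd_DNA_nM", "k_pol_s", "Kd_app_uM", "specificity_uM_s",
                    "k_exo_s") %in% names(tab)))
  expect_error(run_fit(list(data_csv = "does-not-exist.csv")), "not found")
  unlink(c(out_csv, sub("\\.csv$", ".json", out_csv), out_json, report_txt))
})

test_that("zero-noise recovery has zero bias and noisy limits bracket the estimates", {
  d0 <- design_single_turnover("S305R", noise = noise_model(0, 0), seed = 1)
  rs <- quiet(recover_study(d0, replicates = 2, free = c("k_minus2", "k3"),
                            fixed = fixed_dna_s305r, n_starts = 1))
  k3row <- rs$summary[rs$summary$param == "k3", ]
  expect_lt(abs(k3row$bias) / 12.4, 0.005)
  dn <- small_st_design(seed = 31)
  rsn <- quiet(recover_study(dn, replicates = 1, free = c("k_minus2", "k3"),
                             fixed = fixed_dna_s305r, n_starts = 1,
                             compute_limits = TRUE))
  est <- rsn$estimates
  for (p in c("k_minus2", "k3")) {
    row <- est[est$param == p, ]
    if (!is.na(row$low)) expect_lte(row$low, row$estimate * (1 + 1e-6))
    if (!is.na(row$high)) expect_gte(row$high, row$estimate * (1 - 1e-6))
  }
})

test_that("report_table assembles the conventional row layout", {
  set <- gen_single_turnover(design_single_turnover(
    "S305R", noise = noise_model(0, 0), seed = 1))
  fit <- quiet(fit_global(set, free = c("k_minus2", "k3"),
                          fixed = fixed_dna_s305r, n_starts = 1, seed = 1))
  tab <- report_table(list(S305R = list(global = fit,
                                        excision = list(k_exo = 0.11))))
  expect_equal(nrow(tab), 1)
  expect_equal(tab$k_exo_s, 0.11)
  expect_equal(tab$Kd_DNA_nM, 100, tolerance = 1e-6)
})
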