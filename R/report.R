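#' @title Workflow drivers: simulate, fit, recover, report
#' @description Thin configuration-driven wrappers tying the generator,
#'   fitting and error-analysis layers together; these are what the
#'   numbered analysis scripts call.  Configs are plain named lists, or
#'   paths to YAML/JSON files with the same fields.
#' @name workflow
NULL

.load_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- if (grepl("\\.ya?ml$", config)) yaml::read_yaml(config)
              else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  if (!is.list(config)) stop("config must be a named list or a file path")
  config
}

.design_from_config <- function(config) {
  cls <- config$class
  if (is.null(cls))
    stop("config must name an experiment class ",
         "(single_turnover, dna_titration, burst, excision, processive)")
  seed <- if (is.null(config$seed)) 1 else as.integer(config$seed)
  noise <- if (is.null(config$noise)) noise_model()
           else noise_model(rel = config$noise$rel, add = config$noise$add)
  enzyme <- if (is.null(config$enzyme)) "S305R" else config$enzyme
  args <- c(list(noise = noise, seed = seed),
            config$design_args)
  switch(cls,
    single_turnover = do.call(design_single_turnover,
                              c(list(enzyme = enzyme), args)),
    dna_titration = do.call(design_dna_titration,
                            c(list(enzyme = enzyme), args)),
    burst = do.call(design_burst, c(list(enzyme = enzyme), args)),
    excision = do.call(design_excision, c(list(enzyme = enzyme), args)),
    processive = do.call(design_processive, args),
    stop("unknown experiment class: ", cls))
}

.generate <- function(design) {
  switch(design$scheme,
         scheme1 = if (identical(design$titration$name, "DNA"))
           gen_dna_titration(design) else gen_single_turnover(design),
         burst = gen_burst(design),
         exponential = gen_excision(design),
         scheme2 = gen_processive(design))
}

#' @rdname workflow
#' @param config named list (or YAML/JSON path) describing the run; see the
#'   analysis scripts for worked examples.  `run_simulate` needs `class`,
#'   optionally `enzyme`, `seed`, `noise`, `design_args`, and output paths
#'   `out_csv` / `out_json`.
#' @return `run_simulate`: invisibly, a list with the generated data and the
#'   output paths.
#' @export
run_simulate <- function(config) {
  config <- .load_config(config)
  design <- .design_from_config(config)
  data <- .generate(design)
  paths <- NULL
  if (!is.null(config$out_csv)) {
    json <- if (is.null(config$out_json))
      sub("\\.csv$", ".json", config$out_csv) else config$out_json
    paths <- write_dataset(data, config$out_csv, json)
  }
  invisible(list(data = data, design = design, paths = paths))
}

#' Kinetic-parameter summary table
#'
#' Formats fitted parameters as one row per enzyme with the conventional
#' columns: K_d,DNA (nM), k_pol (s^-1), K_d,app (uM), k_pol/K_d,app
#' (uM^-1 s^-1) and k_exo (s^-1).
#'
#' @param fits named list (one element per enzyme/row); each element a list
#'   with a scheme1 `fit_result` under `$global` and optionally a
#'   [fit_exponential()] result under `$excision`.
#' @return A data.frame.
#' @export
report_table <- function(fits) {
  rows <- lapply(names(fits), function(nm) {
    f <- fits[[nm]]
    d <- f$global$derived
    data.frame(
      enzyme = nm,
      Kd_DNA_nM = if (is.null(d)) NA else d$Kd_dna_nM,
      k_pol_s = if (is.null(d)) NA else d$k_pol,
      Kd_app_uM = if (is.null(d)) NA else d$Kd_app_uM,
      specificity_uM_s = if (is.null(d)) NA else d$specificity,
      k_exo_s = if (is.null(f$excision)) NA else f$excision$k_exo,
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' @rdname workflow
#' @return `run_fit`: invisibly, a list with the `fit_result` (or
#'   burst/exponential fit) and output paths.  Config fields: `data_csv`
#'   plus `sidecar_json` (a dataset written by [run_simulate()]), `free`,
#'   `fixed`, `n_starts`, `seed`, and output paths `out_json` /
#'   `report_txt`.
#' @export
run_fit <- function(config) {
  config <- .load_config(config)
  if (is.null(config$data_csv)) stop("config$data_csv is required")
  if (!file.exists(config$data_csv))
    stop("data file not found: ", config$data_csv)
  sidecar <- if (!is.null(config$sidecar_json)) {
    if (!file.exists(config$sidecar_json))
      stop("sidecar file not found: ", config$sidecar_json)
    jsonlite::read_json(config$sidecar_json, simplifyVector = TRUE)
  }
  courses <- read_timecourse_csv(config$data_csv)
  scheme <- if (!is.null(sidecar)) sidecar$scheme else config$scheme
  seed <- if (is.null(config$seed)) 1 else as.integer(config$seed)
  n_starts <- if (is.null(config$n_starts)) 5 else config$n_starts

  fit <- if (scheme %in% c("scheme1", "scheme2")) {
    inits <- sidecar$inits
    inits <- if (is.data.frame(inits))  # simplifyVector collapses the list
      lapply(seq_len(nrow(inits)), function(i) as.list(inits[i, ]))
    else lapply(inits, as.list)
    set <- experiment_set(courses, scheme, inits,
                          titration = sidecar$titration$name,
                          scheme_args = if (scheme == "scheme2")
                            list(k_on = sidecar$truth$k_on) else list())
    if (scheme == "scheme1") {
      free <- if (is.null(config$free))
        c("k1", "k_minus1", "k_minus2", "k3") else config$free
      fit_global(set, free = free, fixed = config$fixed,
                 guesses = config$guesses, n_starts = n_starts, seed = seed)
    } else {
      fit_processive(set, n_steps = length(courses) - 1L,
                     n_starts = n_starts, seed = seed)
    }
  } else if (scheme == "burst") {
    fit_burst(courses[[1]])
  } else if (scheme == "exponential") {
    fit_exponential(courses[[1]])
  } else stop("unknown scheme '", scheme, "'")

  if (!is.null(config$out_json)) {
    payload <- if (inherits(fit, "fit_result")) list(
      parameters = as.list(fit$par), fixed = as.list(fit$fixed),
      chisq = fit$chisq, n_points = fit$n_points,
      converged = fit$converged, warnings = fit$warnings,
      derived = if (!is.null(fit$derived))
        unclass(fit$derived) else NULL,
      seed = seed,
      package_version = as.character(utils::packageVersion("polgkin")))
    else c(fit[setdiff(names(fit), "fitted")], list(seed = seed))
    jsonlite::write_json(payload, config$out_json, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  if (!is.null(config$report_txt) && inherits(fit, "fit_result") &&
      fit$scheme_id == "scheme1") {
    nm <- if (!is.null(config$enzyme)) config$enzyme else "enzyme"
    tab <- report_table(stats::setNames(list(list(global = fit)), nm))
    utils::write.table(format(tab, digits = 4), config$report_txt,
                       quote = FALSE, row.names = FALSE, sep = "\t")
  }
  invisible(list(fit = fit, config = config))
}

#' Parameter-recovery study
#'
#' Repeats generate-and-fit over seeded replicates of one experiment class
#' and summarizes recovery of every truth parameter: per-replicate
#' estimates, mean, bias and RMSE, optionally with per-replicate
#' chi-square-threshold confidence limits.
#'
#' @param design an [experiment_design()]; its seed is the base seed
#'   (replicate r uses `seed + r - 1`).
#' @param replicates number of replicates (defaults to the design's).
#' @param free free parameters for scheme1 global fits.
#' @param fixed named list of fixed parameters for scheme1 global fits
#'   (k2 = 0.5 is supplied automatically).
#' @param weighted if `TRUE`, scheme1 fits weight each point by
#'   1/sigma^2 with sigma taken from the design's noise model applied to
#'   the observed course range (the efficient estimator when courses span
#'   very different dynamic ranges).
#' @param n_starts multi-start count passed to the fitters.
#' @param compute_limits if `TRUE`, 1-D profile confidence limits (10%
#'   threshold) are computed for each free parameter of each replicate.
#' @return List with `estimates` (long data.frame: replicate, seed, param,
#'   truth, estimate, and limits when requested) and `summary`
#'   (per-parameter truth, mean, bias, rmse).
#' @export
recover_study <- function(design, replicates = design$replicates,
                          free = c("k1", "k_minus1", "k_minus2", "k3"),
                          fixed = list(), weighted = FALSE,
                          n_starts = 3, compute_limits = FALSE) {
  stopifnot(inherits(design, "experiment_design"), replicates >= 1)
  truth_vec <- function() {
    tr <- design$truth
    if (design$scheme == "scheme1") {
      v <- c(k1 = tr$k1, k_minus1 = tr$k_minus1, k_minus2 = tr$k_minus2,
             k3 = tr$k3)[free]
      der <- derived_parameters(tr)
      c(v, Kd_app_uM = der$Kd_app_uM, Kd_dna_nM = der$Kd_dna_nM,
        specificity = der$specificity)
    } else if (design$scheme == "burst") {
      c(k_off = tr$k_minus1)
    } else if (design$scheme == "exponential") {
      c(k_exo = tr$k_exo)
    } else {
      stats::setNames(c(tr$kpol, tr$Kd_dna),
                      c(paste0("kpol", seq_along(tr$kpol)), "Kd_dna"))
    }
  }
  truth <- truth_vec()
  rows <- list()
  for (r in seq_len(replicates)) {
    d <- design; d$seed <- design$seed + r - 1L
    data <- .generate(d)
    est <- rep(NA_real_, length(truth)); names(est) <- names(truth)
    lims <- NULL
    if (design$scheme == "scheme1") {
      w <- if (weighted)
        lapply(data$courses, function(tc)
          rep(1 / (design$noise$rel * max(abs(tc$values)) +
                     design$noise$add)^2, length(tc$values)))
      fit <- fit_global(data, free = free, fixed = fixed, weights = w,
                        n_starts = n_starts, seed = d$seed)
      est[free] <- fit$par[free]
      if (!is.null(fit$derived)) {
        est["Kd_app_uM"] <- fit$derived$Kd_app_uM
        est["Kd_dna_nM"] <- fit$derived$Kd_dna_nM
        est["specificity"] <- fit$derived$specificity
      }
      if (compute_limits) {
        lims <- lapply(free, function(p)
          confidence_limits(profile_param(fit, p, n_grid = 11))[[p]])
        names(lims) <- free
      }
    } else if (design$scheme == "burst") {
      # a noise realization can bury the burst phase entirely; such
      # replicates are recorded as failed, not silently dropped
      est["k_off"] <- tryCatch(fit_burst(data)$k_off,
                               error = function(e) NA_real_)
    } else if (design$scheme == "exponential") {
      est["k_exo"] <- fit_exponential(data)$k_exo
    } else {
      fit <- fit_processive(data, n_steps = length(design$truth$kpol),
                            n_starts = n_starts, seed = d$seed)
      est[names(truth)] <- fit$par[names(truth)]
    }
    df <- data.frame(replicate = r, seed = d$seed, param = names(truth),
                     truth = unname(truth), estimate = unname(est),
                     stringsAsFactors = FALSE)
    if (!is.null(lims)) {
      df$low <- NA_real_; df$high <- NA_real_
      for (p in names(lims)) {
        df$low[df$param == p] <- lims[[p]]$low
        df$high[df$param == p] <- lims[[p]]$high
      }
    }
    rows[[r]] <- df
  }
  est_long <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(split(est_long, est_long$param), function(d)
    data.frame(param = d$param[1], truth = d$truth[1],
               mean = mean(d$estimate, na.rm = TRUE),
               bias = mean(d$estimate - d$truth, na.rm = TRUE),
               rmse = sqrt(mean((d$estimate - d$truth)^2, na.rm = TRUE)),
               n_failed = sum(is.na(d$estimate)),
               stringsAsFactors = FALSE)))
  rownames(summ) <- NULL
  list(estimates = est_long, summary = summ)
}

#' @rdname workflow
#' @return `run_recover`: invisibly, the [recover_study()] result.  Config
#'   fields: those of `run_simulate` plus `replicates`, `free`, `n_starts`,
#'   `compute_limits`, and output paths `out_csv` (estimates) / `out_json`
#'   (summary).
#' @export
run_recover <- function(config) {
  config <- .load_config(config)
  design <- .design_from_config(config)
  res <- recover_study(
    design,
    replicates = if (is.null(config$replicates)) design$replicates
                 else config$replicates,
    free = if (is.null(config$free)) c("k1", "k_minus1", "k_minus2", "k3")
           else config$free,
    fixed = if (is.null(config$fixed)) list() else config$fixed,
    weighted = isTRUE(config$weighted),
    n_starts = if (is.null(config$n_starts)) 3 else config$n_starts,
    compute_limits = isTRUE(config$compute_limits))
  if (!is.null(config$out_csv))
    utils::write.csv(res$estimates, config$out_csv, row.names = FALSE)
  if (!is.null(config$out_json))
    jsonlite::write_json(
      list(seed = design$seed, summary = res$summary,
           package_version = as.character(utils::packageVersion("polgkin"))),
      config$out_json, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(res)
}
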