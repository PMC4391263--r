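#' Write time courses to the standard CSV format
#'
#' Columns: `experiment_id`, `series_value`, `series_unit`, `time_s`,
#' `observable`, `value_nM`.  Numbers are formatted with 12 significant
#' digits so identical inputs produce byte-identical files.
#'
#' @param x an [experiment_set()] or a single [time_course()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_timecourse_csv <- function(x, path) {
  courses <- if (inherits(x, "experiment_set")) x$courses else list(x)
  rows <- do.call(rbind, lapply(courses, function(tc) {
    data.frame(
      experiment_id = if (is.null(tc$meta$experiment_id)) "exp"
                      else tc$meta$experiment_id,
      series_value = if (is.null(tc$meta$series_value)) NA
                     else tc$meta$series_value,
      series_unit = if (is.null(tc$meta$series_unit)) ""
                    else tc$meta$series_unit,
      time_s = sprintf("%.12g", tc$times),
      observable = tc$observable,
      value_nM = sprintf("%.12g", tc$values),
      stringsAsFactors = FALSE)
  }))
  utils::write.table(rows, path, sep = ",", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read time courses from the standard CSV format
#'
#' @param path CSV file written by [write_timecourse_csv()].
#' @return A list of [time_course()] objects, one per `experiment_id`.
#' @export
read_timecourse_csv <- function(path) {
  if (!file.exists(path)) stop("data file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("experiment_id", "time_s", "observable", "value_nM")
  if (!all(need %in% names(df)))
    stop("CSV is missing required columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  lapply(split(df, factor(df$experiment_id, unique(df$experiment_id))),
         function(d) {
           d <- d[order(d$time_s), ]
           time_course(d$time_s, d$value_nM, d$observable[1],
                       meta = list(experiment_id = d$experiment_id[1],
                                   series_value = d$series_value[1],
                                   series_unit = d$series_unit[1]))
         })
}

# Serialize an experiment set plus its generating design into a sidecar
# JSON (truth parameters, seed, noise and per-course initial-state specs)
# so a dataset on disk can be refit or audited.
.sidecar_payload <- function(set_or_tc) {
  design <- attr(set_or_tc, "design")
  truth <- design$truth
  truth_out <- if (inherits(truth, "rate_constants"))
    c(unclass(truth), list(k_exo = attr(truth, "k_exo")))
  else if (inherits(truth, "processive_rates")) unclass(truth)
  else truth
  payload <- list(
    package_version = as.character(utils::packageVersion("polgkin")),
    scheme = design$scheme,
    seed = design$seed,
    noise = unclass(design$noise),
    truth = truth_out,
    titration = design$titration,
    init = design$init)
  if (inherits(set_or_tc, "experiment_set"))
    payload$inits <- set_or_tc$inits
  payload
}

#' Write a synthetic dataset (CSV plus truth sidecar)
#'
#' @param x output of a `gen_*` generator (an experiment set or time
#'   course carrying its design).
#' @param csv_path,json_path output paths.
#' @return List of the two paths, invisibly.
#' @export
write_dataset <- function(x, csv_path, json_path) {
  write_timecourse_csv(x, csv_path)
  payload <- .sidecar_payload(x)
  payload$config_hash <- unname(tools::md5sum(csv_path))
  jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(list(csv = csv_path, json = json_path))
}
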