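#' Read a trial-level dataset from CSV
#'
#' Expects header columns `rt` (seconds), `response` (0 = lower, 1 =
#' upper) and `condition` (positive integer).  Validation failures name
#' the offending row; a median reaction time above 100 triggers a
#' warning that times look like milliseconds (no conversion is applied).
#'
#' @param path CSV file path.
#' @return Validated data frame.
#' @export
read_dataset <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  validate_dataset(read.csv(path))
}

#' Write a trial-level dataset to CSV
#'
#' @param data dataset data frame.
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_dataset <- function(data, path) {
  write.csv(validate_dataset(data), path, row.names = FALSE)
  invisible(path)
}

#' Read a run configuration from JSON or YAML
#'
#' @param path file ending in `.json`, `.yaml` or `.yml`.
#' @return Named list of configuration values.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
}

report_to_list <- function(report) {
  if (inherits(report, "recovery_report")) {
    list(type = "recovery", n_datasets = report$n_datasets,
         n_used = report$n_used, n_excluded = report$n_excluded,
         n_trials = report$n_trials, table = report$table,
         bias = as.data.frame(report$bias))
  } else if (inherits(report, "sbc_report")) {
    list(type = "sbc", n_datasets = report$n_datasets,
         n_used = report$n_used, n_excluded = report$n_excluded,
         n_trials = report$n_trials, B = report$B, L = report$L,
         ranks = as.data.frame(report$ranks),
         chi2 = lapply(report$chi2, unclass),
         fisher = report$fisher)
  } else as.list(report)
}

#' Serialize a study report to JSON
#'
#' Calibration reports additionally get a `<path>_ranks.csv` sidecar with
#' the per-dataset rank vectors (one column per test quantity), so the
#' raw ranks stay diff-able and language-neutral.
#'
#' @param report a `recovery_report` or `sbc_report`.
#' @param path output JSON path.
#' @return The path, invisibly.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(report_to_list(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  if (inherits(report, "sbc_report"))
    write.csv(as.data.frame(report$ranks),
              sub("\\.json$", "", path) |> paste0("_ranks.csv"),
              row.names = FALSE)
  invisible(path)
}
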