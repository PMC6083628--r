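# Plain-text persistence: the study dataset as one CSV (calorimetry series
# collapsed to ';'-separated strings) with a YAML sidecar of the generating
# parameters.

#' Write a study dataset to CSV (plus a YAML parameter sidecar)
#'
#' @param dataset a study dataset.
#' @param path CSV path; when `config` is given a sidecar with the same stem
#'   and extension `.yaml` is written next to it.
#' @param config optional [simulation_config()] recorded as provenance.
#' @export
write_study_dataset <- function(dataset, path, config = NULL) {
  out <- as.data.frame(dataset)
  for (col in c("vo2_series", "vco2_series"))
    if (col %in% names(out))
      out[[col]] <- vapply(out[[col]], function(x)
        if (is.null(x) || all(is.na(x))) "" else
          paste(format(x, digits = 12, trim = TRUE, scientific = FALSE),
                collapse = ";"), character(1))
  utils::write.csv(out, path, row.names = FALSE)
  if (!is.null(config))
    yaml::write_yaml(config_to_list(config), sub("\\.csv$", ".yaml", path),
                     precision = 15L)
  invisible(path)
}

#' Read a study dataset written by [write_study_dataset()]
#'
#' @param path CSV path.
#' @return A `study_dataset` data.frame.
#' @export
read_study_dataset <- function(path) {
  ds <- utils::read.csv(path, stringsAsFactors = FALSE)
  if ("date" %in% names(ds)) ds$date <- as.Date(ds$date)
  for (col in c("vo2_series", "vco2_series"))
    if (col %in% names(ds))
      ds[[col]] <- lapply(ds[[col]], function(s)
        if (is.na(s) || !nzchar(s)) NULL else
          as.numeric(strsplit(s, ";", fixed = TRUE)[[1]]))
  class(ds) <- c("study_dataset", "data.frame")
  ds
}

config_to_list <- function(config) {
  # named atomic vectors must become lists or YAML drops their names
  to_yaml <- function(x) {
    if (is.data.frame(x)) lapply(x, unname)
    else if (is.list(x)) lapply(x, to_yaml)
    else if (is.atomic(x) && !is.null(names(x))) as.list(x)
    else x
  }
  lapply(unclass(config), to_yaml)
}

#' Rebuild a simulation configuration from its YAML representation
#'
#' @param x a list as produced by reading the YAML sidecar.
#' @return A `simulation_config` object.
#' @export
config_from_list <- function(x) {
  for (f in c("nutrients", "tools"))
    x[[f]] <- as.data.frame(x[[f]], stringsAsFactors = FALSE)
  for (f in c("missingness"))
    x[[f]] <- unlist(x[[f]])
  for (nm in c("weight_mean", "weight_sd"))
    x$demographics[[nm]] <- unlist(x$demographics[[nm]])
  x$demographics$age_range <- unlist(x$demographics$age_range)
  x$raw$plasma <- lapply(x$raw$plasma, unlist)
  cfg <- structure(x, class = "simulation_config")
  validate_simulation_config(cfg)
  cfg
}
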