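#' Read a cohort table from tab-delimited text
#'
#' Expects a header with at least \code{id}, an exposure column,
#' \code{age_at_assessment}, \code{event_age} (empty/NA when censored) and
#' \code{censor_age}.  Ranges are validated and basic counts logged via
#' \code{message()}.
#'
#' @param path File path.
#' @param required Columns that must be present.
#' @param quiet Suppress the row-count message.
#' @return A \code{data.frame} of class \code{"chronomr_cohort"}.
#' @export
read_cohort <- function(path,
                        required = c("id", "exposure_raw",
                                     "age_at_assessment", "event_age",
                                     "censor_age"),
                        quiet = FALSE) {
  dat <- utils::read.delim(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  miss <- setdiff(required, names(dat))
  if (length(miss)) {
    stop("cohort file is missing required column(s): ",
         paste(miss, collapse = ", "))
  }
  for (col in c("age_at_assessment", "event_age", "censor_age")) {
    if (col %in% names(dat) && !is.numeric(dat[[col]])) {
      stop("unparseable ages in column ", col)
    }
  }
  has_ev <- !is.na(dat$event_age)
  if (any(dat$event_age[has_ev] > dat$censor_age[has_ev])) {
    stop("event_age exceeds censor_age for some individuals")
  }
  if (any(dat$censor_age < 0) || any(dat$event_age[has_ev] < 0)) {
    stop("negative ages in cohort file")
  }
  dupes <- anyDuplicated(dat$id)
  if (dupes && !isTRUE(any(dat$selection_duplicate))) {
    stop("duplicate ids in cohort file (not flagged as selection duplicates)")
  }
  if (!quiet) {
    message(sprintf("read %d individuals (%d events, %.1f%% exposure missing)",
                    nrow(dat), sum(has_ev),
                    100 * mean(is.na(dat$exposure_raw))))
  }
  class(dat) <- c("chronomr_cohort", "data.frame")
  dat
}

#' Write a cohort table as tab-delimited text
#'
#' @param cohort Cohort table.
#' @param path File path.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.table(cohort, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Default run configuration
#'
#' Analysis settings with the package defaults: follow-up to age 76, yearly
#' grid, quartic instrument model, kernel FDHM \code{b = 10} years, HP
#' penalty \code{lambda = 50}, 10,000 bootstrap samples, \code{alpha = 0.05}
#' (CI multiplier 1.96), weak-instrument floor 0.01 exposure SD.
#'
#' @param cohort_path,output_dir Optional file paths for [run_pipeline()].
#' @param ... Overrides of any setting.
#' @return A named list of class \code{"run_config"}.
#' @export
run_config <- function(cohort_path = NULL, output_dir = NULL, ...) {
  cfg <- list(
    cohort_path = cohort_path,
    output_dir = output_dir,
    instrument = "instrument",
    exposure = "exposure_raw",
    covariates = character(),
    standardize = FALSE,
    beta_model = "quartic",
    max_follow_age = 76,
    weak_instrument_floor = 0.01,
    alpha = 0.05,
    b = 10,
    lambda = 50,
    n_boot = 10000,
    sex_stratified = FALSE,
    seed = 1L
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) {
    stop("unknown run_config setting(s): ", paste(unknown, collapse = ", "))
  }
  cfg[names(dots)] <- dots
  class(cfg) <- "run_config"
  cfg
}

#' Read or write a run configuration as YAML
#'
#' Round-trips losslessly through [yaml::write_yaml()].
#'
#' @param path YAML file path.
#' @return For \code{read_run_config}, a \code{"run_config"}.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$covariates <- as.character(raw$covariates %||% character())
  do.call(run_config, raw)
}

#' @rdname read_run_config
#' @param config A [run_config()].
#' @export
write_run_config <- function(config, path) {
  out <- unclass(config)
  out <- out[!vapply(out, is.null, logical(1))]
  yaml::write_yaml(out, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# stable short hash of a configuration (polynomial rolling hash, kept well
# inside double-precision integer range)
config_hash <- function(config) {
  settings <- unclass(config)
  settings$cohort_path <- NULL       # hash the analysis, not the file layout
  settings$output_dir <- NULL
  txt <- paste(deparse(settings), collapse = "")
  bytes <- utf8ToInt(txt)
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}
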