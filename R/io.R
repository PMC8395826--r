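#' Read and write cohort, outcome, and plate tables
#'
#' Plain-CSV serialisation of the package's tabular objects. Every writer
#' has a reader that restores column types, so a written file round-trips to
#' an identical data.frame.
#'
#' @param cohort,outcomes The data.frame to write.
#' @param path File path.
#' @return Readers return the data.frame; writers return `path` invisibly.
#' @name trecscreen-io
NULL

#' @rdname trecscreen-io
#' @export
write_cohort_csv <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' @rdname trecscreen-io
#' @export
read_cohort_csv <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = c(child_id = "character"))
  x$arrival_date <- as.Date(x$arrival_date)
  x$ga_weeks <- as.integer(x$ga_weeks)
  x$spot <- as.integer(x$spot)
  x
}

#' @rdname trecscreen-io
#' @export
write_outcomes_csv <- function(outcomes, path) {
  utils::write.csv(outcomes, path, row.names = FALSE)
  invisible(path)
}

#' @rdname trecscreen-io
#' @export
read_outcomes_csv <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = c(child_id = "character"))
  x$replicates_used <- as.integer(x$replicates_used)
  x$replicates_excluded <- as.integer(x$replicates_excluded)
  x$epoch <- as.integer(x$epoch)
  x
}

#' Write a plate export (wells and standard-curve points)
#'
#' One CSV row per well x analyte, plus a companion standard-curve CSV with
#' the nominal calibrator concentrations, the dialect instrument exports are
#' commonly munged into.
#'
#' @param plate A [simulate_plate()] record.
#' @param path Path of the wells CSV; the curve file is written next to it
#'   with suffix `_curves.csv`.
#' @return `path`, invisibly.
#' @export
write_plate_csv <- function(plate, path) {
  stopifnot(inherits(plate, "plate_record"))
  w <- plate$wells
  w$plate_id <- plate$plate_id
  utils::write.csv(w[, c("plate_id", "well", "sample_ref", "role", "analyte",
                         "ct", "amplification_ok")], path, row.names = FALSE)
  curves <- do.call(rbind, lapply(plate$curves, function(cv) {
    data.frame(plate_id = plate$plate_id, analyte = cv$analyte,
               copies = cv$points$copies, ct = cv$points$ct,
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(curves, sub("\\.csv$", "_curves.csv", path),
                   row.names = FALSE)
  invisible(path)
}

#' Read a plate export back into a plate record
#'
#' @param path Path of the wells CSV written by [write_plate_csv()].
#' @return A `plate_record` with curves refit from the calibrator points.
#' @export
read_plate_csv <- function(path) {
  w <- utils::read.csv(path, stringsAsFactors = FALSE)
  cv <- utils::read.csv(sub("\\.csv$", "_curves.csv", path),
                        stringsAsFactors = FALSE)
  curves <- lapply(split(cv, cv$analyte), function(d) {
    fit_standard_curve(data.frame(copies = d$copies, ct = d$ct),
                       analyte = d$analyte[1])
  })
  curves <- curves[c("TREC", "KREC", "ACTB")]
  structure(list(plate_id = w$plate_id[1], curves = curves,
                 wells = w[, c("well", "sample_ref", "role", "analyte", "ct",
                               "amplification_ok")]),
            class = "plate_record")
}

#' Read or write a pipeline configuration
#'
#' Configurations are plain nested lists serialised as YAML (`.yaml`/`.yml`)
#' or JSON (`.json`), chosen by file extension.
#'
#' @param config A configuration list (see [pipeline_config()]).
#' @param path File path.
#' @return `read_config()` returns the list; `write_config()` returns
#'   `path` invisibly.
#' @export
write_config <- function(config, path) {
  ext <- tolower(tools::file_ext(path))
  plain <- rapply(config, function(x) {
    if (inherits(x, "Date")) format(x) else x
  }, how = "replace")
  class(plain) <- NULL
  if (ext %in% c("yaml", "yml")) {
    yaml::write_yaml(plain, path)
  } else if (ext == "json") {
    jsonlite::write_json(plain, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, dataframe = "columns")
  } else {
    stop("usage error: config must be .yaml, .yml, or .json", call. = FALSE)
  }
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  if (!file.exists(path)) {
    stop("missing input file: ", path, call. = FALSE)
  }
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    stop("usage error: config must be .yaml, .yml, or .json", call. = FALSE)
  }
}
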