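# CSV dialects used by the pipeline. All tables are UTF-8,
# comma-separated with a header row; missing values are empty fields.

qpcr_cols <- readr::cols(
  sample = readr::col_character(),
  condition = readr::col_character(),
  region = readr::col_character(),
  compartment = readr::col_character(),
  time_min = readr::col_double(),
  bio_rep = readr::col_integer(),
  tech_rep = readr::col_integer(),
  target = readr::col_character(),
  ct = readr::col_double()
)

#' Read / write the qPCR Ct CSV
#'
#' Columns: `sample, condition, region, compartment, time_min, bio_rep,
#' tech_rep, target, ct`.
#'
#' @param path File path.
#' @return `read_qpcr_csv`: a tibble of Ct records.
#' @export
read_qpcr_csv <- function(path) {
  readr::read_csv(path, col_types = qpcr_cols)
}

#' @rdname read_qpcr_csv
#' @param records Tibble of Ct records (as from [simulate_chase()]).
#' @export
write_qpcr_csv <- function(records, path) {
  readr::write_csv(records, path, na = "")
  invisible(path)
}

#' Read / write the relative-quantity CSV
#'
#' Columns: `condition, region, compartment, bio_rep, series, time_min,
#' rq`.
#'
#' @param path File path.
#' @return `read_rq_csv`: a tibble of relative quantities.
#' @export
read_rq_csv <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    condition = readr::col_character(),
    region = readr::col_character(),
    compartment = readr::col_character(),
    bio_rep = readr::col_integer(),
    series = readr::col_character(),
    time_min = readr::col_double(),
    rq = readr::col_double()
  ))
}

#' @rdname read_rq_csv
#' @param rq Tibble of relative quantities (as from [delta_delta_ct()]).
#' @export
write_rq_csv <- function(rq, path) {
  readr::write_csv(rq, path, na = "")
  invisible(path)
}

#' Read / write the decay-fit results CSV
#'
#' Columns: `condition, compartment, lambda, half_life, ci_low, ci_high,
#' rss, n_points, n_series, flagged`.
#'
#' @param path File path.
#' @return `read_fits_csv`: a tibble of fit results.
#' @export
read_fits_csv <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    condition = readr::col_character(),
    compartment = readr::col_character(),
    .default = readr::col_double(),
    n_points = readr::col_integer(),
    n_series = readr::col_integer(),
    flagged = readr::col_logical()
  ))
}

#' @rdname read_fits_csv
#' @param fits Tibble from [fit_decay()] (the `fit` list-column is
#'   dropped on write).
#' @export
write_fits_csv <- function(fits, path) {
  out <- fits[setdiff(names(fits), "fit")]
  readr::write_csv(out, path, na = "")
  invisible(path)
}

#' Read / write the intensity fold-change CSV
#'
#' Columns: `comparison, numerator, denominator, fc`.
#'
#' @param path File path.
#' @return `read_intensity_csv`: a tibble of fold changes.
#' @export
read_intensity_csv <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    comparison = readr::col_character(),
    numerator = readr::col_character(),
    denominator = readr::col_character(),
    fc = readr::col_double()
  ))
}

#' @rdname read_intensity_csv
#' @param fc Tibble from [simulate_intensity_fc()].
#' @export
write_intensity_csv <- function(fc, path) {
  readr::write_csv(fc, path, na = "")
  invisible(path)
}

#' Write a provenance sidecar for an artifact
#'
#' Every pipeline artifact gets `<artifact>.provenance.json` recording
#' the stage, its parameters, the seed, the package version and the MD5
#' of each input file, so a run can be reproduced from the sidecar
#' alone.
#'
#' @param artifact_path Path of the artifact the sidecar describes.
#' @param stage Stage name.
#' @param params Named list of stage parameters (must be
#'   JSON-serialisable).
#' @param seed Seed in force for the stage (or `NULL`).
#' @param inputs Character vector of input file paths to hash.
#' @return The sidecar path, invisibly.
#' @export
write_provenance <- function(artifact_path, stage, params = list(),
                             seed = NULL, inputs = character()) {
  sidecar <- paste0(artifact_path, ".provenance.json")
  hashes <- if (length(inputs)) {
    as.list(tools::md5sum(inputs))
  } else {
    stats::setNames(list(), character())
  }
  jsonlite::write_json(
    list(
      stage = stage,
      artifact = basename(artifact_path),
      parameters = params,
      seed = seed,
      inputs_md5 = hashes,
      package = "chaseterm",
      version = as.character(utils::packageVersion("chaseterm"))
    ),
    sidecar, auto_unbox = TRUE, pretty = TRUE, null = "null", digits = NA
  )
  invisible(sidecar)
}
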