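# Dataset writer/reader: one CSV per patient in the standard sensor-export
# schema plus a JSON manifest.

TABLE1_COLS <- c("time", "patient_id", "age", "sex", "type", "sensor_r",
                 "sensor_k", "needle_id", "sensor_id", "WE1", "WE2", "ratio",
                 "Temperature", "Battery Voltage", "glucose")

#' Write a CGM dataset to disk
#'
#' One delimited file per patient with the standard sensor-export column
#' names (`time, patient_id, age, sex, type, sensor_r, sensor_k, needle_id,
#' sensor_id, WE1, WE2, ratio, Temperature, Battery Voltage, glucose`),
#' ISO-8601 timestamps and missing glucose encoded as an empty field, plus a
#' `manifest.json` listing the patients.  Round-trips losslessly through
#' [read_cgm_dataset()].
#'
#' @param data Cohort tibble (e.g. from [simulate_cohort()]).
#' @param path Output directory (created if needed).
#' @param seed Optional seed to record in the manifest.
#' @return The manifest, invisibly.
#' @export
write_cgm_dataset <- function(data, path, seed = NULL) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  ids <- if (nrow(data) > 0L) sort(unique(data$patient_id)) else integer(0)
  entries <- lapply(ids, function(id) {
    d <- dplyr::filter(data, .data$patient_id == id)
    d <- d[, TABLE1_COLS]
    d$time <- format(d$time, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
    file <- sprintf("patient_%03d.csv", id)
    readr::write_csv(d, file.path(path, file), na = "")
    list(patient_id = id, file = file, n_readings = nrow(d))
  })
  manifest <- list(format = "dscinet-cgm-csv-1", n_patients = length(ids),
                   seed = seed, patients = entries)
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  invisible(manifest)
}

#' Read a CGM dataset written by [write_cgm_dataset()]
#'
#' @param path Dataset directory containing `manifest.json`.
#' @return A cohort tibble; empty glucose fields become `NA` with
#'   `is_missing = TRUE`, and `minute` (minutes since each patient's first
#'   reading) is reconstructed from the timestamps.
#' @export
read_cgm_dataset <- function(path) {
  mf <- file.path(path, "manifest.json")
  if (!file.exists(mf)) abort(sprintf("no manifest.json in %s", path))
  manifest <- jsonlite::read_json(mf)
  cts <- readr::cols(
    time = readr::col_datetime(format = "%Y-%m-%dT%H:%M:%SZ"),
    patient_id = readr::col_integer(),
    needle_id = readr::col_integer(),
    sensor_id = readr::col_integer(),
    .default = readr::col_double()
  )
  parts <- lapply(manifest$patients, function(e) {
    d <- readr::read_csv(file.path(path, e$file), col_types = cts, na = "")
    missing_cols <- setdiff(TABLE1_COLS, names(d))
    if (length(missing_cols) > 0L) {
      abort(sprintf("file %s lacks columns: %s", e$file,
                    paste(missing_cols, collapse = ", ")))
    }
    d$minute <- as.numeric(difftime(d$time, d$time[1], units = "mins"))
    d$is_missing <- is.na(d$glucose)
    d
  })
  if (length(parts) == 0L) {
    return(tibble(time = as.POSIXct(character(0), tz = "UTC"),
                  patient_id = integer(0), glucose = numeric(0)))
  }
  dplyr::bind_rows(parts)
}
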