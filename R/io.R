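#' Write a record dataset as delimited text
#'
#' Writes the four tables (`patients.csv`, `diagnoses.csv`,
#' `prescriptions.csv`, `covariates.csv`) as comma-separated text with a
#' header row and ISO-8601 dates, plus a `metadata.json` sidecar recording
#' the provenance (including the generator seed).
#'
#' @param data an `ehr_dataset`.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_ehr_dataset <- function(data, dir) {
  validate_ehr(data)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (tab in c("patients", "diagnoses", "prescriptions", "covariates")) {
    data.table::fwrite(data[[tab]], file.path(dir, paste0(tab, ".csv")),
                       dateTimeAs = "ISO")
  }
  jsonlite::write_json(data$provenance, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Read a record dataset written by [write_ehr_dataset()]
#'
#' @param dir directory containing the four tables and the metadata sidecar.
#' @return an `ehr_dataset`; structural invariants are re-validated on read.
#' @export
read_ehr_dataset <- function(dir) {
  read_one <- function(name, date_cols, classes = NULL) {
    f <- file.path(dir, paste0(name, ".csv"))
    if (!file.exists(f)) stop("missing table file: ", f)
    t <- if (is.null(classes)) data.table::fread(f)
         else data.table::fread(f, colClasses = classes)
    for (dc in date_cols) if (dc %in% names(t)) t[[dc]] <- as.Date(t[[dc]])
    t
  }
  meta_file <- file.path(dir, "metadata.json")
  prov <- if (file.exists(meta_file)) jsonlite::read_json(meta_file) else list()
  out <- structure(
    list(patients = read_one("patients", c("birth_date", "reg_start",
                                           "reg_end", "death_date")),
         diagnoses = read_one("diagnoses", "event_date"),
         prescriptions = read_one("prescriptions", "issue_date"),
         covariates = read_one("covariates", "measurement_date",
                               classes = list(character = "value")),
         provenance = prov),
    class = "ehr_dataset")
  validate_ehr(out)
  out
}
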