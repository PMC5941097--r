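#' @importFrom rlang .data
#' @importFrom stats rnorm runif rbinom setNames sd
#' @importFrom utils head
NULL

PATIENT_COLS <- c("patient_id", "birth_date", "sex", "bmi", "marital_status",
                  "income_level", "occupation", "death_date")
EVENT_COLS <- c("patient_id", "event_date", "dimension", "code", "setting",
                "duration_days")
ENCOUNTER_COLS <- c("patient_id", "encounter_date", "setting")

SEX_LEVELS <- c("female", "male", "unknown")
MARITAL_LEVELS <- c("married", "unmarried", "unknown")
INCOME_LEVELS <- c("normal", "low", "unknown")
DIMENSIONS <- c("diagnosis", "pharmacy", "procedure", "laboratory")
SETTINGS <- c("outpatient", "admission", "emergency")

#' Construct a longitudinal patient-level dataset
#'
#' Bundles the three clinical tables the engine operates on: one row per
#' patient (demographics), one row per clinical event (diagnoses, drug
#' dispensings, procedures, laboratory orders) and one row per encounter
#' (hospital contact). Columns are coerced to their declared types, exact
#' duplicate event rows are dropped (claims extracts commonly repeat lines and
#' all cohort logic is set-based), and rows are put into a canonical sort
#' order so that identical datasets compare and serialize identically.
#'
#' No invariants are enforced here beyond column types: use
#' [validate_dataset()] to obtain a violation report, or [load_dataset()]
#' which refuses files with broken referential integrity.
#'
#' @param patients Data frame with columns `patient_id`, `birth_date`, `sex`
#'   (`female`/`male`/`unknown`), `bmi` (kg/m^2, optional), `marital_status`
#'   (`married`/`unmarried`/`unknown`), `income_level`
#'   (`normal`/`low`/`unknown`), `occupation` (optional free string),
#'   `death_date` (optional).
#' @param events Data frame with columns `patient_id`, `event_date`,
#'   `dimension` (`diagnosis`/`pharmacy`/`procedure`/`laboratory`), `code`
#'   (ICD-9 for diagnoses, drug identifier for pharmacy), `setting`
#'   (`outpatient`/`admission`/`emergency`), `duration_days` (pharmacy only:
#'   days the dispensing covers).
#' @param encounters Data frame with columns `patient_id`, `encounter_date`,
#'   `setting`.
#' @param quiet Suppress the dropped-duplicates message.
#' @return An object of class `ehr_dataset`: a list with tibbles `patients`,
#'   `events`, `encounters`.
#' @examples
#' ds <- ehr_dataset(
#'   patients = data.frame(patient_id = "P1", birth_date = "1940-05-01",
#'                         sex = "female"),
#'   events = data.frame(patient_id = "P1", event_date = "2012-03-01",
#'                       dimension = "diagnosis", code = "820.21",
#'                       setting = "admission"),
#'   encounters = data.frame(patient_id = "P1", encounter_date = "2012-03-01",
#'                           setting = "admission")
#' )
#' nrow(ds$patients)
#' @export
ehr_dataset <- function(patients = NULL, events = NULL, encounters = NULL,
                        quiet = FALSE) {
  patients <- coerce_patients(patients)
  events <- coerce_events(events)
  encounters <- coerce_encounters(encounters)

  n0 <- nrow(events)
  events <- dplyr::distinct(events, .data$patient_id, .data$event_date,
                            .data$dimension, .data$code, .data$setting,
                            .keep_all = TRUE)
  if (!quiet && nrow(events) < n0) {
    message(sprintf("ehr_dataset: dropped %d duplicate event row(s)",
                    n0 - nrow(events)))
  }

  structure(
    list(
      patients = dplyr::arrange(patients, .data$patient_id),
      events = dplyr::arrange(events, .data$patient_id, .data$event_date,
                              .data$dimension, .data$code, .data$setting),
      encounters = dplyr::arrange(encounters, .data$patient_id,
                                  .data$encounter_date, .data$setting)
    ),
    class = "ehr_dataset"
  )
}

coerce_patients <- function(x) {
  if (is.null(x) || nrow(as.data.frame(x)) == 0) {
    return(tibble::tibble(
      patient_id = character(), birth_date = as.Date(character()),
      sex = character(), bmi = numeric(), marital_status = character(),
      income_level = character(), occupation = character(),
      death_date = as.Date(character())
    ))
  }
  x <- tibble::as_tibble(x)
  if (!"bmi" %in% names(x)) x$bmi <- NA_real_
  if (!"marital_status" %in% names(x)) x$marital_status <- "unknown"
  if (!"income_level" %in% names(x)) x$income_level <- "unknown"
  if (!"occupation" %in% names(x)) x$occupation <- NA_character_
  if (!"death_date" %in% names(x)) x$death_date <- as.Date(NA)
  missing <- setdiff(c("patient_id", "birth_date", "sex"), names(x))
  if (length(missing)) {
    stop("patients table lacks column(s): ", paste(missing, collapse = ", "))
  }
  tibble::tibble(
    patient_id = as.character(x$patient_id),
    birth_date = as_iso_date(x$birth_date, "patients$birth_date"),
    sex = as.character(x$sex),
    bmi = as.numeric(x$bmi),
    marital_status = as.character(x$marital_status),
    income_level = as.character(x$income_level),
    occupation = as.character(x$occupation),
    death_date = as_iso_date(x$death_date, "patients$death_date")
  )
}

coerce_events <- function(x) {
  if (is.null(x) || nrow(as.data.frame(x)) == 0) {
    return(tibble::tibble(
      patient_id = character(), event_date = as.Date(character()),
      dimension = character(), code = character(), setting = character(),
      duration_days = integer()
    ))
  }
  x <- tibble::as_tibble(x)
  if (!"duration_days" %in% names(x)) x$duration_days <- NA_integer_
  missing <- setdiff(c("patient_id", "event_date", "dimension", "code",
                       "setting"), names(x))
  if (length(missing)) {
    stop("events table lacks column(s): ", paste(missing, collapse = ", "))
  }
  tibble::tibble(
    patient_id = as.character(x$patient_id),
    event_date = as_iso_date(x$event_date, "events$event_date"),
    dimension = as.character(x$dimension),
    code = as.character(x$code),
    setting = as.character(x$setting),
    duration_days = as.integer(x$duration_days)
  )
}

coerce_encounters <- function(x) {
  if (is.null(x) || nrow(as.data.frame(x)) == 0) {
    return(tibble::tibble(
      patient_id = character(), encounter_date = as.Date(character()),
      setting = character()
    ))
  }
  x <- tibble::as_tibble(x)
  missing <- setdiff(ENCOUNTER_COLS, names(x))
  if (length(missing)) {
    stop("encounters table lacks column(s): ", paste(missing, collapse = ", "))
  }
  tibble::tibble(
    patient_id = as.character(x$patient_id),
    encounter_date = as_iso_date(x$encounter_date, "encounters$encounter_date"),
    setting = as.character(x$setting)
  )
}

# strict ISO-8601 date parse; anything non-empty that fails to parse is a
# row-level error surfaced with the offending values
as_iso_date <- function(x, what) {
  if (inherits(x, "Date")) return(x)
  x <- as.character(x)
  x[!is.na(x) & x == ""] <- NA_character_
  out <- as.Date(rep(NA_character_, length(x)))
  ok <- is.na(x)
  parsed <- suppressWarnings(as.Date(x[!ok], format = "%Y-%m-%d"))
  bad <- is.na(parsed)
  if (any(bad)) {
    stop(sprintf("unparseable date(s) in %s: %s", what,
                 paste(unique(head(x[!ok][bad], 5)), collapse = ", ")))
  }
  out[!ok] <- parsed
  out
}

#' @export
print.ehr_dataset <- function(x, ...) {
  cat(sprintf("<ehr_dataset> %d patients, %d events, %d encounters\n",
              nrow(x$patients), nrow(x$events), nrow(x$encounters)))
  invisible(x)
}

#' Validate a dataset against the data-model invariants
#'
#' Checks every row of the three tables against the type invariants
#' (unique patient identifiers, resolvable references, valid category levels,
#' death after birth, BMI in (5, 100), positive pharmacy-only dispensing
#' durations, non-empty codes) and returns the violations as data, not
#' exceptions: one row per violation with the table, the offending row key and
#' a stable rule identifier.
#'
#' @param ds An [ehr_dataset()].
#' @return A tibble with columns `table`, `row_key`, `rule`; zero rows iff the
#'   dataset is clean.
#' @export
validate_dataset <- function(ds) {
  stopifnot(inherits(ds, "ehr_dataset"))
  v <- list()
  add <- function(table, row_key, rule) {
    if (length(row_key)) {
      v[[length(v) + 1]] <<- tibble::tibble(table = table,
                                            row_key = as.character(row_key),
                                            rule = rule)
    }
  }
  p <- ds$patients
  dup <- p$patient_id[duplicated(p$patient_id)]
  add("patients", unique(dup), "PAT_ID_UNIQUE")
  add("patients",
      p$patient_id[!is.na(p$death_date) & p$death_date < p$birth_date],
      "PAT_DEATH_BEFORE_BIRTH")
  add("patients", p$patient_id[!is.na(p$bmi) & (p$bmi <= 5 | p$bmi >= 100)],
      "PAT_BMI_RANGE")
  add("patients", p$patient_id[!p$sex %in% SEX_LEVELS], "PAT_SEX_LEVEL")
  add("patients", p$patient_id[!p$marital_status %in% MARITAL_LEVELS],
      "PAT_MARITAL_LEVEL")
  add("patients", p$patient_id[!p$income_level %in% INCOME_LEVELS],
      "PAT_INCOME_LEVEL")
  add("patients", p$patient_id[is.na(p$birth_date)], "PAT_BIRTH_MISSING")

  e <- ds$events
  ekey <- paste(e$patient_id, e$event_date, e$dimension, e$code, e$setting)
  add("events", ekey[!e$patient_id %in% p$patient_id], "EVT_PATIENT_RESOLVES")
  add("events", ekey[!e$dimension %in% DIMENSIONS], "EVT_DIMENSION_LEVEL")
  add("events", ekey[!e$setting %in% SETTINGS], "EVT_SETTING_LEVEL")
  add("events", ekey[is.na(e$code) | e$code == ""], "EVT_CODE_NONEMPTY")
  add("events", ekey[!is.na(e$duration_days) & e$dimension != "pharmacy"],
      "EVT_DURATION_PHARMACY_ONLY")
  add("events", ekey[!is.na(e$duration_days) & e$duration_days <= 0],
      "EVT_DURATION_POSITIVE")
  add("events", unique(ekey[duplicated(ekey)]), "EVT_DUPLICATE")

  en <- ds$encounters
  nkey <- paste(en$patient_id, en$encounter_date, en$setting)
  add("encounters", nkey[!en$patient_id %in% p$patient_id],
      "ENC_PATIENT_RESOLVES")
  add("encounters", nkey[!en$setting %in% SETTINGS], "ENC_SETTING_LEVEL")

  if (!length(v)) {
    return(tibble::tibble(table = character(), row_key = character(),
                          rule = character()))
  }
  dplyr::bind_rows(v)
}

dataset_paths <- function(dir) {
  list(patients = file.path(dir, "patients.csv"),
       events = file.path(dir, "events.csv"),
       encounters = file.path(dir, "encounters.csv"))
}

#' Load a dataset from delimited text tables
#'
#' Reads the three headered CSV tables (ISO-8601 dates), coerces and
#' canonicalises them via [ehr_dataset()], and refuses datasets whose event or
#' encounter rows reference unknown patients, naming the offenders. Duplicate
#' event rows are dropped with a message. A malformed date anywhere aborts the
#' load with the offending values.
#'
#' @param dir Directory containing `patients.csv`, `events.csv`,
#'   `encounters.csv`; alternatively a named list of the three file paths.
#' @param quiet Suppress the dropped-duplicates message.
#' @return A validated [ehr_dataset()].
#' @export
load_dataset <- function(dir, quiet = FALSE) {
  paths <- if (is.list(dir)) dir else dataset_paths(dir)
  for (p in unlist(paths)) {
    if (!file.exists(p)) stop("missing input file: ", p)
  }
  read1 <- function(path) {
    readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                    progress = FALSE)
  }
  ds <- ehr_dataset(read1(paths$patients), read1(paths$events),
                    read1(paths$encounters), quiet = quiet)
  viol <- validate_dataset(ds)
  dangling <- viol[viol$rule %in% c("EVT_PATIENT_RESOLVES",
                                    "ENC_PATIENT_RESOLVES"), ]
  if (nrow(dangling)) {
    ids <- unique(vapply(strsplit(dangling$row_key, " "), `[`, "", 1))
    stop("referential-integrity error: unknown patient_id(s) ",
         paste(ids, collapse = ", "))
  }
  ds
}

#' Write a dataset as delimited text tables
#'
#' Serialises the three tables as headered CSV with ISO-8601 dates, missing
#' values as empty fields, and canonical row order, so that two writes of the
#' same dataset are byte-identical and [load_dataset()] inverts the write
#' exactly.
#'
#' @param ds An [ehr_dataset()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the list of file paths written.
#' @export
write_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "ehr_dataset"))
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", dir)
  }
  paths <- dataset_paths(dir)
  readr::write_csv(ds$patients, paths$patients, na = "")
  readr::write_csv(ds$events, paths$events, na = "")
  readr::write_csv(ds$encounters, paths$encounters, na = "")
  invisible(paths)
}
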