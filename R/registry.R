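#' @name registry
#' @title Longitudinal diagnosis registry container
#'
#' @description A `registry` bundles a patient table (id, sex, birth date,
#' optional death date), a diagnosis event table (one row per patient, date,
#' level-3 ICD-10 code and discharge metadata) and an observation window.
#' All mining operates on first occurrences: per (patient, code) the minimum
#' event date.
NULL

DISCHARGE_TYPES <- c("inpatient", "outpatient", "emergency")
SEXES <- c("male", "female")

## whole-year age at `date` for someone born `birth` (calendar-exact floor)
age_at <- function(date, birth) {
  dy <- data.table::year(date) - data.table::year(birth)
  before_birthday <- (data.table::month(date) < data.table::month(birth)) |
    (data.table::month(date) == data.table::month(birth) &
       data.table::mday(date) < data.table::mday(birth))
  as.integer(dy - before_birthday)
}

#' Construct a diagnosis registry
#'
#' @param patients data.frame with columns `patient_id`, `sex`
#'   ("male"/"female"), `birth_date` (Date or ISO-8601 string), `death_date`
#'   (Date/string or `NA` if alive).
#' @param events data.frame with columns `patient_id`, `date`, `code`
#'   (level-3 ICD-10 or `Y99`), `discharge_type` ("inpatient", "outpatient",
#'   "emergency"; `NA` allowed only for `Y99`). An ISO-week column `week` is
#'   (re)computed from `date`.
#' @param window length-2 observation window (start, end) as Dates or
#'   ISO-8601 strings; defaults to the range of the event dates.
#' @param validate run the invariant checks (default `TRUE`).
#' @return an object of class `registry`: a list with `patients`, `events`
#'   (both `data.table`s) and `window`.
#' @export
new_registry <- function(patients, events, window = NULL, validate = TRUE) {
  patients <- data.table::as.data.table(patients)
  events <- data.table::as.data.table(events)
  patients[, `:=`(patient_id = as.character(patient_id),
                  sex = as.character(sex),
                  birth_date = as.Date(birth_date))]
  if (!"death_date" %in% names(patients)) patients[, death_date := as.Date(NA)]
  patients[, death_date := as.Date(death_date)]
  if (nrow(events)) {
    events[, `:=`(patient_id = as.character(patient_id),
                  code = as.character(code),
                  date = as.Date(date))]
    if (!"discharge_type" %in% names(events))
      events[, discharge_type := NA_character_]
    events[, discharge_type := as.character(discharge_type)]
    events[, week := as.integer(data.table::isoweek(date))]
    data.table::setcolorder(
      events, c("patient_id", "date", "code", "discharge_type", "week"))
    data.table::setkey(events, patient_id, date)
  } else {
    events <- data.table::data.table(
      patient_id = character(), date = as.Date(character()),
      code = character(), discharge_type = character(), week = integer())
  }
  if (is.null(window)) {
    window <- if (nrow(events)) range(events$date)
              else as.Date(c("1994-01-01", "2018-04-30"))
  }
  window <- as.Date(window)
  reg <- structure(list(patients = patients, events = events,
                        window = window),
                   class = "registry")
  if (validate) validate_registry(reg)
  reg
}

#' Validate registry invariants
#'
#' Checks patient id uniqueness, sex/discharge enumerations, date ordering
#' (birth <= event <= death), foreign keys, week consistency and that event
#' dates lie in the observation window.
#'
#' @param reg a `registry`.
#' @return the registry, invisibly; stops with a descriptive error otherwise.
#' @export
validate_registry <- function(reg) {
  p <- reg$patients; e <- reg$events
  if (anyDuplicated(p$patient_id))
    stop("duplicate patient_id in patient table", call. = FALSE)
  if (!all(p$sex %in% SEXES))
    stop("sex must be one of: ", paste(SEXES, collapse = ", "), call. = FALSE)
  bad_death <- !is.na(p$death_date) & p$death_date < p$birth_date
  if (any(bad_death))
    stop("death_date before birth_date for patient(s): ",
         paste(utils::head(p$patient_id[bad_death], 5L), collapse = ", "),
         call. = FALSE)
  if (nrow(e)) {
    orphan <- setdiff(e$patient_id, p$patient_id)
    if (length(orphan))
      stop("event(s) reference unknown patient_id: ",
           paste(utils::head(orphan, 5L), collapse = ", "), call. = FALSE)
    ok_code <- grepl("^[A-Z][0-9]{2}$", e$code)
    if (!all(ok_code))
      stop("event code(s) not level-3 ICD-10: ",
           paste(utils::head(unique(e$code[!ok_code]), 5L), collapse = ", "),
           call. = FALSE)
    ok_dt <- is.na(e$discharge_type) | e$discharge_type %in% DISCHARGE_TYPES
    if (!all(ok_dt))
      stop("unknown discharge_type: ",
           paste(utils::head(unique(e$discharge_type[!ok_dt]), 3L),
                 collapse = ", "), call. = FALSE)
    if (any(is.na(e$discharge_type) & e$code != DEATH_CODE))
      stop("discharge_type missing for non-death event(s)", call. = FALSE)
    m <- merge(e, p[, .(patient_id, birth_date, death_date)],
               by = "patient_id")
    if (any(m$date < m$birth_date))
      stop("event date before patient birth_date", call. = FALSE)
    late <- !is.na(m$death_date) & m$date > m$death_date
    if (any(late))
      stop("event date after patient death_date", call. = FALSE)
    if (any(e$date < reg$window[1] | e$date > reg$window[2]))
      stop("event date outside observation window", call. = FALSE)
    if (!all(e$week == data.table::isoweek(e$date)))
      stop("week column inconsistent with date", call. = FALSE)
  }
  invisible(reg)
}

#' @export
print.registry <- function(x, ...) {
  cat(sprintf("<registry> %d patients, %d events, %d codes, window %s .. %s\n",
              nrow(x$patients), nrow(x$events),
              data.table::uniqueN(x$events$code),
              format(x$window[1]), format(x$window[2])))
  invisible(x)
}

#' First occurrence of every (patient, code)
#'
#' @param reg a `registry`.
#' @return `data.table` with columns `patient_id`, `code`, `first_date`.
#' @export
first_occurrences <- function(reg) {
  if (!nrow(reg$events))
    return(data.table::data.table(patient_id = character(),
                                  code = character(),
                                  first_date = as.Date(character())))
  reg$events[, .(first_date = min(date)), by = .(patient_id, code)]
}

#' Append death events to a registry
#'
#' For every deceased patient one event with the reserved code `Y99` dated at
#' the death date is appended (discharge metadata left missing). Existing
#' events are untouched; registries without deaths pass through unchanged.
#' Downstream, `Y99` only ever acts as the second disease of a pair, and the
#' pairing window (default 5 years, see [threshold_config()]) is what
#' restricts a D1 -> Y99 pair to deaths within the horizon of D1's first
#' occurrence.
#'
#' @param reg a `registry`.
#' @param horizon_years documented horizon linking a diagnosis to death;
#'   enforced by the pair-mining window, recorded here for provenance.
#' @return a new `registry` with the death events appended.
#' @export
inject_death_events <- function(reg, horizon_years = 5) {
  stopifnot(horizon_years > 0)
  dead <- reg$patients[!is.na(death_date)]
  if (!nrow(dead)) return(reg)
  death_ev <- data.table::data.table(
    patient_id = dead$patient_id,
    date = dead$death_date,
    code = DEATH_CODE,
    discharge_type = NA_character_,
    week = as.integer(data.table::isoweek(dead$death_date)))
  window <- c(min(reg$window[1], min(death_ev$date)),
              max(reg$window[2], max(death_ev$date)))
  new_registry(reg$patients, rbind(reg$events, death_ev),
               window = window, validate = FALSE)
}

## skip leading '#' provenance lines, then fread
fread_skip_comments <- function(path, ...) {
  head_lines <- readLines(path, n = 50L)
  n_skip <- 0L
  while (n_skip < length(head_lines) && startsWith(head_lines[n_skip + 1L], "#"))
    n_skip <- n_skip + 1L
  data.table::fread(path, skip = n_skip, ...)
}

#' Read a registry from delimited text files
#'
#' The events file has columns `patient_id`, `date` (ISO-8601), `code`,
#' `discharge_type`; the patients file has `patient_id`, `sex`, `birth_date`,
#' `death_date` (empty if alive). Lines starting with `#` are treated as
#' provenance comments and skipped.
#'
#' @param events_path,patients_path paths to the two delimited files.
#' @param window optional observation window override.
#' @return a validated `registry`.
#' @export
read_registry <- function(events_path, patients_path, window = NULL) {
  pat <- fread_skip_comments(patients_path, colClasses = "character",
                             na.strings = c("", "NA"))
  need_p <- c("patient_id", "sex", "birth_date", "death_date")
  miss <- setdiff(need_p, names(pat))
  if (length(miss))
    stop("patients file missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  ev <- fread_skip_comments(events_path, colClasses = "character",
                            na.strings = c("", "NA"))
  need_e <- c("patient_id", "date", "code", "discharge_type")
  miss <- setdiff(need_e, names(ev))
  if (length(miss))
    stop("events file missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  parse_date <- function(x, what) {
    d <- as.Date(x, format = "%Y-%m-%d")
    bad <- which(is.na(d) & !is.na(x))
    if (length(bad))
      stop("unparseable ", what, " at row(s): ",
           paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
    d
  }
  pat[, birth_date := parse_date(birth_date, "birth_date")]
  pat[, death_date := parse_date(death_date, "death_date")]
  if (nrow(ev)) ev[, date := parse_date(date, "event date")]
  new_registry(pat, ev, window = window)
}

#' Write a registry to delimited text files
#'
#' Inverse of [read_registry()]; the round trip reproduces an equal registry.
#'
#' @param reg a `registry`.
#' @param events_path,patients_path output paths.
#' @param provenance optional character vector written as leading `#` lines.
#' @return invisibly, the two paths.
#' @export
write_registry <- function(reg, events_path, patients_path,
                           provenance = NULL) {
  write_one <- function(dt, path) {
    if (length(provenance))
      writeLines(paste0("# ", provenance), path)
    data.table::fwrite(dt, path, append = length(provenance) > 0,
                       col.names = TRUE, dateTimeAs = "ISO")
  }
  ev <- reg$events[, .(patient_id, date, code, discharge_type)]
  pat <- reg$patients[, .(patient_id, sex, birth_date, death_date)]
  write_one(ev, events_path)
  write_one(pat, patients_path)
  invisible(c(events_path, patients_path))
}
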