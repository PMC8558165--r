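#' Read a registry patient table
#'
#' Expected CSV columns:
#' `pid,sex,birth_date,diagnosis_date,topography,vital_status,death_date,death_cause_cancer`
#' with ISO-8601 dates. Month-only dates (`"2010-06"`) are imputed to day 15
#' with a warning.
#'
#' @param path path to the patients CSV.
#' @return a validated patient tibble.
#' @export
read_patients <- function(path) {
  if (!file.exists(path)) abort(paste0("patient file not found: ", path))
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()))
  check_columns(raw, c("pid", "diagnosis_date", "vital_status"), "patient table")
  raw$diagnosis_date <- parse_registry_date(raw$diagnosis_date, "diagnosis_date")
  if ("birth_date" %in% names(raw)) {
    raw$birth_date <- parse_registry_date(raw$birth_date, "birth_date")
  }
  if ("death_date" %in% names(raw)) {
    raw$death_date <- parse_registry_date(raw$death_date, "death_date")
  } else {
    raw$death_date <- as.Date(NA)
  }
  if ("death_cause_cancer" %in% names(raw)) {
    raw$death_cause_cancer <- as.logical(raw$death_cause_cancer)
  } else {
    raw$death_cause_cancer <- NA
  }
  validate_patients(raw)
}

validate_patients <- function(patients) {
  patients <- tibble::as_tibble(patients)
  check_columns(patients, c("pid", "diagnosis_date", "vital_status"), "patient table")
  if (!"death_date" %in% names(patients)) patients$death_date <- as.Date(NA)
  if (!"death_cause_cancer" %in% names(patients)) patients$death_cause_cancer <- NA
  if (anyDuplicated(patients$pid)) {
    abort("duplicate patient ids", class = "cp_validation_error")
  }
  dead <- patients$vital_status == "DEAD"
  if (any(dead & is.na(patients$death_date))) {
    abort("DEAD patients must carry a death_date", class = "cp_validation_error")
  }
  if (any(!dead & !is.na(patients$death_date))) {
    abort("ALIVE patients must not carry a death_date", class = "cp_validation_error")
  }
  bad <- !is.na(patients$death_date) & patients$death_date < patients$diagnosis_date
  if (any(bad)) {
    abort(paste0("death before diagnosis for: ",
                 paste(patients$pid[bad], collapse = ", ")),
          class = "cp_validation_error")
  }
  patients
}

#' Assign each prevalent patient to a phase of care
#'
#' Cross-sectional phase assignment on the prevalence date. Three mutually
#' exclusive phases are defined: the first year after diagnosis (initial),
#' the last year of life (final) and everything in between (continuing).
#' A patient alive on the prevalence date is assigned:
#'
#' * `final` if she dies of cancer within 12 months after the prevalence date,
#'   regardless of when she was diagnosed;
#' * `censored` if she dies in that interval of a non-cancer cause;
#' * `initial` if diagnosed within the 12 months before the prevalence date
#'   (and not final/censored);
#' * `continuing` otherwise.
#'
#' All intervals are half-open (`[start, end)`) and use calendar-month
#' arithmetic. Each non-censored patient also receives her 12-month
#' observation window: from diagnosis onwards (initial), from death backward
#' (final), or from 6 months before to 6 months after the prevalence date
#' (continuing). Censored patients carry no window and drop out of all
#' downstream tabulations.
#'
#' @param patients patient tibble (see [read_patients()]).
#' @param prevalence_date the index date (Date or ISO string).
#' @return a tibble with `pid`, `phase` (factor: initial/continuing/final/
#'   censored), `window_start`, `window_end`.
#' @export
#' @examples
#' p <- tibble::tibble(
#'   pid = "a", sex = "F", diagnosis_date = as.Date("2010-06-15"),
#'   vital_status = "ALIVE", death_date = as.Date(NA), death_cause_cancer = NA
#' )
#' assign_phases(p, "2011-01-01")
assign_phases <- function(patients, prevalence_date) {
  patients <- validate_patients(patients)
  prev <- as_cp_date(prevalence_date, "prevalence_date")

  not_prev <- patients$diagnosis_date >= prev
  if (any(not_prev)) {
    abort(
      paste0("patients diagnosed on/after the prevalence date are not prevalent: ",
             paste(patients$pid[not_prev], collapse = ", ")),
      class = "cp_not_prevalent_error"
    )
  }
  dead_before <- !is.na(patients$death_date) & patients$death_date < prev
  if (any(dead_before)) {
    abort(
      paste0("patients dead before the prevalence date are not prevalent: ",
             paste(patients$pid[dead_before], collapse = ", ")),
      class = "cp_not_prevalent_error"
    )
  }

  horizon <- add_months(prev, 12)
  dies_in_year <- !is.na(patients$death_date) &
    patients$death_date >= prev & patients$death_date < horizon
  phase <- dplyr::case_when(
    dies_in_year & patients$death_cause_cancer %in% TRUE ~ "final",
    dies_in_year ~ "censored",
    patients$diagnosis_date >= add_months(prev, -12) ~ "initial",
    TRUE ~ "continuing"
  )

  start <- dplyr::case_when(
    phase == "initial" ~ patients$diagnosis_date,
    phase == "final" ~ add_months(patients$death_date, -12),
    phase == "continuing" ~ add_months(prev, -6),
    TRUE ~ as.Date(NA)
  )
  end <- dplyr::case_when(
    phase == "initial" ~ add_months(patients$diagnosis_date, 12),
    phase == "final" ~ patients$death_date,
    phase == "continuing" ~ add_months(prev, 6),
    TRUE ~ as.Date(NA)
  )

  tibble::tibble(
    pid = patients$pid,
    phase = factor(phase, levels = c(cp_phases, "censored")),
    window_start = start,
    window_end = end
  )
}

#' Phase census of a cohort
#'
#' Counts and within-cohort percent shares of the three phases of care,
#' excluding censored patients (who contribute no observation window). The
#' censored count is kept as the `n_censored` attribute.
#'
#' @param assignments output of [assign_phases()].
#' @param digits decimals for the percent share.
#' @return tibble with `phase`, `n`, `share_pct`; shares sum to 100 up to
#'   rounding. Empty (all-censored) cohorts yield a census of zeros.
#' @export
phase_census <- function(assignments, digits = 1) {
  n_cens <- sum(assignments$phase == "censored")
  counts <- assignments %>%
    dplyr::filter(.data$phase != "censored") %>%
    dplyr::count(.data$phase, .drop = FALSE) %>%
    dplyr::filter(.data$phase != "censored")
  total <- sum(counts$n)
  counts$share_pct <- if (total > 0) round_half_up(100 * counts$n / total, digits) else 0
  attr(counts, "n_censored") <- n_cens
  counts
}
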