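# Small in-code fixtures shared across test files.

library(lubridate) # calendar-month arithmetic (%m+%) in window checks

tiny_dlist <- function() {
  as_codelist(tibble::tibble(
    code = c("85.21", "99.25", "174.9", "92.24.1", "89.01", "L02BA01", "N02AB03", "90.62.2"),
    system = c("ICD9CM_PROC", "ICD9CM_PROC", "ICD9CM_DIAG", "OUTPATIENT_NATIONAL",
               "OUTPATIENT_NATIONAL", "ATC", "ATC", "OUTPATIENT_NATIONAL"),
    stream = c("HD", "HD", "HD", "OPS", "OPS", "DP", "DP", "OPS"),
    category = c("Surgery", "Chemotherapy", "Diagnosis and monitoring",
                 "Radiotherapy", "Diagnosis and monitoring", "Hormone therapy",
                 "Analgesic", "Diagnosis and monitoring"),
    subcategory = c("Lumpectomy", NA, "Diagnosis", NA, "Specialist examination",
                    NA, NA, "Standard blood test"),
    excluded_from_frequency = c(rep(FALSE, 7), TRUE)
  ))
}

tiny_patients <- function() {
  tibble::tibble(
    pid = c("A", "B", "C", "D"),
    sex = "F",
    birth_date = as.Date("1950-01-01"),
    diagnosis_date = as.Date(c("2010-06-15", "2005-03-01", "2004-01-01", "2010-06-15")),
    topography = "C50.9",
    vital_status = c("ALIVE", "ALIVE", "DEAD", "DEAD"),
    death_date = as.Date(c(NA, NA, "2011-08-01", "2011-08-01")),
    death_cause_cancer = c(NA, NA, TRUE, FALSE)
  )
}

# one HD episode builder with explicit slot contents
hd_episode <- function(pid = "A", admission = "2010-07-01",
                       diags = "401.9", procs = character(0)) {
  row <- tibble::tibble(
    pid = pid,
    admission_date = as.Date(admission),
    discharge_date = as.Date(admission) + 3
  )
  for (j in 1:6) row[[paste0("diag", j)]] <- if (j <= length(diags)) diags[j] else NA_character_
  for (j in 1:6) row[[paste0("proc", j)]] <- if (j <= length(procs)) procs[j] else NA_character_
  row$drg <- "DRG001"
  row
}

# brute-force oracle: scan a code list row by row for a normalized match
brute_force_member <- function(code, stream, codelist) {
  target <- normalize_code(code, stream)
  any(vapply(seq_len(nrow(codelist)), function(i) {
    codelist$stream[i] == stream &&
      normalize_code(codelist$code[i], codelist$stream[i]) == target
  }, logical(1)))
}
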