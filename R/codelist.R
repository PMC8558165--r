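#' Normalize a clinical code for matching
#'
#' Discharge abstracts circulate both dotted ("85.21") and undotted ("8521")
#' ICD-9-CM forms, with stray whitespace and mixed case. Matching is performed
#' on a canonical form: whitespace stripped, upper-cased, and dots removed for
#' ICD-9-CM-based systems (hospital and outpatient codes). ATC codes are
#' compared verbatim after trimming and upper-casing, since the dot is not
#' part of ATC syntax anyway.
#'
#' @param code character vector of codes.
#' @param stream character vector (recycled) of service streams
#'   (`"HD"`, `"OPS"`, `"DP"`, `"HP"`).
#' @return character vector of canonical codes.
#' @export
#' @examples
#' normalize_code(c(" 85.21", "l02ba01"), c("HD", "DP"))
normalize_code <- function(code, stream) {
  code <- toupper(trimws(as.character(code)))
  icd_based <- stream %in% c("HD", "OPS")
  code[icd_based] <- gsub(".", "", code[icd_based], fixed = TRUE)
  code
}

#' Construct a validated code list
#'
#' A code list (D-list or derived C-list) holds one row per cancer-related
#' code: the code itself, its coding system, the administrative stream it
#' applies to, and a clinical category / sub-category. Validation enforces the
#' stream/system pairing (drug streams carry ATC codes, hospital codes are
#' ICD-9-CM, outpatient codes use the national ICD-9-CM-based system) and
#' uniqueness of the normalized (code, stream) key.
#'
#' @param x a data frame with columns `code`, `system`, `stream`, `category`,
#'   and optionally `subcategory` and `excluded_from_frequency` (defaults:
#'   empty / `FALSE`). `excluded_from_frequency` marks codes (e.g. standard
#'   blood tests, genetic markers) that belong to the list but are left out of
#'   frequency tabulations.
#' @param label a label for the list, e.g. `"D-list"` or `"C-list"`.
#' @return a tibble of class `codelist` with an added `code_norm` column.
#' @export
as_codelist <- function(x, label = "D-list") {
  x <- tibble::as_tibble(x)
  check_columns(x, c("code", "system", "stream", "category"), "code list")
  if (!"subcategory" %in% names(x)) x$subcategory <- NA_character_
  if (!"excluded_from_frequency" %in% names(x)) x$excluded_from_frequency <- FALSE
  x <- dplyr::mutate(
    x,
    code = as.character(.data$code),
    system = as.character(.data$system),
    stream = as.character(.data$stream),
    category = as.character(.data$category),
    subcategory = dplyr::if_else(
      is.na(.data$subcategory) | .data$subcategory == "",
      NA_character_, as.character(.data$subcategory)
    ),
    excluded_from_frequency = as.logical(.data$excluded_from_frequency) %in% TRUE
  )

  if (any(is.na(x$code) | trimws(x$code) == "")) {
    abort("code list has empty codes", class = "cp_validation_error")
  }
  if (any(is.na(x$category) | trimws(x$category) == "")) {
    abort("code list has empty categories", class = "cp_validation_error")
  }
  bad_stream <- setdiff(unique(x$stream), cp_streams)
  if (length(bad_stream) > 0) {
    abort(paste0("unknown stream(s): ", paste(bad_stream, collapse = ", ")),
          class = "cp_validation_error")
  }
  bad_system <- setdiff(unique(x$system), cp_systems)
  if (length(bad_system) > 0) {
    abort(paste0("unknown system(s): ", paste(bad_system, collapse = ", ")),
          class = "cp_validation_error")
  }
  ok <- (x$stream %in% c("DP", "HP") & x$system == "ATC") |
    (x$stream == "HD" & x$system %in% c("ICD9CM_PROC", "ICD9CM_DIAG")) |
    (x$stream == "OPS" & x$system == "OUTPATIENT_NATIONAL")
  if (any(!ok)) {
    bad <- x[!ok, c("code", "system", "stream")]
    abort(
      paste0(
        "stream/system mismatch for: ",
        paste(paste0(bad$code, " (", bad$system, "/", bad$stream, ")"), collapse = ", ")
      ),
      class = "cp_validation_error"
    )
  }

  x$code_norm <- normalize_code(x$code, x$stream)
  key <- paste(x$code_norm, x$stream)
  if (anyDuplicated(key)) {
    dups <- unique(key[duplicated(key)])
    abort(paste0("duplicate (code, stream) entries: ", paste(dups, collapse = "; ")),
          class = "cp_validation_error")
  }

  class(x) <- c("codelist", class(x))
  attr(x, "label") <- label
  x
}

#' Read a code list from CSV or JSON
#'
#' Expected CSV columns (header row, UTF-8):
#' `code,system,stream,category,subcategory,excluded_from_frequency`;
#' the JSON form is an array of objects with the same keys.
#'
#' @param path path to the file.
#' @param format `"auto"` (by extension), `"csv"` or `"json"`.
#' @param label list label, stored as an attribute.
#' @return a validated [as_codelist()] tibble.
#' @export
read_codelist <- function(path, format = c("auto", "csv", "json"), label = "D-list") {
  format <- match.arg(format)
  if (!file.exists(path)) {
    abort(paste0("code list file not found: ", path))
  }
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  raw <- if (format == "json") {
    tibble::as_tibble(jsonlite::fromJSON(path))
  } else {
    readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()))
  }
  if ("excluded_from_frequency" %in% names(raw)) {
    raw$excluded_from_frequency <- as.logical(raw$excluded_from_frequency)
  }
  as_codelist(raw, label = label)
}

#' Write a code list to CSV or JSON
#'
#' @param x a `codelist`.
#' @param path destination path.
#' @param format `"auto"` (by extension), `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_codelist <- function(x, path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  out <- dplyr::select(
    tibble::as_tibble(x), "code", "system", "stream", "category",
    "subcategory", "excluded_from_frequency"
  )
  if (format == "json") {
    jsonlite::write_json(out, path, dataframe = "rows", na = "null", auto_unbox = TRUE)
  } else {
    readr::write_csv(out, path, na = "")
  }
  invisible(path)
}

#' Test whether codes belong to a code list
#'
#' An event is cancer-related if its code belongs to the cancer-related list
#' for its stream. Matching is exact on the normalized code (see
#' [normalize_code()]); no prefix matching is performed, unless
#' `atc_prefix = TRUE` is set, in which case an ATC code also matches any
#' list entry that is a prefix of it (off by default: the lists enumerate
#' explicit codes and prefix semantics would silently widen them).
#'
#' @param code character vector of codes.
#' @param stream character vector (recycled) of streams.
#' @param codelist a `codelist`.
#' @param system optional character vector restricting the match to one coding
#'   system (used for hospital records, whose diagnosis and procedure slots
#'   must not match each other's codes).
#' @param atc_prefix logical; enable ATC prefix matching.
#' @return logical vector, `TRUE` where the code is in the list.
#' @export
is_cancer_related <- function(code, stream, codelist, system = NULL, atc_prefix = FALSE) {
  norm <- normalize_code(code, stream)
  if (is.null(system)) {
    key <- paste(norm, stream)
    lkey <- paste(codelist$code_norm, codelist$stream)
  } else {
    key <- paste(norm, stream, system)
    lkey <- paste(codelist$code_norm, codelist$stream, codelist$system)
  }
  hit <- key %in% lkey
  if (atc_prefix) {
    is_atc <- stream %in% c("DP", "HP") & !hit & !is.na(code)
    if (any(is_atc)) {
      atc_list <- codelist$code_norm[codelist$stream %in% c("DP", "HP")]
      hit[is_atc] <- vapply(
        norm[is_atc],
        function(cd) any(startsWith(cd, atc_list)),
        logical(1)
      )
    }
  }
  hit & !is.na(code)
}

#' @export
print.codelist <- function(x, ...) {
  cat(attr(x, "label") %||% "code list", ": ", nrow(x), " codes across streams ",
      paste(unique(x$stream), collapse = ", "), "\n", sep = "")
  NextMethod()
}

`%||%` <- function(a, b) if (is.null(a)) b else a
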