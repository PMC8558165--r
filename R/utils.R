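#' Round half away from zero
#'
#' Commercial rounding as used in published frequency tables: halves round
#' away from zero (2.45 -> 2.5), unlike [base::round()]'s round-half-even.
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places.
#' @return numeric vector rounded to `digits` decimals.
#' @export
#' @examples
#' round_half_up(c(2.45, 2.35, -2.45), 1)
round_half_up <- function(x, digits = 0) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

## Calendar-month shift; 12 months after 2010-06-15 is 2011-06-15, with
## end-of-month rollback (lubridate's %m+%), not a fixed 365 days.
add_months <- function(date, n) {
  date %m+% months(n)
}

## Half-open interval membership: start <= date < end. NA windows never match.
in_window <- function(date, start, end) {
  !is.na(start) & !is.na(end) & date >= start & date < end
}

## Coerce a scalar date-like input (Date or ISO string) to Date.
as_cp_date <- function(x, what = "date") {
  out <- tryCatch(lubridate::as_date(x), warning = function(w) NA)
  if (any(is.na(out) & !is.na(x))) {
    abort(paste0("Cannot parse ", what, ": ", paste(x[is.na(out) & !is.na(x)], collapse = ", ")))
  }
  out
}

## Parse dates that may carry month-only granularity ("2010-06"): imputed to
## day 15 with a warning, so registry records with incomplete dates keep a
## deterministic, reproducible value.
parse_registry_date <- function(x, what = "date") {
  x <- as.character(x)
  month_only <- !is.na(x) & grepl("^\\d{4}-\\d{2}$", x)
  if (any(month_only)) {
    warn(paste0(
      sum(month_only), " ", what, " value(s) have month-only granularity; ",
      "imputed to day 15"
    ))
    x[month_only] <- paste0(x[month_only], "-15")
  }
  x[!is.na(x) & x == ""] <- NA_character_
  as_cp_date(x, what)
}

check_columns <- function(df, required, what) {
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    abort(
      paste0(what, " is missing required column(s): ", paste(missing, collapse = ", ")),
      class = "cp_schema_error"
    )
  }
  invisible(df)
}
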