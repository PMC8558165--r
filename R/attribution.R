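#' Read an administrative event table
#'
#' CSV schemas by stream (empty slots as empty strings, ISO-8601 dates):
#'
#' * `HD`: `pid,admission_date,discharge_date,diag1..diag6,proc1..proc6,drg`
#' * `OPS`: `pid,date,code`
#' * `DP` / `HP`: `pid,date,atc`
#'
#' @param path path to the CSV file.
#' @param stream one of `"HD"`, `"OPS"`, `"DP"`, `"HP"`.
#' @return a validated event tibble.
#' @export
read_events <- function(path, stream = c("HD", "OPS", "DP", "HP")) {
  stream <- match.arg(stream)
  if (!file.exists(path)) abort(paste0("event file not found: ", path))
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()))
  if (stream == "HD") {
    check_columns(raw, c("pid", "admission_date", "discharge_date",
                         paste0("diag", 1:6), paste0("proc", 1:6)), "HD table")
    raw$admission_date <- as_cp_date(raw$admission_date, "admission_date")
    raw$discharge_date <- as_cp_date(raw$discharge_date, "discharge_date")
    validate_hd(raw)
  } else {
    code_col <- if (stream == "OPS") "code" else "atc"
    check_columns(raw, c("pid", "date", code_col), paste0(stream, " table"))
    raw$date <- as_cp_date(raw$date, "date")
    raw
  }
}

validate_hd <- function(hd) {
  hd <- tibble::as_tibble(hd)
  slot_cols <- c(paste0("diag", 1:6), paste0("proc", 1:6))
  check_columns(hd, c("pid", "admission_date", slot_cols), "HD table")
  for (cl in slot_cols) {
    v <- as.character(hd[[cl]])
    v[!is.na(v) & trimws(v) == ""] <- NA_character_
    hd[[cl]] <- v
  }
  if (!"episode_id" %in% names(hd)) {
    hd$episode_id <- seq_len(nrow(hd))
  }
  if (any(!is.na(hd$discharge_date) & hd$discharge_date < hd$admission_date)) {
    abort("discharge before admission", class = "cp_validation_error")
  }
  if (nrow(hd) > 0 && any(is.na(hd$diag1))) {
    abort("HD episodes must carry a main diagnosis", class = "cp_validation_error")
  }
  hd
}

#' Link events to registry patients by pseudonymous id
#'
#' Exact-key deterministic linkage: each event row gains a `matched` flag
#' indicating whether its `pid` exists in the patient table. No rows are
#' dropped, so `sum(matched) + sum(!matched) == nrow(events)` always holds;
#' the number of unmatched events is reported as a message.
#'
#' @param events an event tibble with a `pid` column.
#' @param patients a patient tibble.
#' @return `events` with an added logical `matched` column.
#' @export
link_events <- function(events, patients) {
  events <- tibble::as_tibble(events)
  check_columns(events, "pid", "event table")
  events$matched <- events$pid %in% patients$pid
  n_un <- sum(!events$matched)
  if (n_un > 0) {
    message(n_un, " event(s) could not be linked to a registry patient")
  }
  events
}

## One row per populated HD code slot, in slot order: procedures main ->
## secondary, then diagnoses main -> secondary. slot_rank orders the scan.
hd_code_slots <- function(hd) {
  hd <- validate_hd(hd)
  slots <- c(paste0("proc", 1:6), paste0("diag", 1:6))
  long <- hd %>%
    dplyr::select("episode_id", "pid", "admission_date", dplyr::all_of(slots)) %>%
    tidyr::pivot_longer(dplyr::all_of(slots), names_to = "slot", values_to = "code") %>%
    dplyr::filter(!is.na(.data$code))
  long$slot_type <- ifelse(startsWith(long$slot, "proc"), "proc", "diag")
  long$system <- ifelse(long$slot_type == "proc", "ICD9CM_PROC", "ICD9CM_DIAG")
  long$slot_rank <- match(long$slot, slots)
  dplyr::arrange(long, .data$episode_id, .data$slot_rank)
}

#' Flag cancer-related hospitalizations
#'
#' A hospital episode carries up to six diagnosis and six procedure codes; it
#' is cancer-related if at least one of them belongs to the D-list (procedure
#' slots matched against procedure entries, diagnosis slots against diagnosis
#' entries). All matches are returned in slot order (procedures main to
#' secondary, then diagnoses main to secondary).
#'
#' @param hd HD episode tibble (see [read_events()]).
#' @param dlist a `codelist`.
#' @return `hd` with added columns `cancer_related` (logical) and
#'   `matched_codes` (list of character vectors in slot order).
#' @export
flag_hospitalizations <- function(hd, dlist) {
  hd <- validate_hd(hd)
  long <- hd_code_slots(hd)
  long$hit <- is_cancer_related(long$code, "HD", dlist, system = long$system)
  matches <- long %>%
    dplyr::filter(.data$hit) %>%
    dplyr::group_by(.data$episode_id) %>%
    dplyr::summarise(matched_codes = list(.data$code), .groups = "drop")
  hd$matched_codes <- rep(list(character(0)), nrow(hd))
  idx <- match(matches$episode_id, hd$episode_id)
  hd$matched_codes[idx] <- matches$matched_codes
  hd$cancer_related <- lengths(hd$matched_codes) > 0
  hd
}

## Category priority used by the alternative classification rule.
cp_category_priority <- c(
  "Surgery", "Chemotherapy", "Radiotherapy", "Biologic therapy",
  "Hormone therapy", "Diagnosis and monitoring", "Support therapy",
  "Transfusion"
)

#' Classify cancer-related hospitalizations into a single category
#'
#' Each cancer-related hospitalization is classified according to its main
#' cancer-related intervention/procedure: the default rule takes the first
#' D-list match in slot order (procedure slots main to secondary, then
#' diagnosis slots main to secondary), reflecting that slot 1 is the "main"
#' code in discharge abstracts and procedures define the episode when
#' present. An alternative `"category_priority"` rule (Surgery >
#' Chemotherapy > Radiotherapy > ...) is available for sensitivity analysis.
#'
#' @param hd HD episode tibble.
#' @param dlist a `codelist`.
#' @param rule `"slot_order"` (default) or `"category_priority"`.
#' @return a tibble with one row per cancer-related episode: `episode_id`,
#'   `pid`, `admission_date`, `matched_code`, `category`, `subcategory`.
#'   Non-cancer-related episodes contribute no row.
#' @export
classify_hospitalizations <- function(hd, dlist, rule = c("slot_order", "category_priority")) {
  rule <- match.arg(rule)
  long <- hd_code_slots(hd)
  long$hit <- is_cancer_related(long$code, "HD", dlist, system = long$system)
  long <- dplyr::filter(long, .data$hit)
  long$code_norm <- normalize_code(long$code, "HD")
  meta <- dlist %>%
    dplyr::filter(.data$stream == "HD") %>%
    dplyr::select("code_norm", "system", "category", "subcategory")
  long <- dplyr::left_join(long, meta, by = c("code_norm", "system"))
  if (rule == "category_priority") {
    long$cat_rank <- match(long$category, cp_category_priority)
    long$cat_rank[is.na(long$cat_rank)] <- length(cp_category_priority) + 1L
    long <- dplyr::arrange(long, .data$episode_id, .data$cat_rank, .data$slot_rank)
  }
  long %>%
    dplyr::group_by(.data$episode_id) %>%
    dplyr::slice(1) %>%
    dplyr::ungroup() %>%
    dplyr::transmute(
      episode_id = .data$episode_id,
      pid = .data$pid,
      admission_date = .data$admission_date,
      matched_code = .data$code,
      category = .data$category,
      subcategory = .data$subcategory
    )
}

#' Collect all streams into one flagged event table
#'
#' Normalizes the four administrative tables into a single long table of
#' candidate events with a `cancer_related` flag and, where matched, the
#' D-list category. Hospital episodes are reduced to one row per episode
#' anchored on the admission date (an episode straddling a window boundary
#' belongs to the window containing its admission) and carrying the category
#' of the main cancer-related code; outpatient and drug records contribute
#' one row each.
#'
#' @param dlist a `codelist`.
#' @param hd,ops,dp,hp the four stream tibbles; any may be `NULL`.
#' @param rule classification rule for hospitalizations, see
#'   [classify_hospitalizations()].
#' @return tibble with `pid`, `stream`, `date`, `code`, `cancer_related`,
#'   `category`, `subcategory`, `excluded_from_frequency`.
#' @export
collect_events <- function(dlist, hd = NULL, ops = NULL, dp = NULL, hp = NULL,
                           rule = "slot_order") {
  pieces <- list()

  if (!is.null(hd) && nrow(hd) > 0) {
    hd <- validate_hd(hd)
    cls <- classify_hospitalizations(hd, dlist, rule = rule)
    hd_rows <- tibble::tibble(
      pid = hd$pid,
      stream = "HD",
      date = hd$admission_date,
      code = NA_character_,
      cancer_related = FALSE,
      category = NA_character_,
      subcategory = NA_character_,
      excluded_from_frequency = FALSE
    )
    idx <- match(cls$episode_id, hd$episode_id)
    hd_rows$code[idx] <- cls$matched_code
    hd_rows$cancer_related[idx] <- TRUE
    hd_rows$category[idx] <- cls$category
    hd_rows$subcategory[idx] <- cls$subcategory
    pieces$hd <- hd_rows
  }

  flat_stream <- function(tbl, stream, code_col) {
    tbl <- tibble::as_tibble(tbl)
    meta <- dlist %>%
      dplyr::filter(.data$stream == !!stream) %>%
      dplyr::select("code_norm", "category", "subcategory", "excluded_from_frequency")
    out <- tibble::tibble(
      pid = tbl$pid,
      stream = stream,
      date = tbl$date,
      code = as.character(tbl[[code_col]])
    )
    out$code_norm <- normalize_code(out$code, stream)
    out <- dplyr::left_join(out, meta, by = "code_norm")
    out$cancer_related <- !is.na(out$category)
    out$excluded_from_frequency <- out$excluded_from_frequency %in% TRUE
    dplyr::select(out, "pid", "stream", "date", "code", "cancer_related",
                  "category", "subcategory", "excluded_from_frequency")
  }

  if (!is.null(ops) && nrow(ops) > 0) pieces$ops <- flat_stream(ops, "OPS", "code")
  if (!is.null(dp) && nrow(dp) > 0) pieces$dp <- flat_stream(dp, "DP", "atc")
  if (!is.null(hp) && nrow(hp) > 0) pieces$hp <- flat_stream(hp, "HP", "atc")

  if (length(pieces) == 0) {
    return(tibble::tibble(
      pid = character(), stream = character(), date = as.Date(character()),
      code = character(), cancer_related = logical(), category = character(),
      subcategory = character(), excluded_from_frequency = logical()
    ))
  }
  dplyr::bind_rows(pieces)
}

#' Attribute cancer-related events to phases of care
#'
#' Restricts the flagged event table to cancer-related events falling inside
#' the owning patient's 12-month observation window (half-open: an event on
#' the window start is in, one on the window end is out) and tags each with
#' the patient's phase. Censored patients have no window, so none of their
#' events are retained; events of patients absent from the assignment table
#' are likewise dropped.
#'
#' @param events output of [collect_events()].
#' @param assignments output of [assign_phases()].
#' @return tibble of attributed events: `pid`, `stream`, `date`, `code`,
#'   `category`, `subcategory`, `excluded_from_frequency`, `phase`.
#' @export
attribute_events <- function(events, assignments) {
  events <- tibble::as_tibble(events)
  joined <- dplyr::inner_join(
    dplyr::filter(events, .data$cancer_related),
    dplyr::select(assignments, "pid", "phase", "window_start", "window_end"),
    by = "pid"
  )
  joined %>%
    dplyr::filter(
      .data$phase != "censored",
      in_window(.data$date, .data$window_start, .data$window_end)
    ) %>%
    dplyr::mutate(phase = factor(as.character(.data$phase), levels = cp_phases)) %>%
    dplyr::select("pid", "stream", "date", "code", "category", "subcategory",
                  "excluded_from_frequency", "phase")
}
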