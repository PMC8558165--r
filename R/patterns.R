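#' Within-phase percentage table from pre-aggregated counts
#'
#' Computes the within-phase percent distribution of a counts table shaped
#' like the published frequency tables: one row per category (with
#' `subcategory = NA`) and optionally one row per sub-category nested under
#' it. Phase totals are the sums of the category-level rows; every percent is
#' `100 * n / phase_total`, computed in full precision and rounded half away
#' from zero to `digits` decimals. A phase with zero total reports 0.0
#' percents and is flagged in the `empty_phases` attribute.
#'
#' @param counts tibble with columns `category`, `subcategory` (NA for the
#'   category-level row), `n_initial`, `n_continuing`, `n_final`.
#' @param digits decimals for the percentages.
#' @return a `care_freqtab` tibble with added `pct_initial`, `pct_continuing`,
#'   `pct_final` columns; phase totals in the `phase_totals` attribute.
#' @export
frequency_table <- function(counts, digits = 1) {
  counts <- tibble::as_tibble(counts)
  check_columns(counts, c("category", "n_initial", "n_continuing", "n_final"),
                "counts table")
  if (!"subcategory" %in% names(counts)) counts$subcategory <- NA_character_
  counts$subcategory[!is.na(counts$subcategory) & counts$subcategory == ""] <- NA_character_

  cat_rows <- is.na(counts$subcategory)
  totals <- vapply(
    c("n_initial", "n_continuing", "n_final"),
    function(cl) sum(counts[[cl]][cat_rows]),
    numeric(1)
  )
  names(totals) <- cp_phases
  empty <- names(totals)[totals == 0]
  if (length(empty) > 0) {
    warn(paste0("phase(s) with zero events: ", paste(empty, collapse = ", "),
                "; percents reported as 0"))
  }

  pct <- function(n, tot) if (tot > 0) round_half_up(100 * n / tot, digits) else 0
  counts$pct_initial <- pct(counts$n_initial, totals[["initial"]])
  counts$pct_continuing <- pct(counts$n_continuing, totals[["continuing"]])
  counts$pct_final <- pct(counts$n_final, totals[["final"]])

  class(counts) <- c("care_freqtab", class(counts))
  attr(counts, "phase_totals") <- totals
  attr(counts, "empty_phases") <- empty
  counts
}

#' Phase-stratified frequency table of attributed events
#'
#' Tabulates attributed events of one stream into the published table layout:
#' absolute counts and within-phase percent distribution by clinical category
#' (and sub-category, except for pharmacy prescriptions which carry
#' categories only). Outpatient codes flagged `excluded_from_frequency`
#' (standard blood tests, genetic markers) belong to the list but are left
#' out of the tabulation, since their one-record-per-test granularity would
#' swamp the distribution. The hospital-pharmacy stream is qualitative only
#' and cannot be tabulated.
#'
#' @param events attributed events from [attribute_events()].
#' @param stream one of `"HD"`, `"OPS"`, `"DP"`.
#' @param subcategories include sub-category rows (default: all streams but
#'   `DP`).
#' @param digits decimals for the percentages.
#' @return a `care_freqtab` tibble (see [frequency_table()]).
#' @export
tabulate_patterns <- function(events, stream = c("HD", "OPS", "DP"),
                              subcategories = NULL, digits = 1) {
  stream <- match.arg(stream)
  if (is.null(subcategories)) subcategories <- stream != "DP"
  ev <- events %>%
    dplyr::filter(.data$stream == !!stream, !.data$excluded_from_frequency)

  count_phase <- function(grouped) {
    grouped %>%
      dplyr::count(.data$phase, .drop = FALSE) %>%
      tidyr::pivot_wider(
        names_from = "phase", values_from = "n",
        names_prefix = "n_", values_fill = 0
      )
  }

  cat_counts <- ev %>%
    dplyr::group_by(.data$category) %>%
    count_phase() %>%
    dplyr::mutate(subcategory = NA_character_)

  if (subcategories) {
    sub_counts <- ev %>%
      dplyr::filter(!is.na(.data$subcategory)) %>%
      dplyr::group_by(.data$category, .data$subcategory) %>%
      count_phase()
    counts <- dplyr::bind_rows(cat_counts, sub_counts)
  } else {
    counts <- cat_counts
  }

  counts <- counts %>%
    dplyr::arrange(.data$category, !is.na(.data$subcategory), .data$subcategory) %>%
    dplyr::select("category", "subcategory", "n_initial", "n_continuing", "n_final")
  out <- frequency_table(counts, digits = digits)
  attr(out, "stream") <- stream
  out
}

#' Most frequent codes by phase of care
#'
#' Ranks the individual cancer-related codes of one stream within each phase,
#' with percentages computed over the total of cancer-related events of that
#' stream and phase. Ties in count are broken lexicographically by code.
#'
#' @param events attributed events from [attribute_events()].
#' @param stream one of `"HD"`, `"OPS"`, `"DP"`.
#' @param phase optional single phase; default ranks all three.
#' @param k number of top codes per phase.
#' @param digits decimals for the percentage.
#' @return tibble with `phase`, `rank`, `code`, `n`, `pct`.
#' @export
top_codes <- function(events, stream = c("HD", "OPS", "DP"), phase = NULL, k = 10,
                      digits = 1) {
  stream <- match.arg(stream)
  stopifnot(k >= 1)
  ev <- dplyr::filter(events, .data$stream == !!stream)
  if (!is.null(phase)) {
    ev <- dplyr::filter(ev, .data$phase %in% !!phase)
  }
  if (nrow(ev) == 0) {
    return(tibble::tibble(phase = factor(character(), levels = cp_phases),
                          rank = integer(), code = character(),
                          n = integer(), pct = numeric()))
  }
  ev %>%
    dplyr::count(.data$phase, .data$code, name = "n") %>%
    dplyr::group_by(.data$phase) %>%
    dplyr::mutate(pct = round_half_up(100 * .data$n / sum(.data$n), digits)) %>%
    dplyr::arrange(dplyr::desc(.data$n), .data$code, .by_group = TRUE) %>%
    dplyr::slice(seq_len(min(k, dplyr::n()))) %>%
    dplyr::mutate(rank = dplyr::row_number()) %>%
    dplyr::ungroup() %>%
    dplyr::select("phase", "rank", "code", "n", "pct")
}

#' Phase-weighted distribution of a category across phases of care
#'
#' The raw within-phase counts are dominated by the continuing phase simply
#' because most prevalent patients are in it. To compare phases on an equal
#' footing, each category's count is first converted into a per-patient rate
#' (count divided by the number of cohort patients in that phase) and the
#' three rates are then normalized to sum to 100%. This weighting by the
#' patient distribution answers "in which phase is this care concentrated,
#' per patient at risk?".
#'
#' @param counts tibble with columns `category`, `n_initial`, `n_continuing`,
#'   `n_final` (category-level rows; rows with a non-missing `subcategory`
#'   column are dropped).
#' @param cohort_sizes numeric vector of patients per phase, named
#'   `initial`, `continuing`, `final`; all positive.
#' @return tibble with `category`, `share_initial`, `share_continuing`,
#'   `share_final` in percent (full precision; shares sum to 100). Categories
#'   with zero counts in every phase get `NA` shares and a warning.
#' @export
#' @examples
#' phase_weighted_distribution(
#'   tibble::tibble(category = "Surgery", n_initial = 8021,
#'                  n_continuing = 2560, n_final = 93),
#'   c(initial = 7501, continuing = 39369, final = 2400)
#' )
phase_weighted_distribution <- function(counts, cohort_sizes) {
  counts <- tibble::as_tibble(counts)
  check_columns(counts, c("category", "n_initial", "n_continuing", "n_final"),
                "counts table")
  if ("subcategory" %in% names(counts)) {
    counts <- dplyr::filter(counts, is.na(.data$subcategory) | .data$subcategory == "")
  }
  if (!all(cp_phases %in% names(cohort_sizes))) {
    abort("cohort_sizes must be named initial, continuing, final")
  }
  if (any(cohort_sizes[cp_phases] <= 0)) {
    abort("cohort sizes must be positive")
  }

  rate <- cbind(
    counts$n_initial / cohort_sizes[["initial"]],
    counts$n_continuing / cohort_sizes[["continuing"]],
    counts$n_final / cohort_sizes[["final"]]
  )
  tot <- rowSums(rate)
  zero <- tot == 0
  if (any(zero)) {
    warn(paste0("categories with zero events in all phases: ",
                paste(counts$category[zero], collapse = ", ")))
    tot[zero] <- NA_real_
  }
  share <- 100 * rate / tot

  tibble::tibble(
    category = counts$category,
    share_initial = share[, 1],
    share_continuing = share[, 2],
    share_final = share[, 3]
  )
}

#' Write a frequency table as CSV
#'
#' Mirrors the published table columns:
#' `category,subcategory,N_initial,pct_initial,N_continuing,pct_continuing,N_final,pct_final`,
#' followed by a `Total` row.
#'
#' @param x a `care_freqtab`.
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_freqtab <- function(x, path) {
  totals <- attr(x, "phase_totals")
  out <- tibble::as_tibble(x) %>%
    dplyr::transmute(
      category = .data$category,
      subcategory = .data$subcategory,
      N_initial = .data$n_initial, pct_initial = .data$pct_initial,
      N_continuing = .data$n_continuing, pct_continuing = .data$pct_continuing,
      N_final = .data$n_final, pct_final = .data$pct_final
    )
  total_row <- tibble::tibble(
    category = "Total", subcategory = NA_character_,
    N_initial = totals[["initial"]], pct_initial = if (totals[["initial"]] > 0) 100 else 0,
    N_continuing = totals[["continuing"]], pct_continuing = if (totals[["continuing"]] > 0) 100 else 0,
    N_final = totals[["final"]], pct_final = if (totals[["final"]] > 0) 100 else 0
  )
  readr::write_csv(dplyr::bind_rows(out, total_row), path, na = "")
  invisible(path)
}
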