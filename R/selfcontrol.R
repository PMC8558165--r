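#' Pre/post diagnosis windows for the self-control validation
#'
#' The code lists are validated against the same patients' own pre-diagnostic
#' care: each patient recently diagnosed contributes a 10-month case window
#' starting at diagnosis and a 10-month control window running from 12 to 2
#' months before diagnosis. The 2 months immediately before diagnosis are
#' left out of both windows, because pre-diagnostic work-up in that period is
#' already cancer-related and would bias the contrast. Both windows are
#' half-open.
#'
#' @param patients patient tibble (typically the self-control subcohort, see
#'   [self_control_subcohort()]).
#' @return tibble with `pid`, `control_start`, `control_end`, `case_start`,
#'   `case_end`.
#' @export
#' @examples
#' p <- tibble::tibble(pid = "a", diagnosis_date = as.Date("2010-06-15"),
#'                     vital_status = "ALIVE")
#' self_control_windows(p)
self_control_windows <- function(patients) {
  patients <- tibble::as_tibble(patients)
  check_columns(patients, c("pid", "diagnosis_date"), "patient table")
  tibble::tibble(
    pid = patients$pid,
    control_start = add_months(patients$diagnosis_date, -12),
    control_end = add_months(patients$diagnosis_date, -2),
    case_start = patients$diagnosis_date,
    case_end = add_months(patients$diagnosis_date, 10)
  )
}

#' Select the self-control subcohort
#'
#' Patients usable as their own controls are those in the initial phase,
#' i.e. diagnosed within 12 months before the prevalence date: for them the
#' administrative data also cover the pre-diagnostic year.
#'
#' @param patients patient tibble.
#' @param prevalence_date the index date.
#' @return the subset of `patients` assigned to the initial phase.
#' @export
self_control_subcohort <- function(patients, prevalence_date) {
  a <- assign_phases(patients, prevalence_date)
  dplyr::semi_join(
    tibble::as_tibble(patients),
    dplyr::filter(a, .data$phase == "initial"),
    by = "pid"
  )
}

#' Per-patient occurrence counts of each code in case and control windows
#'
#' For every candidate (code, stream) pair, counts the occurrences per
#' patient inside the case (post-diagnosis) and control (pre-diagnosis)
#' windows. Patients with no occurrences contribute explicit zeros, so both
#' samples always have one count per subcohort patient.
#'
#' @param events long event tibble with `pid`, `stream`, `date`, `code` (one
#'   row per code occurrence; see [events_long()] for hospital episodes).
#' @param windows output of [self_control_windows()].
#' @param candidates tibble with `code`, `stream` (one row per candidate).
#' @return nested tibble with `code`, `stream`, `case_counts`,
#'   `control_counts` (integer vectors of length `nrow(windows)`),
#'   `n_case`, `n_control`.
#' @export
self_control_counts <- function(events, windows, candidates) {
  events <- tibble::as_tibble(events)
  candidates <- dplyr::distinct(tibble::as_tibble(candidates), .data$code, .data$stream)
  candidates$code_norm <- normalize_code(candidates$code, candidates$stream)

  ev <- dplyr::inner_join(events, windows, by = "pid")
  ev$code_norm <- normalize_code(ev$code, ev$stream)
  ev <- dplyr::semi_join(ev, candidates, by = c("code_norm", "stream"))
  ev$in_case <- in_window(ev$date, ev$case_start, ev$case_end)
  ev$in_control <- in_window(ev$date, ev$control_start, ev$control_end)

  per_patient <- ev %>%
    dplyr::group_by(.data$code_norm, .data$stream, .data$pid) %>%
    dplyr::summarise(
      case = sum(.data$in_case),
      control = sum(.data$in_control),
      .groups = "drop"
    )

  pids <- windows$pid
  n <- length(pids)
  counts_for <- function(cn, st) {
    rows <- per_patient[per_patient$code_norm == cn & per_patient$stream == st, ]
    case <- integer(n)
    control <- integer(n)
    idx <- match(rows$pid, pids)
    case[idx] <- rows$case
    control[idx] <- rows$control
    list(case = case, control = control)
  }
  got <- purrr::map2(candidates$code_norm, candidates$stream, counts_for)

  tibble::tibble(
    code = candidates$code,
    stream = candidates$stream,
    case_counts = purrr::map(got, "case"),
    control_counts = purrr::map(got, "control"),
    n_case = n,
    n_control = n
  )
}

#' Welch two-sample t-test with Satterthwaite degrees of freedom
#'
#' The unequal-variance two-sample t-test used to compare average per-patient
#' occurrences between case and control windows:
#' `t = (mean(x) - mean(y)) / sqrt(sx2/nx + sy2/ny)` with the Satterthwaite
#' approximation for the degrees of freedom, and a two-sided p-value from the
#' t distribution. Degenerate inputs follow deterministic conventions: if
#' both samples are constant, `p = 1` when the means are equal and `p = 0`
#' when they differ (the statistic itself is undefined); samples of fewer
#' than two observations yield an insufficient-data result with `NA`
#' statistics.
#'
#' @param x,y numeric vectors (per-patient counts for cases and controls).
#' @return one-row tibble with `mean_x`, `mean_y`, `t`, `df`, `p_value`,
#'   `reason` (NA, `"zero variance"` or `"insufficient data"`).
#' @export
#' @examples
#' welch_t_test(c(1, 2, 3, 4, 5), c(2, 3, 4, 5, 6))
welch_t_test <- function(x, y) {
  nx <- length(x)
  ny <- length(y)
  res <- function(mx, my, t, df, p, reason = NA_character_) {
    tibble::tibble(mean_x = mx, mean_y = my, t = t, df = df,
                   p_value = p, reason = reason)
  }
  if (nx < 2 || ny < 2) {
    return(res(if (nx > 0) mean(x) else NA_real_,
               if (ny > 0) mean(y) else NA_real_,
               NA_real_, NA_real_, NA_real_, "insufficient data"))
  }
  mx <- mean(x)
  my <- mean(y)
  vx <- var(x)
  vy <- var(y)
  if (vx == 0 && vy == 0) {
    return(res(mx, my, NA_real_, NA_real_,
               if (mx == my) 1 else 0, "zero variance"))
  }
  se2 <- vx / nx + vy / ny
  t <- (mx - my) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  p <- 2 * pt(-abs(t), df)
  res(mx, my, t, df, p)
}

#' Derive the empirical C-list by the self-control method
#'
#' Runs the Welch-Satterthwaite test on every candidate code's per-patient
#' case vs control occurrence counts and includes in the C-list the codes
#' whose post-diagnosis mean occurrence is significantly different at
#' `alpha`. By default inclusion additionally requires the case mean to
#' exceed the control mean (`direction = "greater"`), so that codes
#' suppressed after diagnosis are not admitted as cancer-related; the pure
#' two-sided rule is available with `direction = "two.sided"` (the
#' significance threshold itself is always the two-sided p-value).
#'
#' @param counts output of [self_control_counts()].
#' @param dlist optional `codelist` supplying system/category metadata for
#'   included codes; candidates absent from it are labelled
#'   `"Empirically identified"`.
#' @param alpha significance level (default 0.05, uncorrected: the audit
#'   table carries all p-values so users can apply multiplicity corrections
#'   downstream).
#' @param direction `"greater"` (default) or `"two.sided"`.
#' @return an object of class `clist_fit`: a list with `clist` (a
#'   [as_codelist()] tibble of included codes) and `audit` (per-code test
#'   table with `code`, `stream`, `n`, `mean_case`, `mean_control`, `t`,
#'   `df`, `p_value`, `included`, `reason`). [tidy()] returns the audit
#'   table, [glance()] a one-row summary.
#' @export
derive_clist <- function(counts, dlist = NULL, alpha = 0.05,
                         direction = c("greater", "two.sided")) {
  direction <- match.arg(direction)
  tests <- purrr::map2(counts$case_counts, counts$control_counts, welch_t_test)
  audit <- dplyr::bind_rows(tests)
  audit <- tibble::tibble(
    code = counts$code,
    stream = counts$stream,
    n = counts$n_case,
    mean_case = audit$mean_x,
    mean_control = audit$mean_y,
    t = audit$t,
    df = audit$df,
    p_value = audit$p_value,
    reason = audit$reason
  )
  sig <- !is.na(audit$p_value) & audit$p_value < alpha
  if (direction == "greater") {
    sig <- sig & audit$mean_case > audit$mean_control
  }
  audit$included <- sig

  inc <- audit[audit$included, c("code", "stream")]
  if (!is.null(dlist)) {
    meta <- dlist %>%
      tibble::as_tibble() %>%
      dplyr::mutate(code_norm = .data$code_norm) %>%
      dplyr::select("code_norm", "stream", "system", "category", "subcategory")
    inc$code_norm <- normalize_code(inc$code, inc$stream)
    inc <- dplyr::left_join(inc, meta, by = c("code_norm", "stream"))
    inc$code_norm <- NULL
  } else {
    inc$system <- NA_character_
    inc$category <- NA_character_
    inc$subcategory <- NA_character_
  }
  inc$system <- dplyr::coalesce(
    inc$system,
    dplyr::case_when(
      inc$stream %in% c("DP", "HP") ~ "ATC",
      inc$stream == "OPS" ~ "OUTPATIENT_NATIONAL",
      TRUE ~ "ICD9CM_PROC"
    )
  )
  inc$category <- dplyr::coalesce(inc$category, "Empirically identified")

  clist <- as_codelist(inc, label = "C-list")
  structure(
    list(clist = clist, audit = audit, alpha = alpha, direction = direction),
    class = "clist_fit"
  )
}

#' @export
print.clist_fit <- function(x, ...) {
  cat("Self-control C-list fit: ", sum(x$audit$included), " of ",
      nrow(x$audit), " candidate codes included (alpha = ", x$alpha,
      ", direction = ", x$direction, ")\n", sep = "")
  invisible(x)
}

#' @rdname derive_clist
#' @param x a `clist_fit`.
#' @param ... unused.
#' @export
#' @method tidy clist_fit
tidy.clist_fit <- function(x, ...) {
  x$audit
}

#' @rdname derive_clist
#' @export
#' @method glance clist_fit
glance.clist_fit <- function(x, ...) {
  tibble::tibble(
    n_candidates = nrow(x$audit),
    n_included = sum(x$audit$included),
    alpha = x$alpha,
    direction = x$direction
  )
}

#' Occurrence-weighted concordance between D-list and C-list
#'
#' Agreement between the clinician-drawn D-list and the empirically derived
#' C-list, per stream: the unweighted ratio `|D intersect C| / |D|` and the
#' occurrence-weighted ratio `sum(w_c, c in D intersect C) / sum(w_c, c in D)`,
#' where each code's weight is its number of occurrences (by default counted
#' over the case windows of the self-control subcohort; any nonnegative
#' weight table may be supplied). D-list codes with no occurrences carry zero
#' weight: they cannot be confirmed or contradicted by the data, so they do
#' not move the weighted ratio.
#'
#' @param dlist a `codelist` (the reference list).
#' @param clist a `codelist` (the derived list).
#' @param weights tibble with `code`, `stream`, `weight`; codes missing from
#'   it get weight 0.
#' @return tibble with one row per stream present in `dlist` plus an
#'   `"overall"` row: `stream`, `n_d`, `n_both`, `ratio_unweighted`,
#'   `weight_d`, `weight_both`, `ratio_weighted`. Streams with zero total
#'   weight report `NA` weighted ratio with a warning.
#' @export
weighted_concordance <- function(dlist, clist, weights) {
  weights <- tibble::as_tibble(weights)
  check_columns(weights, c("code", "stream", "weight"), "weights table")
  if (any(weights$weight < 0)) abort("weights must be nonnegative")
  weights$code_norm <- normalize_code(weights$code, weights$stream)

  d <- tibble::as_tibble(dlist)[, c("code_norm", "stream")]
  ckey <- paste(clist$code_norm, clist$stream)
  d$in_c <- paste(d$code_norm, d$stream) %in% ckey
  d <- dplyr::left_join(d, weights[, c("code_norm", "stream", "weight")],
                        by = c("code_norm", "stream"))
  d$weight <- dplyr::coalesce(d$weight, 0)

  one <- function(rows, label) {
    wd <- sum(rows$weight)
    tibble::tibble(
      stream = label,
      n_d = nrow(rows),
      n_both = sum(rows$in_c),
      ratio_unweighted = if (nrow(rows) > 0) sum(rows$in_c) / nrow(rows) else NA_real_,
      weight_d = wd,
      weight_both = sum(rows$weight[rows$in_c]),
      ratio_weighted = if (wd > 0) sum(rows$weight[rows$in_c]) / wd else NA_real_
    )
  }
  per_stream <- d %>%
    dplyr::group_by(.data$stream) %>%
    dplyr::group_map(~ one(.x, .y$stream)) %>%
    dplyr::bind_rows()
  out <- dplyr::bind_rows(per_stream, one(d, "overall"))
  if (any(out$weight_d == 0)) {
    warn(paste0("zero total occurrence weight for: ",
                paste(out$stream[out$weight_d == 0], collapse = ", "),
                "; weighted ratio undefined"))
  }
  out
}

#' Occurrence weights from case windows
#'
#' Total occurrences of each code over the case (post-diagnosis) windows of
#' the self-control subcohort, the default weighting for
#' [weighted_concordance()]. Set `whole_cohort = TRUE` to weight by all
#' occurrences in the event table instead.
#'
#' @param events long event tibble (`pid`, `stream`, `date`, `code`).
#' @param windows output of [self_control_windows()].
#' @param whole_cohort logical; ignore windows and count all occurrences.
#' @return tibble with `code`, `stream`, `weight`.
#' @export
case_occurrence_weights <- function(events, windows, whole_cohort = FALSE) {
  events <- tibble::as_tibble(events)
  if (!whole_cohort) {
    events <- dplyr::inner_join(events, windows, by = "pid")
    events <- dplyr::filter(events, in_window(.data$date, .data$case_start, .data$case_end))
  }
  events %>%
    dplyr::count(.data$code, .data$stream, name = "weight") %>%
    dplyr::select("code", "stream", "weight")
}

#' Flatten stream tables into one long code-occurrence table
#'
#' Hospital episodes contribute one row per populated diagnosis/procedure
#' slot (the self-control method compares per-code occurrences, not
#' per-episode ones); outpatient and drug tables contribute one row per
#' record.
#'
#' @param hd,ops,dp,hp stream tibbles; any may be `NULL`.
#' @return tibble with `pid`, `stream`, `date`, `code`, `system`.
#' @export
events_long <- function(hd = NULL, ops = NULL, dp = NULL, hp = NULL) {
  pieces <- list()
  if (!is.null(hd) && nrow(hd) > 0) {
    slots <- hd_code_slots(hd)
    pieces$hd <- tibble::tibble(
      pid = slots$pid, stream = "HD", date = slots$admission_date,
      code = slots$code, system = slots$system
    )
  }
  if (!is.null(ops) && nrow(ops) > 0) {
    pieces$ops <- tibble::tibble(
      pid = ops$pid, stream = "OPS", date = ops$date,
      code = as.character(ops$code), system = "OUTPATIENT_NATIONAL"
    )
  }
  if (!is.null(dp) && nrow(dp) > 0) {
    pieces$dp <- tibble::tibble(
      pid = dp$pid, stream = "DP", date = dp$date,
      code = as.character(dp$atc), system = "ATC"
    )
  }
  if (!is.null(hp) && nrow(hp) > 0) {
    pieces$hp <- tibble::tibble(
      pid = hp$pid, stream = "HP", date = hp$date,
      code = as.character(hp$atc), system = "ATC"
    )
  }
  if (length(pieces) == 0) {
    return(tibble::tibble(pid = character(), stream = character(),
                          date = as.Date(character()), code = character(),
                          system = character()))
  }
  dplyr::bind_rows(pieces)
}
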