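#' Demo code intensity table
#'
#' The event-rate table driving the demo simulation profile: one row per
#' code with its stream, coding-system metadata and piecewise-constant
#' Poisson intensities in events per patient-year. `lambda0` is the
#' background rate of non-cancer care (active before diagnosis and, added to
#' the phase excess, after it); `lambda_initial` / `lambda_continuing` /
#' `lambda_final` are the cancer-related excess rates in the corresponding
#' period of the disease course. Codes with a positive excess in any phase
#' are the planted cancer-related codes (10 of them, excesses 0.8-3.0);
#' codes with only background intensity are nulls that the self-control
#' validation must reject (20 of them, including one list member flagged
#' `excluded_from_frequency`, emulating high-volume standard blood tests).
#'
#' @return a tibble, one row per simulated code.
#' @export
demo_code_intensities <- function() {
  tribble_cols <- c("code", "stream", "system", "category", "subcategory",
                    "lambda_initial", "lambda_continuing", "lambda_final", "lambda0")
  rows <- list(
    ## planted cancer-related codes
    list("85.21", "HD", "ICD9CM_PROC", "Surgery", "Lumpectomy", 1.2, 0.05, 0.02, 0),
    list("99.25", "HD", "ICD9CM_PROC", "Chemotherapy", NA, 1.5, 0.3, 1.2, 0),
    list("92.29", "HD", "ICD9CM_PROC", "Radiotherapy", NA, 0.8, 0.05, 0.8, 0),
    list("89.52", "OPS", "OUTPATIENT_NATIONAL", "Diagnosis and monitoring", "Cardiologic assessment", 1.0, 0.5, 1.5, 0.5),
    list("87.37.1", "OPS", "OUTPATIENT_NATIONAL", "Diagnosis and monitoring", "High diagnostic", 2.0, 1.0, 0.8, 0.3),
    list("89.01", "OPS", "OUTPATIENT_NATIONAL", "Diagnosis and monitoring", "Specialist examination", 3.0, 2.0, 2.5, 1.0),
    list("92.24.1", "OPS", "OUTPATIENT_NATIONAL", "Radiotherapy", NA, 2.5, 0.1, 0.5, 0),
    list("L02BA01", "DP", "ATC", "Hormone therapy", NA, 3.0, 2.5, 0.5, 0),
    list("N02AB03", "DP", "ATC", "Analgesic", NA, 0.8, 0.3, 3.0, 0.1),
    list("H02AB02", "DP", "ATC", "Cortisone", NA, 1.0, 0.5, 2.5, 0.2),
    ## null codes: background-only care, not cancer-related
    list("401.9", "HD", "ICD9CM_DIAG", "null", NA, 0, 0, 0, 0.30),
    list("250.00", "HD", "ICD9CM_DIAG", "null", NA, 0, 0, 0, 0.20),
    list("715.9", "HD", "ICD9CM_DIAG", "null", NA, 0, 0, 0, 0.15),
    list("530.81", "HD", "ICD9CM_DIAG", "null", NA, 0, 0, 0, 0.10),
    list("486", "HD", "ICD9CM_DIAG", "null", NA, 0, 0, 0, 0.10),
    list("45.13", "HD", "ICD9CM_PROC", "null", NA, 0, 0, 0, 0.10),
    list("88.72", "HD", "ICD9CM_PROC", "null", NA, 0, 0, 0, 0.20),
    list("95.02", "OPS", "OUTPATIENT_NATIONAL", "null", NA, 0, 0, 0, 0.30),
    list("89.13", "OPS", "OUTPATIENT_NATIONAL", "null", NA, 0, 0, 0, 0.20),
    list("93.08", "OPS", "OUTPATIENT_NATIONAL", "null", NA, 0, 0, 0, 0.20),
    list("88.77.2", "OPS", "OUTPATIENT_NATIONAL", "null", NA, 0, 0, 0, 0.30),
    list("90.44.3", "OPS", "OUTPATIENT_NATIONAL", "null", NA, 0, 0, 0, 0.40),
    list("90.62.2", "OPS", "OUTPATIENT_NATIONAL", "null", NA, 0, 0, 0, 2.00),
    list("A02BC01", "DP", "ATC", "null", NA, 0, 0, 0, 1.50),
    list("C09AA05", "DP", "ATC", "null", NA, 0, 0, 0, 1.20),
    list("C10AA01", "DP", "ATC", "null", NA, 0, 0, 0, 0.80),
    list("J01CA04", "DP", "ATC", "null", NA, 0, 0, 0, 0.60),
    list("N05BA06", "DP", "ATC", "null", NA, 0, 0, 0, 0.40),
    list("B01AC06", "DP", "ATC", "null", NA, 0, 0, 0, 0.70),
    list("M01AE01", "DP", "ATC", "null", NA, 0, 0, 0, 0.50)
  )
  out <- purrr::map(rows, ~ stats::setNames(.x, tribble_cols)) %>%
    purrr::map(tibble::as_tibble) %>%
    dplyr::bind_rows()
  out$subcategory <- as.character(out$subcategory)
  out
}

#' Simulation configuration
#'
#' Bundles the study-design parameters of the synthetic linked dataset:
#' cohort size, diagnosis accrual window, prevalence date, post-prevalence
#' cancer-death hazard, the fraction of deaths from non-cancer causes, and
#' the per-code intensity table (see [demo_code_intensities()]). All
#' randomness flows from `seed`; a fixed config and seed reproduce the
#' dataset exactly.
#'
#' @param n_patients cohort size (prevalent patients).
#' @param seed integer RNG seed.
#' @param accrual_start,accrual_end diagnosis-date accrual window.
#' @param prevalence_date the index date.
#' @param death_rate exponential hazard (per year) of death after the
#'   prevalence date.
#' @param noncancer_death_frac fraction of deaths from non-cancer causes
#'   (these patients end up censored).
#' @param code_intensities intensity table; see [demo_code_intensities()].
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_patients = 500,
                       seed = 20110101,
                       accrual_start = "2003-01-01",
                       accrual_end = "2010-12-31",
                       prevalence_date = "2011-01-01",
                       death_rate = 0.06,
                       noncancer_death_frac = 0.15,
                       code_intensities = demo_code_intensities()) {
  if (n_patients < 1) abort("n_patients must be positive", class = "cp_config_error")
  if (death_rate < 0) abort("death_rate must be nonnegative", class = "cp_config_error")
  if (noncancer_death_frac < 0 || noncancer_death_frac > 1) {
    abort("noncancer_death_frac must be in [0, 1]", class = "cp_config_error")
  }
  ci <- tibble::as_tibble(code_intensities)
  check_columns(ci, c("code", "stream", "system", "lambda_initial",
                      "lambda_continuing", "lambda_final", "lambda0"),
                "code_intensities")
  if (any(ci$lambda_initial < 0 | ci$lambda_continuing < 0 |
            ci$lambda_final < 0 | ci$lambda0 < 0)) {
    abort("intensities must be nonnegative", class = "cp_config_error")
  }
  cfg <- list(
    n_patients = as.integer(n_patients),
    seed = as.integer(seed),
    accrual_start = as_cp_date(accrual_start, "accrual_start"),
    accrual_end = as_cp_date(accrual_end, "accrual_end"),
    prevalence_date = as_cp_date(prevalence_date, "prevalence_date"),
    death_rate = death_rate,
    noncancer_death_frac = noncancer_death_frac,
    code_intensities = ci
  )
  if (cfg$accrual_end < cfg$accrual_start || cfg$accrual_end >= cfg$prevalence_date) {
    abort("accrual window must precede the prevalence date",
          class = "cp_config_error")
  }
  class(cfg) <- "sim_config"
  cfg
}

#' Generate a synthetic prevalent cohort
#'
#' Diagnosis dates are uniform over the accrual window. Survival after the
#' prevalence date is exponential (all simulated patients are prevalent, i.e.
#' alive on that date, by construction — the memoryless residual-survival
#' draw is equivalent to rejection-sampling deaths before it). The cause of
#' death is cancer with probability `1 - noncancer_death_frac`. Deaths within
#' 12 months of the prevalence date are recorded in the registry columns
#' (`vital_status`, `death_date`); later deaths stay in the internal
#' `true_death_date` column, which the event generator uses to position the
#' end-of-life intensity period.
#'
#' @param cfg a [sim_config()].
#' @return patient tibble (registry schema plus `true_death_date`).
#' @export
simulate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  withr::with_seed(cfg$seed, {
    n <- cfg$n_patients
    span <- as.integer(cfg$accrual_end - cfg$accrual_start)
    dx <- cfg$accrual_start + floor(runif(n) * (span + 1))
    age <- pmin(pmax(rnorm(n, 62, 10), 25), 95)
    birth <- dx - round(age * 365.25)
    surv_years <- if (cfg$death_rate > 0) rexp(n, cfg$death_rate) else rep(Inf, n)
    true_death <- cfg$prevalence_date + floor(surv_years * 365.25)
    cancer_cause <- rbinom(n, 1, 1 - cfg$noncancer_death_frac) == 1

    horizon <- add_months(cfg$prevalence_date, 12)
    recorded <- is.finite(surv_years) & true_death < horizon
    tibble::tibble(
      pid = sprintf("P%05d", seq_len(n)),
      sex = "F",
      birth_date = birth,
      diagnosis_date = dx,
      topography = "C50.9",
      vital_status = ifelse(recorded, "DEAD", "ALIVE"),
      death_date = dplyr::if_else(recorded, true_death, as.Date(NA)),
      death_cause_cancer = ifelse(recorded, cancer_cause, NA),
      true_death_date = dplyr::if_else(is.finite(surv_years), true_death, as.Date(NA))
    )
  })
}

## Piecewise-constant intensity segments of one patient's simulated timeline:
## background before diagnosis, then initial / continuing / final excess
## periods. The final-phase period (last 12 months of life) takes precedence
## over initial/continuing where they overlap.
patient_segments <- function(pid, dx, true_death, sim_start, sim_end) {
  brk <- c(sim_start, dx, add_months(dx, 12), sim_end)
  if (!is.na(true_death)) {
    brk <- c(brk, add_months(true_death, -12), true_death)
  }
  brk <- sort(unique(pmin(pmax(brk, sim_start), sim_end)))
  starts <- brk[-length(brk)]
  ends <- brk[-1]
  keep <- ends > starts
  starts <- starts[keep]
  ends <- ends[keep]
  mid <- starts + as.numeric(ends - starts) / 2
  label <- rep("pre", length(starts))
  post <- mid >= dx
  label[post & mid < add_months(dx, 12)] <- "initial"
  label[post & mid >= add_months(dx, 12)] <- "continuing"
  if (!is.na(true_death)) {
    in_final <- post & mid >= add_months(true_death, -12) & mid < true_death
    label[in_final] <- "final"
  }
  tibble::tibble(pid = pid, seg_start = starts, seg_end = ends, period = label)
}

#' Generate synthetic administrative event tables
#'
#' For each patient and code, event dates are drawn from a piecewise-constant
#' Poisson process over the patient's simulated timeline (12 months before
#' diagnosis up to death or 12 months after the prevalence date): rate
#' `lambda0` before diagnosis and `lambda0 + lambda(period)` after, where the
#' period-specific excess follows the phase definitions (first year after
#' diagnosis, last year of life, the time in between). Hospital events are
#' packaged into discharge episodes with the cancer-related code in a random
#' slot of its type and unrelated distractor codes in other slots, so that
#' the multi-code attribution rule is exercised non-trivially.
#'
#' @param cfg a [sim_config()].
#' @param patients output of [simulate_cohort()].
#' @return list with tibbles `hd`, `ops`, `dp`, `hp` in the reader schemas.
#' @export
simulate_events <- function(cfg, patients) {
  stopifnot(inherits(cfg, "sim_config"))
  ci <- cfg$code_intensities
  horizon <- add_months(cfg$prevalence_date, 12)
  true_death <- if ("true_death_date" %in% names(patients)) {
    patients$true_death_date
  } else {
    patients$death_date
  }

  withr::with_seed(cfg$seed + 1L, {
    segs <- purrr::pmap(
      list(patients$pid, patients$diagnosis_date, true_death),
      function(pid, dx, dth) {
        sim_end <- if (!is.na(dth)) min(dth, horizon) else horizon
        patient_segments(pid, dx, dth, add_months(dx, -12), sim_end)
      }
    ) %>% dplyr::bind_rows()

    grid <- tidyr::crossing(segs, ci)
    lam_excess <- dplyr::case_when(
      grid$period == "initial" ~ grid$lambda_initial,
      grid$period == "continuing" ~ grid$lambda_continuing,
      grid$period == "final" ~ grid$lambda_final,
      TRUE ~ 0
    )
    len_days <- as.numeric(grid$seg_end - grid$seg_start)
    rate <- (grid$lambda0 + lam_excess) * len_days / 365.25
    grid$n_events <- rpois(nrow(grid), rate)
    grid <- grid[grid$n_events > 0,
                 c("pid", "seg_start", "seg_end", "code", "stream", "system", "n_events")]
    ev <- tidyr::uncount(grid, weights = .data$n_events)
    len <- as.numeric(ev$seg_end - ev$seg_start)
    ev$date <- ev$seg_start + floor(runif(nrow(ev)) * len)

    ops <- ev %>%
      dplyr::filter(.data$stream == "OPS") %>%
      dplyr::transmute(pid = .data$pid, date = .data$date, code = .data$code) %>%
      dplyr::arrange(.data$pid, .data$date, .data$code)
    dp <- ev %>%
      dplyr::filter(.data$stream == "DP") %>%
      dplyr::transmute(pid = .data$pid, date = .data$date, atc = .data$code) %>%
      dplyr::arrange(.data$pid, .data$date, .data$atc)
    hp <- ev %>%
      dplyr::filter(.data$stream == "HP") %>%
      dplyr::transmute(pid = .data$pid, date = .data$date, atc = .data$code) %>%
      dplyr::arrange(.data$pid, .data$date, .data$atc)

    hd_ev <- ev %>%
      dplyr::filter(.data$stream == "HD") %>%
      dplyr::arrange(.data$pid, .data$date, .data$code)
    hd <- simulate_hd_episodes(hd_ev)
    list(hd = hd, ops = ops, dp = dp, hp = hp)
  })
}

## Distractor codes used to fill unrelated HD slots; none belong to any
## cancer-related list.
cp_distractor_diag <- c("401.9", "250.00", "715.9", "530.81", "486", "272.4")
cp_distractor_proc <- c("93.94", "99.18", "38.93", "89.65")

simulate_hd_episodes <- function(hd_ev) {
  n <- nrow(hd_ev)
  empty <- tibble::tibble(
    pid = character(), admission_date = as.Date(character()),
    discharge_date = as.Date(character()),
    !!!stats::setNames(rep(list(character()), 12),
                       c(paste0("diag", 1:6), paste0("proc", 1:6))),
    drg = character()
  )
  if (n == 0) return(empty)

  slot_mat_diag <- matrix(NA_character_, nrow = n, ncol = 6)
  slot_mat_proc <- matrix(NA_character_, nrow = n, ncol = 6)
  is_proc <- hd_ev$system == "ICD9CM_PROC"
  slot <- 1L + floor(runif(n) * 6)
  for (i in seq_len(n)) {
    if (is_proc[i]) {
      slot_mat_proc[i, slot[i]] <- hd_ev$code[i]
    } else {
      slot_mat_diag[i, slot[i]] <- hd_ev$code[i]
    }
  }
  ## main diagnosis always populated; sprinkle extra distractors
  need_diag1 <- is.na(slot_mat_diag[, 1])
  slot_mat_diag[need_diag1, 1] <-
    cp_distractor_diag[1L + floor(runif(sum(need_diag1)) * length(cp_distractor_diag))]
  extra <- runif(n) < 0.4
  slot2_free <- extra & is.na(slot_mat_diag[, 2])
  slot_mat_diag[slot2_free, 2] <-
    cp_distractor_diag[1L + floor(runif(sum(slot2_free)) * length(cp_distractor_diag))]
  extra_p <- runif(n) < 0.25
  procslot_free <- extra_p & is.na(slot_mat_proc[, 2])
  slot_mat_proc[procslot_free, 2] <-
    cp_distractor_proc[1L + floor(runif(sum(procslot_free)) * length(cp_distractor_proc))]

  out <- tibble::tibble(
    pid = hd_ev$pid,
    admission_date = hd_ev$date,
    discharge_date = hd_ev$date + floor(runif(n) * 11)
  )
  for (j in 1:6) out[[paste0("diag", j)]] <- slot_mat_diag[, j]
  for (j in 1:6) out[[paste0("proc", j)]] <- slot_mat_proc[, j]
  out$drg <- sprintf("DRG%03d", 1L + floor(runif(n) * 490))
  out
}

#' Planted ground-truth code list
#'
#' The codes the simulation makes genuinely cancer-related: exactly those
#' with a positive excess intensity in any phase. This is the recovery target
#' for [derive_clist()] on simulated data.
#'
#' @param cfg a [sim_config()].
#' @return a `codelist` labelled `"planted-truth"`.
#' @export
planted_truth <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  ci <- cfg$code_intensities
  planted <- ci %>%
    dplyr::filter(.data$lambda_initial > 0 | .data$lambda_continuing > 0 |
                    .data$lambda_final > 0) %>%
    dplyr::select("code", "system", "stream", "category",
                  dplyr::any_of("subcategory"))
  as_codelist(planted, label = "planted-truth")
}

#' Simulate a full linked study dataset
#'
#' Convenience wrapper: cohort plus the four event tables.
#'
#' @param cfg a [sim_config()].
#' @return list with `patients`, `hd`, `ops`, `dp`, `hp`, `truth`.
#' @export
simulate_study <- function(cfg = sim_config()) {
  patients <- simulate_cohort(cfg)
  events <- simulate_events(cfg, patients)
  c(list(patients = patients), events, list(truth = planted_truth(cfg)))
}
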