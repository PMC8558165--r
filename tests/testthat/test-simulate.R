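test_that("simulation is deterministic under a fixed seed", {
  cfg <- sim_config(n_patients = 120, seed = 3)
  s1 <- simulate_study(cfg)
  s2 <- simulate_study(cfg)
  expect_identical(s1$patients, s2$patients)
  expect_identical(s1$hd, s2$hd)
  expect_identical(s1$ops, s2$ops)
  expect_identical(s1$dp, s2$dp)
  # a different seed moves the data
  s3 <- simulate_cohort(sim_config(n_patients = 120, seed = 4))
  expect_false(identical(s1$patients$diagnosis_date, s3$diagnosis_date))
})

test_that("cohort generation respects the configured design", {
  cfg <- sim_config(n_patients = 400, seed = 5)
  pats <- simulate_cohort(cfg)
  expect_equal(nrow(pats), 400)
  expect_true(all(pats$diagnosis_date >= cfg$accrual_start &
                    pats$diagnosis_date <= cfg$accrual_end))
  # everyone is prevalent: no recorded death before the prevalence date
  expect_true(all(is.na(pats$death_date) | pats$death_date >= cfg$prevalence_date))

  # zero non-cancer-death fraction -> no censored patients downstream
  cfg0 <- sim_config(n_patients = 200, seed = 6, noncancer_death_frac = 0)
  a0 <- assign_phases(simulate_cohort(cfg0), cfg0$prevalence_date)
  expect_equal(sum(a0$phase == "censored"), 0)

  # accrual limited to the final pre-prevalence year forbids the continuing phase
  cfg1 <- sim_config(n_patients = 150, seed = 7,
                     accrual_start = "2010-01-01", accrual_end = "2010-12-31")
  a1 <- assign_phases(simulate_cohort(cfg1), cfg1$prevalence_date)
  expect_equal(sum(a1$phase == "continuing"), 0)

  expect_error(sim_config(n_patients = 0), class = "cp_config_error")
})

test_that("event counts follow the configured Poisson intensities", {
  # single always-alive patient type, one code with known rate, no background
  ci <- tibble::tibble(
    code = "T01", stream = "OPS", system = "OUTPATIENT_NATIONAL",
    category = "test", subcategory = NA_character_,
    lambda_initial = 2.0, lambda_continuing = 0, lambda_final = 0, lambda0 = 0
  )
  cfg <- sim_config(n_patients = 300, seed = 8, death_rate = 0,
                    accrual_start = "2010-06-01", accrual_end = "2010-06-30",
                    code_intensities = ci)
  s <- simulate_study(cfg)
  # each patient contributes a 12-month initial period at rate 2/yr
  expected <- 2.0 * 300
  expect_lt(abs(nrow(s$ops) - expected), 3 * sqrt(expected))
  # a post-only code never appears before diagnosis
  by_pid <- dplyr::left_join(s$ops, s$patients[, c("pid", "diagnosis_date")], "pid")
  expect_true(all(by_pid$date >= by_pid$diagnosis_date))

  # all-zero intensities produce no events at all
  ci0 <- dplyr::mutate(ci, lambda_initial = 0)
  s0 <- simulate_study(sim_config(n_patients = 50, seed = 9, code_intensities = ci0))
  expect_equal(nrow(s0$ops) + nrow(s0$hd) + nrow(s0$dp) + nrow(s0$hp), 0)
})

test_that("planted truth is exactly the codes with positive excess intensity", {
  cfg <- sim_config()
  truth <- planted_truth(cfg)
  expect_equal(nrow(truth), 10)
  ci <- cfg$code_intensities
  manual <- ci$code[ci$lambda_initial > 0 | ci$lambda_continuing > 0 | ci$lambda_final > 0]
  expect_setequal(truth$code, manual)
  # the planted codes are all members of the shipped demo D-list
  d <- demo_dlist()
  expect_true(all(paste(truth$code_norm, truth$stream) %in%
                    paste(d$code_norm, d$stream)))
})

test_that("hospital episodes package codes into valid multi-slot records", {
  s <- simulate_study(sim_config(n_patients = 150, seed = 10))
  hd <- s$hd
  expect_true(all(!is.na(hd$diag1)))
  expect_true(all(hd$discharge_date >= hd$admission_date))
  # every simulated HD code is present somewhere in its episode's 12 slots
  d <- demo_dlist()
  flagged <- flag_hospitalizations(hd, d)
  expect_gt(sum(flagged$cancer_related), 0)
  expect_gt(sum(!flagged$cancer_related), 0) # distractor-only episodes exist
})

test_that("simulated pattern recovery orders surgery-like care into the initial phase", {
  cfg <- sim_config(seed = 12)
  s <- simulate_study(cfg)
  a <- assign_phases(s$patients, cfg$prevalence_date)
  att <- attribute_events(
    collect_events(demo_dlist(), hd = s$hd, ops = s$ops, dp = s$dp, hp = s$hp), a
  )
  tab <- tabulate_patterns(att, "HD")
  surg <- tab[tab$category == "Surgery" & is.na(tab$subcategory), ]
  # surgery-like intensity concentrates in the first year after diagnosis
  expect_gt(surg$pct_initial, surg$pct_final)
  # within-phase percents are column-conservative
  cats <- tab[is.na(tab$subcategory), ]
  expect_equal(sum(cats$n_initial), unname(attr(tab, "phase_totals")["initial"]))
  expect_lt(abs(sum(cats$pct_initial) - 100), 0.3)
})
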