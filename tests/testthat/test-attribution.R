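test_that("linkage conserves events and reports unmatched ones", {
  ev <- tibble::tibble(pid = c("A", "A", "B", "Z"), date = as.Date("2010-07-01"),
                       code = "x")
  expect_message(out <- link_events(ev, tiny_patients()), "1 event")
  expect_equal(nrow(out), 4)
  expect_equal(sum(out$matched), 3)
  expect_equal(sum(out$matched) + sum(!out$matched), nrow(ev))
  expect_silent(link_events(ev[0, ], tiny_patients()))
})

test_that("hospitalization flagging equals a brute-force scan over all 12 slots", {
  d <- tiny_dlist()
  episodes <- dplyr::bind_rows(
    hd_episode(diags = "401.9", procs = "85.21"),
    hd_episode(diags = c("401.9", "250.00"), procs = c("93.94", "99.18")),
    hd_episode(diags = c("401.9", "250.00", "715.9", "530.81", "486", "174.9")),
    hd_episode(diags = "174.9", procs = c("93.94", "85.21", "99.25"))
  )
  flagged <- flag_hospitalizations(episodes, d)
  expect_equal(flagged$cancer_related, c(TRUE, FALSE, TRUE, TRUE))
  # listed code in the last secondary diagnosis slot alone is enough
  expect_equal(flagged$matched_codes[[3]], "174.9")

  # oracle: per-episode loop over every populated slot
  oracle <- vapply(seq_len(nrow(episodes)), function(i) {
    hit <- FALSE
    for (j in 1:6) {
      dc <- episodes[[paste0("diag", j)]][i]
      pc <- episodes[[paste0("proc", j)]][i]
      if (!is.na(dc) && any(d$stream == "HD" & d$system == "ICD9CM_DIAG" &
                              d$code_norm == normalize_code(dc, "HD"))) hit <- TRUE
      if (!is.na(pc) && any(d$stream == "HD" & d$system == "ICD9CM_PROC" &
                              d$code_norm == normalize_code(pc, "HD"))) hit <- TRUE
    }
    hit
  }, logical(1))
  expect_equal(flagged$cancer_related, oracle)
})

test_that("classification picks the first match in slot order, procedures first", {
  d <- tiny_dlist()
  episodes <- dplyr::bind_rows(
    # main procedure lumpectomy beats secondary chemotherapy
    hd_episode(diags = "401.9", procs = c("85.21", "99.25")),
    # no listed procedure: falls back to the listed diagnosis
    hd_episode(diags = c("401.9", "174.9"), procs = "93.94"),
    # listed procedure in a secondary slot beats any diagnosis
    hd_episode(diags = "174.9", procs = c("93.94", "99.25"))
  )
  cls <- classify_hospitalizations(episodes, d)
  expect_equal(cls$matched_code, c("85.21", "174.9", "99.25"))
  expect_equal(cls$category, c("Surgery", "Diagnosis and monitoring", "Chemotherapy"))
  expect_equal(cls$subcategory, c("Lumpectomy", "Diagnosis", NA))

  # oracle: first hit scanning proc1..proc6 then diag1..diag6
  oracle <- vapply(seq_len(nrow(episodes)), function(i) {
    for (slot in c(paste0("proc", 1:6), paste0("diag", 1:6))) {
      cd <- episodes[[slot]][i]
      sys <- if (startsWith(slot, "proc")) "ICD9CM_PROC" else "ICD9CM_DIAG"
      if (!is.na(cd) && any(d$stream == "HD" & d$system == sys &
                              d$code_norm == normalize_code(cd, "HD"))) {
        return(cd)
      }
    }
    NA_character_
  }, character(1))
  expect_equal(cls$matched_code, oracle)

  # the category-priority variant prefers Surgery over an earlier chemo slot
  ep <- hd_episode(diags = "401.9", procs = c("99.25", "85.21"))
  expect_equal(classify_hospitalizations(ep, d)$category, "Chemotherapy")
  expect_equal(classify_hospitalizations(ep, d, rule = "category_priority")$category,
               "Surgery")
})

test_that("window selection is half-open, drops censored patients and conserves events", {
  d <- tiny_dlist()
  a <- assign_phases(tiny_patients(), "2011-01-01")
  # patient A window [2010-06-15, 2011-06-15); D is censored
  ops <- tibble::tibble(
    pid = c("A", "A", "A", "D", "A"),
    date = as.Date(c("2010-06-15", "2011-06-15", "2010-01-01", "2010-08-01", "2010-09-09")),
    code = c("89.01", "89.01", "89.01", "89.01", "00.00")
  )
  ev <- collect_events(d, ops = ops)
  att <- attribute_events(ev, a)
  expect_equal(nrow(att), 1)
  expect_equal(att$date, as.Date("2010-06-15"))
  expect_equal(as.character(att$phase), "initial")

  # conservation: attributed + out-of-window + non-cancer-related = total
  n_cancer <- sum(ev$cancer_related)
  expect_equal(nrow(att) + (n_cancer - nrow(att)) + sum(!ev$cancer_related), nrow(ops))

  # idempotent under permutation of the event order
  perm <- withr::with_seed(1, ops[sample(nrow(ops)), ])
  att2 <- attribute_events(collect_events(d, ops = perm), a)
  expect_equal(dplyr::arrange(att2, date, code), dplyr::arrange(att, date, code))
})

test_that("hospital episodes contribute one attributed row anchored on admission", {
  d <- tiny_dlist()
  a <- assign_phases(tiny_patients(), "2011-01-01")
  hd <- dplyr::bind_rows(
    hd_episode(pid = "A", admission = "2010-07-01", diags = "174.9",
               procs = c("85.21", "99.25")),
    hd_episode(pid = "A", admission = "2009-01-01", procs = "85.21") # out of window
  )
  att <- attribute_events(collect_events(d, hd = hd), a)
  expect_equal(nrow(att), 1)
  expect_equal(att$code, "85.21")
  expect_equal(att$stream, "HD")
})
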