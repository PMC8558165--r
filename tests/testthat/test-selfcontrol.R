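test_that("pre/post windows are 10 months each and skip the 2 months before diagnosis", {
  p <- tibble::tibble(pid = "a", diagnosis_date = as.Date("2010-06-15"))
  w <- self_control_windows(p)
  expect_equal(w$control_start, as.Date("2009-06-15"))
  expect_equal(w$control_end, as.Date("2010-04-15"))
  expect_equal(w$case_start, as.Date("2010-06-15"))
  expect_equal(w$case_end, as.Date("2011-04-15"))
  # the gap [diagnosis - 2m, diagnosis) is in neither window
  probe <- as.Date("2010-05-15")
  ev <- tibble::tibble(pid = "a", stream = "OPS", date = probe, code = "x")
  cc <- self_control_counts(ev, w, tibble::tibble(code = "x", stream = "OPS"))
  expect_equal(cc$case_counts[[1]], 0L)
  expect_equal(cc$control_counts[[1]], 0L)
})

test_that("per-code counts include explicit zeros for event-free patients", {
  w <- self_control_windows(tibble::tibble(
    pid = c("a", "b", "c"), diagnosis_date = as.Date("2010-06-15")
  ))
  ev <- tibble::tibble(
    pid = c("a", "a", "c"), stream = "OPS",
    date = as.Date(c("2010-07-01", "2010-08-01", "2010-07-01")), code = "x"
  )
  cc <- self_control_counts(ev, w, tibble::tibble(code = c("x", "y"), stream = "OPS"))
  expect_equal(cc$case_counts[[1]], c(2L, 0L, 1L))
  expect_equal(cc$control_counts[[1]], c(0L, 0L, 0L))
  expect_equal(cc$case_counts[[2]], c(0L, 0L, 0L)) # code never occurring
  expect_equal(cc$n_case, c(3L, 3L))
})

test_that("the Welch-Satterthwaite test matches the independent implementation", {
  # frozen worked example
  r <- welch_t_test(c(1, 2, 3, 4, 5), c(2, 3, 4, 5, 6))
  o <- stats::t.test(c(1, 2, 3, 4, 5), c(2, 3, 4, 5, 6), var.equal = FALSE)
  expect_equal(r$t, unname(o$statistic), tolerance = 1e-10)
  expect_equal(r$df, unname(o$parameter), tolerance = 1e-10)
  expect_equal(r$p_value, o$p.value, tolerance = 1e-10)

  # symmetry: identical samples give t = 0, p = 1
  s <- welch_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(s$t, 0)
  expect_equal(s$p_value, 1)

  # 1000 random count vectors against the reference implementation
  withr::with_seed(42, {
    for (i in 1:1000) {
      nx <- sample(2:60, 1)
      ny <- sample(2:60, 1)
      x <- rpois(nx, runif(1, 0.2, 4))
      y <- rpois(ny, runif(1, 0.2, 4))
      if (var(x) == 0 && var(y) == 0) next
      r <- welch_t_test(x, y)
      o <- stats::t.test(x, y, var.equal = FALSE)
      expect_equal(r$t, unname(o$statistic), tolerance = 1e-8)
      expect_equal(r$df, unname(o$parameter), tolerance = 1e-8)
      expect_equal(r$p_value, o$p.value, tolerance = 1e-8)
    }
  })
})

test_that("degenerate samples follow the documented conventions", {
  both_const_eq <- welch_t_test(c(2, 2, 2), c(2, 2, 2))
  expect_equal(both_const_eq$p_value, 1)
  expect_equal(both_const_eq$reason, "zero variance")
  both_const_ne <- welch_t_test(c(2, 2, 2), c(3, 3, 3))
  expect_equal(both_const_ne$p_value, 0)
  short <- welch_t_test(c(1), c(1, 2, 3))
  expect_true(is.na(short$p_value))
  expect_equal(short$reason, "insufficient data")
})

test_that("C-list derivation includes separated codes and honours directionality", {
  n <- 50
  counts <- tibble::tibble(
    code = c("up", "down", "flat", "absent"),
    stream = "OPS",
    case_counts = list(rep(1L, n), rep(0L, n), rep(c(0L, 1L), n / 2), rep(0L, n)),
    control_counts = list(rep(0L, n), rep(1L, n), rep(c(1L, 0L), n / 2), rep(0L, n)),
    n_case = n, n_control = n
  )
  fit <- derive_clist(counts)
  aud <- tidy(fit)
  expect_true(aud$included[aud$code == "up"])
  expect_false(aud$included[aud$code == "down"])   # suppressed post-diagnosis
  expect_false(aud$included[aud$code == "flat"])
  expect_false(aud$included[aud$code == "absent"]) # zero occurrences
  # the pure two-sided rule admits the suppressed code too
  fit2 <- derive_clist(counts, direction = "two.sided")
  expect_true(tidy(fit2)$included[tidy(fit2)$code == "down"])
  expect_equal(glance(fit)$n_candidates, 4L)
})

test_that("weighted concordance matches hand arithmetic and is monotone", {
  dl <- as_codelist(tibble::tibble(
    code = c("a1", "b1", "c1"), system = "ATC", stream = "DP", category = "x"
  ))
  cl_ab <- as_codelist(tibble::tibble(
    code = c("a1", "b1"), system = "ATC", stream = "DP", category = "x"
  ), label = "C-list")
  w <- tibble::tibble(code = c("a1", "b1", "c1"), stream = "DP",
                      weight = c(10, 5, 5))
  res <- weighted_concordance(dl, cl_ab, w)
  dp <- res[res$stream == "DP", ]
  expect_equal(dp$ratio_weighted, 15 / 20)
  expect_equal(dp$ratio_unweighted, 2 / 3)

  # identity and disjoint cases
  expect_equal(weighted_concordance(dl, dl, w)$ratio_weighted[1], 1)
  cl_none <- as_codelist(tibble::tibble(code = "z9", system = "ATC",
                                        stream = "DP", category = "x"))
  expect_equal(weighted_concordance(dl, cl_none, w)$ratio_weighted[1], 0)

  # monotone: adding a D-list code to C never decreases the weighted ratio
  withr::with_seed(11, {
    for (i in 1:20) {
      wts <- tibble::tibble(code = c("a1", "b1", "c1"), stream = "DP",
                            weight = runif(3, 0, 10))
      base <- weighted_concordance(dl, cl_ab, wts)
      grown <- weighted_concordance(dl, dl, wts)
      expect_gte(grown$ratio_weighted[1], base$ratio_weighted[1])
    }
  })

  # unobserved D-list codes carry zero weight
  res0 <- weighted_concordance(dl, cl_ab,
                               tibble::tibble(code = c("a1", "b1"), stream = "DP",
                                              weight = c(10, 5)))
  expect_equal(res0$ratio_weighted[res0$stream == "DP"], 1)
})

test_that("the initial-phase subcohort feeds the self-control design", {
  sub <- self_control_subcohort(tiny_patients(), "2011-01-01")
  expect_equal(sub$pid, "A")
})
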