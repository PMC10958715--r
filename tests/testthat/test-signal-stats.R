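# Frozen expected values below were computed by hand from the closed-form
# definitions (see oracle_stats() in helper-fixtures.R for the independent
# arithmetic).

test_that("statistics reproduce hand-computed values on (25, 75, 100, 900)", {
  a <- 25; b <- 75; c <- 100; d <- 900
  r <- ror(a, b, c, d)
  expect_equal(r$est, 3)
  expect_equal(r$lower, 1.8240, tolerance = 1e-4)
  expect_equal(r$upper, 4.9341, tolerance = 1e-4)

  p <- prr(a, b, c, d)
  expect_equal(p$est, 2.5)
  expect_equal(p$lower, 1.6977, tolerance = 1e-4)
  expect_equal(p$upper, 3.6817, tolerance = 1e-4)

  expect_equal(chi_square(a, b, c, d, yates = FALSE), 20.3077,
               tolerance = 1e-4)
  expect_equal(chi_square(a, b, c, d, yates = TRUE), 18.8452,
               tolerance = 1e-4)

  e <- ebgm(a, b, c, d)
  expect_equal(e$est, 2.2)
  expect_equal(e$lower, 1.3376, tolerance = 1e-4)
  expect_equal(e$upper, 3.6185, tolerance = 1e-4)

  i <- bcpnn_ic(a, b, c, d)
  expect_equal(i$est, log2(2.2))
  expect_equal(i$est, 1.1375, tolerance = 1e-4)
})

test_that("chi-squared agrees with stats::chisq.test on both variants", {
  set.seed(99)
  for (k in 1:25) {
    cells <- sample(1:400, 4)
    m <- matrix(cells, nrow = 2, byrow = TRUE)
    expect_equal(chi_square(cells[1], cells[2], cells[3], cells[4],
                            yates = FALSE),
                 suppressWarnings(
                   unname(stats::chisq.test(m, correct = FALSE)$statistic)))
    expect_equal(chi_square(cells[1], cells[2], cells[3], cells[4],
                            yates = TRUE),
                 suppressWarnings(
                   unname(stats::chisq.test(m, correct = TRUE)$statistic)))
  }
  # Yates clamps at zero when the correction exceeds |ad - bc|
  expect_equal(chi_square(10, 10, 10, 11, yates = TRUE), 0)
})

test_that("uniform tables are the exact null point of all four statistics", {
  a <- 10; b <- 90; c <- 10; d <- 90
  expect_equal(ror(a, b, c, d)$est, 1)
  expect_equal(prr(a, b, c, d)$est, 1)
  expect_equal(ebgm(a, b, c, d)$est, 1)
  expect_equal(bcpnn_ic(a, b, c, d)$est, 0)
  expect_equal(chi_square(a, b, c, d, yates = FALSE), 0)
})

test_that("ic equals log2(ebgm) and intervals are ordered on random tables", {
  set.seed(7)
  for (k in 1:200) {
    cells <- sample(1:500, 4, replace = TRUE)
    e <- ebgm(cells[1], cells[2], cells[3], cells[4])
    i <- bcpnn_ic(cells[1], cells[2], cells[3], cells[4])
    expect_equal(i$est, log2(e$est))
    expect_equal(i$lower, log2(e$lower))
    for (tb in list(e, i, ror(cells[1], cells[2], cells[3], cells[4]),
                    prr(cells[1], cells[2], cells[3], cells[4]))) {
      expect_lt(tb$lower, tb$est)
      expect_gt(tb$upper, tb$est)
    }
  }
})

test_that("all four statistics are strictly increasing in a", {
  b <- 100; c <- 30; d <- 900
  a <- 1:60
  for (v in list(ror(a, b, c, d)$est, prr(a, b, c, d)$est,
                 bcpnn_ic(a, b, c, d)$est, ebgm(a, b, c, d)$est)) {
    expect_true(all(diff(v) > 0))
  }
})

test_that("zero cells yield undefined markers unless Haldane is requested", {
  expect_true(is.na(ror(5, 10, 0, 100)$est))
  expect_true(is.na(prr(5, 10, 0, 100)$est))
  expect_true(is.na(ebgm(0, 10, 5, 100)$est))
  expect_true(is.na(bcpnn_ic(0, 10, 5, 100)$est))
  expect_true(is.na(chi_square(0, 0, 5, 100)))  # zero margin a+b
  h <- ror(5, 10, 0, 100, zero_cell = "haldane")
  expect_true(is.finite(h$est) && is.finite(h$lower))
  # a defined point with an undefined interval: a > 0 but a zero elsewhere
  r <- ror(5, 10, 3, 0)
  expect_true(is.na(r$est))
  expect_error(ror(-1, 2, 3, 4), "non-negative")
})

test_that("signal criteria follow the minimum-count and lower-bound rules", {
  th <- signal_thresholds()
  # a = 2 with an enormous ROR still fails the minimum-count rule
  res <- tibble::tibble(
    a = 2, ror = 50, ror_lower = 10, prr = 50, chi2 = 100,
    ic_lower = 2, ebgm_lower = 10)
  out <- evaluate_signals(res, th)
  expect_false(out$ror_pos)
  expect_false(out$prr_pos)
  expect_true(out$bcpnn_pos)
  expect_false(out$combined)
  # the tiny fixture cannot reach the thresholds: no combined signal
  u <- screen_signals(deduplicate(six_case_raw()), c("C1", "C2", "C3"),
                      level = "pt", map = toy_map())
  expect_false(any(u$combined))
  # undefined statistics never satisfy a criterion
  res_na <- tibble::tibble(a = 10, ror = NA_real_, ror_lower = NA_real_,
                           prr = NA_real_, chi2 = NA_real_,
                           ic_lower = NA_real_, ebgm_lower = NA_real_)
  out_na <- evaluate_signals(res_na, th)
  expect_false(any(out_na$ror_pos, out_na$prr_pos, out_na$bcpnn_pos,
                   out_na$ebgm_pos, out_na$combined))
})

test_that("contingency tables match hand counts on the six-case fixture", {
  cases <- deduplicate(six_case_raw())
  target <- c("C1", "C2", "C3")
  for (unit in c("case", "event")) {
    exp_tabs <- six_case_expected(unit)
    for (level in c("pt", "soc")) {
      got <- contingency_tables(cases, target, level = level,
                                map = toy_map(), unit = unit)
      want <- exp_tabs[[level]][order(exp_tabs[[level]]$term), ]
      got <- got[order(got$term), c("term", "a", "b", "c", "d")]
      expect_equal(as.data.frame(got), as.data.frame(want),
                   ignore_attr = TRUE,
                   label = paste(level, unit))
    }
  }
  # margins are fixed across terms within a run
  tt <- contingency_tables(cases, target, "pt", toy_map(), unit = "case")
  expect_equal(unique(tt$a + tt$b), 3)
  expect_equal(unique(tt$c + tt$d), 3)
  # the duplicated Diarrhoea row of C1 contributed once (a = 2, not 3)
  expect_equal(tt$a[tt$term == "Diarrhoea"], 2)
})

test_that("screening equals independent scalar recomputation per table", {
  cases <- deduplicate(six_case_raw())
  res <- screen_signals(cases, c("C1", "C2", "C3"), level = "pt",
                        map = toy_map(), zero_cell = "haldane",
                        yates = FALSE)
  expect_true(all(res$a >= 1))
  expect_equal(res$a, sort(res$a, decreasing = TRUE))
  for (k in seq_len(nrow(res))) {
    cells <- as.numeric(res[k, c("a", "b", "c", "d")])
    if (any(cells == 0)) cells <- cells + 0.5
    o <- oracle_stats(cells[1], cells[2], cells[3], cells[4])
    expect_equal(res$ror[k], o$ror)
    expect_equal(res$ror_lower[k], o$ror_lo)
    expect_equal(res$ror_upper[k], o$ror_hi)
    expect_equal(res$prr[k], o$prr)
    expect_equal(res$prr_lower[k], o$prr_lo)
    expect_equal(res$ic[k], o$ic)
    expect_equal(res$ic_lower[k], o$ic_lo)
    expect_equal(res$ic_upper[k], o$ic_hi)
    expect_equal(res$ebgm[k], o$ebgm)
    expect_equal(res$ebgm_lower[k], o$ebgm_lo)
  }
  # chi-squared is computed on the raw (uncorrected) cells
  for (k in seq_len(nrow(res))) {
    cells <- as.numeric(res[k, c("a", "b", "c", "d")])
    expect_equal(res$chi2[k], oracle_stats(cells[1], cells[2], cells[3],
                                           cells[4])$chi2_plain)
  }
})

test_that("screening an empty database errors and zero-a terms are dropped", {
  empty <- deduplicate(make_raw(demo = tibble::tibble(
    primaryid = character(0), caseid = character(0))))
  expect_error(contingency_tables(empty, character(0), "pt", toy_map()),
               "background")
  cases <- deduplicate(six_case_raw())
  res <- screen_signals(cases, c("C1", "C2", "C3"), "pt", toy_map())
  expect_false("Insomnia" %in% res$term)  # a = 0 at PT level for targets
})
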