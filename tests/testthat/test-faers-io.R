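test_that("read_quarter parses the $ dialect and enforces mandatory columns", {
  b <- generate_bundle(generator_config(n_reports = 60, seed = 4))
  dir <- withr::local_tempdir()
  write_faers_ascii(b, dir)
  raw <- read_quarter(dir)
  for (tb in names(raw)) {
    expect_equal(nrow(raw[[tb]]), nrow(b[[tb]]), label = tb)
  }
  # empty fields come back as NA, not empty strings
  expect_true(all(is.na(raw$demo$age) | nzchar(raw$demo$age)))

  # a DEMO file lacking caseid triggers a schema error naming file and column
  demo <- utils::read.delim(file.path(dir, "DEMO.txt"), sep = "$",
                            colClasses = "character")
  demo$caseid <- NULL
  utils::write.table(demo, file.path(dir, "DEMO.txt"), sep = "$",
                     quote = FALSE, row.names = FALSE, na = "")
  expect_error(read_quarter(dir), "DEMO.*caseid")
})

test_that("verbatim values pass through the io layer unnormalized", {
  raw <- make_raw(
    demo = tibble::tibble(primaryid = "P1", caseid = "C1",
                          age = "780", age_cod = "MON", fda_dt = "20200101")
  )
  dir <- withr::local_tempdir()
  b <- structure(c(unclass(raw),
                   list(ground_truth = list(), config = list())),
                 class = "faers_bundle")
  write_faers_ascii(b, dir)
  back <- read_quarter(dir)
  expect_identical(back$demo$age, "780")
  expect_identical(back$demo$age_cod, "MON")
})

test_that("deduplication keeps the latest receipt date, ties to larger primaryid", {
  raw <- make_raw(demo = tibble::tibble(
    primaryid = c("101", "102", "201", "202", "301"),
    caseid = c("C1", "C1", "C2", "C2", "C3"),
    fda_dt = c("20200101", "20200301", "20200101", "20200101", NA)
  ))
  cases <- deduplicate(raw)
  keep <- cases$demo
  expect_equal(nrow(keep), 3)
  expect_equal(keep$primaryid[keep$caseid == "C1"], "102")  # later date
  expect_equal(keep$primaryid[keep$caseid == "C2"], "202")  # tie -> larger id
  expect_equal(keep$primaryid[keep$caseid == "C3"], "301")
  expect_setequal(attr(cases, "discarded_primaryids"), c("101", "201"))
})

test_that("deduplication is idempotent and keeps child rows of the survivor only", {
  b <- generate_bundle(generator_config(n_reports = 300,
                                        duplicate_fraction = 0.2, seed = 8))
  cases <- deduplicate(as_raw_quarter(b))
  expect_equal(nrow(cases$demo), length(unique(b$demo$caseid)))
  for (tb in c("drug", "reac", "outc", "ther", "indi")) {
    expect_true(all(cases[[tb]]$primaryid %in% cases$demo$primaryid),
                label = tb)
  }
  again <- deduplicate(cases)
  for (tb in names(faersignal:::faers_schema())) {
    expect_equal(as.data.frame(again[[tb]][order(again[[tb]]$primaryid), ]),
                 as.data.frame(cases[[tb]][order(cases[[tb]]$primaryid), ]),
                 ignore_attr = TRUE, label = tb)
  }
})

test_that("discarded primaryids equal the generator's superseded list", {
  b <- generate_bundle(generator_config(n_reports = 500,
                                        duplicate_fraction = 0.15, seed = 21))
  cases <- deduplicate(as_raw_quarter(b))
  expect_setequal(attr(cases, "discarded_primaryids"),
                  b$ground_truth$superseded_primaryids)
})

test_that("multiple overlapping quarters deduplicate across inputs", {
  q1 <- make_raw(demo = tibble::tibble(
    primaryid = c("11", "21"), caseid = c("C1", "C2"),
    fda_dt = c("20200101", "20200201")))
  q2 <- make_raw(demo = tibble::tibble(
    primaryid = c("12", "31"), caseid = c("C1", "C3"),
    fda_dt = c("20200401", "20200301")))
  cases <- deduplicate(q1, q2)
  expect_equal(nrow(cases$demo), 3)
  expect_equal(cases$demo$primaryid[cases$demo$caseid == "C1"], "12")
})

test_that("digit-string dates parse by precision", {
  p <- parse_faers_date(c("20200215", "202002", "2020", "2020023",
                          "20200230", NA, "abc"))
  expect_equal(p$precision,
               c("day", "month", "year", "none", "none", "none", "none"))
  expect_equal(p$date[1], as.Date("2020-02-15"))
  expect_equal(p$date[2], as.Date("2020-02-01"))
  expect_equal(p$date[3], as.Date("2020-01-01"))
  expect_true(all(is.na(p$date[4:7])))
})
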