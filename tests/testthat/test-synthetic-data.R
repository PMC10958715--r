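test_that("a fixed seed reproduces the bundle exactly", {
  cfg <- generator_config(n_reports = 300, duplicate_fraction = 0.1, seed = 42)
  b1 <- generate_bundle(cfg)
  b2 <- generate_bundle(cfg)
  expect_identical(b1, b2)
  # and a different seed changes it
  b3 <- generate_bundle(generator_config(n_reports = 300,
                                         duplicate_fraction = 0.1, seed = 43))
  expect_false(identical(b1$demo, b3$demo))
})

test_that("invalid configurations are rejected naming the offending field", {
  expect_error(generator_config(n_reports = 0), "n_reports")
  expect_error(generator_config(background_rate = 1.5), "background_rate")
  expect_error(generator_config(duplicate_fraction = -0.1),
               "duplicate_fraction")
  expect_error(generator_config(partial_date_fraction = 2),
               "partial_date_fraction")
  expect_error(
    generator_config(planted_signals = data.frame(
      drug = "nosuchdrug", pt_name = "Diarrhoea", rate_ratio = 2)),
    "planted_signals")
  expect_error(
    generator_config(planted_signals = data.frame(
      drug = "lenvatinib", pt_name = "Nosuch term", rate_ratio = 2)),
    "planted_signals")
  expect_error(
    generator_config(planted_signals = data.frame(
      drug = "lenvatinib", pt_name = "Diarrhoea", rate_ratio = -1)),
    "rate_ratio")
})

test_that("bundle structure honours the report model", {
  cfg <- generator_config(n_reports = 400, duplicate_fraction = 0.15,
                          partial_date_fraction = 0.2, seed = 11)
  b <- generate_bundle(cfg)

  # every child-table primaryid exists in demo
  for (tb in c("drug", "reac", "outc", "ther", "indi")) {
    expect_true(all(b[[tb]]$primaryid %in% b$demo$primaryid), label = tb)
  }
  # demo rows = raw reports plus duplicate re-emissions
  expect_equal(nrow(b$demo),
               400 + length(b$ground_truth$superseded_primaryids))
  # at least one PS drug row per report
  ps <- unique(b$drug$caseid[b$drug$role_cod == "PS"])
  expect_setequal(ps, unique(b$demo$caseid))
  # a PT appears at most once per report version
  expect_equal(anyDuplicated(b$reac[, c("primaryid", "pt")]), 0L)
  # duplicate pairs share caseid, differ in primaryid and receipt date
  gt <- b$ground_truth
  expect_gt(length(gt$superseded_primaryids), 0)
  for (cid in head(gt$superseded_caseids, 10)) {
    versions <- b$demo[b$demo$caseid == cid, ]
    expect_equal(nrow(versions), 2)
    expect_equal(length(unique(versions$primaryid)), 2)
    expect_equal(length(unique(versions$fda_dt)), 2)
  }
  # a configurable majority of onset intervals is non-negative
  expect_lt(mean(gt$onset_days$negative), 0.1)
})

test_that("no duplicates requested leaves the superseded list empty", {
  b <- generate_bundle(generator_config(n_reports = 200,
                                        duplicate_fraction = 0, seed = 5))
  expect_length(b$ground_truth$superseded_primaryids, 0)
  expect_equal(nrow(b$demo), 200)
})

test_that("FAERS ASCII serialization round-trips losslessly", {
  b <- generate_bundle(generator_config(n_reports = 150,
                                        duplicate_fraction = 0.1, seed = 9))
  dir <- withr::local_tempdir()
  paths <- write_faers_ascii(b, dir)
  expect_setequal(basename(paths),
                  c("DEMO.txt", "DRUG.txt", "REAC.txt", "OUTC.txt",
                    "THER.txt", "INDI.txt"))
  raw <- read_quarter(dir)
  for (tb in c("demo", "drug", "reac", "outc", "ther", "indi")) {
    expect_equal(as.data.frame(raw[[tb]]), as.data.frame(b[[tb]]),
                 label = tb)
  }
})

test_that("fields containing the delimiter are rejected at write time", {
  b <- generate_bundle(generator_config(n_reports = 20, seed = 2))
  b$demo$reporter_country[3] <- "US$CA"
  expect_error(write_faers_ascii(b, withr::local_tempdir()),
               "delimiter")
})

test_that("pair counts are calibrated to n_reports x weight x rate", {
  # E[count(drug, PT)] = n w r; the only bias is the tiny guaranteed-one-
  # reaction fill, well below the 3-standard-error band checked here
  n <- 400
  w <- 1 / 6
  r <- 0.15
  counts <- vapply(1:200, function(s) {
    b <- generate_bundle(generator_config(
      n_reports = n, background_rate = r, duplicate_fraction = 0,
      partial_date_fraction = 0, seed = 1000 + s))
    tgt <- b$ground_truth$ps_drug$caseid[
      b$ground_truth$ps_drug$drug == "lenvatinib"]
    sum(b$reac$pt == "Diarrhoea" & b$reac$caseid %in% tgt)
  }, numeric(1))
  expected <- n * w * r
  expect_lt(abs(mean(counts) - expected),
            3 * stats::sd(counts) / sqrt(length(counts)))
})
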