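# Synthetic FAERS-format quarterly bundles with known ground truth.
#
# The generator emits the six quarterly tables in the canonical schema with
# planted drug-event reporting-rate elevations, duplicate case versions,
# partial dates and demographic missingness, so every downstream stage
# (dedup, cohort, screening, onset) is testable offline against known truth.
#
# Sampling model: each report carries exactly one primary-suspect (PS) drug,
# drawn by weight, plus independently included concomitants. Each preferred
# term is then an independent Bernoulli draw with probability
# background_rate * rate_ratio(PS drug, PT). The expected count of a
# (drug, PT) pair over a bundle is therefore
#   n_reports * weight(drug) * background_rate * rate_ratio,
# which is what the marginal-calibration property checks. A report drawing
# zero reactions is given one (reports without an adverse event do not occur
# in spontaneous-reporting data).

#' Toy drug vocabulary for synthetic bundles
#'
#' Six drugs with synonym lists (trade names, development codes, salt
#' forms); the first, lenvatinib, is the conventional target in examples.
#'
#' @return a tibble with columns `canonical` and `synonyms` (list column)
#' @export
default_drug_vocab <- function() {
  tibble(
    canonical = c("lenvatinib", "sorafenib", "pembrolizumab",
                  "sunitinib", "everolimus", "levothyroxine"),
    synonyms = list(
      c("LENVIMA", "E7080", "LENVATINIB MESYLATE"),
      c("NEXAVAR", "SORAFENIB TOSYLATE"),
      c("KEYTRUDA"),
      c("SUTENT", "SUNITINIB MALATE"),
      c("AFINITOR"),
      c("SYNTHROID", "LEVOTHYROXINE SODIUM")
    )
  )
}

#' Toy event vocabulary for synthetic bundles
#'
#' A small synthetic MedDRA-like vocabulary: 24 preferred terms across six
#' system organ classes, each PT mapping to exactly one SOC. Codes are
#' formatted like MedDRA numeric codes but the table is a toy, not the
#' licensed dictionary.
#'
#' @return a tibble with columns `pt_code`, `pt_name`, `soc_code`, `soc_name`
#' @export
default_event_vocab <- function() {
  gi <- c("10017947", "Gastrointestinal disorders")
  met <- c("10027433", "Metabolism and nutrition disorders")
  vas <- c("10047065", "Vascular disorders")
  hep <- c("10019805", "Hepatobiliary disorders")
  end <- c("10014698", "Endocrine disorders")
  res <- c("10038738", "Respiratory, thoracic and mediastinal disorders")
  gen <- c("10018065", "General disorders and administration site conditions")
  psy <- c("10037175", "Psychiatric disorders")
  rows <- list(
    c("10012735", "Diarrhoea", gi),
    c("10047700", "Vomiting", gi),
    c("10028813", "Nausea", gi),
    c("10042128", "Stomatitis", gi),
    c("10000081", "Abdominal pain", gi),
    c("10061428", "Decreased appetite", met),
    c("10012174", "Dehydration", met),
    c("10021036", "Hyponatraemia", met),
    c("10020772", "Hypokalaemia", met),
    c("10020949", "Hypocalcaemia", met),
    c("10020538", "Hypertension", vas),
    c("10055798", "Haemorrhage", vas),
    c("10019465", "Hepatic encephalopathy", hep),
    c("10019670", "Hepatic function abnormal", hep),
    c("10020850", "Hypothyroidism", end),
    c("10062767", "Hypophysitis", end),
    c("10001367", "Adrenal insufficiency", end),
    c("10022611", "Interstitial lung disease", res),
    c("10035759", "Pneumothorax", res),
    c("10013952", "Dysphonia", res),
    c("10016256", "Fatigue", gen),
    c("10037660", "Pyrexia", gen),
    c("10025482", "Malaise", gen),
    c("10022437", "Insomnia", psy)
  )
  m <- do.call(rbind, rows)
  tibble(pt_code = m[, 1], pt_name = m[, 2],
         soc_code = m[, 3], soc_name = m[, 4])
}

#' Default demographic distributions for synthetic bundles
#'
#' Categorical distributions shaped like a large oncology spontaneous-report
#' cohort: near-equal sex split with a small unknown fraction, ages centred
#' in the late sixties with about a fifth missing, reporting dominated by
#' Japan and the United States, hospitalization the most frequent serious
#' outcome, and oncology indications.
#'
#' @return a named list of distribution parameters
#' @export
default_demographics <- function() {
  list(
    sex = c(M = 0.494, F = 0.4655, UNK = 0.0405),
    age_unknown = 0.21, age_mean = 67, age_sd = 12,
    age_unit = c(YR = 0.88, MON = 0.10, DEC = 0.02),
    country = c(JP = 0.32, US = 0.25, GB = 0.06, DE = 0.06, IT = 0.05,
                CA = 0.05, AU = 0.04, FR = 0.019, CN = 0.019, ES = 0.014,
                BR = 0.118),
    outcomes = c(HO = 0.73, DE = 0.168, LT = 0.046, DS = 0.012, OT = 0.1),
    indication = c("Hepatocellular carcinoma" = 0.27,
                   "Endometrial cancer" = 0.157,
                   "Thyroid cancer" = 0.13,
                   "Renal cell carcinoma" = 0.072,
                   "Product used for unknown indication" = 0.028,
                   "Other neoplasm" = 0.343)
  )
}

check_prob <- function(x, field) {
  if (any(is.na(x)) || any(x < 0) || any(x > 1)) {
    abort(sprintf("generator_config: '%s' must be a probability in [0, 1]",
                  field))
  }
}

#' Configuration for the synthetic-report generator
#'
#' @param n_reports number of raw (pre-duplication) reports, >= 1
#' @param drugs drug vocabulary tibble (`canonical`, `synonyms` list column)
#' @param events event vocabulary tibble (`pt_code`, `pt_name`, `soc_code`,
#'   `soc_name`); every PT must map to exactly one SOC
#' @param drug_weights sampling weights for the primary-suspect drug, one
#'   per vocabulary row (default uniform)
#' @param background_rate per-(drug, PT) probability of the PT appearing on
#'   a report; scalar or one value per PT
#' @param mean_events_per_report optional target mean reaction count per
#'   report; when given, `background_rate` is rescaled uniformly so the
#'   expected count matches
#' @param planted_signals data frame of planted reporting-rate elevations
#'   with columns `drug` (canonical name), `pt_name` and `rate_ratio`
#'   (multiplier >= 0 on `background_rate`); both must exist in the
#'   vocabularies
#' @param duplicate_fraction probability that a case is re-emitted as a
#'   newer version (later receipt date, one perturbed demographic field)
#' @param partial_date_fraction probability that the event or therapy-start
#'   date is truncated to month (YYYYMM) or year (YYYY) precision
#' @param negative_onset_fraction probability that therapy starts after the
#'   event (yielding a negative, excluded onset interval)
#' @param concomitant_rate expected number of concomitant (role "C") drugs
#'   per report; each non-suspect vocabulary drug is included independently
#' @param demographics list of categorical distributions, see
#'   [default_demographics()]
#' @param onset_meanlog,onset_sdlog log-normal parameters of the onset-day
#'   distribution (defaults give median 37 days with a wide right tail,
#'   IQR roughly 10-116 days)
#' @param date_window two YYYYMMDD strings bounding event dates (one bundle
#'   = one reporting window; no cross-quarter logic)
#' @param seed integer RNG seed; a fixed seed makes [generate_bundle()]
#'   byte-reproducible
#' @return a validated object of class `generator_config`
#' @export
generator_config <- function(n_reports = 2000,
                             drugs = default_drug_vocab(),
                             events = default_event_vocab(),
                             drug_weights = NULL,
                             background_rate = 0.14,
                             mean_events_per_report = NULL,
                             planted_signals = NULL,
                             duplicate_fraction = 0.05,
                             partial_date_fraction = 0.10,
                             negative_onset_fraction = 0.02,
                             concomitant_rate = 0.8,
                             demographics = default_demographics(),
                             onset_meanlog = log(37),
                             onset_sdlog = 1.7,
                             date_window = c("20150101", "20230331"),
                             seed = 1L) {
  if (!is.numeric(n_reports) || length(n_reports) != 1 ||
      is.na(n_reports) || n_reports < 1) {
    abort("generator_config: 'n_reports' must be a positive integer")
  }
  drugs <- as_tibble(drugs)
  events <- as_tibble(events)
  stopifnot(all(c("canonical", "synonyms") %in% names(drugs)),
            all(c("pt_code", "pt_name", "soc_code", "soc_name") %in%
                  names(events)))
  if (anyDuplicated(events$pt_name)) {
    abort("generator_config: 'events' has duplicated PT names")
  }
  # each PT maps to exactly one SOC (validated by construction of the map)
  meddra_map(events)
  P <- nrow(events)
  if (length(background_rate) == 1) {
    background_rate <- rep(background_rate, P)
  }
  if (length(background_rate) != P) {
    abort("generator_config: 'background_rate' must be scalar or one per PT")
  }
  check_prob(background_rate, "background_rate")
  if (!is.null(mean_events_per_report)) {
    if (mean_events_per_report <= 0) {
      abort("generator_config: 'mean_events_per_report' must be positive")
    }
    background_rate <- background_rate *
      mean_events_per_report / sum(background_rate)
    check_prob(background_rate, "background_rate (rescaled)")
  }
  check_prob(duplicate_fraction, "duplicate_fraction")
  check_prob(partial_date_fraction, "partial_date_fraction")
  check_prob(negative_onset_fraction, "negative_onset_fraction")
  if (is.null(drug_weights)) drug_weights <- rep(1, nrow(drugs))
  if (length(drug_weights) != nrow(drugs) || any(drug_weights < 0) ||
      sum(drug_weights) <= 0) {
    abort("generator_config: 'drug_weights' must be non-negative, one per drug")
  }
  if (is.null(planted_signals)) {
    planted_signals <- tibble(drug = character(0), pt_name = character(0),
                              rate_ratio = numeric(0))
  }
  planted_signals <- as_tibble(planted_signals)
  stopifnot(all(c("drug", "pt_name", "rate_ratio") %in%
                  names(planted_signals)))
  if (!all(planted_signals$drug %in% drugs$canonical)) {
    abort("generator_config: 'planted_signals' references a drug absent from the vocabulary")
  }
  if (!all(planted_signals$pt_name %in% events$pt_name)) {
    abort("generator_config: 'planted_signals' references a PT absent from the vocabulary")
  }
  if (any(planted_signals$rate_ratio < 0)) {
    abort("generator_config: 'planted_signals' rate_ratio must be >= 0")
  }
  dw <- parse_faers_date(date_window)
  if (any(dw$precision != "day")) {
    abort("generator_config: 'date_window' must be two YYYYMMDD strings")
  }
  structure(list(
    n_reports = as.integer(n_reports), drugs = drugs, events = events,
    drug_weights = drug_weights / sum(drug_weights),
    background_rate = background_rate,
    planted_signals = planted_signals,
    duplicate_fraction = duplicate_fraction,
    partial_date_fraction = partial_date_fraction,
    negative_onset_fraction = negative_onset_fraction,
    concomitant_rate = concomitant_rate,
    demographics = demographics,
    onset_meanlog = onset_meanlog, onset_sdlog = onset_sdlog,
    date_window = sort(dw$date), seed = as.integer(seed)
  ), class = "generator_config")
}

#' Read a generator configuration from a YAML file
#'
#' Scalar fields map directly to [generator_config()] arguments;
#' `planted_signals` is a list of `{drug, pt_name, rate_ratio}` records,
#' `drugs` a list of `{canonical, synonyms}` records and `events` a list of
#' `{pt_code, pt_name, soc_code, soc_name}` records. Omitted fields take
#' the defaults.
#'
#' @param path YAML file path
#' @return a `generator_config`
#' @export
read_generator_config <- function(path) {
  if (!file.exists(path)) abort(paste0("generator config not found: ", path))
  y <- yaml::read_yaml(path)
  args <- y
  if (!is.null(y$drugs)) {
    args$drugs <- tibble(
      canonical = vapply(y$drugs, function(d) d$canonical, character(1)),
      synonyms = lapply(y$drugs, function(d) as.character(unlist(d$synonyms)))
    )
  }
  if (!is.null(y$events)) {
    args$events <- bind_rows(lapply(y$events, as_tibble))
  }
  if (!is.null(y$planted_signals)) {
    args$planted_signals <- bind_rows(lapply(y$planted_signals, as_tibble))
  }
  do.call(generator_config, args)
}

fmt_date <- function(d) format(d, "%Y%m%d")

#' Generate a synthetic FAERS-format quarter bundle
#'
#' Deterministic for a fixed seed. The demo table holds one row per raw
#' report plus one re-emitted (newer) version per injected duplicate; at
#' least one drug row per report carries role code "PS"; reactions are drawn
#' per (drug, PT) with the planted rate-ratio multipliers applied; therapy
#' start and event dates are ordered so that all but a configurable minority
#' of onset intervals are non-negative.
#'
#' @param config a [generator_config()]
#' @return an object of class `faers_bundle`: the six canonical-schema
#'   tibbles (`demo`, `drug`, `reac`, `outc`, `ther`, `indi`) plus
#'   `ground_truth`, a list with the planted signals, the superseded
#'   duplicate primaryids/caseids, and the per-case PS drug assignment
#' @export
generate_bundle <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  }
  set.seed(config$seed)

  n <- config$n_reports
  drugs <- config$drugs
  events <- config$events
  K <- nrow(drugs)
  P <- nrow(events)
  dem <- config$demographics

  caseid <- as.character(10000000L + seq_len(n))
  primaryid <- paste0(caseid, "1")

  # primary-suspect drug per report
  ps_idx <- sample.int(K, n, replace = TRUE, prob = config$drug_weights)

  # (drug, PT) rate matrix with planted multipliers
  rate <- matrix(rep(config$background_rate, each = K), nrow = K)
  if (nrow(config$planted_signals) > 0) {
    for (i in seq_len(nrow(config$planted_signals))) {
      ki <- match(config$planted_signals$drug[i], drugs$canonical)
      pi <- match(config$planted_signals$pt_name[i], events$pt_name)
      rate[ki, pi] <- min(0.99, rate[ki, pi] *
                            config$planted_signals$rate_ratio[i])
    }
  }
  hit <- matrix(runif(n * P), nrow = n) < rate[ps_idx, , drop = FALSE]
  empty <- which(rowSums(hit) == 0)
  for (i in empty) {
    hit[i, sample.int(P, 1, prob = rate[ps_idx[i], ])] <- TRUE
  }
  rx <- which(hit, arr.ind = TRUE)
  rx <- rx[order(rx[, 1], rx[, 2]), , drop = FALSE]
  reac <- tibble(primaryid = primaryid[rx[, 1]], caseid = caseid[rx[, 1]],
                 pt = events$pt_name[rx[, 2]])

  # drug rows: one PS row with a sampled verbatim synonym, then concomitants
  verbatim <- character(n)
  for (k in seq_len(K)) {
    idx <- which(ps_idx == k)
    syn <- c(toupper(drugs$canonical[k]), drugs$synonyms[[k]])
    verbatim[idx] <- syn[sample.int(length(syn), length(idx), replace = TRUE)]
  }
  drug_ps <- tibble(primaryid = primaryid, caseid = caseid, drug_seq = "1",
                    role_cod = "PS", drugname = verbatim)
  # concomitants: each non-PS drug independently, Binomial(K-1, q) per
  # report with q chosen so the expected concomitant count is concomitant_rate
  drug_con <- NULL
  if (K > 1 && config$concomitant_rate > 0) {
    q <- min(1, config$concomitant_rate / (K - 1))
    inc <- matrix(runif(n * K), nrow = n) < q
    inc[cbind(seq_len(n), ps_idx)] <- FALSE
    ci <- which(inc, arr.ind = TRUE)
    ci <- ci[order(ci[, 1], ci[, 2]), , drop = FALSE]
    if (nrow(ci) > 0) {
      per_report <- tabulate(ci[, 1], nbins = n)
      drug_con <- tibble(
        primaryid = primaryid[ci[, 1]], caseid = caseid[ci[, 1]],
        drug_seq = as.character(1 + sequence(per_report[per_report > 0])),
        role_cod = "C", drugname = toupper(drugs$canonical[ci[, 2]])
      )
    }
  }
  drug <- bind_rows(drug_ps, drug_con) %>%
    arrange(.data$caseid, as.integer(.data$drug_seq))

  # dates: event in the window, therapy start = event - onset, receipt after
  win <- config$date_window
  span <- as.integer(win[2] - win[1])
  event_date <- win[1] + floor(runif(n) * (span + 1))
  onset_days <- round(rlnorm(n, config$onset_meanlog, config$onset_sdlog))
  neg <- runif(n) < config$negative_onset_fraction
  start_date <- event_date - onset_days
  start_date[neg] <- event_date[neg] + 1 + floor(runif(sum(neg)) * 30)
  fda_date <- event_date + 1 + rpois(n, 30)

  event_dt <- fmt_date(event_date)
  start_dt <- fmt_date(start_date)
  # partial-date truncation (event and start dates only; receipt stays full)
  trunc_one <- function(x, p) {
    u <- runif(length(x))
    to_month <- u < p / 2
    to_year <- u >= p / 2 & u < p
    x[to_month] <- substr(x[to_month], 1, 6)
    x[to_year] <- substr(x[to_year], 1, 4)
    x
  }
  event_dt <- trunc_one(event_dt, config$partial_date_fraction)
  start_dt <- trunc_one(start_dt, config$partial_date_fraction)

  # demographics
  sex <- sample(names(dem$sex), n, replace = TRUE, prob = dem$sex)
  sex[sex == "UNK"] <- NA_character_
  age_known <- runif(n) >= dem$age_unknown
  age_years <- pmin(95, pmax(18, rnorm(n, dem$age_mean, dem$age_sd)))
  age_unit <- sample(names(dem$age_unit), n, replace = TRUE,
                     prob = dem$age_unit)
  age_val <- ifelse(age_unit == "YR", as.character(round(age_years)),
             ifelse(age_unit == "MON", as.character(round(age_years * 12)),
                    as.character(round(age_years / 10, 1))))
  age_val[!age_known] <- NA_character_
  age_unit[!age_known] <- NA_character_
  country <- sample(names(dem$country), n, replace = TRUE, prob = dem$country)

  demo <- tibble(
    primaryid = primaryid, caseid = caseid, caseversion = "1",
    fda_dt = fmt_date(fda_date), event_dt = event_dt,
    age = age_val, age_cod = age_unit, sex = sex, reporter_country = country
  )

  outc_list <- lapply(names(dem$outcomes), function(code) {
    on <- rbinom(n, 1, dem$outcomes[[code]]) == 1
    tibble(primaryid = primaryid[on], caseid = caseid[on], outc_cod = code)
  })
  outc <- bind_rows(outc_list) %>% arrange(.data$caseid, .data$outc_cod)

  ther <- tibble(primaryid = primaryid, caseid = caseid,
                 dsg_drug_seq = "1", start_dt = start_dt)

  indication <- sample(names(dem$indication), n, replace = TRUE,
                       prob = dem$indication)
  indi <- tibble(primaryid = primaryid, caseid = caseid,
                 indi_drug_seq = "1", indi_pt = indication)

  # duplicate injection: re-emit with a later receipt date, version 2,
  # numerically larger primaryid, and one perturbed demographic field
  dup <- runif(n) < config$duplicate_fraction
  superseded_pid <- character(0)
  if (any(dup)) {
    di <- which(dup)
    new_pid <- paste0(caseid[di], "2")
    demo2 <- demo[di, ] %>%
      mutate(primaryid = new_pid, caseversion = "2",
             fda_dt = fmt_date(fda_date[di] + 1 +
                                 floor(runif(length(di)) * 90)),
             reporter_country = sample(names(dem$country), length(di),
                                       replace = TRUE, prob = dem$country))
    orig_pids <- primaryid[di]
    clone <- function(tb) {
      sub <- tb[tb$primaryid %in% orig_pids, ]
      sub$primaryid <- paste0(sub$caseid, "2")
      sub
    }
    demo <- bind_rows(demo, demo2) %>% arrange(.data$caseid, .data$caseversion)
    drug <- bind_rows(drug, clone(drug)) %>%
      arrange(.data$caseid, .data$primaryid, as.integer(.data$drug_seq))
    reac <- bind_rows(reac, clone(reac)) %>%
      arrange(.data$caseid, .data$primaryid, .data$pt)
    outc <- bind_rows(outc, clone(outc)) %>%
      arrange(.data$caseid, .data$primaryid, .data$outc_cod)
    ther <- bind_rows(ther, clone(ther)) %>%
      arrange(.data$caseid, .data$primaryid)
    indi <- bind_rows(indi, clone(indi)) %>%
      arrange(.data$caseid, .data$primaryid)
    superseded_pid <- primaryid[di]
  }

  structure(list(
    demo = demo, drug = drug, reac = reac, outc = outc, ther = ther,
    indi = indi,
    ground_truth = list(
      planted_signals = config$planted_signals,
      superseded_primaryids = superseded_pid,
      superseded_caseids = caseid[dup],
      ps_drug = tibble(caseid = caseid, drug = drugs$canonical[ps_idx]),
      onset_days = tibble(caseid = caseid, onset_days = onset_days,
                          negative = neg),
      n_unique_cases = n
    ),
    config = config
  ), class = "faers_bundle")
}

#' @export
print.faers_bundle <- function(x, ...) {
  cat(sprintf("<faers_bundle> %d cases (%d duplicate re-emissions)\n",
              x$ground_truth$n_unique_cases,
              length(x$ground_truth$superseded_primaryids)))
  invisible(x)
}

#' Interpret a bundle as a raw quarter
#'
#' Gives the in-memory equivalent of writing a bundle with
#' [write_faers_ascii()] and reading it back with [read_quarter()].
#'
#' @param bundle a `faers_bundle`
#' @return a `faers_raw` object
#' @export
as_raw_quarter <- function(bundle) {
  stopifnot(inherits(bundle, "faers_bundle"))
  structure(bundle[names(faers_schema())], class = "faers_raw")
}

#' PT to SOC map of a bundle's event vocabulary
#'
#' @param bundle a `faers_bundle`
#' @return a `meddra_map` covering every PT the bundle can emit
#' @export
bundle_meddra_map <- function(bundle) {
  stopifnot(inherits(bundle, "faers_bundle"))
  meddra_map(bundle$config$events)
}

#' Drug dictionary for a bundle drug
#'
#' @param bundle a `faers_bundle`
#' @param canonical canonical drug name (default: the first vocabulary drug)
#' @return a `drug_dictionary` with that drug's synonyms
#' @export
bundle_drug_dictionary <- function(bundle, canonical = NULL) {
  stopifnot(inherits(bundle, "faers_bundle"))
  drugs <- bundle$config$drugs
  canonical <- canonical %||% drugs$canonical[1]
  k <- match(canonical, drugs$canonical)
  if (is.na(k)) abort(paste0("drug not in bundle vocabulary: ", canonical))
  drug_dictionary(drugs$canonical[k], drugs$synonyms[[k]])
}

#' Write a bundle as FAERS-dialect ASCII files
#'
#' Serializes the six tables as "$"-delimited text with one header line and
#' no quoting, the public FAERS quarterly dialect. Because the dialect has
#' no quoting, a field containing the delimiter cannot be represented and is
#' rejected at write time. Missing values are written as empty fields and
#' round-trip back to `NA` through [read_quarter()].
#'
#' @param bundle a `faers_bundle`
#' @param directory output directory (created if needed)
#' @return invisibly, the six file paths written (DEMO.txt ... INDI.txt)
#' @export
write_faers_ascii <- function(bundle, directory) {
  stopifnot(inherits(bundle, "faers_bundle"))
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  files <- faers_file_names()
  paths <- character(0)
  for (tb in names(files)) {
    df <- as.data.frame(bundle[[tb]])
    has_dollar <- vapply(df, function(col) any(grepl("$", col, fixed = TRUE)),
                         logical(1))
    if (any(has_dollar)) {
      abort(sprintf(
        "cannot serialize %s: field(s) %s contain the '$' delimiter (the FAERS dialect has no quoting)",
        toupper(tb), paste(names(df)[has_dollar], collapse = ", ")))
    }
    path <- file.path(directory, files[[tb]])
    utils::write.table(df, path, sep = "$", quote = FALSE,
                       row.names = FALSE, na = "", eol = "\n")
    paths <- c(paths, path)
  }
  invisible(paths)
}
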