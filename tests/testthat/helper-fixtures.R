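# Fixtures built in code: a toy PT->SOC map, a toy drug dictionary, a
# six-case hand-countable database, generator configurations for the
# Monte-Carlo properties, and independent scalar oracles for the statistics.

toy_map <- function() {
  meddra_map(tibble::tibble(
    pt_code = c("10012735", "10047700", "10020538", "10022437"),
    pt_name = c("Diarrhoea", "Vomiting", "Hypertension", "Insomnia"),
    soc_code = c("10017947", "10017947", "10047065", "10037175"),
    soc_name = c("Gastrointestinal disorders", "Gastrointestinal disorders",
                 "Vascular disorders", "Psychiatric disorders")
  ))
}

toy_dict <- function() drug_dictionary("lenvatinib", c("LENVIMA", "E7080"))

# Build a faers_raw object from partial tables, filling canonical columns.
make_raw <- function(demo, drug = NULL, reac = NULL, outc = NULL,
                     ther = NULL, indi = NULL) {
  sch <- faersignal:::faers_schema()
  fill <- function(df, cols) {
    if (is.null(df)) {
      df <- tibble::tibble(primaryid = character(0), caseid = character(0))
    }
    df <- tibble::as_tibble(lapply(df, as.character))
    for (cl in cols) if (!cl %in% names(df)) df[[cl]] <- NA_character_
    df
  }
  structure(list(demo = fill(demo, sch$demo), drug = fill(drug, sch$drug),
                 reac = fill(reac, sch$reac), outc = fill(outc, sch$outc),
                 ther = fill(ther, sch$ther), indi = fill(indi, sch$indi)),
            class = "faers_raw")
}

# Six cases: C1-C3 have lenvatinib as primary suspect (with verbatim name
# variants), C4-C6 do not. C5 carries lenvatinib only as concomitant. C1
# reports Diarrhoea twice (set semantics). Hand-counted tables below.
six_case_raw <- function() {
  make_raw(
    demo = tibble::tibble(
      primaryid = paste0("P", 1:6), caseid = paste0("C", 1:6),
      fda_dt = rep("20200110", 6), event_dt = rep("20200105", 6)
    ),
    drug = tibble::tibble(
      primaryid = c("P1", "P2", "P3", "P4", "P5", "P5", "P6"),
      caseid = c("C1", "C2", "C3", "C4", "C5", "C5", "C6"),
      drug_seq = c("1", "1", "1", "1", "1", "2", "1"),
      role_cod = c("PS", "PS", "PS", "PS", "PS", "C", "PS"),
      drugname = c("LENVIMA", "Lenvatinib", "LENVATINIB MESYLATE.",
                   "IBUPROFEN", "SORAFENIB", "LENVIMA", "ASPIRIN")
    ),
    reac = tibble::tibble(
      primaryid = c("P1", "P1", "P1", "P2", "P3", "P4", "P5", "P5",
                    "P6", "P6"),
      caseid = c("C1", "C1", "C1", "C2", "C3", "C4", "C5", "C5",
                 "C6", "C6"),
      pt = c("Diarrhoea", "Diarrhoea", "Vomiting", "Diarrhoea",
             "Hypertension", "Insomnia", "Diarrhoea", "Insomnia",
             "Hypertension", "Vomiting")
    )
  )
}

# Hand-counted contingency tables for the six-case fixture.
# Targets: C1, C2, C3 (3 cases, 4 unique case-PT pairs).
# Background: C4, C5, C6 (3 cases, 5 unique case-PT pairs).
six_case_expected <- function(unit = "case") {
  pt <- tibble::tibble(
    term = c("Diarrhoea", "Hypertension", "Vomiting", "Insomnia"),
    a = c(2, 1, 1, 0), tot = c(3, 2, 2, 2)
  )
  soc <- tibble::tibble(
    term = c("Gastrointestinal disorders", "Vascular disorders",
             "Psychiatric disorders"),
    a = c(2, 1, 0), tot = c(4, 2, 2)
  )
  margins <- if (unit == "case") {
    list(pt = c(t = 3, o = 3), soc = c(t = 3, o = 3))
  } else {
    # target case-SOC pairs: C1 GI, C2 GI, C3 Vascular = 3;
    # background: C4 Psych, C5 GI+Psych, C6 Vascular+GI = 5
    list(pt = c(t = 4, o = 5), soc = c(t = 3, o = 5))
  }
  finish <- function(df, m) {
    df$c <- df$tot - df$a
    df$b <- m[["t"]] - df$a
    df$d <- m[["o"]] - df$c
    df[, c("term", "a", "b", "c", "d")]
  }
  list(pt = finish(pt, margins$pt), soc = finish(soc, margins$soc))
}

# Independent scalar oracle: different algebraic forms from the package
# (odds as ad/bc, expected counts written out), plain base arithmetic.
oracle_stats <- function(a, b, c, d) {
  n <- a + b + c + d
  se_all <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  ror <- (a * d) / (b * c)
  prr <- (a * (c + d)) / (c * (a + b))
  se_prr <- sqrt(1 / a - 1 / (a + b) + 1 / c - 1 / (c + d))
  ebgm <- (a * n) / ((a + b) * (a + c))
  list(
    ror = ror, ror_lo = ror * exp(-1.96 * se_all),
    ror_hi = ror * exp(1.96 * se_all),
    prr = prr, prr_lo = prr * exp(-1.96 * se_prr),
    prr_hi = prr * exp(1.96 * se_prr),
    chi2_plain = n * (a * d - b * c)^2 /
      ((a + b) * (c + d) * (a + c) * (b + d)),
    chi2_yates = n * max(0, abs(a * d - b * c) - n / 2)^2 /
      ((a + b) * (c + d) * (a + c) * (b + d)),
    ic = log(ebgm, base = 2),
    ic_lo = log(ebgm, base = 2) - 1.96 * se_all / log(2),
    ic_hi = log(ebgm, base = 2) + 1.96 * se_all / log(2),
    ebgm = ebgm, ebgm_lo = ebgm * exp(-1.96 * se_all),
    ebgm_hi = ebgm * exp(1.96 * se_all)
  )
}

# Monte-Carlo study configuration: one drug-event pair planted at a
# rate ratio of 5 on a low-background PT (expected a about 32), target
# drug at 4% of reports so the observed/expected statistics are not
# attenuated by the target's own contribution to the background.
mc_signal_config <- function(seed) {
  ev <- default_event_vocab()
  br <- rep(0.15, nrow(ev))
  br[ev$pt_name == "Hypophysitis"] <- 0.01
  generator_config(
    n_reports = 16000,
    drug_weights = c(0.04, rep(0.96 / 5, 5)),
    background_rate = br,
    planted_signals = data.frame(drug = "lenvatinib",
                                 pt_name = "Hypophysitis", rate_ratio = 5),
    duplicate_fraction = 0.03, partial_date_fraction = 0.1, seed = seed
  )
}

# Null configuration: no planted signals, uniform background.
mc_null_config <- function(seed) {
  generator_config(n_reports = 800, background_rate = 0.15,
                   planted_signals = NULL, duplicate_fraction = 0,
                   partial_date_fraction = 0, seed = seed)
}

screen_bundle <- function(bundle, level = "pt", ...) {
  cases <- deduplicate(as_raw_quarter(bundle))
  cohort <- filter_primary_suspect(cases, bundle_drug_dictionary(bundle))
  screen_signals(cases, cohort, level = level,
                 map = bundle_meddra_map(bundle), ...)
}
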