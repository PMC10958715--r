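# Target-drug cohort construction: synonym matching, primary-suspect
# filtering, age normalization, PT->SOC mapping, demographic summary.

#' Build a drug synonym dictionary
#'
#' Spontaneous reports carry verbatim drug strings (trade names, salt forms,
#' case and spacing variants). The dictionary holds a canonical name and its
#' synonyms; matching is case-insensitive, whitespace-normalized and
#' punctuation-insensitive.
#'
#' @param canonical canonical drug name (e.g. "lenvatinib")
#' @param synonyms character vector of synonyms (trade names, codes, salt
#'   forms); the canonical name is always included
#' @return an object of class `drug_dictionary`
#' @export
drug_dictionary <- function(canonical, synonyms = character(0)) {
  canonical <- as.character(canonical)[1]
  syn <- unique(normalize_term(c(canonical, synonyms)))
  syn <- syn[nzchar(syn)]
  if (length(syn) == 0) abort("drug_dictionary(): no usable synonyms")
  structure(list(canonical = canonical, synonyms = syn),
            class = "drug_dictionary")
}

#' Read a drug dictionary from a two-column delimited file
#'
#' Expected format: tab- or comma-delimited with a header and two columns,
#' `canonical` and `synonym`; one synonym per row. All rows must share one
#' canonical name.
#'
#' @param path file path
#' @return a `drug_dictionary`
#' @export
read_drug_dictionary <- function(path) {
  if (!file.exists(path)) abort(paste0("drug dictionary not found: ", path))
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- read.delim(path, sep = sep, colClasses = "character",
                   stringsAsFactors = FALSE)
  if (!all(c("canonical", "synonym") %in% names(df))) {
    abort("drug dictionary file needs columns 'canonical' and 'synonym'")
  }
  drug_dictionary(df$canonical[1], df$synonym)
}

#' Match a verbatim drug string against a dictionary
#'
#' A verbatim string matches when, after normalization (uppercase, punctuation
#' stripped, whitespace collapsed), it equals a synonym or contains one as a
#' token sequence. So "LENVATINIB MESYLATE." matches a dictionary containing
#' "lenvatinib", while "LEVOTHYROXINE" does not.
#'
#' @param verbatim character vector of verbatim drug names
#' @param dict a `drug_dictionary`
#' @return logical vector
#' @export
match_drug <- function(verbatim, dict) {
  stopifnot(inherits(dict, "drug_dictionary"))
  x <- normalize_term(verbatim)
  hit <- rep(FALSE, length(x))
  for (s in dict$synonyms) {
    hit <- hit | x == s |
      grepl(paste0("(^| )", s, "( |$)"), x, fixed = FALSE)
  }
  hit & !is.na(x)
}

#' Filter a case database to target-drug primary-suspect cases
#'
#' Retains cases with at least one drug row whose verbatim name matches the
#' dictionary and whose role code is "PS" (primary suspect). The matched
#' drug sequence numbers are recorded (attribute `target_seq`) so that
#' therapy-start dates and indications can later be looked up for the target
#' drug specifically.
#'
#' @param cases a deduplicated `faers_cases` database
#' @param dict a `drug_dictionary`
#' @return a `faers_cases` subset (the PS cohort) with attribute
#'   `target_seq`, a tibble of (caseid, drug_seq) for matching PS rows
#' @export
filter_primary_suspect <- function(cases, dict) {
  stopifnot(inherits(cases, "faers_cases"))
  hits <- cases$drug %>%
    filter(toupper(trimws(.data$role_cod %||% "")) == "PS",
           match_drug(.data$drugname, dict))
  target_ids <- unique(hits$caseid)
  out <- lapply(unclass(cases), function(tb) {
    tb %>% filter(.data$caseid %in% target_ids)
  })
  structure(out, class = "faers_cases",
            discarded_primaryids = character(0),
            target_seq = hits %>% distinct(.data$caseid, .data$drug_seq))
}

#' Normalize a reported age to years
#'
#' FAERS ages come with a unit code: DEC (decades), YR (years), MON (months),
#' WK (weeks), DY (days), HR (hours). Values outside \[0, 130\] years or with
#' an unrecognized unit become unknown (`NA`).
#'
#' @param value numeric (or numeric-coercible) age values
#' @param unit_code character unit codes
#' @return numeric age in years, `NA` when unknown
#' @export
normalize_age <- function(value, unit_code) {
  v <- as_num(value)
  u <- toupper(trimws(as.character(unit_code)))
  factor <- c(DEC = 10, YR = 1, MON = 1 / 12, WK = 1 / 52.18,
              DY = 1 / 365.25, HR = 1 / 8766)
  f <- unname(factor[u])
  yrs <- v * f
  yrs[is.na(yrs) | yrs < 0 | yrs > 130] <- NA_real_
  yrs
}

age_band <- function(age_years) {
  cut(age_years,
      breaks = c(-Inf, 18, 45, 65, 75, Inf),
      labels = c("<18", "18-44", "45-64", "65-74", ">=75"),
      right = FALSE)
}

#' Build a PT to SOC mapping table
#'
#' MedDRA is licensed and cannot be redistributed: the preferred-term to
#' system-organ-class map is a user input. Each PT must map to exactly one
#' (primary) SOC.
#'
#' @param df a data frame with columns `pt_code`, `pt_name`, `soc_code`,
#'   `soc_name`
#' @return an object of class `meddra_map`
#' @export
meddra_map <- function(df) {
  need <- c("pt_code", "pt_name", "soc_code", "soc_name")
  if (!all(need %in% names(df))) {
    abort(paste0("meddra_map() needs columns: ", paste(need, collapse = ", ")))
  }
  df <- as_tibble(df) %>%
    mutate(across(dplyr::all_of(need), as.character),
           pt_key = normalize_term(.data$pt_name))
  dup <- df %>% distinct(.data$pt_key, .data$soc_code) %>% count(.data$pt_key) %>%
    filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort(paste0("PT maps to more than one SOC: ",
                 paste(head(dup$pt_key, 5), collapse = "; ")))
  }
  structure(distinct(df, .data$pt_key, .keep_all = TRUE), class = c("meddra_map", class(df)))
}

#' Read a PT to SOC map from a four-column delimited file
#'
#' Expected format: tab- or comma-delimited with header columns `pt_code`,
#' `pt_name`, `soc_code`, `soc_name`.
#'
#' @param path file path
#' @return a `meddra_map`
#' @export
read_meddra_map <- function(path) {
  if (!file.exists(path)) abort(paste0("PT->SOC map not found: ", path))
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  meddra_map(read.delim(path, sep = sep, colClasses = "character",
                        stringsAsFactors = FALSE))
}

#' Map preferred terms to their system organ class
#'
#' @param pt character vector of PT names
#' @param map a `meddra_map`
#' @return a tibble with columns `soc_code`, `soc_name`; PTs absent from the
#'   map are routed to the explicit "Unmapped" bucket (a value, not an error)
#' @export
map_pt_to_soc <- function(pt, map) {
  stopifnot(inherits(map, "meddra_map"))
  key <- normalize_term(pt)
  idx <- match(key, map$pt_key)
  tibble(
    soc_code = ifelse(is.na(idx), "UNMAPPED", map$soc_code[idx]),
    soc_name = ifelse(is.na(idx), "Unmapped", map$soc_name[idx])
  )
}

outcome_labels <- function() {
  c(DE = "Death", DS = "Disability", HO = "Hospitalization",
    LT = "Life-threatening")
}

#' Summarize a primary-suspect cohort
#'
#' Produces the standard cohort description of a spontaneous-report drug
#' cohort: sex, age bands (<18, 18-44, 45-64, 65-74, >=75, plus unknown),
#' top reporter countries, serious-outcome classes (death, disability,
#' hospitalization, life-threatening) and top indications. Percents are over
#' `n_cases`, rounded half-up to two decimals. Sex and age are partitions of
#' the cohort (their counts, including the unknown bucket, sum to `n_cases`);
#' outcomes are not, because one case can carry several outcome codes.
#'
#' @param cohort a `faers_cases` cohort from [filter_primary_suspect()]
#' @param top_k number of countries and indications to report
#' @return a tibble with columns `block` (sex / age_group / country /
#'   outcome / indication), `category`, `count`, `percent`, with attribute
#'   `n_cases`. An empty cohort yields a zero-row summary with
#'   `n_cases = 0` and no division performed.
#' @export
summarize_cohort <- function(cohort, top_k = 10) {
  stopifnot(inherits(cohort, "faers_cases"))
  nc <- nrow(cohort$demo)
  if (nc == 0) {
    out <- tibble(block = character(0), category = character(0),
                  count = integer(0), percent = numeric(0))
    attr(out, "n_cases") <- 0L
    return(out)
  }
  demo <- cohort$demo %>%
    mutate(
      sex_cat = dplyr::case_when(
        toupper(trimws(.data$sex %||% "")) == "M" ~ "Male",
        toupper(trimws(.data$sex %||% "")) == "F" ~ "Female",
        TRUE ~ "Unknown"),
      age_years = normalize_age(.data$age, .data$age_cod),
      age_cat = as.character(age_band(.data$age_years)),
      age_cat = ifelse(is.na(.data$age_cat), "Unknown", .data$age_cat),
      country = ifelse(is.na(.data$reporter_country) |
                         !nzchar(trimws(.data$reporter_country)),
                       "Unknown", trimws(.data$reporter_country))
    )

  block_tbl <- function(x, block, levels = NULL) {
    tb <- tibble(category = x) %>% count(.data$category, name = "count")
    if (!is.null(levels)) {
      tb <- tibble(category = levels) %>%
        left_join(tb, by = "category") %>%
        mutate(count = ifelse(is.na(.data$count), 0L, .data$count))
    }
    tb %>% mutate(block = block, percent = percent_of(.data$count, nc))
  }

  sex_tb <- block_tbl(demo$sex_cat, "sex", c("Male", "Female", "Unknown"))
  age_tb <- block_tbl(demo$age_cat, "age_group",
                      c("<18", "18-44", "45-64", "65-74", ">=75", "Unknown"))
  country_tb <- block_tbl(demo$country, "country") %>%
    filter(.data$category != "Unknown") %>%
    arrange(desc(.data$count)) %>% slice_head(n = top_k)

  outc <- cohort$outc %>%
    mutate(code = toupper(trimws(.data$outc_cod %||% ""))) %>%
    filter(.data$code %in% names(outcome_labels())) %>%
    distinct(.data$caseid, .data$code)
  outc_tb <- tibble(code = names(outcome_labels())) %>%
    left_join(count(outc, .data$code, name = "count"), by = "code") %>%
    mutate(count = ifelse(is.na(.data$count), 0L, .data$count),
           block = "outcome", category = unname(outcome_labels()),
           percent = percent_of(.data$count, nc)) %>%
    dplyr::select(-"code")

  # indications for the matched target-drug sequences where recorded
  indi <- cohort$indi
  tseq <- attr(cohort, "target_seq")
  if (!is.null(tseq) && nrow(tseq) > 0 && "indi_drug_seq" %in% names(indi)) {
    matched <- indi %>%
      inner_join(tseq, by = c(caseid = "caseid", indi_drug_seq = "drug_seq"))
    if (nrow(matched) > 0) indi <- matched
  }
  indi_tb <- indi %>%
    filter(!is.na(.data$indi_pt), nzchar(trimws(.data$indi_pt))) %>%
    distinct(.data$caseid, .data$indi_pt) %>%
    count(.data$indi_pt, name = "count") %>%
    rename(category = "indi_pt") %>%
    arrange(desc(.data$count)) %>% slice_head(n = top_k) %>%
    mutate(block = "indication", percent = percent_of(.data$count, nc))

  out <- bind_rows(sex_tb, age_tb, country_tb, outc_tb, indi_tb) %>%
    dplyr::select("block", "category", "count", "percent")
  attr(out, "n_cases") <- nc
  out
}
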