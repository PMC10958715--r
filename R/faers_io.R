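# Reading FAERS-style quarterly ASCII tables and deduplicating case versions.
#
# The public FAERS quarterly extract ships six "$"-delimited text files with
# one header line and no quoting. One *case* (caseid) may appear as several
# report *versions* (primaryid); analyses keep one version per case.

# Canonical column set, modeled on the post-2014 FAERS ASCII schema. Older
# schema variants are out of scope. Extra columns in input files are
# preserved; canonical columns that are absent (other than the mandatory
# primaryid/caseid) are created as NA.
faers_schema <- function() {
  list(
    demo = c("primaryid", "caseid", "caseversion", "fda_dt", "event_dt",
             "age", "age_cod", "sex", "reporter_country"),
    drug = c("primaryid", "caseid", "drug_seq", "role_cod", "drugname"),
    reac = c("primaryid", "caseid", "pt"),
    outc = c("primaryid", "caseid", "outc_cod"),
    ther = c("primaryid", "caseid", "dsg_drug_seq", "start_dt"),
    indi = c("primaryid", "caseid", "indi_drug_seq", "indi_pt")
  )
}

faers_file_names <- function() {
  c(demo = "DEMO.txt", drug = "DRUG.txt", reac = "REAC.txt",
    outc = "OUTC.txt", ther = "THER.txt", indi = "INDI.txt")
}

read_faers_table <- function(path, table) {
  if (!file.exists(path)) {
    abort(sprintf("FAERS %s file not found: %s", toupper(table), path))
  }
  df <- read.delim(path, sep = "$", quote = "", header = TRUE,
                   colClasses = "character", stringsAsFactors = FALSE,
                   na.strings = "", check.names = FALSE)
  for (col in c("primaryid", "caseid")) {
    if (!col %in% names(df)) {
      abort(sprintf("FAERS %s file %s lacks mandatory column '%s'",
                    toupper(table), path, col))
    }
  }
  for (col in faers_schema()[[table]]) {
    if (!col %in% names(df)) df[[col]] <- NA_character_
  }
  as_tibble(df)
}

#' Read one FAERS quarter
#'
#' Reads the six quarterly tables (DEMO, DRUG, REAC, OUTC, THER, INDI) from
#' "$"-delimited ASCII files with a single header line, as distributed in the
#' public FAERS quarterly extracts. All fields are kept as character at this
#' layer; normalization (ages, dates, drug names) happens downstream. Missing
#' fields become `NA`, never empty-string sentinels.
#'
#' @param paths either a directory containing `DEMO.txt`, `DRUG.txt`,
#'   `REAC.txt`, `OUTC.txt`, `THER.txt`, `INDI.txt`, or a named character
#'   vector/list with elements `demo`, `drug`, `reac`, `outc`, `ther`, `indi`.
#' @return an object of class `faers_raw`: a list of six tibbles. Each table
#'   carries at least `primaryid` and `caseid` plus its table-specific
#'   canonical columns; unknown extra columns are preserved.
#' @export
read_quarter <- function(paths) {
  tables <- names(faers_schema())
  if (is.character(paths) && length(paths) == 1 && dir.exists(paths)) {
    files <- file.path(paths, faers_file_names())
    names(files) <- tables
  } else {
    paths <- unlist(paths)
    missing <- setdiff(tables, names(paths))
    if (length(missing) > 0) {
      abort(paste0("read_quarter() needs paths named: ",
                   paste(missing, collapse = ", ")))
    }
    files <- paths[tables]
  }
  raw <- lapply(tables, function(tb) read_faers_table(files[[tb]], tb))
  names(raw) <- tables
  structure(raw, class = "faers_raw")
}

#' @export
print.faers_raw <- function(x, ...) {
  cat("<faers_raw> quarterly tables\n")
  for (tb in names(x)) cat(sprintf("  %s: %d rows\n", tb, nrow(x[[tb]])))
  invisible(x)
}

#' Deduplicate case versions across quarters
#'
#' A FAERS case may be reported or updated several times; each submission is
#' a distinct `primaryid` sharing the same `caseid`. For each case exactly
#' one version survives: the one with the latest receipt date (`fda_dt`),
#' ties broken by the numerically larger `primaryid` (the most recent case
#' version, following FDA guidance). All child-table rows are taken from the
#' surviving primaryid only, and reactions are reduced to a set per case.
#'
#' @param ... one or more `faers_raw` quarters (they may overlap in caseids)
#' @return an object of class `faers_cases`: a list of the six tables with
#'   exactly one `demo` row per caseid. The attribute `discarded_primaryids`
#'   lists the report versions that were superseded. Deduplication is
#'   idempotent: `deduplicate(deduplicate(x))` has the same rows.
#' @export
deduplicate <- function(...) {
  quarters <- list(...)
  quarters <- lapply(quarters, unclass)
  tables <- names(faers_schema())
  merged <- lapply(tables, function(tb) {
    bind_rows(lapply(quarters, function(q) q[[tb]]))
  })
  names(merged) <- tables

  demo <- merged$demo
  if (nrow(demo) == 0) {
    return(structure(merged, class = "faers_cases",
                     discarded_primaryids = character(0)))
  }
  demo <- demo %>%
    mutate(
      .fda = as_num(.data$fda_dt),
      .pid = as_num(.data$primaryid)
    ) %>%
    mutate(.fda = ifelse(is.na(.data$.fda), -Inf, .data$.fda))
  ord <- order(demo$caseid, -demo$.fda, -demo$.pid)
  demo <- demo[ord, ]
  survivors <- demo[!duplicated(demo$caseid), ]
  discarded <- setdiff(demo$primaryid, survivors$primaryid)
  keep <- survivors %>% dplyr::select(-".fda", -".pid")

  out <- lapply(tables, function(tb) {
    if (tb == "demo") return(keep)
    merged[[tb]] %>% filter(.data$primaryid %in% keep$primaryid)
  })
  names(out) <- tables
  # reactions are a set per case
  out$reac <- distinct(out$reac, .data$primaryid, .data$caseid, .data$pt,
                       .keep_all = TRUE)
  structure(out, class = "faers_cases", discarded_primaryids = discarded)
}

#' @export
print.faers_cases <- function(x, ...) {
  cat(sprintf("<faers_cases> %d deduplicated cases\n", nrow(x$demo)))
  for (tb in setdiff(names(x), "demo")) {
    cat(sprintf("  %s: %d rows\n", tb, nrow(x[[tb]])))
  }
  invisible(x)
}

#' Number of cases in a deduplicated database
#' @param cases a `faers_cases` object
#' @return integer count of distinct cases
#' @export
n_cases <- function(cases) {
  stopifnot(inherits(cases, "faers_cases"))
  nrow(cases$demo)
}
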