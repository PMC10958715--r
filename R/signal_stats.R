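# Disproportionality statistics on drug-event 2x2 tables.
#
# For a drug-event pair against the database background:
#   a = target-drug cases with the term      b = target-drug cases without it
#   c = other-drug cases with the term       d = other-drug cases without it
# N = a + b + c + d.
#
# ROR  = (a/b)/(c/d),            CI exp(ln ROR  +/- 1.96 sqrt(1/a+1/b+1/c+1/d))
# PRR  = [a/(a+b)]/[c/(c+d)],    CI exp(ln PRR  +/- 1.96 sqrt(1/a-1/(a+b)+1/c-1/(c+d)))
# chi2 = Pearson (optionally Yates-corrected) on the 2x2
# EBGM = a*N/((a+b)(a+c)),       CI exp(ln EBGM +/- 1.96 sqrt(1/a+1/b+1/c+1/d))
# IC   = log2 EBGM,              CI IC +/- 1.96 sqrt(1/a+1/b+1/c+1/d)/ln 2
#
# The EBGM/IC forms are the simplified observed-over-expected ratios (no
# gamma-mixture shrinkage), so IC = log2(EBGM) holds exactly on every table.
# Zero cells yield an undefined marker (NA) by default; the Haldane +0.5
# correction is available behind `zero_cell = "haldane"`.

check_cells <- function(a, b, c, d) {
  lens <- c(length(a), length(b), length(c), length(d))
  n <- max(lens)
  if (!all(lens %in% c(1L, n))) {
    abort("contingency cells must have equal length (or length 1)")
  }
  if (any(c(a, b, c, d) < 0, na.rm = TRUE)) {
    abort("contingency cells must be non-negative")
  }
  invisible(NULL)
}

apply_zero_cell <- function(a, b, c, d, zero_cell) {
  n <- max(length(a), length(b), length(c), length(d))
  a <- rep_len(as.numeric(a), n); b <- rep_len(as.numeric(b), n)
  c <- rep_len(as.numeric(c), n); d <- rep_len(as.numeric(d), n)
  if (zero_cell == "haldane") {
    z <- a == 0 | b == 0 | c == 0 | d == 0
    z[is.na(z)] <- FALSE
    a[z] <- a[z] + 0.5; b[z] <- b[z] + 0.5
    c[z] <- c[z] + 0.5; d[z] <- d[z] + 0.5
  }
  list(a = a, b = b, c = c, d = d)
}

ci_tibble <- function(est, lower, upper) {
  bad <- is.na(est)
  lower[bad] <- NA_real_
  upper[bad] <- NA_real_
  tibble(est = est, lower = lower, upper = upper)
}

#' Reporting odds ratio with 95% interval
#'
#' @param a,b,c,d contingency cells (vectorized); see package overview for
#'   the cell layout
#' @param zero_cell zero-cell policy: `"undefined"` (default) marks the
#'   point/interval undefined (`NA`) where a required cell is zero;
#'   `"haldane"` adds 0.5 to all four cells of any table with a zero cell
#' @return a tibble with columns `est`, `lower`, `upper`
#' @export
ror <- function(a, b, c, d, zero_cell = c("undefined", "haldane")) {
  zero_cell <- match.arg(zero_cell)
  check_cells(a, b, c, d)
  cc <- apply_zero_cell(a, b, c, d, zero_cell)
  est <- ifelse(cc$b > 0 & cc$c > 0 & cc$d > 0,
                (cc$a / cc$b) / (cc$c / cc$d), NA_real_)
  se <- ifelse(cc$a > 0 & cc$b > 0 & cc$c > 0 & cc$d > 0,
               sqrt(1 / cc$a + 1 / cc$b + 1 / cc$c + 1 / cc$d), NA_real_)
  ci_tibble(est, est * exp(-1.96 * se), est * exp(1.96 * se))
}

#' Proportional reporting ratio with 95% interval
#'
#' @inheritParams ror
#' @return a tibble with columns `est`, `lower`, `upper`
#' @export
prr <- function(a, b, c, d, zero_cell = c("undefined", "haldane")) {
  zero_cell <- match.arg(zero_cell)
  check_cells(a, b, c, d)
  cc <- apply_zero_cell(a, b, c, d, zero_cell)
  ab <- cc$a + cc$b
  cd <- cc$c + cc$d
  est <- ifelse(ab > 0 & cc$c > 0 & cd > 0,
                (cc$a / ab) / (cc$c / cd), NA_real_)
  se <- ifelse(cc$a > 0 & cc$c > 0 & ab > 0 & cd > 0,
               sqrt(pmax(0, 1 / cc$a - 1 / ab + 1 / cc$c - 1 / cd)), NA_real_)
  ci_tibble(est, est * exp(-1.96 * se), est * exp(1.96 * se))
}

#' Pearson chi-squared statistic for a 2x2 table
#'
#' Plain form `N(ad-bc)^2 / ((a+b)(c+d)(a+c)(b+d))`; the Yates continuity
#' correction replaces `|ad-bc|` with `max(0, |ad-bc| - N/2)`.
#'
#' @inheritParams ror
#' @param yates apply the Yates continuity correction (default `TRUE`, the
#'   classical companion to the PRR signal rule)
#' @return numeric vector; `NA` where any margin is zero
#' @export
chi_square <- function(a, b, c, d, yates = TRUE) {
  check_cells(a, b, c, d)
  a <- as.numeric(a); b <- as.numeric(b)
  c <- as.numeric(c); d <- as.numeric(d)
  n <- a + b + c + d
  denom <- (a + b) * (c + d) * (a + c) * (b + d)
  num <- abs(a * d - b * c)
  if (yates) num <- pmax(0, num - n / 2)
  ifelse(denom > 0, n * num^2 / denom, NA_real_)
}

#' Information component (BCPNN) with 95% interval
#'
#' Simplified information component `IC = log2(a*N / ((a+b)(a+c)))`, the
#' base-2 log of the observed-over-expected reporting ratio; the point
#' estimate equals `log2(ebgm())` on the same table. The interval is the
#' normal approximation `IC +/- 1.96 sqrt(1/a+1/b+1/c+1/d)/ln 2`.
#'
#' @inheritParams ror
#' @return a tibble with columns `est`, `lower`, `upper`; undefined when
#'   `a = 0`
#' @export
bcpnn_ic <- function(a, b, c, d, zero_cell = c("undefined", "haldane")) {
  e <- ebgm(a, b, c, d, zero_cell)
  ic_tbl <- log2(e)
  names(ic_tbl) <- c("est", "lower", "upper")
  ic_tbl
}

#' Empirical Bayes geometric mean (simplified) with 95% interval
#'
#' Simplified observed-over-expected ratio `EBGM = a*N / ((a+b)(a+c))` with
#' log-normal interval `exp(ln EBGM +/- 1.96 sqrt(1/a+1/b+1/c+1/d))`. No
#' gamma-mixture shrinkage is applied, so `bcpnn_ic()` is exactly its log2.
#'
#' @inheritParams ror
#' @return a tibble with columns `est`, `lower`, `upper`; undefined when
#'   `a = 0`
#' @export
ebgm <- function(a, b, c, d, zero_cell = c("undefined", "haldane")) {
  zero_cell <- match.arg(zero_cell)
  check_cells(a, b, c, d)
  cc <- apply_zero_cell(a, b, c, d, zero_cell)
  n <- cc$a + cc$b + cc$c + cc$d
  expct <- (cc$a + cc$b) * (cc$a + cc$c)
  est <- ifelse(cc$a > 0 & expct > 0, cc$a * n / expct, NA_real_)
  se <- ifelse(cc$a > 0 & cc$b > 0 & cc$c > 0 & cc$d > 0,
               sqrt(1 / cc$a + 1 / cc$b + 1 / cc$c + 1 / cc$d), NA_real_)
  ci_tibble(est, est * exp(-1.96 * se), est * exp(1.96 * se))
}

#' Signal-criterion thresholds
#'
#' The conventional positive-signal criteria for the four algorithms:
#' \itemize{
#'   \item ROR: `a >= min_count` and ROR 95% lower bound `> ror_lower`
#'   \item PRR: `a >= min_count`, `PRR >= prr_min` and `chi2 >= chi2_min`
#'   \item BCPNN: IC 95% lower bound `> ic_lower`
#'   \item EBGM: EBGM 95% lower bound `> ebgm_lower`
#' }
#' The combined criterion requires all four simultaneously.
#'
#' @param min_count minimum report count a (default 3)
#' @param ror_lower ROR interval lower-bound threshold (default 1)
#' @param prr_min PRR point threshold (default 2)
#' @param chi2_min chi-squared threshold (default 4)
#' @param ic_lower IC interval lower-bound threshold (default 0)
#' @param ebgm_lower EBGM interval lower-bound threshold (default 2)
#' @return a named list of thresholds
#' @export
signal_thresholds <- function(min_count = 3, ror_lower = 1, prr_min = 2,
                              chi2_min = 4, ic_lower = 0, ebgm_lower = 2) {
  stopifnot(min_count >= 0, prr_min > 0, chi2_min > 0)
  list(min_count = min_count, ror_lower = ror_lower, prr_min = prr_min,
       chi2_min = chi2_min, ic_lower = ic_lower, ebgm_lower = ebgm_lower)
}

#' Apply the per-algorithm and combined signal criteria
#'
#' Undefined statistics (zero-cell markers) never satisfy a criterion: the
#' corresponding flag is `FALSE`.
#'
#' @param results a tibble as produced by [screen_signals()] (columns `a`,
#'   `ror_lower`, `prr`, `chi2`, `ic_lower`, `ebgm_lower`)
#' @param thresholds a list from [signal_thresholds()]
#' @return `results` with added logical columns `ror_pos`, `prr_pos`,
#'   `bcpnn_pos`, `ebgm_pos` and `combined` (the conjunction of the four)
#' @export
evaluate_signals <- function(results, thresholds = signal_thresholds()) {
  tf <- function(x) !is.na(x) & x
  results %>% mutate(
    ror_pos = tf(.data$a >= thresholds$min_count &
                   .data$ror_lower > thresholds$ror_lower),
    prr_pos = tf(.data$a >= thresholds$min_count &
                   .data$prr >= thresholds$prr_min &
                   .data$chi2 >= thresholds$chi2_min),
    bcpnn_pos = tf(.data$ic_lower > thresholds$ic_lower),
    ebgm_pos = tf(.data$ebgm_lower > thresholds$ebgm_lower),
    combined = .data$ror_pos & .data$prr_pos & .data$bcpnn_pos & .data$ebgm_pos
  )
}

case_terms <- function(cases, level, map) {
  reac <- cases$reac %>%
    filter(!is.na(.data$pt), nzchar(trimws(.data$pt)))
  if (level == "pt") {
    terms <- reac %>%
      transmute(.data$caseid, term_key = normalize_term(.data$pt),
                term = trimws(.data$pt))
    if (!is.null(map)) {
      idx <- match(terms$term_key, map$pt_key)
      terms$code <- ifelse(is.na(idx), NA_character_, map$pt_code[idx])
      terms$term <- ifelse(is.na(idx), terms$term, map$pt_name[idx])
    } else {
      terms$code <- NA_character_
    }
  } else {
    if (is.null(map)) abort("SOC-level screening needs a PT->SOC map")
    soc <- map_pt_to_soc(reac$pt, map)
    terms <- tibble(caseid = reac$caseid, term_key = soc$soc_code,
                    term = soc$soc_name, code = soc$soc_code)
  }
  distinct(terms, .data$caseid, .data$term_key, .keep_all = TRUE)
}

#' Build drug-event 2x2 contingency tables
#'
#' Counts unique (case, term) pairs: a case reporting the same PT twice
#' contributes once, and at SOC level a case counts once per SOC regardless
#' of how many member PTs it reported. The margins are fixed across all
#' terms of one screening run:
#' \itemize{
#'   \item `unit = "case"`: `a+b` = number of target cases, `c+d` = number of
#'     background cases;
#'   \item `unit = "event"`: `a+b` = total unique (case, term) pairs among
#'     target cases, `c+d` = the same among background cases (the convention
#'     under which a drug's total "number of AEs" is the target margin).
#' }
#' In both units `a` is the number of target cases reporting the term.
#'
#' @param cases a deduplicated `faers_cases` database (the full background)
#' @param target caseids of the target-drug cohort (character vector), or a
#'   `faers_cases` cohort from [filter_primary_suspect()]
#' @param level `"pt"` or `"soc"`
#' @param map a `meddra_map`; required for SOC level, optional at PT level
#'   (used to attach PT codes)
#' @param unit counting-unit convention for the margins (see above)
#' @return a tibble with columns `term`, `code`, `a`, `b`, `c`, `d`, `n`,
#'   one row per term observed in the database
#' @export
contingency_tables <- function(cases, target, level = c("pt", "soc"),
                               map = NULL, unit = c("case", "event")) {
  level <- match.arg(level)
  unit <- match.arg(unit)
  stopifnot(inherits(cases, "faers_cases"))
  if (inherits(target, "faers_cases")) target <- target$demo$caseid
  if (nrow(cases$demo) == 0) abort("empty case database: no background to screen against")
  target <- unique(as.character(target))
  is_target <- cases$demo$caseid %in% target

  terms <- case_terms(cases, level, map) %>%
    mutate(tgt = .data$caseid %in% target)
  counts <- terms %>%
    group_by(.data$term_key, .data$term, .data$code) %>%
    summarise(a = sum(.data$tgt), tot = n(), .groups = "drop")

  if (unit == "case") {
    m_target <- sum(is_target)
    m_other <- sum(!is_target)
  } else {
    m_target <- sum(terms$tgt)
    m_other <- nrow(terms) - m_target
  }
  counts %>%
    mutate(c = .data$tot - .data$a,
           b = m_target - .data$a,
           d = m_other - .data$c,
           n = .data$a + .data$b + .data$c + .data$d) %>%
    dplyr::select("term", "code", "a", "b", "c", "d", "n") %>%
    arrange(desc(.data$a), .data$term)
}

#' Screen all terms of a database for disproportionality signals
#'
#' Runs the full screening: builds the 2x2 table for every term with at
#' least one target report, computes ROR, PRR, chi-squared, IC and EBGM with
#' 95% intervals, and applies the per-algorithm and combined signal
#' criteria. Results are sorted by `a` descending.
#'
#' @inheritParams contingency_tables
#' @param thresholds a list from [signal_thresholds()]
#' @param yates use the Yates-corrected chi-squared (default `TRUE`)
#' @param zero_cell zero-cell policy, see [ror()]
#' @return a tibble with one row per term (`a >= 1`): the cells, the four
#'   statistics with `_lower`/`_upper` bounds, `chi2`, the per-algorithm
#'   flags and `combined`
#' @export
screen_signals <- function(cases, target, level = c("pt", "soc"), map = NULL,
                           thresholds = signal_thresholds(),
                           unit = c("case", "event"), yates = TRUE,
                           zero_cell = c("undefined", "haldane")) {
  level <- match.arg(level)
  unit <- match.arg(unit)
  zero_cell <- match.arg(zero_cell)
  tabs <- contingency_tables(cases, target, level, map, unit) %>%
    filter(.data$a >= 1)
  r <- ror(tabs$a, tabs$b, tabs$c, tabs$d, zero_cell)
  p <- prr(tabs$a, tabs$b, tabs$c, tabs$d, zero_cell)
  i <- bcpnn_ic(tabs$a, tabs$b, tabs$c, tabs$d, zero_cell)
  e <- ebgm(tabs$a, tabs$b, tabs$c, tabs$d, zero_cell)
  res <- tabs %>% mutate(
    ror = r$est, ror_lower = r$lower, ror_upper = r$upper,
    prr = p$est, prr_lower = p$lower, prr_upper = p$upper,
    chi2 = chi_square(tabs$a, tabs$b, tabs$c, tabs$d, yates = yates),
    ic = i$est, ic_lower = i$lower, ic_upper = i$upper,
    ebgm = e$est, ebgm_lower = e$lower, ebgm_upper = e$upper
  )
  evaluate_signals(res, thresholds) %>%
    arrange(desc(.data$a), .data$term)
}

#' Format a screening table for report output
#'
#' Two-decimal, round-half-up presentation with "est (lower-upper)" interval
#' columns, mirroring the conventional published layout.
#'
#' @param results output of [screen_signals()]
#' @return a tibble with formatted character columns
#' @export
format_signal_table <- function(results) {
  f2 <- function(x) ifelse(is.na(x), "", sprintf("%.2f", round_half_up(x, 2)))
  fci <- function(est, lo, hi) {
    ifelse(is.na(est), "",
           ifelse(is.na(lo), f2(est),
                  sprintf("%s (%s-%s)", f2(est), f2(lo), f2(hi))))
  }
  results %>% transmute(
    term = .data$term, code = .data$code, a = .data$a,
    ror_ci = fci(.data$ror, .data$ror_lower, .data$ror_upper),
    prr_ci = fci(.data$prr, .data$prr_lower, .data$prr_upper),
    chi2 = f2(.data$chi2),
    ic_ci = fci(.data$ic, .data$ic_lower, .data$ic_upper),
    ebgm_ci = fci(.data$ebgm, .data$ebgm_lower, .data$ebgm_upper),
    ror_pos = .data$ror_pos, prr_pos = .data$prr_pos,
    bcpnn_pos = .data$bcpnn_pos, ebgm_pos = .data$ebgm_pos,
    combined = .data$combined
  )
}
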