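---
title: "Disproportionality screening of spontaneous adverse-event reports"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disproportionality screening of spontaneous adverse-event reports}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(faersignal)
```

## The problem

Spontaneous-report systems such as FAERS collect voluntary reports of
suspected adverse drug reactions. There is no denominator of exposed
patients, so incidence cannot be estimated; what can be estimated is
whether a drug–event pair is reported *disproportionately* often relative
to the database background. `faersignal` implements this screening for a
single target drug treated as the primary suspect (PS): the role code under
which the reporter names the drug they consider most likely responsible.

The unit of analysis is the deduplicated *case*. A FAERS case may be
submitted repeatedly (follow-ups, corrections); each submission is a
report version (`primaryid`) under a stable case identifier (`caseid`).
`deduplicate()` keeps, per case, the version with the latest receipt date,
breaking ties toward the numerically larger `primaryid` — the rule FDA
documents for selecting the most recent case version. The rule is
idempotent and, on synthetic bundles, provably discards exactly the
generator's superseded versions.

## The statistics

For each term (MedDRA preferred term, PT, or system organ class, SOC) the
2×2 table against the background is

|              | term | no term |
|--------------|------|---------|
| target cases | a    | b       |
| other cases  | c    | d       |

with N = a + b + c + d, and the four screening statistics are

* ROR = (a/b)/(c/d), CI₉₅ = exp(ln ROR ± 1.96·√(1/a + 1/b + 1/c + 1/d));
* PRR = [a/(a+b)]/[c/(c+d)],
  CI₉₅ = exp(ln PRR ± 1.96·√(1/a − 1/(a+b) + 1/c − 1/(c+d)));
* Pearson χ² = N(ad − bc)²/[(a+b)(c+d)(a+c)(b+d)], with the Yates variant
  replacing |ad − bc| by max(0, |ad − bc| − N/2);
* IC = log₂[aN/((a+b)(a+c))], CI₉₅ = IC ± 1.96·√(1/a + 1/b + 1/c + 1/d)/ln 2;
* EBGM = aN/((a+b)(a+c)), CI₉₅ = exp(ln EBGM ± 1.96·√(1/a + 1/b + 1/c + 1/d)).

The IC and EBGM here are the *simplified* observed-over-expected forms, not
the fully Bayesian versions: no gamma-mixture prior is fitted and no
shrinkage applied (DuMouchel's gamma-Poisson-shrinker EM is a declared
non-goal). Consequently `bcpnn_ic()` is exactly the base-2 log of `ebgm()`
— point and bounds — and the package enforces and tests this identity.
This choice is not merely convenient: on published SOC-level screening
tables of this form the printed IC equals log₂ of the printed EBGM across
rows, which identifies the simplified forms as the ones in actual use; the
acceptance suite checks that identity and reproduces printed RORs from
printed PRRs by back-solving the background proportion.

The shrinkage-free forms are anti-conservative for very small a compared
with a true Bayesian IC/EBGM; the minimum-count rule (a ≥ 3) in the
combined criterion is what guards the screen against 1- and 2-report
flukes, and users comparing against gamma-Poisson-shrinker outputs should
expect those to sit closer to 1 for rare terms.

### Signal criteria

`signal_thresholds()` encodes the conventional rules: ROR positive when
a ≥ 3 and the ROR CI lower bound exceeds 1; PRR positive when a ≥ 3,
PRR ≥ 2 and χ² ≥ 4; BCPNN positive when the IC lower bound exceeds 0; EBGM
positive when the EBGM lower bound exceeds 2. The *combined* signal is the
conjunction of all four, which trades sensitivity for a lower false-positive
rate. All thresholds are overridable. The χ² in the PRR rule uses the Yates
correction by default (the classical Evans rule); published tables rarely
state which variant they used, so `yates = FALSE` is available and both are
exposed by `chi_square()`.

### Counting unit and margins

a is always the number of target cases reporting the term at least once
(set semantics: a PT reported twice in one case counts once; at SOC level a
case counts once per SOC however many member PTs it reported). The margins
are a config switch, `unit`:

* `"case"` (default): a + b = number of target cases, c + d = number of
  background cases — the textbook case-level 2×2;
* `"event"`: a + b = the drug's total unique (case, term) pairs — the
  convention under which a drug's printed "total number of AEs" is the
  target margin, as in published tables where per-term counts are case
  numbers but the margin is the AE total.

Because both conventions share a, the identity IC = log₂ EBGM and all
monotonicity properties hold under either; only the magnitudes of b, c, d
differ.

### Zero cells and degenerate input

A zero in a required cell makes a statistic undefined; the package returns
an `NA` marker rather than applying a continuity correction, because silent
+0.5 corrections change reproductions of published values. The Haldane
correction (add 0.5 to all four cells of an affected table) is available
behind `zero_cell = "haldane"`. Undefined statistics never satisfy a signal
criterion. An empty background is an error; an empty cohort summarizes to
`n_cases = 0` with no division.

## Cohort description

`summarize_cohort()` reports sex, age bands (<18, 18–44, 45–64, 65–74,
≥75, unknown), top-k reporter countries, the four serious-outcome classes
(death DE, disability DS, hospitalization HO, life-threatening LT) and
top-k indications. All percents use the cohort size `n_cases` as the
denominator and round half-up to two decimals. Sex and age (with their
unknown buckets) partition the cohort and are tested to sum to `n_cases`;
**outcomes deliberately do not partition it** — one case can carry several
outcome codes, and published cohort tables of this kind use n_cases
denominators for outcomes too, so their outcome percents do not sum to
100%. Ages are normalized to years from the FAERS unit codes (DEC ×10,
YR ×1, MON ÷12, WK ÷52.18, DY ÷365.25, HR ÷8766) with values outside
[0, 130] treated as unknown. Indication strings are taken verbatim at
whatever granularity they were reported; no harmonization is attempted.

MedDRA is licensed, so the PT→SOC map is a required user input (four
columns: `pt_code`, `pt_name`, `soc_code`, `soc_name`). A PT belonging to
several SOCs in full MedDRA must be resolved to its primary SOC in that
file; the package enforces single mapping and routes unmapped PTs to an
explicit "Unmapped" bucket rather than erroring.

## Time to onset

Onset is the day count from the earliest therapy start among the matched
target-drug sequence numbers to the case-level event date. A case is
excluded — exclusion is a value, not an error — when either date is missing
or has less than day precision (FAERS partial dates are 6- or 4-digit
strings), or when the difference is negative. Quantiles use linear
interpolation between order statistics (position 1 + (n−1)p, R's type 7).
"Months" are fixed 30-day windows (bin k covers 30(k−1) < days ≤ 30k, day 0
in bin 1, ">360" beyond twelve bins): calendar months would make the
summary depend on the start date, and published month-binned onset figures
do not define their bins, so the reproducible convention is used.

## The synthetic-report generator

`generate_bundle()` emits the six quarterly tables in the canonical
post-2014 FAERS ASCII schema with known ground truth. The model:

* each report carries exactly one PS drug (sampled by `drug_weights`) plus
  independently included concomitants (role C, expected count
  `concomitant_rate`);
* each PT is an independent Bernoulli draw with probability
  `background_rate × rate_ratio(PS drug, PT)`, the rate ratios coming from
  `planted_signals`. The expected count of a (drug, PT) pair is therefore
  `n_reports × weight × background_rate × rate_ratio`, which the
  calibration test verifies to within three standard errors. A report that
  draws no reaction is given one (sampled proportionally to its rates),
  since reports without an event do not occur in spontaneous data — this
  adds a relative bias of well under 1% at the default rates;
* onsets are log-normal (default meanlog = log 37, sdlog = 1.7, i.e.
  median 37 days with an IQR of roughly 10–116 — the shape of published
  onset distributions for chronic-dosing oncology drugs); a small
  configurable fraction of therapy starts falls after the event, producing
  the negative intervals the onset module must exclude;
* duplicates are re-emissions of a case with a strictly later receipt
  date, caseversion 2, a numerically larger primaryid and one perturbed
  demographic field, so deduplication correctness is observable;
* event and therapy dates are truncated to month or year precision with
  probability `partial_date_fraction`; receipt dates stay full (the dedup
  key);
* demographics default to the shape of a large oncology cohort: sex
  ≈49/47/4% M/F/unknown, age ≈ N(67, 12²) with 21% missing (encoded in
  mixed units — years, months, decades — to exercise normalization),
  reporting dominated by Japan and the US, hospitalization the most common
  serious outcome (73%), oncology indications. These were chosen once to
  emulate the published cohort profile of a multikinase-inhibitor drug and
  are not tuning knobs.

Defaults: `background_rate = 0.14` over the 24-PT toy vocabulary gives
≈3.4 reactions per report, matching the ≈3.3 AEs-per-case ratio of large
FAERS drug cohorts. One bundle is one reporting window; cross-quarter
follow-up chains, reporter-level biases (Weber, notoriety) and free-text
verbatim noise beyond the synonym list are out of scope. The serialized
form is "$"-delimited ASCII with one header line and **no quoting** — a
field containing "$" is unrepresentable and rejected at write time.

What passing tests on these bundles shows — and does not show: they
validate the pipeline's bookkeeping (dedup, role filtering, set-semantics
counting, margins), its statistical formulas, and its operating
characteristics under a clean generative model with independent PTs and a
single-version history. Real FAERS data add schema drift across years,
misspelled verbatim drug names beyond any synonym list, correlated
reactions, nullification records and indication noise that the generator
deliberately does not model.

## Monte-Carlo operating characteristics

Two studies are run by the acceptance suite and `scripts/acceptance.R`,
200 seeded replicates each (sizes chosen so each study completes in about
two minutes on one CPU):

* **planted-signal recovery** — 16,000 reports, target drug on 4% of them,
  one pair planted at rate ratio 5 on a PT with background rate 0.01
  (expected a ≈ 32). The 95% ROR interval covers 5, and the combined
  criterion fires, in well over 90% of replicates. The target share and
  the planted PT's background matter: the ROR estimates an odds ratio
  (≈5.2 at these rates, converging to the rate ratio as the event gets
  rarer), and the observed-over-expected statistics are attenuated by the
  target's own contribution to the background, which is why the target is
  kept to a few percent of reports — as it is in real databases;
* **null calibration** — 800-report bundles with nothing planted: the
  fraction of screened terms flagged by the combined criterion stays below
  2.5%, the nominal rate of the most permissive single test (a one-sided
  lower-bound rule); empirically it is ≈0, since a null term essentially
  never clears the EBGM-lower-bound-above-2 hurdle.

## Known limitations

* The comparator is always all non-target cases in the loaded database;
  restricted comparators (same-class drugs, same-indication cases) and
  stratified or age/sex-adjusted disproportionality are not provided.
* No multiple-comparison correction is applied across terms — conventional
  in this screening literature, but worth remembering when reading a
  PT-level table with hundreds of rows.
* Nullification/amendment semantics beyond latest-version-wins, the FAERS
  XML dialect, and pre-2014 ASCII schema variants are not handled.
* Published cohort tables built on the real FAERS corpus occasionally
  contain internal inconsistencies (counts whose text and table versions
  disagree); the package reports whatever it computes from its inputs and
  takes no side.
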