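# faersignal

Pharmacovigilance signal detection for spontaneous adverse-event reports in
the public FAERS quarterly ASCII dialect.

Spontaneous-report databases such as the FDA Adverse Event Reporting System
(FAERS) collect voluntary case reports linking drugs to suspected adverse
events, without a denominator of exposed patients. Safety signals are
therefore screened by *disproportionality*: for a drug–event pair, the 2×2
table

|                  | event reported | event not reported |
|------------------|----------------|--------------------|
| target drug      | a              | b                  |
| all other drugs  | c              | d                  |

is compared against the database background with four classical statistics:

- **ROR** (reporting odds ratio) = (a/b)/(c/d), with
  CI₉₅ = exp(ln ROR ± 1.96·√(1/a + 1/b + 1/c + 1/d));
- **PRR** (proportional reporting ratio) = [a/(a+b)]/[c/(c+d)], paired with
  the Pearson χ² (optionally Yates-corrected) and a minimum-count rule;
- **IC** (information component of the Bayesian confidence propagation
  neural network) = log₂[aN/((a+b)(a+c))];
- **EBGM** (empirical Bayes geometric mean, simplified
  observed-over-expected form) = aN/((a+b)(a+c)), so that IC = log₂ EBGM.

A term is a *signal* when it meets all four criteria simultaneously
(a ≥ 3 with ROR lower bound > 1; PRR ≥ 2 with χ² ≥ 4; IC lower bound > 0;
EBGM lower bound > 2). The package is aimed at pharmacoepidemiologists who
want a reproducible, offline-testable version of this standard workflow:
reading FAERS quarterly tables, deduplicating case versions, isolating a
target drug as primary suspect (PS) through a synonym dictionary,
screening at the MedDRA preferred-term (PT) and system-organ-class (SOC)
levels, summarizing demographics / serious outcomes / indications, and
computing time to onset. A synthetic-report generator with planted signals
makes every stage testable without the multi-gigabyte FAERS download.

MedDRA is licensed and is **not** bundled: PT→SOC mapping is a user-supplied
four-column table.

## Worked example

```r
library(faersignal)

# a synthetic quarter with one planted drug-event signal: the target drug
# elevates a rare PT (background rate 0.01 per report) fivefold
ev <- default_event_vocab()
br <- rep(0.14, nrow(ev))
br[ev$pt_name == "Hypophysitis"] <- 0.01
cfg <- generator_config(
  n_reports = 8000, background_rate = br,
  drug_weights = c(0.1, rep(0.9 / 5, 5)),
  planted_signals = data.frame(drug = "lenvatinib",
                               pt_name = "Hypophysitis", rate_ratio = 5),
  seed = 7)
bundle <- generate_bundle(cfg)

cases  <- deduplicate(as_raw_quarter(bundle))
cohort <- filter_primary_suspect(cases, bundle_drug_dictionary(bundle))
res    <- screen_signals(cases, cohort, level = "pt",
                         map = bundle_meddra_map(bundle))
print(subset(as.data.frame(res), term == "Hypophysitis",
             select = c(a, ror, ror_lower, ror_upper, ebgm, ebgm_lower,
                        combined)), digits = 4)
#>     a   ror ror_lower ror_upper  ebgm ebgm_lower combined
#> 24 45 5.546     3.807     8.079 3.696      2.537     TRUE
```

The planted pair is reported by 45 of the 805 primary-suspect cases; its
ROR of 5.55 (95% CI 3.81–8.08) covers the planted rate ratio of 5, all four
algorithms exceed their thresholds, and the combined criterion flags it.
The EBGM point (3.70) sits below the ROR because the target drug's own
reports contribute to the expected count — the attenuation shrinks as the
target's share of the database falls.

Onset summary for the same cohort (the generator draws onsets from a
log-normal with median 37 days):

```r
s <- summarize_onset(compute_onset(cohort))
c(n = s$n, median = s$median, q1 = s$q1, q3 = s$q3)
#>      n median     q1     q3
#> 640.00  37.00  11.75 105.50
```

A complete run (cohort table, SOC and PT screening tables, onset bins and a
reproducibility manifest, written as CSV/JSON) is one call:

```r
run_pipeline(pipeline_config(generator = cfg,
                             drug_dict = bundle_drug_dictionary(bundle),
                             out_dir = "out"))
```

or, from a shell, via the thin CLI in `inst/cli/faersignal.R`
(`simulate`, `screen` and `stats` subcommands; `stats --a 25 --b 75
--c 100 --d 900` prints all four statistics for one table).

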