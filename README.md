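# pvsignal

Disproportionality signal detection and time-to-onset analysis for
FAERS-style spontaneous adverse event report data.

Pharmacovigilance teams mine spontaneous reporting systems such as the FDA
Adverse Event Reporting System (FAERS) to find drug–event pairs reported
more often than expected. `pvsignal` implements that workflow end to end
for the quarterly '$'-delimited ASCII tables: case deduplication, drug-name
standardization, drug–event contingency tables at MedDRA preferred-term
(PT) and system-organ-class (SOC) level, the four standard
disproportionality algorithms with their signal criteria, sex-stratified
subgroup analysis, and Weibull modelling of time-to-onset (TTO). A
synthetic FAERS-like generator with planted ground truth makes every stage
testable without access to the live database.

## Methods at the core

For each event term, reports are cross-tabulated as drug–event pairs:

|                    | event of interest | all other events |
|--------------------|-------------------|------------------|
| target drug        | a                 | b                |
| all other drugs    | c                 | d                |

with `N = a + b + c + d`, margins `n1 = a + b`, `n2 = a + c`, and expected
count `E = n1 n2 / N`. The four statistics are

- **ROR** `= ad / bc`, with the Woolf interval
  `exp(ln ROR ± 1.96 √(1/a + 1/b + 1/c + 1/d))`;
- **PRR** `= [a/(a+b)] / [c/(c+d)]` with its log-scale interval, plus the
  Pearson χ² (optionally Yates-corrected);
- **BCPNN information component** `IC`, a shrunken `log2(a N / (n1 n2))`
  with Bayesian lower bound `IC025` (Bate 1998 moment approximation by
  default; Norén variant available);
- **MGPS EBGM**: a two-component gamma mixture prior on the true relative
  reporting rate λ is fitted across all cells by maximum marginal
  (negative-binomial mixture) likelihood; `EBGM` is the posterior geometric
  mean of λ and `EB05` its 5th posterior percentile.

A term is a *signal* when it simultaneously satisfies the four standard
criteria (`n ≥ 3` and ROR lower bound > 1; `PRR ≥ 2`, `χ² ≥ 4`, `n ≥ 3`;
`IC025 > 0`; `EB05 > 2`). Onset times (therapy start to event onset) are
fitted with a two-parameter Weibull by profile maximum likelihood; a shape
β with 95% CI entirely below 1 indicates an *early failure* hazard
(risk concentrated soon after treatment start).

`invert_published_stats()` does the reverse direction: given a published
row (`n`, ROR with CI, χ²), it numerically recovers the underlying 2×2
table, so published signal tables can be checked for internal consistency
and their unprinted statistics recomputed.

## Worked example

```r
library(pvsignal)

cfg <- sim_config(n_reports = 20000,
                  planted_rr = c(PT0010 = 10, PT0025 = 6, PT0040 = 3),
                  seed = 101)
db  <- generate_database(cfg)
res <- run_pipeline(db, out_dir = "results/run1")

res$signals$pt[signal == TRUE,
               .(term, n, ror = round(ror, 2), ror_low = round(ror_low, 2),
                 prr = round(prr, 2), chi2 = round(chi2, 1),
                 ic = round(ic, 2), ic025 = round(ic025, 2),
                 ebgm = round(ebgm, 2), ebgm05 = round(ebgm05, 2))]
```

```
     term     n   ror ror_low   prr   chi2    ic ic025  ebgm ebgm05
1: PT0010  1250  9.54    8.59  8.16 2474.9  1.65  1.54  3.13   2.99
2: PT0025   287  5.40    4.49  5.24  396.5  1.42  1.20  2.68   2.44
```

Two of the three planted terms are flagged by all four algorithms: the
term planted at relative rate 10 is reported 1,250 times against ~131
expected under independence, and even after empirical-Bayes shrinkage its
5th posterior percentile (2.99) clears the EB05 > 2 criterion. The weak
λ = 3 term is shrunk below threshold — the usual conservatism of the
combined criterion. The onset stage recovers the planted early-failure
regime:

```r
res$weibull
#> Weibull time-to-onset fit (n = 3218)
#>   scale alpha: 96.07 days (95% CI 90.75-101.70)
#>   shape beta:  0.640 (95% CI 0.623-0.658)
#>   hazard pattern: early failure
res$tto_summary$median
#> [1] 49
```

The shape estimate 0.64 (CI below 1) correctly classifies the planted
Weibull(shape 0.62, scale 95.51 days) onset distribution as early failure.

Checking a published signal row for internal consistency:

```r
invert_published_stats(415, 17.49, c(15.70, 19.49), 5126.5)[c("prr", "log2_oe")]
#> $prr
#> [1] 14.07999
#> $log2_oe
#> [1] 3.815569
```

## Vignette

`vignettes/pvsignal-methods.Rmd` documents the models, the counting
conventions, the numerical choices, what the synthetic generator does and
does not emulate, and known limitations.
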