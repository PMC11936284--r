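---
title: "Disproportionality signal detection with pvsignal: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disproportionality signal detection with pvsignal}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pvsignal)
library(data.table)
```

`pvsignal` analyses spontaneous adverse event report databases in the
FAERS quarterly-extract dialect. This vignette is the package's own
account of the statistics it implements, the conventions it commits to,
and the limits of what its tests demonstrate.

## The data model and cleaning rules

A FAERS-style extract distributes one '$'-delimited ASCII table per
entity: DEMO (one row per report version: identifiers, dates,
demographics), DRUG (drugs per report with role codes — PS primary
suspect, SS secondary suspect, C concomitant, I interacting), REAC (coded
reactions as MedDRA preferred terms), OUTC (outcome codes DE/LT/HO/DS/CA/
RI/OT) and THER (therapy start dates). Cases are resubmitted over time, so
one physical patient case (CASEID) may appear under several report
versions (PRIMARYID). `deduplicate_cases()` applies the standard rule:
keep the version with the latest FDA receipt date (FDA_DT); on ties, the
higher PRIMARYID; versions without a parseable FDA_DT lose to any dated
version. The operation is total and idempotent, and it reports what it
removed.

Dates are `YYYYMMDD` strings; partially known dates arrive truncated
(`YYYYMM`, `YYYY`) or blank. `parse_faers_date()` classifies each string
as full, partial or missing, and treats calendar-impossible strings
(e.g. `20230230`) as missing. Ages are converted to years from the
AGE/AGE_COD pair (`DY`/365.25, `WK`/52.18, `MON`/12, `DEC`×10, `YR`×1);
values at or above 150 years are treated as recording errors. Drug names
are standardized by exact matching on a normalized key (upper-case,
punctuation and whitespace collapsed) against a user-supplied synonym
dictionary; full clinical-text normalization of drug names is out of
scope, so the dictionary is an input, not embedded data. The case set is
the reports naming the target drug with role PS (configurable to include
SS for sensitivity analyses).

## Counting convention: drug–event pairs

All 2×2 tables count *(report, term)* pairs, not reports. Each report
contributes one pair per distinct preferred term it lists; `a` counts
case-set pairs with the term, `b` the case set's other pairs, `c` and `d`
the same over all other reports; `a + b` is therefore constant across
terms. The SOC rollup maps terms to system organ classes first and then
counts distinct (report, SOC) pairs, so three terms from one SOC in one
report contribute a single pair. Pair-level counting is the only
convention under which a printed Woolf interval can be consistent with a
large per-term count when one term (such as a fatal outcome) appears in a
third of the case set: at report-level counting `1/a + 1/b` alone can
exceed the variance implied by a published interval, whereas the pair
universe gives `b` room to grow. The consistency checker described below
makes that arithmetic explicit.

Sex subgroups restrict the *entire* pair universe — case set and
comparator — to reports of one sex before counting; unknown-sex reports
are excluded from both arms, so stratum cells never exceed, and sum to at
most, the unstratified cells.

## The four disproportionality statistics

With margins `n1 = a + b`, `n2 = a + c`, total `N` and expected count
`E = n1 n2 / N`:

**ROR** `= ad/bc` with `CI = exp(ln ROR ± 1.96·√(1/a+1/b+1/c+1/d))`.
**PRR** `= [a/(a+b)]/[c/(c+d)]` with
`CI = exp(ln PRR ± 1.96·√(1/a − 1/(a+b) + 1/c − 1/(c+d)))`. When a cell
is zero the classical 0.5 continuity correction is added to all four
cells for ROR/PRR only, and the row is flagged `corrected` so downstream
consumers can audit it. The χ² statistic always uses the uncorrected
counts, with margin-based expectations and (by default) the Yates
correction capped at `|O − E|`, matching `chisq.test()`.

**BCPNN.** The default information component is the Bate (1998) moment
approximation: with hyperparameters `α₁′ = β₁′ = 1`, `α′ = β′ = 2`,
`γ₁₁ = 1` and `γ = γ₁₁(N+α′)(N+β′)/((n1+α₁′)(n2+β₁′))`,

```
E(IC)  = log2[ (a+γ₁₁)(N+α′)(N+β′) / ((N+γ)(n1+α₁′)(n2+β₁′)) ]
IC025  = E(IC) − 2·√V(IC)
```

with the matching variance expansion. For large cells `E(IC)` approaches
`log2(a N / (n1 n2))`; the shrinkage terms decay like `1/E`. The Norén
gamma-mixture form (`IC = log2((a+0.5)/(E+0.5))` with its asymptotic
credibility bound) is available as a configuration switch. The moment
variant is the default because published signal tables in this literature
print IC values that coincide with `log2` of the observed-to-expected
ratio to two decimals, which is this variant's large-sample behaviour.

**MGPS.** The observed count of a cell is modelled as Poisson(λE) with a
two-component gamma mixture prior on the relative reporting rate λ:
`Q·Gamma(α₁, β₁) + (1−Q)·Gamma(α₂, β₂)` (shape/rate). Marginally each
count is a mixture of negative binomials; `fit_mgps()` maximizes the
summed log marginal likelihood over the five hyperparameters on an
unconstrained transform (logit Q, log shapes/rates), by Nelder–Mead with
a BFGS polish from the classical starting point
`(Q = 1/3, α₁ = 0.2, β₁ = 0.1, α₂ = 2, β₂ = 4)` plus four jittered
restarts under a fixed internal seed. The cell posterior is again a
two-component gamma mixture with posterior weight `Q*` from the marginal
densities; `EBGM = exp(Q*(ψ(α₁+a) − ln(β₁+E)) + (1−Q*)(ψ(α₂+a) −
ln(β₂+E)))` (ψ the digamma function) and `EB05` solves
posterior-CDF(λ) = 0.05 by bracketed root-finding to 10⁻¹⁰. The prior is
fitted unstratified, across all cells of one level. `run_pipeline()` fits
it once on the preferred-term cells and reuses it for the SOC rollup and
the sex subgroups: a shrinkage prior estimated from ten SOC cells would
be meaningless, and the prior describes the database, not the level. On
small cell sets (a few hundred terms with a lone extreme outlier)
maximum likelihood can drive one mixture component toward a point mass at
the outlier's rate — the fit warns below 20 cells, and EB05 values that
nearly equal EBGM are the visible symptom. With databases of thousands of
cells, where MGPS is meant to live, this does not occur.

**Signal criteria.** The default quartet is the standard one in the
FAERS disproportionality literature: ROR lower bound > 1 with `n ≥ 3`;
`PRR ≥ 2 ∧ χ² ≥ 4 ∧ n ≥ 3`; `IC025 > 0`; `EB05 > 2`. A term is a
combined signal only if all four hold simultaneously, which by
construction can never flag more terms than the most specific single
criterion. All cut-offs are configurable via `signal_thresholds()`.

## Recovering 2×2 tables from published statistics

Published signal tables usually print `n`, ROR with CI, and χ² — but not
`b`, `c`, `d`. Those three quantities determine the cells:
`invert_published_stats()` eliminates `d` through the ROR equation and
solves the Woolf-variance and χ² equations for `(log b, log c)` by
multi-start Nelder–Mead. Two caveats are inherent to the problem rather
than to the solver. First, every equation is symmetric under swapping
`b` and `c`, so solutions come in transpose pairs; the branch with
`c ≥ b` is returned, which is the generic configuration in a
spontaneous-report database (comparator events outnumber the target
drug's other events). Second, the printed inputs are rounded, which makes
the system slightly inconsistent and leaves the comparator scale on a
flat residual ridge; the search is bounded to database-plausible
magnitudes, the attained residual is reported, and the quantities read
off the solved table that are actually of interest — PRR and
`log2(a N/(n1 n2))` — are insensitive to position along the ridge. With
exact (unrounded) inputs the round trip recovers the generating table to
well below 0.1%.

## Time-to-onset and the Weibull model

TTO is the day count from the earliest fully specified therapy start date
of the target drug to the event onset date. Partial or missing dates and
negative intervals are excluded, with per-reason counts attached to the
result. Summaries use median-unbiased quantiles (`type = 8`) and 30-day
bins with the first bin `[0, 30]` closed on both ends so same-day events
count as first-month.

The Weibull fit maximizes
`Σ[ln β − β ln α + (β−1) ln t − (t/α)^β]` by profiling: for fixed shape
the scale MLE has the closed form `α(β)^β = mean(t^β)`, leaving a 1-D
search over `log β` (solved to 10⁻¹² by `optimize()` from a Gumbel
moment start). This makes the score identity hold to machine precision
and the fit exactly scale-equivariant. Zero onset days are replaced by
0.5 day — the Weibull support is `t > 0`, same-day onsets are real, and
the half-day substitution is the smallest documented perturbation that
keeps them in the sample. 95% intervals are Wald on `(log α, log β)`
from the inverse observed information (a likelihood-ratio interval would
also be defensible; the Wald-on-log choice is the documented default and
is what the coverage simulations exercise). The hazard pattern is
classified from the shape interval: *early failure* when it lies
entirely below 1, *wear-out* entirely above, *random* otherwise. No
censoring model is used: spontaneous reports are realized events, not
at-risk times, so the fit is an unconditional description of reported
onsets, not a survival analysis.

## The synthetic generator

`generate_database()` exists so every downstream stage has known ground
truth. It emulates, per report: demographic margins (sex, age band,
country, reporter occupation, outcome codes, reporting year) whose
defaults follow the published descriptive profile of a recent
hyperkalemia-drug cohort (male 48.44%, US 76.6%, death outcome 51.61%,
reporting years 2018–2023, ...); one target drug (with spelling variants
resolved by the shipped synonym map) plus a background drug pool, extra
drugs per report via 1 + Poisson(1); reactions drawn per term as
independent Bernoulli with probability `base_rate` (Zipf-like by
default), multiplied by a planted relative rate λ for target-drug
reports and capped at 1, with a categorical rescue draw guaranteeing at
least one reaction per report; onset times from a planted
Weibull(shape 0.62, scale 95.51 days) by default, rounded to whole days
because dates are calendar days; duplicate case submissions (70% earlier
FDA_DT, 20% tied date with lower PRIMARYID, 10% blank FDA_DT — one
planted duplicate per branch of the deduplication rule); and partial
dates by truncating a configurable fraction of event/therapy-start dates
to `YYYYMM`/`YYYY` or blank. A single seeded generator drives
everything; identical seeds give byte-identical files.
`planted_truth()` returns the exact per-term expectation of the `a` cell
under this model (including the rescue-draw correction), which the
moment tests check against an independent re-derivation.

What the generator does *not* emulate — and what passing tests therefore
do not demonstrate about real data: misspelled or free-text drug names
(real pipelines need name normalization far beyond a synonym table),
correlated reaction terms within a report (terms are drawn
independently), country-specific reporting lags, indication and
report-source tables, secular trends in reporting rates, and
event-dependent duplicate content (duplicates are faithful copies). Null
behaviour, margin recovery and planted-signal detection on this
generator validate the *computational* pipeline, not the epidemiology of
any particular drug.

## Numerical choices and degenerate inputs

* Zero cells: 0.5 added to all four cells for ROR/PRR only, flagged;
  χ² and IC operate on raw counts; EBGM needs no correction.
* χ² Yates subtraction capped at `|O − E|` (the `chisq.test()`
  convention); plain χ² available and both conventions are attempted by
  the inversion utility.
* Half-up rounding to two decimals for published-style percentages
  (base `round()` is half-even); denominators are reports for
  demographic blocks and outcome *entries* for the outcome block, since
  a report may carry several outcome codes — the only denominator under
  which the published percentages re-derive from their counts.
* MGPS optimization rejects iterates with `|log parameter| > 25` before
  the negative-binomial density can overflow; EB05 root-finding brackets
  by component gamma quantiles and tolerates 10⁻¹⁰.
* Deduplication treats any unparseable FDA_DT as minus infinity; ties
  beyond (date, PRIMARYID) cannot occur since PRIMARYID is unique.
* Empty case sets warn (selection) or error (description) rather than
  silently producing empty output; pipeline stages report which stage
  failed.

## Problem sizes exercised by the test suite

The suite validates margins at 50,000 simulated reports; end-to-end runs
at 5,000–20,000 reports; formula-oracle equivalence on 1,000 random
tables (10⁻¹⁰ for ROR/PRR/χ² against direct evaluation, 10⁻⁶ for
EBGM/EB05 against quadrature of the posterior); MGPS recovery on 5,000
cells simulated from a known prior (marginal log-likelihood within 2
units of the generating prior's, cellwise EBGM correlation above 0.99);
and Weibull interval coverage over 500 replicates of 240 draws in the
early-failure regime (shape 0.62), the sample size and regime of the
published onset analyses this pipeline is patterned on.

## Known limitations

Disproportionality quantifies reporting, not risk: no denominator of
exposed patients exists, and no causal claim follows from any flag this
package raises. No multiplicity adjustment is applied across terms (the
combined four-algorithm criterion is the field's pragmatic specificity
device). The MGPS fit is unstratified; age/sex-stratified expected
counts are a possible extension. The BCPNN implementation is the
closed-form approximation, not the full propagation network. The
inversion utility assumes the published CI is a Woolf interval computed
with z = 1.96; intervals from other methods will show up as a large
reported residual rather than a wrong table.
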