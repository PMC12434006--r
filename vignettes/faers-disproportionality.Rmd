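---
title: "Disproportionality signal detection in FAERS: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disproportionality signal detection in FAERS: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(faersdispro)
```

This vignette documents the statistical model, the data-handling rules, and
the design decisions behind `faersdispro`. The running application is the
safety profile of immune-checkpoint-inhibitor (ICI) therapy: four
monotherapies (ipilimumab, nivolumab, durvalumab, tremelimumab) and the two
approved combinations (ipilimumab+nivolumab, durvalumab+tremelimumab),
compared within a six-group background of ICI-treated cases drawn from
FAERS.

## 1. Data model and cleaning

FAERS quarterly packages are `$`-delimited ASCII tables (DEMO, DRUG, REAC,
OUTC, THER) with one header line and no quoting mechanism. The reader
matches header names case-insensitively, ignores extra columns, and counts
lines with the wrong field count as *malformed* rather than dropping them
silently, so `records + malformed = data lines` always holds. Because the
dialect has no escape character, the writer replaces literal `$` in free
text by `/`; round-tripping the sanitized form is exact.

Dates in FAERS are frequently partial (`YYYY`, `YYYYMM`). We store them as
strings and parse components on demand: partial dates are usable for year
tabulations but compare as missing for arithmetic (onset times). For the
deduplication sort only, missing month/day are treated as zero so the order
is total and deterministic.

**Deduplication.** A FAERS case (CASEID) accumulates versions (PRIMARYID);
the cleaning rule sorts by CASEID, FDA_DT, PRIMARYID and keeps the last
record per case — i.e. the latest FDA receipt date, with the larger
PRIMARYID breaking ties (numeric comparison when both ids are numeric,
lexicographic otherwise). The operation is idempotent and independent of
input order, which the tests verify against a brute-force group-by-argmax
oracle. **Deleted reports** (quarterly withdrawal lists, available since
2019Q1) are removed *after* deduplication, by CASEID; lists from all
quarters are unioned first, because a case withdrawn in a later quarter
must not survive from an earlier one. Each stage logs a record count, so
any run produces the familiar filtering funnel.

## 2. Cohort construction

Only suspect roles decide group membership. With P the set of canonical
study drugs among a case's Primary-Suspect (PS) records and S the set with
role PS or SS:

- monotherapy: P names one study drug and S contains no other study drug;
- combination: every PS study drug belongs to the partner pair and S is
  exactly the pair (the partner may be recorded as SS or as a second PS —
  real reports do both);
- everything else, including a non-study PS drug, three or more study
  suspects, or a case with no PS record at all, is `OTHER` and excluded
  from the background.

Concomitant (C) and interacting (I) roles never create a combination: a
patient on nivolumab with ipilimumab listed as concomitant is a nivolumab
monotherapy case. This suspect-only reading is the conservative choice when
the provenance of dual-therapy labels is not recorded explicitly.

Drug names are normalized by case-insensitive substring matching against a
synonym table seeded with the generic and US brand names (Yervoy, Opdivo,
Imfinzi, Imjudo); the active-ingredient field is consulted when the
verbatim name fails. Matching by substring is deliberate: FAERS names carry
dose suffixes, punctuation, and bracketed ingredient annotations.

## 3. Baseline description

Baseline tables are computed at patient level, pooling the four
monotherapy groups as sICI and the two combinations as DIG. For each
categorical variable we report counts, column percentages, and an
association statistic: Pearson's chi-square **without continuity
correction** and Cramér's V = √(χ²/(N·(min(r,c)−1))). The continuity
correction is omitted deliberately — with N in the tens of thousands it is
negligible anyway, and omitting it is what makes near-null published values
(e.g. a disability outcome with V = 0.004, p = 0.411) exactly reproducible
from printed counts. At these sample sizes nearly every comparison is
"significant"; V is the number to read, which is why both are always
reported together.

Ages are converted to years from the FAERS unit codes (DEC ×10, YR ×1,
MON ÷12, WK ÷52, DY ÷365.25, HR ÷8766); a missing unit with a present age
is read as years, the dominant FAERS convention. Age bands are closed-open:
[0,18), [18,45), [45,65), [65,75), [75,∞).

A case is *serious* iff it has at least one OUTC record; outcome flags
(death, life-threatening, hospitalization, disability, congenital anomaly,
required intervention, other) are presence flags per code. Onset time is
the difference between the case's event date and the earliest full therapy
start date among its PS-drug therapy records; either date partial or absent
gives a missing onset. Negative onsets (event before recorded start) occur
in real data; they are kept in the quantitative summaries by default —
mirroring summaries that impute and retain sub-zero durations — but always
excluded from the banded tables, and a `negative_onset` flag travels with
every value. Setting `include_negative_onset = FALSE` switches the
quantitative block to the strict reading.

Country counts use the occurrence country with reporter-country fallback;
whether published country shares use patients or reports as denominator is
ambiguous in the literature we mirror, so we count patients and say so.

## 4. Signal statistics

Counting for disproportionality is at **AE-record level** (one REAC row =
one record), not patient level; patient-level counts are carried alongside
in the output for context. For a target group and PT, the comparator is
the rest of the six-group background — a case/non-case design *within* the
ICI-treated population, so signals express excess reporting relative to
other ICI regimens, not relative to all of FAERS. (A full-database
comparison is a different scientific question; the module boundary makes it
easy to pass different assignments if that is wanted.)

**ROR.** ROR = (a·d)/(b·c) with the Wald interval
exp(ln ROR ± 1.96·√(1/a+1/b+1/c+1/d)); 1.96 is fixed, not a software
default. With any zero cell the Haldane correction adds 0.5 to all four
cells and the row is flagged; an all-zero table is marked not computable.

**IC.** The default information component is the gamma-shrinkage
observed/expected form: E = (a+b)(a+c)/N, IC = log₂((a+0.5)/(E+0.5)),
IC₀₂₅ = log₂ of the 2.5% quantile of Gamma(shape a+0.5, rate E+0.5). It is
unambiguous, needs no zero-cell correction (the +0.5 is built in), shrinks
toward 0 (independence), and converges to log₂(a/E) as counts grow — all
properties the test suite checks, including agreement with a Monte-Carlo
posterior quantile. The closed-form BCPNN of the original
neural-network formulation (priors centred on independence;
IC₀₂₅ = E[IC] − 1.96·sd[IC]) is selectable with `ic_method = "bate"`;
the two agree closely at large counts but differ in small cells, and
published IC values computed with unstated variants should not be expected
to reproduce exactly under either.

**Joint rule.** positive ⇔ a ≥ 3 ∧ ROR₀₂₅ > 1 ∧ IC₀₂₅ > 0. Requiring both
methods trades sensitivity for a lower false-positive rate; on null
synthetic data the empirical positive rate is well under 5% (the suite
measures it). A not-computable component always yields a negative flag.

**p-values.** Pearson chi-square without continuity correction, switching
to two-sided Fisher's exact when any expected cell is below 5 (the method
used is recorded per row). Benjamini–Hochberg adjustment is applied within
one drug group's PTs as the testing family, matching per-group reporting;
adjusting across groups would mix families of very different sizes.

## 5. SOC aggregation

PT→SOC mapping is user-supplied (MedDRA is licensed). Validation enforces
unique (PT, SOC) pairs and exactly one primary SOC per PT. Positive PT
*types* are counted once each under the primary SOC — multiaxial
secondary links are ignored, since per-SOC type counts with multi-counting
would double-book PTs. Unmapped positives land in an explicit `UNMAPPED`
bucket rather than vanishing.

## 6. The synthetic generator

The generator emits complete FAERS-dialect packages with known truth, so
every pipeline stage is testable without downloads. Its defaults are
calibrated once to the published ICI cohort and are not tuning knobs:

- group weights proportional to the published subgroup sizes
  (7,386/29,544/5,278/25/12,256/563 of 55,052), with 20% of cases assigned
  to a non-study `OTHER` stratum;
- AE records per case 1 + Poisson(1.14), matching ≈2.14 records per
  patient (118,001 AEs / 55,052 patients);
- sex, age-band, reporter-occupation, reporting-year and country marginals
  from the published totals; seriousness 86% with per-code conditional
  flag rates;
- onset log-normal with median 50 d (sdlog 1.558, from the published IQR
  16–131) for monotherapy and 36 d (sdlog 1.310, IQR 14–82) for
  combinations; 76% of cases lack a usable start date;
- 15% of cases re-emitted as a superseded earlier version (the published
  funnel removes ≈14.9% of raw records as duplicates) and 1% placed on the
  deletion list (a rate the literature does not report; chosen small);
- a 30-PT vocabulary over 12 SOC-like classes with baseline probabilities
  renormalized per group after applying planted multipliers λ: the
  per-record PT distribution of group g is p(pt|g) ∝ baseline(pt)·λ(g,pt).

Planted multipliers act multiplicatively on reporting rates, so for a rare
PT the expected ROR approximately equals λ, and `expected_table()` gives
the exact expected fourfold cells in closed form — the analytic oracle the
tests compare observed cells against (within 4 Poisson standard
deviations).

What the generator does **not** emulate: correlated PTs within a case
(records are i.i.d. multinomial draws), drug-name noise beyond simple
case/brand/suffix variation, indication and dose fields, reporting-rate
drift over calendar time, or same-patient duplicates under *different*
CASEIDs. Passing recovery tests therefore demonstrates correctness of the
statistical machinery under a clean reporting model, not robustness to
every real-world FAERS artifact — fuzzy cross-case duplicate detection in
particular is explicitly out of scope.

## 7. Numerical choices and degenerate inputs

- Deterministic tie-breaks everywhere: the dedup sort is total; PT tables
  are ordered by descending a then PT name.
- `cramers_v()` drops all-zero rows/columns with a warning and refuses
  tables with fewer than two non-degenerate levels.
- Degenerate fourfold margins give p = 1 and a `degenerate` method marker;
  the signal flag is false whenever any component is not computable.
- All randomness in the generator flows from one integer seed; the same
  config writes byte-identical files.

## 8. Problem sizes used in the checks

The bundled checks run at sizes chosen to make sampling error negligible
relative to the tolerances: oracle equivalence on 1,000 random tables at
1e-9; IC₀₂₅ against 10⁶ Monte-Carlo draws within ±0.05; signal recovery on
20,000-case synthetic runs (planted λ ≥ 4 pairs with expected a ≥ 30:
sensitivity ≥ 0.9 and null positive rate < 5%; a lone λ = 5 rare pair
recovers ROR in [3.5, 7]); onset-median recovery at ≥5,000 non-missing
onsets within 10%. Unit tests use smaller cohorts (600–8,000 cases) where
only structural properties are at stake.

## 9. Known limitations

- Substring drug matching can over-match pathological names containing a
  brand string; the synonym table is small and auditable by design.
- The background-restricted comparator means signals are relative to other
  ICI regimens; rates relative to all of FAERS require a different
  assignment table.
- Patient-level seriousness follows the report: a case without OUTC rows
  is non-serious by definition, which undercounts seriousness where
  outcomes simply went unreported.
- No probabilistic duplicate detection across CASEIDs, no legacy (pre-2012)
  LAERS schema support, no automated FAERS download.
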