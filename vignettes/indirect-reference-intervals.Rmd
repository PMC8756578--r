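---
title: "Indirect pediatric creatinine reference intervals: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Indirect pediatric creatinine reference intervals: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(creatref)
```

## The problem and the approach

Serum creatinine is the workhorse index of renal function, but its healthy
range in children moves every year: creatinine tracks muscle mass, which
rises steadily from infancy through adolescence and diverges between the
sexes once androgen-driven growth begins. Broad age bands ("under 4 years")
therefore hide clinically meaningful shifts, and a fixed pediatric cutoff
underestimates kidney injury in infants and toddlers.

Direct reference-interval studies recruit healthy volunteers; for children,
drawing blood from thousands of healthy subjects is rarely feasible.
`creatref` implements the *indirect* alternative: start from routinely
collected hospital laboratory data and filter it until what remains behaves
like a reference population. The filtering chain is:

1. **Eligibility.** Measurements drawn between 1 month (30 days) and the 18th
   birthday. Neonates are excluded — their creatinine initially reflects the
   maternal level and falls throughout the first weeks of life, so no stable
   reference exists for that window.
2. **Single-measurement selection.** Children measured repeatedly during the
   study window are presumed to be under renal follow-up (acute kidney
   injury, chronic kidney disease, cardiac surgery, intensive care) and are
   excluded *as individuals*. A child measured once was typically measured
   incidentally, and is the best available proxy for "healthy".
3. **Stratification.** 36 strata: per sex, one infant bin (1–12 months) and
   seventeen 1-year bins. Windows are half-open (`>=1 to <2 years`), with
   yearly edges at multiples of 365.25 days.
4. **Upper-fence trimming.** Within each stratum, values strictly above
   Q3 + 1.5·IQR are removed in a single pass (Tukey's rule, upper side
   only). This catches sick children who happened to be measured only once.
   Low values are never trimmed: a low creatinine is not evidence of disease
   here, and the clinically actionable limit is the upper one.
5. **Estimation.** Within each trimmed stratum the values are treated as
   normal (empirically defensible for same-age children after the filtering
   above): mean, sample SD (n−1), parametric limits mean ± 1.96·SD, and
   order-statistic P2.5/P97.5. The reported reference interval is the
   parametric one; the empirical percentiles are kept alongside as a check.
   Strata below 120 individuals — the IFCC minimum for establishing
   reference values — are flagged.

## Tunable parameters

All constants live in one `pipeline_config()` object:

| parameter | default | meaning |
|---|---|---|
| `fence_multiplier` | 1.5 | IQR multiple above Q3 for the upper fence |
| `z_value` | 1.96 | normal multiplier for the central 95% (the conventional constant, deliberately not `qnorm(0.975)`) |
| `min_group_n` | 120 | IFCC adequacy threshold per stratum |
| `rounding_decimals` | 2 | reporting precision, 0.01 mg/dL |
| `quantile_method` | `"linear"` | quantile interpolation rule (below) |
| `age_lower_days` | 30 | eligibility lower bound ("1 month") |
| `age_upper_years` | 18 | eligibility upper bound (exclusive) |
| `outlier_floor_n` | 4 | smallest stratum the fence is applied to |
| `collapse_same_day` | `FALSE` | whether same-day duplicate draws count once |
| `multiplicity_scope` | `"eligible"` | count repeat measurements after or before the age filter |

## Numerical choices

**Quantile estimator.** Quartiles and empirical percentiles default to
linear interpolation at h = (n−1)p (`stats::quantile` type 7), the
spreadsheet-default rule — the natural choice for an analysis designed to be
reproducible in ordinary spreadsheet software. Tukey-hinge–style
(`"hinges"`, type 2) and nearest-order-statistic (`"nearest"`, type 3) rules
are selectable for sensitivity analysis; at the stratum sizes involved
(hundreds to thousands) the choice moves limits by far less than the
reporting precision.

**Fence semantics.** The fence is computed once on the stratum and applied
once; it is *not* recomputed after removal, so a second application could
remove more. Removal uses a strict inequality (only values *above* the
fence), the minimum always survives, and the fence is always per-stratum,
never pooled. Strata smaller than `outlier_floor_n = 4` are flagged and left
untrimmed — a fence from three points is noise (real use never hits this;
the smallest real stratum the method was designed around had 371
individuals).

**Rounding.** Reported values use half-away-from-zero rounding
(`round_limit()`), the clinical-reporting convention, not R's
round-half-even; the implementation guards against binary representation
noise (`0.145 * 100` is fractionally below 14.5 in floating point). Tests
that compare reported concentrations do so in integer hundredths, because
differences of rounded doubles (e.g. `0.61 - 0.63`) carry 1e-17-scale noise.

**Age arithmetic.** Ages are exact calendar-day differences. The infant bin
is `[30, 365.25)` days rather than `[30, 365)`: yearly bin edges sit at
365.25-day multiples, and aligning the infant bin's upper edge with the
1-year edge makes the 36 windows an exact gap-free tiling of
[30 days, 18 years) — otherwise whole-day age 365 would belong to no
stratum.

**Open choices made explicit.** Same-day duplicate draws count as multiple
measurements (repeat draws on one day signal monitoring, the very thing the
exclusion targets); `collapse_same_day = TRUE` reverses this. Multiplicity
is counted over age-eligible records (`multiplicity_scope = "eligible"`),
matching a retrieval that applies the age window first; `"all"` counts
repeat draws anywhere. The displayed P2.5/P97.5 are the parametric limits;
empirical ones are in the estimates tibble.

## The synthetic cohort generator

No public pediatric EHR creatinine database exists, so every pipeline stage
is validated against `generate_cohort()`, whose defaults emulate the
population the method was built for: ~44,200 children producing ~152,000
measurements, of whom 28,595 are measured once; repeat-measured individuals
average ~7.9 draws (counts 2 + Poisson(5.9)); 20% of repeat-measured
individuals carry a persistent multiplicative creatinine elevation with
median factor 2 (factor = 1 + Lognormal(0, 0.5), always > 1 — an AKI/CKD
follow-up model); and 2.1% of single-measurement individuals carry a
kidney/urinary diagnosis flag *independent of their value*, mimicking
incidental coding in otherwise healthy children.

Healthy draws sample a normal distribution per age/sex stratum, truncated at
0.01 mg/dL and quantized to 0.01 mg/dL (laboratory resolution); the default
true means and SDs are the bundled reference table
(`default_group_params()`), so a default run reproduces a realistic
reference table end to end. Strata are sampled with weights proportional to
that table's n column, which reproduces realistic stratum sizes and the
~55% male share; `age_law = "uniform"` instead draws ages uniformly over
the window. Draw dates are uniform over a fixed 2011–2018 window with birth
dates back-computed; repeat draws are spaced days to weeks apart and share
the individual's elevation state.

What the generator deliberately does **not** emulate: secular and assay
drift, within-child biological correlation beyond the elevation state,
mixed healthy/sick single-measurement children (its single-measurement pool
is clean apart from value-independent flags), non-normal tails, and
informative missingness. Consequently the clean-cohort fence removes ~0.4%
of values (the one-sided normal tail beyond ~2.7 SD), below the low
single-digit percentages seen in real hospital data where residual
pathology thickens the upper tail. Passing recovery tests therefore show
the *machinery* is correct under the model's assumptions, not that any
particular hospital's data meets them.

## What the tests establish

Worked-example tests pin the desk arithmetic to the bundled reference table
(e.g. 0.61 + 1.96·0.09 → 0.79 mg/dL after rounding; adolescent male−female
URL differences spanning 0.11–0.23 mg/dL; a known external URL series
reverting at exactly its marked age bins). Property tests cover the fence
invariants, scale equivariance, shift equivariance, the partition property
of stratification, and agreement of all quantile paths with a brute-force
sort-and-interpolate oracle on 1,000 random vectors.

The stochastic recovery suite generates ten clean cohorts of 27,911
single-measurement children (stratum sizes 371–2,227) and ten contaminated
full-scale cohorts (~152,000 measurements), and requires the median number
of strata whose rounded limits land within 0.02 mg/dL of the rounded truth
to be at least 34 of 36 in both arms. The 0.02 mg/dL tolerance is the
resolvable scale at these stratum sizes: the sampling SE of mean ± 1.96·s is
0.003–0.009 mg/dL, so agreement of 2-decimal rounded values cannot be exact
in every stratum, while 0.02 separates cleanly from the contamination
signal (elevated individuals shift naive limits by ~0.1 mg/dL or more). The
contaminated arm passing at the clean-arm level is the design's core claim:
single-measurement exclusion plus the fence screens follow-up pathology out
of the reference population.

## Known limitations

- mg/dL only; no µmol/L conversion.
- Strictly binned limits; no continuous age-smoothing across bins.
- No eGFR, no AKI staging, no neonatal support.
- The indirect design inherits hospital-population bias: limits describe
  children measured at a hospital, filtered to look healthy — not a
  population sample. The diagnosis-flag sensitivity comparison
  (`sensitivity_compare()`) quantifies one facet of that risk, not all of it.
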