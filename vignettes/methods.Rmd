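---
title: "Methods: scoring, prescription and follow-up logic in cvhrx"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scoring, prescription and follow-up logic in cvhrx}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cvhrx)
```

`cvhrx` is the computational core of a point-of-care behavior-change
workflow for adolescents with overweight or obesity. This vignette explains
the models and rules it implements, the parameters that matter, and the
design choices made where the underlying clinical material leaves the
design open.

## Cardiovascular health scoring

The seven Life's Simple 7 factors — BMI percentile, blood pressure,
cholesterol, glucose, smoking, physical activity, diet — are each rated
ideal / intermediate / poor (green / yellow / red; 2 / 1 / 0 points). The
total is divided by the maximum attainable, 2 points per *available*
factor, so a complete profile is scored out of 14 and a factor with no
recorded value shrinks the denominator rather than counting against the
patient. The score is stored as a fraction in [0, 1]; rendering it as a
percentage or as "T/14 points" is a display concern.

### Cut-points

The shipped cut-point table (`inst/extdata/cutpoints_default.yaml`) uses
AHA-style pediatric conventions:

| factor | ideal | intermediate | poor | units |
|---|---|---|---|---|
| BMI percentile | < 85 | 85–<95 | ≥ 95 | percentile |
| blood pressure | <120 and <80 | <140 and <90 | ≥140 or ≥90 | mmHg (sys/dia) |
| cholesterol | < 170 | 170–199 | ≥ 200 | mg/dL |
| glucose | < 100 | 100–125 | ≥ 126 | mg/dL |
| smoking | never | former | current | category |
| physical activity | ≥ 420 | 1–419 | 0 | min/week MVPA |
| diet | 4–5 | 2–3 | 0–1 | healthy components |

Boundary convention is half-open toward the worse category: a value equal
to a boundary lands in the worse-adjacent band (cholesterol 170 is
intermediate). Blood pressure takes the worse of the systolic and
diastolic bands; a percentile-by-height blood-pressure computation is
deliberately out of scope — callers supply mmHg or a precomputed category.
The whole table is configuration, not code: any table with the same schema
can be loaded, and validation rejects unordered boundaries or an
incomplete categorical map. The three-level smoking map (never / former /
current) reflects the distinction clinics ask for between former and
never smokers.

`what_if()` implements the interactive "slider": it rescores a copy of the
profile with one factor changed and returns a fresh score object, leaving
the input untouched. Because each factor contributes its points
independently, raising one factor by one category raises the total by
exactly one point — a property the test suite verifies exhaustively over
all 3^7 category assignments.

Willingness-to-change items are carried alongside the profile for the
clinical conversation but never alter the score and never auto-prioritize
recommendations; automatic prioritization is a known limitation of the
underlying design, not a feature to emulate silently.

## BMI-for-age via the LMS method

BMI is converted to a z-score against a growth reference parameterised by
the Box-Cox power L, median M and coefficient of variation S:
z = ((x/M)^L − 1)/(L·S), with the log-limit ln(x/M)/S at L = 0 (numerically,
|L| < 1e-12). Parameters are interpolated linearly in age (months) between
table rows — reference tables are monthly or finer, so linear error is
negligible — and interpolation is exact at the knots. Percentiles are the
standard-normal CDF of z on a 0–100 scale.

Weight-status categories: underweight < 5th percentile, healthy 5–<85th,
overweight 85–<95th, obese ≥ 95th, and severe obesity at BMI ≥ 120% of the
95th-percentile BMI — the standard US pediatric convention for the
severe tier; no severe-obesity definition was fixed upstream, so this
choice is documented here rather than presented as a clinical constant.

The package ships a *synthetic* LMS table
(`inst/extdata/lms_reference_synthetic.csv`) covering 144–240 months for
both sexes, generated from smooth parametric curves (M rising ~19→22.8
kg/m² for boys, ~19.4→22.2 for girls; L ≈ −2, S ≈ 0.13). It has the CDC
table's schema and plausible magnitudes but is not fitted to population
data: tests and demonstrations run offline against it, and a real CDC 2000
table should be supplied for clinical use. Extended/modified z-scores above
the 97th percentile are out of scope.

## Physical-activity prescription

Starting doses come from a 3 × 4 matrix keyed by obesity level
(overweight / obese / severe obese) and activity status (inactive /
somewhat / moderately / active). The published description fixes the
matrix's *structure* and one ordering constraint — severely obese,
inactive patients start with shorter durations and no greater frequency
than overweight, inactive patients — but not its numbers, so the shipped
values (20 min × 3/wk at the most conservative cell up to 45 min × 5/wk)
are documented placeholders satisfying that constraint; the constraint is
re-checked whenever a user-supplied matrix is loaded.

Activity status uses thresholds 0 / 1–149 / 150–299 / ≥300 min/week MVPA,
anchored to the familiar 150/300 guideline landmarks; they are
configurable.

Weekly goals progress geometrically: d₁ = minutes × sessions from the
starting cell, d_{w+1} = min(round(d_w × r, 0.1 min), cap) with r = 1.10
(+10% per week) and cap 420 min/week (60 min/day). Sessions per week stay
at the starting cell's value; only total weekly minutes ramp. With the cap
disabled the trajectory matches the closed form d₁·r^(w−1) to within
cumulative rounding. Whether diet goals should also ramp was left
unspecified upstream; here only activity progresses and diet goals hold,
with message tone carrying the encouragement.

The activity menu is data (YAML) with Compendium-style MET values; each
entry's intensity label must equal its MET-band classification (light
< 3.0, moderate 3.0–<6.0, vigorous ≥ 6.0) at load time. Regional pruning
(e.g. dropping coastal activities inland) is tag-based exclusion, keeping
content edits out of code. Patient choice of activities is mandatory in
`generate_pa_plan()` — choice is the intervention's motivational mechanism,
not an optional nicety.

## Stoplight diet logic

Five screener behaviors — fruit, vegetables, whole grains, sugar-sweetened
beverages, snacking — are each answered healthy/unhealthy; a behavior is
flagged iff its answer fails the healthy criterion, and exactly one
recommendation is generated per flagged behavior (never for unflagged
ones). Each recommendation carries the behavior's green "anytime" /
yellow "sometimes" / red "rarely" food lists from an editable YAML
library plus an autonomy-supportive goal statement. An optional
`max_behaviors` cap focuses on the first flags in survey order, mirroring
the clinical practice of targeting a limited number of changes.

## Community resources

The online map-and-directions service is replaced by an offline catalog
(GeoJSON FeatureCollection or CSV) over nine resource categories, each
with a distinct display color. Queries use great-circle (haversine)
distance on a sphere of radius 6371.0 km as the accessibility proxy;
results are filtered by category and radius (default 8 km ≈ 5 miles),
sorted by distance with ties broken by name then catalog order, and
truncated to k (default 10). Invalid catalog records are rejected
individually with line-level diagnostics instead of failing the load.
Geocoding, travel-time routing and live business data are out of scope.

## Follow-up loop

Three check-ins are scheduled at monthly intervals after the visit —
reconciling the stated monthly reporting cadence with the three-message
design over a three-month window; both count and cadence are parameters.
Month arithmetic clamps at month end (Jan 31 → Feb 28), verified against
an independent calendar library in the tests.

Adherence responses on a 5-point Likert scale map to goal multipliers:
≥ 4 advances the goal ×1.10 (matching the weekly progression), 3 holds,
≤ 2 eases ×0.90; results round to 0.1 min and clamp to [initial goal,
cap]. The numeric mapping is this package's design choice to make goals
"progressive and attainable"; it is overridable. Physical-activity and
diet adherence are handled independently, and diet has no numeric dose —
only message tone varies.

All patient-facing text passes an autonomy-supportive language lint:
case-insensitive, word-boundary matching against a controlled lexicon
(default "should", "must", "have to", "need to" — so "shoulder" passes).
Shipped message templates are linted at load time; rendered messages are
linted again after placeholder substitution. Delivery is a stub that
appends JSON-lines records — no email/SMS transport.

## Prescription document

The document model is JSON-first: four sections (goals, selected
activities, resources, education) that always exist even when empty, with
text and HTML renders as deterministic projections. HTML uses one
green/yellow/red stoplight table per diet recommendation. Education blocks
are selected by flagged behavior plus a general activity block and a
family block; "appropriate literacy level" has no agreed metric upstream,
so the package keeps blocks short and plainly worded rather than enforcing
a readability score. Satisfaction summaries are the unweighted mean of
1–5 Likert item means, reported to one decimal.

## Synthetic cohort

`generate_cohort()` emulates the tool's intended population: ages uniform
on 144–239 months, BMI-for-age z ~ N(1.5, 0.6) (skewing toward
overweight/obesity so most synthetic patients are eligible), heights from
sex/age-typical normal curves, and weights back-solved from the sampled z
through the LMS reference — guaranteeing the forward computation recovers
the sampled z to numerical precision (|Δz| < 1e-6 in tests). Sampled z is
truncated at |z| ≤ 3.5 and kept strictly inside the Box-Cox representable
range (1 + L·S·z > 0), since a negative-L reference cannot represent
arbitrarily extreme z. Lab factors (blood pressure, cholesterol, glucose,
smoking) are masked unavailable at rate 0.1 each; MVPA is log-normal with
median 90 min/week; each diet behavior is a problem with probability 0.5.
These defaults are invented for testing and are not epidemiological
claims.

Each patient draws from its own counter-derived RNG substream, so record i
is identical regardless of cohort size, and a fixed seed reproduces the
serialized cohort bit-for-bit. Eligibility is age 144–239 months *and*
BMI percentile ≥ 85, with reason codes for failures.

What passing tests show — and what they do not: the suite verifies the
scoring algebra, progression arithmetic, rule logic and file contracts on
synthetic data with idealized structure (independent factors, clean
values, no measurement error, no missingness beyond the availability
mask). It says nothing about real patients' behavior change or weight
outcomes, which require the clinical trial the tool was built to support.

## Problem sizes and numerical choices

Test and acceptance runs use: exhaustive enumeration of all 2,187 category
profiles and all 32 screener flag sets; 1,000 random 12-response goal
sequences; cohorts of 25–2,000 patients (2,000 for the z-recovery check,
500 for acceptance summaries). Goals and weekly minutes round to 0.1 min;
distances report to 0.01 km; percentiles to one decimal; the L = 0 branch
triggers below |L| = 1e-12. Ties in resource ranking break
deterministically (distance, then name, then catalog order) so queries are
reproducible across platforms.
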