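# cvhrx

Offline clinical decision support for adolescent preventive cardiology.
`cvhrx` implements the computational core of a point-of-care behavior-change
workflow for adolescents (12–19 years) with overweight or obesity: it scores
cardiovascular health, turns the score into a tailored physical-activity and
diet prescription, matches nearby community resources, and drives an
automated follow-up loop — all as a tested, network-free R library with a
seedable synthetic patient generator.

## What it computes

**Cardiovascular health (Life's Simple 7).** Each of the seven AHA factors —
BMI percentile, blood pressure, cholesterol, glucose, smoking status,
physical activity and diet — is rated with pediatric cut-points as ideal
(green, 2 points), intermediate (yellow, 1) or poor (red, 0). The score is

  score = T / (2 × n_available),  T = Σ points,

so a complete profile is scored out of 14 points and missing factors shrink
the denominator instead of penalizing the patient. `what_if()` recalculates
the score for a hypothetical factor value without touching the profile —
the "slider" a clinician moves during the visit.

**BMI-for-age.** z-scores by the LMS method, z = ((x/M)^L − 1)/(L·S)
(ln(x/M)/S when L = 0), against any CDC-schema reference table; weight
status uses the 85th/95th-percentile bands with severe obesity at ≥120% of
the 95th-percentile BMI.

**Prescriptions.** Starting doses come from a 3×4 (obesity level × activity
status) matrix; weekly minutes then progress by +10% per week, capped at
420 min/week. Diet recommendations follow the Stoplight framework — green
"anytime", yellow "sometimes", red "rarely" food lists — generated only for
the screener behaviors a patient actually flags.

**Follow-up.** Three monthly check-ins after the visit; 5-point Likert
adherence responses advance (+10%), hold, or ease (−10%) the goal within
[initial goal, cap]; all patient-facing text passes an autonomy-supportive
language lint (no "should", "must", "have to", "need to").

## Worked example

```r
library(cvhrx)

profile <- risk_profile(
  bmi_percentile = 96, blood_pressure = c(118, 74), cholesterol = 162,
  glucose = 91, smoking = "never", physical_activity = 120, diet = 2)
compute_cvh_score(profile)
#> Cardiovascular health score: 10/14 (71%)
#>             factor     category points  color
#>     bmi_percentile         poor      0    red
#>     blood_pressure        ideal      2  green
#>        cholesterol        ideal      2  green
#>            glucose        ideal      2  green
#>            smoking        ideal      2  green
#>  physical_activity intermediate      1 yellow
#>               diet intermediate      1 yellow

what_if(profile, "physical_activity", 450)$score * 14
#> [1] 11   # one factor moved to ideal: 10 -> 11 points

plan <- generate_pa_plan("obese", "somewhat_active", "playing basketball")
head(plan$weeks, 3)
#>  week minutes_per_week sessions_per_week
#>     1             90.0                 3
#>     2             99.0                 3
#>     3            108.9                 3
```

The score says this patient has 10 of 14 attainable points, with BMI the
only red factor; the what-if shows that reaching 450 min/week of activity
would lift the score to 11/14. The plan starts at 90 min/week (30 min × 3
sessions) and grows 10% weekly toward the 420 min/week cap.

## Command line

A thin CLI over the same functions ships in `inst/cli/cvhrx.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/cvhrx.R", package = "cvhrx"))')" \
  simulate --n 20 --seed 7 --out cohort.csv
```

Subcommands: `score`, `prescribe`, `resources`, `schedule`, `checkin`,
`simulate`, `report`.

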