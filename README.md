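# habitr

Personalized activity and food suggestions from mobile-phone logs, plus
the statistics to evaluate whether they change behavior.

`habitr` is aimed at mobile-health and digital behavior-change
researchers who want to prototype and evaluate automated
suggestion-generation pipelines without deploying a phone app. It
implements the full chain from raw signals to recommendations:

1. **Activity recognition** — statistical features (mean, variance,
   zero-crossing rate per axis and magnitude) from tri-axial
   accelerometer windows, classified into walking / running / stationary
   / driving by per-class Gaussian mixture models.
2. **Life-log generation** — per-second labels are aggregated to minute
   majorities, merged into contiguous events, and short heterogeneous
   sequences within a 15-minute window become single "mixed" events
   (e.g. a walk–wait–bus–walk commute); food and manual exercise entries
   are interleaved chronologically.
3. **Behavior clustering** — stationary episodes cluster by place
   (single linkage, 150 m haversine threshold), walks and runs by
   trajectory shape (arc-length resampling to 32 points, mean point-wise
   distance, leader clustering; direction-sensitive), foods by Jaccard
   similarity of ingredient sets (meals and snacks kept apart).
4. **Suggestion engine** — a multi-armed-bandit exploit–explore scheme.
   Each day it emits 10 activity and 10 food suggestions: 9 exploit
   slots from frequent clusters ranked by projected weekly calorie
   impact, and 1 explore slot drawn from infrequent but demonstrated
   behaviors. The activity score is
   `frequency/week × per-instance kcal`, with per-instance calories from
   the METS formula `kcal = MET × weight(kg) × hours`. Stationary
   clusters compete through small-change suggestions — a 3-minute walk
   per stationary hour (12.25 kcal per episode at 70 kg). Frequent
   high-calorie meal clusters are framed as "avoid" suggestions outside
   the ranked slots. A 42-entry generic pool supports a nonpersonalized
   control arm.
5. **Trial statistics** — weekly-median trend classification (longer
   walks or lower meal calories week 1 → week 3 count as positive),
   exact Fisher 2×2 tests by hypergeometric enumeration, exact /
   normal-approximation Mann–Whitney U, and pooled two-sample t with
   Cohen's d.

A seeded synthetic-data generator (`simulate_user()`,
`simulate_trial()`) produces users with routine commutes, office days,
gym loops, and meals with known ground truth, so every stage is testable
end to end without any external data.

## Worked example

Simulate three weeks of one user's behavior, build their behavior
clusters, and generate a day's activity suggestions:

```r
library(habitr)

u  <- simulate_user(user_profile("u1", weight_kg = 70),
                    scenario_config(days = 21, seed = 5,
                                    gym_visits_per_week = 1.5),
                    sensors = FALSE)
cl <- cluster_lifelog(as_lifelog(u))
generate_daily_batch(cl, "activity", u$profile, engine_config(),
                     date = "2026-01-26")
#>   rank          arm target_cluster_id projected_weekly_kcal
#> 1    1 small_change          stat_001             1426.7452
#> 2    2      exploit          traj_001              666.5914
#> 3    3 small_change          stat_002              629.1913
#> 4    4      exploit          traj_002              586.7037
```

The top suggestion ("Add a 3-minute walk for every hour you spend
stationary near (42.4440, -76.5019)") targets the home-stationary
cluster: many weekly stationary hours × 12.25 kcal per 3-minute walk
projects ~1427 kcal/week, which outranks both the routine commute walk
(~667 kcal/week: 121 kcal per 30-minute walk, ~5.5×/week) and the
rarer, more intense gym run (~587 kcal/week). This user has only four
activity clusters, so the engine emits four suggestions and says so.

Simulate a 9-vs-8 two-arm trial with a +0.3 intervention effect
(longer walks, lighter meals from week 2) and run the analysis plan:

```r
tr  <- simulate_trial(9, 8, scenario_config(days = 21, seed = 42,
                                            intervention_effect = 0.3))
rep <- analyze_trial(tr)
rep
#> <trial_report>
#>   walk_length_minutes: Fisher p = 0.1312
#>              positive non_positive
#> experimental        8            1
#> control             4            4
#>   meal_kcal: Fisher p = 0.0824
#>              positive non_positive
#> experimental        9            0
#> control             5            3
rep$changes[, c("metric", "t", "df", "p_value", "cohens_d")]
#>   metric                  t    df  p_value cohens_d
#> 1 walk_length_minutes  4.06    15 0.00102      1.97
#> 2 meal_kcal            4.76    15 0.000254     2.31
```

Even with a strong planted effect, the exact Fisher test on 17 users is
often nonsignificant — the discrete test is conservative at this sample
size — while the pooled t test on week-3 minus week-1 median changes
(df = 15) detects the effect clearly. `autoplot(rep)` draws the weekly
medians per user with positive trends in green, and `tidy(rep)` /
`glance(rep)` return the per-user trends and per-metric Fisher p-values
as tibbles.

A thin command-line front end with `simulate`, `run`, `lifelog`,
`cluster`, `suggest`, `analyze` and `validate` verbs ships at
`inst/cli/habitr.R`.

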