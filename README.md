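# drgcost

Hospitalization-expense structure and determinants analysis for heart-failure
(ICD-10 I50.9) inpatient cohorts spanning China's staged DRG
(diagnosis-related group) payment reform.

Health-services researchers studying payment reform typically hold front-page
inpatient billing records — one row per admission with demographics, diagnoses,
length of stay, and a total expense subdivided into seven items (comprehensive
medical service, diagnosis, treatment, drug, blood products, material, other
fees). `drgcost` implements the full analysis chain for such data:

1. **Record handling** — parsing with a column-map schema, inclusion filtering
   (study window, primary diagnosis, length of stay 1–60 days, completeness)
   with an audited exclusion log, and categorical coding of the fourteen
   analysis variables X1–X14.
2. **Price standardization** — CPI deflation to base-2015 yuan,
   `real = nominal × CPI(base)/CPI(year)`, then natural-log outcomes
   `Y1 = log(total)`, `Y2 = log(out-of-pocket + 1)`.
3. **Univariate screening** — median/IQR group summaries with tie-corrected
   Mann–Whitney Z (two levels) or Kruskal–Wallis H (three or more) at α = 0.05.
4. **Regression** — dummy-coded OLS of each log outcome on its screened
   factors, with classical SEs, t tests, 95% CIs, overall F and adjusted R².
5. **Structural change** — yearly item shares `p_i(t)` and, per period,

   - VSV: `VSV_i = p_i(t1) − p_i(t0)` (share change per item),
   - DSV: `Σ_i |VSV_i|` (total compositional churn, %),
   - CRSV: `|VSV_i| / Σ_i |VSV_i| × 100` (item contribution, %).

6. **Gray relational analysis** — Deng coefficients applied directly to the
   yuan-denominated yearly mean series (reference `X0(k)` = mean total per
   admission, comparisons `X_i(k)` = mean item expenses):

   ```
   Δ_i(k) = |X_i(k) − X0(k)|
   ξ_i(k) = (Δmin + ρ·Δmax) / (Δ_i(k) + ρ·Δmax),  ρ = 0.5
   γ_i    = mean_k ξ_i(k)
   ```

   ranked by decreasing γ. Because all series share units, no dimensionless
   preprocessing is needed; a classic initial-value-normalized mode is
   available via `normalize = "initial"`.

A synthetic-cohort generator (`generate_cohort()`) draws admissions from
configurable covariate distributions with a known log-linear cost model,
Dirichlet item splits drifting across years (drug share falling, treatment
share rising), and insurance-by-phase out-of-pocket retention — so every
estimator can be validated by parameter recovery without access to hospital
records.

## Worked example

```r
library(drgcost)

cfg <- pipeline_config(synthetic = cohort_config(n_patients = 800, seed = 42),
                       seed = 42)
b <- run_pipeline(cfg)

b$screen_y1$selected
#> [1] "x1_payment_phase" "x2_insurance" "x9_los_group" "x10_other_dx_group"
#> [5] "x13_surgery" "x14_discharge"

round(b$structural$dsv, 2)
#> 2015-2016 2016-2017 2017-2018 2018-2019 2019-2020 2020-2021 2021-2022
#>      6.65      6.19      4.77      8.28      4.20      5.60      5.13
#> 2022-2023 2023-2024 2024-2025 2015-2025
#>      5.21      5.74      3.83     49.32

round(b$gra$gamma, 4)
#> comprehensive_service  diagnosis  treatment   drug  blood_products  material  other
#>                0.8771     0.9385     0.9042  0.9298          0.7940    0.8456 0.8211
```

The screen picks up the factors the generator actually gives nonzero effects
(length of stay, surgery level, insurance, ...). The overall 2015–2025 DSV of
~49% reflects the configured share drift: the drug share falls ~2 percentage
points a year while the treatment share rises, so the composition churns
substantially over the decade even though single-year DSVs stay below 10%.
The gray relational degrees rank diagnosis and drug fees as the items whose
yearly mean trajectories track mean total expense most closely under the
default share dynamics.

The package also ships the reference VSV, CRSV and gray-coefficient tables of
a published 2015–2025 heart-failure cohort under staged DRG reform
(`reference_table()`); `verify_reference_tables()` recomputes every derived
cell (DSV, CRSV, γ, ranks) from the printed inputs and checks them at print
precision.

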