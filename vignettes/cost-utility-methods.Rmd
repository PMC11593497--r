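---
title: "Methods: two-strategy cost-utility analysis with deterministic and probabilistic sensitivity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-strategy cost-utility analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cuaengine)
```

## The decision problem

`cuaengine` compares two care strategies — here an intervention arm (a
pulmonary rehabilitation program plus supervised inspiratory muscle
training, `INT`) against a comparator (the same program with sham training,
`CON`) — from the perspective of a public payer. Each arm is summarised by
its mean per-patient cost $C$ in USD and mean effect $E$ in
quality-adjusted life years (QALYs) over the analysis horizon. The decision
statistic is the incremental cost-effectiveness ratio

$$\mathrm{ICER} = \frac{C_{INT} - C_{CON}}{E_{INT} - E_{CON}}
              = \frac{\Delta C}{\Delta E},$$

read against a willingness-to-pay threshold $\lambda$ per QALY, or
equivalently the incremental net monetary benefit
$\mathrm{iNMB} = \lambda \Delta E - \Delta C$ (positive iff cost-effective
when $\Delta E > 0$).

The packaged base case uses `INT` (317.73 USD, 0.23 QALY) versus `CON`
(293.93 USD, 0.20 QALY), giving $\Delta C = 23.80$, $\Delta E = 0.03$ and
ICER $= 793.33$ USD/QALY:

```{r base}
cfg <- load_config(system.file("extdata", "base_case.json", package = "cuaengine"))
compute_icer(cfg$arms$INT, cfg$arms$CON)
```

## Parameters, units and defaults

| Parameter | Default | Unit | Why |
|---|---|---|---|
| Exchange rate | 5.10 | BRL per USD | study-period average; all costs are held in USD |
| Tariff correction | 2.8 on `SIGTAP` lines | multiplier | public procedure-table values cover only about a third of actual federal spending |
| Horizon | 12 | weeks | typical duration of a post-acute rehabilitation program; no discounting at sub-year horizons |
| Weeks per year | 52 | — | simplest convention consistent with a week-based horizon (not 365.25/7); configurable |
| Threshold $\lambda$ | 40,000 | BRL/QALY | the commonly cited national reference threshold; converted to USD (7,843.14) before comparison because costs are in USD |
| Utilities | 0.724 (ward), 0.693 (ICU) | — | literature post-discharge values, carried with their disutilities (−0.061, −0.155) |
| PSA draws | 1000 | — | conventional Monte-Carlo size for this model class |
| Dispersion | 15% of each mean | relative SD | see below |

QALY accrual is $u \times \mathrm{weeks}/\mathrm{weeks\_per\_year}$
(`compute_qaly()`). Note a deliberate asymmetry: the base-case arm QALYs
(0.23/0.20) are **direct inputs** on the replication path and are *not* the
product of the packaged utilities with the 12-week horizon
(0.724 × 12/52 ≈ 0.167). The source analysis prints arm QALYs whose
derivation from its utilities is not stated (and whose implied baseline
utilities are internally inconsistent), so the engine treats arm means as
given and keeps `compute_qaly()` for de-novo analyses only. For the same
reason the per-patient arm costs are direct inputs rather than being
assembled from the resource table: the amortisation/allocation rule
(equipment lifetime, patients per device, staff-time share) is unknown. A
related printed inconsistency: the headline ICER is quoted once as 793.93
USD/QALY, but 23.80/0.03 = 793.33 exactly, so 793.33 is what the engine
reproduces.

Money is kept at full precision internally; the reporting layer rounds
half-away-from-zero to 2 decimals (`round_half_up()`), matching
presentation conventions.

The tariff correction is **not idempotent** (applying it twice multiplies
by $2.8^2$), so `cost_item` carries a `corrected` provenance flag and
`apply_cost_correction()` refuses a second application. The packaged
cost-table fixture stores already-corrected, already-converted USD line
totals (the printed column is in USD), so `total_cost()` is called on it
with `corr = NULL`; the correction/conversion machinery exists for
ingesting raw BRL tariff values in new analyses.

## One-way sensitivity analysis

`make_bounds()` produces per-parameter intervals from a reported confidence
interval when one exists, otherwise from a ±15% variation (the conventional
fallback). `run_owsa()` re-evaluates the ICER or iNMB with one parameter at
each bound, all others at base, and sorts rows by descending range; ties
keep input order (a documented, stable tie-break). When a bound interval
makes $\Delta C$ or $\Delta E$ change sign the ICER is not monotone across
the interval, so the row is flagged `unstable` and the iNMB outcome is the
recommended tornado display. The source analysis reports no univariate
results, so this module is validated structurally against brute-force
re-evaluation oracles rather than against published numbers. On the
replication path arm-level quantities are varied directly; utilities feed
through `compute_qaly()` only in de-novo mode — the two input pathways are
kept separate.

## Probabilistic sensitivity analysis

Utilities (and effects on the unit interval) get **beta** distributions,
costs get **gamma** — the standard PSA families for bounded and
non-negative right-skewed quantities. The published analysis states the
families but not their parameterisation; the engine fits by the **method of
moments**:

- beta: $\nu = m(1-m)/s^2 - 1$, $\alpha = m\nu$, $\beta = (1-m)\nu$,
  feasible only when $s^2 < m(1-m)$;
- gamma: shape $k = m^2/s^2$, scale $\theta = s^2/m$.

Zero standard error is an explicit degenerate point-mass spec whose draws
equal the mean and consume no random numbers.

Because the dispersions behind the published Monte-Carlo run were never
reported, the default dispersion is **15% of each mean** (mirroring the
±15% univariate rule), overridable per parameter in the config. The
consequence is stated plainly: the published category counts
(122/390/103/80/305) are **not** reproduction targets; what is reproduced
exactly is the decision arithmetic on those counts — the quadrant rule
(dominant + NE-below-threshold)/1000 = 51.2% — plus a battery of
property-based checks (moment recovery, conservation, seed reproducibility,
independent re-classification of exported draws, acceptability-curve
limits, end-to-end parameter recovery).

Other fixed numerical choices:

- the four quantities are sampled **independently** (nothing is reported
  about correlation), in the per-draw stream order
  `cost_int, cost_con, eff_int, eff_con` under one integer seed recorded in
  every output, so exported draw tables are auditable;
- the threshold comparison at $\lambda$ is **inclusive**
  ($\Delta C/\Delta E \le \lambda$ is cost-effective) — arbitrary but fixed;
- exact zeros in $\Delta C$ or $\Delta E$ (measure-zero but possible in
  floating point) go to a separate `boundary` category, counted
  cost-effective iff $\lambda\Delta E - \Delta C \ge 0$;
- south-west draws (cheaper, less effective) are **never** cost-effective
  under the quadrant rule, even when their net benefit is positive; the
  NMB-rule CEAC (`compute_ceac(..., rule = "nmb")`) is provided alongside
  precisely because the two rules differ on that set.

## What the synthetic generator does and does not emulate

`generate_trial()` emulates a small two-arm trial (default 25 vs 27
patients, the scale of the motivating study): per-patient gamma costs and
beta utilities at stated means with 15% relative dispersion, a fixed
horizon per record. It reproduces the *statistical structure the analysis
assumes* — independent patients, exact distributional families, no missing
data, no censoring, no correlation between a patient's cost and utility,
no protocol deviations. A green end-to-end test therefore establishes that
the pipeline recovers parameters from data satisfying its own assumptions;
it says nothing about robustness to real-world messiness (skewed cost
outliers beyond gamma, informative dropout, clustered care).

The end-to-end recovery test runs at $n = 10^4$ per arm with generating
incremental means $\Delta C = 23.80$, $\Delta E = 0.03$ and accepts the
recovered ICER within a 4-standard-error delta-method band
($\mathrm{Var}(\mathrm{ICER}) \approx \mathrm{Var}(\Delta C)/\Delta E^2 +
\Delta C^2\,\mathrm{Var}(\Delta E)/\Delta E^4$). That test fixes a 52-week
horizon so the generating utility means (0.23/0.20) coincide with the arm
QALY means: with a 12-week horizon the implied utilities (≈0.997) would sit
outside the beta-feasible region at 15% dispersion — a structural fact
about patient-level QALYs under sub-year horizons, noted rather than
worked around.

## Known limitations

- Two strategies, two currencies (BRL/USD), no discounting or inflation —
  adequate for a 12-week horizon, not for multi-year models.
- The internal structure of the original cohort model is unknown; the
  engine is a two-strategy comparison of arm-level means, which is the only
  structure its printed inputs support.
- PSA draws are independent; no correlation structure between costs and
  effects is modelled (and none was reported to calibrate one against).
- No figure rendering: the CLI writes scatter/curve coordinate tables and
  leaves plotting to the user.
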