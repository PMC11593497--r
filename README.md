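# cuaengine

A config-driven engine for two-strategy, trial-based **cost–utility
analysis** from a payer perspective, built around the setting of a Brazilian
public-health-system (SUS) evaluation of adding inspiratory muscle training
(IMT) to a post-COVID pulmonary rehabilitation (PR) program. It is for
health-economics analysts who have arm-level (or patient-level) costs and
QALYs for two comparators and want a reproducible deterministic and
probabilistic decision analysis with auditable exports.

## The model

Two strategies (intervention `INT`, comparator `CON`) are summarised by mean
per-patient cost *C* (USD) and mean effect *E* (quality-adjusted life years
over the horizon). The core statistic is the incremental
cost-effectiveness ratio

```
ICER = (C_INT − C_CON) / (E_INT − E_CON) = ΔC / ΔE   [USD/QALY]
```

with strict dominance classification (dominant: ΔC < 0, ΔE > 0; dominated:
ΔC > 0, ΔE < 0), and the equivalent net-monetary-benefit rule
iNMB = λ·ΔE − ΔC at a willingness-to-pay threshold λ (default BRL
40,000/QALY, converted at 5.10 BRL/USD). Around this sit:

- **Parameter handling** — resource cost lines (with the 2.8 correction
  factor for SIGTAP public-tariff values), currency conversion, utilities
  and disutilities, a 12-week default horizon, JSON config ingestion with
  full invariant validation.
- **One-way sensitivity analysis** — confidence-interval or ±15% bounds,
  tornado-ordered ranges, instability flags where the ICER crosses
  quadrants (use the iNMB outcome there).
- **Probabilistic sensitivity analysis** — method-of-moments gamma
  distributions for costs and beta distributions for utilities/effects,
  seeded Monte-Carlo draws (default 1000), cost-effectiveness-plane quadrant
  classification (`dominant`, `ne_below`, `ne_above`, `sw`, `dominated`),
  the quadrant decision rule (cost-effective = dominant + NE-below-λ; SW
  draws never count), and acceptability curves (CEAC).
- **Synthetic trials** — patient-level two-arm data (gamma costs, beta
  utilities) so every stage is testable without external data.
- **CLI** — `deterministic`, `owsa`, `psa`, `ceac`, `simulate` subcommands
  with CSV/JSON exports and a run manifest (seed, config digest, version).

## Worked example

```r
library(cuaengine)
cfg <- load_config(system.file("extdata", "base_case.json", package = "cuaengine"))
res <- compute_icer(cfg$arms$INT, cfg$arms$CON)
print(res)
#> Incremental analysis (INT vs CON)
#>   delta cost:   23.80 USD
#>   delta effect: 0.03 QALY
#>   ICER: 793.33 USD/QALY (trade-off-NE)
print(compute_inmb(res, cfg$threshold, cfg$exchange))
#> iNMB at lambda = 7843.14 USD/QALY: 211.49 USD (cost-effective)
```

The intervention costs 23.80 USD more per patient and gains 0.03 QALYs, so
one extra QALY costs 793.33 USD — far below the threshold (7843.14 USD/QALY
after conversion), hence cost-effective; the positive iNMB (211.49 USD) says
the same thing on the money scale. A seeded probabilistic run:

```r
p <- run_psa(list(cost_int = fit_gamma_moments(317.73, 0.15 * 317.73),
                  cost_con = fit_gamma_moments(293.93, 0.15 * 293.93),
                  eff_int  = fit_beta_moments(0.23, 0.15 * 0.23),
                  eff_con  = fit_beta_moments(0.20, 0.15 * 0.20)),
             n_draws = 1000, seed = 1)
print(p)
#> PSA: 1000 draws (seed 1), lambda = 7843.14 USD/QALY
#>   dominant     291 (29.1%)
#>   ne_below     426 (42.6%)
#>   ne_above      32 (3.2%)
#>   sw            78 (7.8%)
#>   dominated    173 (17.3%)
#>   cost-effective: 71.7%
```

Here 71.7% of draws are cost-effective under the quadrant rule
(dominant + NE-below-threshold; the 7.8% of cheaper-but-less-effective SW
draws are excluded by construction). The same analysis from the shell:

```sh
Rscript inst/exec/cua psa --config inst/extdata/base_case.json --seed 1 --out out/
```

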