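---
title: "A partitioned survival model for immunotherapy cost-effectiveness"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A partitioned survival model for immunotherapy cost-effectiveness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psmcea)
```

## The model

`psmcea` implements a three-state partitioned survival model (PSM) for
first-line treatment of advanced or recurrent endometrial cancer with
immune checkpoint inhibitors added to carboplatin–paclitaxel. Unlike a
Markov model, a PSM needs no transition probabilities: at every time
$t$ the cohort is partitioned directly by two survival functions,

$$
PF(t) = PFS(t), \qquad
PP(t) = OS(t) - PFS(t), \qquad
D(t) = 1 - OS(t),
$$

progression-free, post-progression (alive with progression) and dead.
The construction is valid only while $PFS(t) \le OS(t)$; `partition()`
enforces this, clamping excesses of at most 0.005 (the magnitude of
pixel error when curves are digitized from published figures) with a
warning and raising an error beyond that, naming the first offending
time.

Effectiveness is measured primarily in quality-adjusted
progression-free life-years (QA-PFLYS),

$$
\mathrm{QA\text{-}PFLYS}
  = \int_0^{H} u_{\mathrm{eff}}(t)\, PF(t)\, e^{-rt}\, dt ,
$$

with QALYs (adding $u_{pp} \int PP(t) e^{-rt} dt$) as a secondary
measure. QA-PFLYS is preferred here because overall survival in the
underlying trials is confounded by treatment crossover at progression.
The incremental cost-effectiveness ratio (ICER) of a strategy against
the chemotherapy comparator is $\Delta C / \Delta E$, judged against a
willingness-to-pay (WTP) threshold of \$100,000 per QA-PFLYS.

## Time, integration and extrapolation

All times are years (365.25 days); dosing intervals quoted in weeks
convert via `weeks()`. Reporting can be summarized at any granularity,
but integration never uses a coarse cycle: digitized Kaplan–Meier step
curves are integrated *exactly* as (discounted) rectangle sums, and
parametric curves by adaptive quadrature (`stats::integrate`, relative
tolerance $10^{-12}$). We chose adaptive quadrature over a fixed weekly
trapezoid because the trapezoid's $O(h^2)$ error on a 5-year horizon
(about $2 \times 10^{-6}$ relative for an exponential of rate 0.2) is
avoidable at no cost, and exact step-curve sums make the life-year
accumulator error-free on digitized inputs. State occupancy is still
tabulated on a weekly grid for inspection and for the crossing check.

Beyond the last digitized time point a step curve holds its last value
by default — a conservative, auditable choice; an exponential tail
fitted to the final quarter of the curve is available
(`extrapolation = "exp_tail"`). Discounting defaults to 0%/year with a
standard 3% available, since the deterministic results are reported
undiscounted over the 5-year horizon.

## Regimens, dosing and costs

Each regimen is an induction phase (six q3w cycles of the triplet or
doublet) followed by a maintenance phase, with two cap encodings that
mirror how trials phrase their stopping rules: `max_treatment_years`
caps total time from treatment start ("a maximum total of 2 years"
includes induction), while a phase's `max_doses` caps that phase alone
("up to 42 additional cycles" counts maintenance administrations). The
first three induction cycles are always delivered and costed —
treatment decisions precede the first response assessment — and every
later dose at time $t_k$ is delivered with probability $PFS(t_k)$,
evaluated exactly at the dose time (no half-interval correction).

Per-administration cost decomposes as
`fixed_cost + price_units × drug_price`: the chemotherapy backbone
(\$1,126/cycle) plus a priced immunotherapy component. The bundled
prices per induction administration are \$12,338 (pembrolizumab),
\$13,336 (dostarlimab) and \$9,020 (durvalumab) — each the triplet
cycle cost minus the backbone — and maintenance administrations carry
2 price units where the maintenance dose is double the induction dose
(pembrolizumab 400 mg q6w vs 200 mg q3w; dostarlimab 1000 mg vs
500 mg), or 12,081/9,020 (≈ the 1500/1120 mg dose ratio) for
durvalumab, reproducing the quoted maintenance costs of \$24,676,
\$26,672 and \$12,081 exactly. This decomposition makes total drug
cost *exactly linear* in one price per drug, which the threshold
analysis exploits.

Grade ≥3 toxicity is priced as a one-time expected cost at model start
(probability × \$9,784 for the triplets, \$9,163 for chemotherapy
alone) and reduces the on-treatment utility by a multiplier of 0.70,
probability-weighted, over an 18-week window (the induction length) —
the simplest auditable placement for an event the source parameters
price without timing. Health-state utilities default to 0.84 on
treatment and 0.50 after progression; 0.80 on treatment, an
alternative sometimes used for active treatment, ships as
`inst/extdata/dmmr_u080.yaml`. The post-progression cost rate defaults
to \$0/year: no defensible per-year figure exists in the source
parameter set, and every bundled comparison is independent of it (it
is exposed on `strategy()` for sensitivity work).

## Synthetic trial curves

No patient-level or digitized curve data are redistributable, so the
package generates its own trial-like inputs; everything downstream is
testable against them, and users substitute digitized CSV curves
(`time_years,survival`) for real analyses. `simulate_trial_curves()`
draws per-patient progression times from a Weibull (shape 1 —
exponential — by default, for analytic tractability) and sets each
death time to progression plus an exponential post-progression draw,
so $OS \ge PFS$ holds patient by patient and the Kaplan–Meier
estimates (via `survival::survfit`) can never cross under purely
administrative censoring. Proportional hazards apply the treated-arm
effect.

The bundled scenario conditions, chosen once as representative of the
trial populations: control median PFS 7.6 months (dMMR) and 8.7 months
(pMMR), control median OS 36 months, PFS hazard ratios 0.29
(dostarlimab), 0.30 (pembrolizumab) and 0.42 (durvalumab) in the dMMR
subgroup and 0.54 (pembrolizumab) and 0.76 (dostarlimab) in pMMR, 400
patients per simulated arm, administrative censoring at 5 years, and a
shared OS curve across arms (`hr_os = 1`): with crossover-confounded
OS evidence, the conservative base case grants no post-progression
survival benefit. The 33%/67% dMMR/pMMR prevalence split is carried as
scenario metadata only; results are reported per subgroup, never
prevalence-weighted. The default `curves = "parametric"` mode uses the
implied exponential curves directly (deterministic); `curves = "km"`
swaps in simulated step curves at trial scale.

What passing tests on these inputs do *not* show: real digitized
curves are non-exponential (plateaus, delayed separation), trials
suffer non-administrative dropout, and real OS differs by arm. The
engine is validated against exact arithmetic, closed forms and a
200,000-patient patient-level simulation — not against the published
trial curves themselves, which are external publications.

## Sensitivity analyses

**Threshold.** Because cost is linear in `drug_price`, the break-even
price at which the ICER equals the WTP has the closed form
$p^\* = p_0 - (\Delta C(p_0) - \mathrm{WTP}\,\Delta E)/N$ with $N$ the
expected discounted number of priced units delivered;
`break_even_price()` reports it per induction administration, and the
test suite verifies it against bisection on the full engine to within
\$0.01. A non-positive $\Delta E$ yields no finite break-even price
and is reported as such.

**One-way / tornado.** `one_way()` re-runs the engine at a parameter's
bounds; `tornado()` sorts the ICER ranges by width. Bounds default to
±20% of base for costs, rates and durations and ±10% (capped at 1) for
probabilities and utilities — the same 2:1 uncertainty ratio the
probabilistic distributions use. A symmetric ±20% on a utility that
scales both arms would mechanically dominate every tornado (the ICER
is exactly proportional to $1/u$, giving a bar of width
$0.4167 \times$ ICER regardless of the data), which says something
about the bound convention, not the model. In the bundled dMMR
pembrolizumab comparison the immunotherapy price is the widest bar;
for durvalumab — the weakest effect (HR 0.42) — the response-rate bar
is within a few percent of the price bar, a near-tie worth knowing
about.

**Probabilistic.** `run_psa()` draws parameters independently per
iteration — gamma for costs (SE 20% of base), beta by
method-of-moments for probabilities and utilities (SE 10% of base),
`fixed` for structural settings — and computes the
cost-effectiveness acceptability curve over a \$0–\$300,000 WTP grid
(\$10,000 steps, spanning the \$100,000 base threshold and the
\$300,000 oncology threshold sometimes discussed). The strategy with
the highest net monetary benefit wins each iteration; exact ties go to
the lowest-cost strategy, deterministically. Survival-curve parameters
are held fixed in the PSA: drawing a treated PFS hazard independently
of the shared OS curve can produce $PFS > OS$, and no joint
uncertainty model is specified — a structural limitation of PSMs worth
stating plainly. One seeded generator drives the whole run; the same
seed gives bit-identical results. 1,000 iterations is the conventional
default; the Gaussian-construction validation test uses 10,000.

## Numerical choices and degenerate inputs

* Dose times strictly inside the cap/horizon (`t < cap`): a dose
  scheduled exactly at the cap is not delivered.
* `incremental_analysis()` flags dominance (`dominant` /
  `dominated`) instead of reporting negative ICERs, and reports a zero
  incremental effect as `undefined`.
* Maintenance with `max_doses = 0` or an empty induction phase are
  legal degenerate schedules costing nothing.
* Beta method-of-moments requires $SE^2 < \mu(1-\mu)$; violations are
  errors, not silent truncation. Zero-based parameters are never drawn
  (treated as fixed).
* Problem sizes used by the test suite — 200,000 patients for the
  patient-level cost oracle, 10,000 for parameter recovery and the
  Gaussian PSA check, 50,000 for Kaplan–Meier consistency — were
  chosen so Monte-Carlo error (3 standard errors) sits well below the
  effect sizes being verified.

## Known limitations

Second-line treatment is represented only by the (default zero) flat
post-progression cost rate; there is no vial-sharing, weight-based
dosing or wastage model; PSA draws are uncorrelated; and the
partitioned structure cannot propagate survival-curve uncertainty
without a joint PFS/OS model. Lifetime-horizon extrapolation is out of
scope: the 5-year restricted horizon is a deliberate, conservative
choice given immature follow-up.
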