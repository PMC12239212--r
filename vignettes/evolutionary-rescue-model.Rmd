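---
title: "Evolutionary rescue of tumors by aneuploidy: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evolutionary rescue of tumors by aneuploidy: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aneurescue)
```

## The model

A tumor under drug treatment is modeled as three exchangeable genotype
classes of cancer cell, each dividing and dying independently:

* **sensitive** cells divide at `lambda_s` and die at `mu_s` per day; the
  drug makes them decline, `r_s = lambda_s - mu_s < 0`;
* **aneuploid** cells (`lambda_a`, `mu_a`) arise when a dividing sensitive
  cell missegregates a chromosome, probability `u` per division under the
  drug (`u_pre` before treatment). Depending on `r_a` they are *tolerant*
  (declining, but slower than sensitive cells), *stationary* (`r_a` near
  zero) or *partially resistant* (`r_a > 0`);
* resistant **mutant** cells (`lambda_m`, `mu_m`, with `r_m > 0`) arise by
  a point mutation at probability `v` per division of a sensitive cell, or
  `v_a` per division of an aneuploid cell.

Nine event channels drive the dynamics (birth and death per genotype,
missegregation, and the two mutation channels); missegregation and mutation
add a daughter of the new type and leave the parent count unchanged. The
drug-induced missegregation route makes aneuploidy a potential *stepping
stone*: a tolerant aneuploid lineage outlives the sensitive population and
can still spawn the resistant mutant that ultimately rescues the tumor.

Division rates are approximated as `lambda_s * s` rather than
`lambda_s * s * (1 - u - v)` because `u, v << 1`; the option
`exact_division_factors = TRUE` in the simulators and `event_rates()`
restores the exact factors for sensitivity analysis. An optional carrying
capacity `K` adds a logistic crowding term `lambda_k (s + a + m) / K` to
every death rate; its effective capacity — the size at which aneuploid
division and death balance — is `K r_a / lambda_a`.

## Parameters, units, defaults

All division/death rates and the cost `c` are per day; `u`, `u_pre`, `v`,
`v_a` are probabilities per cell division; sizes are cell counts. Nothing
is ever rescaled implicitly. Two preset families transcribe literature
values:

```{r presets}
rescue_preset("melanoma_a375")
glance(rescue_preset("melanoma_a375"))
```

The melanoma preset (A375 cells under vemurafenib) uses
`lambda_s = lambda_m = 0.1`, `mu_s = 0.14`, `mu_a = mu_m = 0.09`,
`lambda_a = 0.0899` (tolerant aneuploids), `u = 1e-2`, `u_pre = 1e-3`,
`v = 1e-7` and `c = 0.07`. The cost of aneuploidy is reproducible from the
published 1:1 competition outcome — aneuploid fraction 0.15 after 24
drug-free days — via `aneuploidy_cost(0.15, 24)` = `r
round(aneuploidy_cost(0.15, 24), 4)` per day. The three TNBC PDX presets
(cisplatin) share `lambda = 0.0845` and `mu_s = 0.1215` and differ only in
the aneuploid death rate (0.076, 0.1015, 0.1115). Those death rates are
back-calculated from relative Wrightian fitness; rerunning the derivation
(`tnbc_rates_from_fitness()`) gives `mu_s = 0.12196`, slightly off the
published 0.1215 — the presets keep the published value and the helper
documents the discrepancy.

## Theory layer

**Extinction probabilities.** Because founder lineages are independent,
the chance a tumor of `N` cells is rescued is `1 - q_s^N`, where `q_s` is
the extinction probability of a single sensitive founder's lineage. The
`(q_m, q_a, q_s)` triple solves the fixed-point equations of the offspring
generating functions; the hierarchy is triangular, so `q_m = min(1,
mu_m/lambda_m)` comes first and the other two are roots of quadratics.
`extinction_probabilities()` evaluates the closed-form roots with a
cancellation-safe quadratic formula, and independently by
Steffensen-accelerated fixed-point iteration (`method = "iterate"`); the two
routes agree to better than 1e-10 across random parameter sweeps.

**Critical time and regimes.** An aneuploid lineage must survive about
`T* = sqrt(lambda_m / (v_a r_m)) / (2 lambda_a)` days to produce a mutant
lineage that escapes drift. The dimensionless `r_a T*` — the change in an
aneuploid lineage's log size over that window — classifies the phenotype:
tolerant (`<= -1`), stationary (inside `(-1, 1)`), resistant (`>= 1`). The
asymptotic conditions are implemented as hard cutoffs at ±1, the same
scale on which the TNBC clones are reported (`r_a T*` of +501, −1003 and
−1593). `classify_regime()` additionally reports the *rescue route*: when
missegregation is too rare to matter (`u lambda_a T* < 1`, or
`u lambda_a < -r_a` for a drug-sensitive aneuploid), rescue proceeds by
direct mutation regardless of the aneuploid phenotype, and the two TNBC
tolerant clones are exactly of this kind. Both columns are returned
because the phenotype label and the operative rescue route genuinely
differ there.

**Threshold tumor sizes.** `threshold_direct()` gives
`Nm* = (|r_s|/(v lambda_s)) (lambda_m/r_m)`, the classic single-path
threshold; `threshold_aneuploid()` multiplies `|r_s|/(u lambda_s)` by a
branch factor — `(|r_a|/(v_a lambda_a))(lambda_m/r_m)` (tolerant),
`2 lambda_a T*` (stationary; exact at `r_a = 0`), `lambda_a/r_a`
(resistant). The square-root reading of `T*` is the one that makes the
stationary branch of the threshold ratio an exact identity and reproduces
the published TNBC bounds, so it is adopted throughout. Standing
variation (a pretreatment aneuploid fraction `f = u_pre lambda_s / c` at
missegregation–selection balance) has threshold ratio
`(u/u_pre)(c/|r_s|)` relative to the de novo path; the three ratios are
constructed to be mutually consistent to machine precision.

**Rescue hazard and times.** In the direct-mutation and tolerant regimes
the arrival of successful resistant lineages is modeled as an
inhomogeneous Poisson process with intensity
`p_m (v lambda_s s(t) + v_a lambda_a a(t))` along the deterministic
(mean-field) trajectories, integrated in closed form
(`rescue_hazard()`). Its total mass satisfies
`Lambda(Inf) = N/Nm* + N/Na*` exactly, tying the hazard back to the
thresholds. Mean rescue/recurrence/detection times use asymptotic closed
forms for small (`N <= N*/10`) and large (`N >= 10 Nm*`) tumors, the
conditional-survival integral or a Monte-Carlo over conditioned lineage
arrivals in between, and mean-field ODE crossing times where the mutant
dynamics are deterministic; every returned value carries a method tag. In
stationary and resistant regimes lineage-level stochasticity is not
subdominant, so the analytic time layer refuses and directs callers to
`run_replicates()`.

## Simulators

`simulate_tumor()` implements the exact Gillespie algorithm over the nine
channels (exponential waiting time with the summed rate, event chosen
proportionally) and a tau-leaping variant (fixed step, Poisson counts per
channel, genotype counts clamped at zero — the clamp slightly biases totals
and is kept because it is the standard formulation for this model). The
default tau step is 0.1 days for the preset rate scale; the tau-vs-SSA
agreement test runs at 0.05 days. Runs stop at extinction, at the
establishment threshold `floor(3 ln 10 / ln(lambda_m/mu_m)) + 1` mutants
(joint extinction probability below 0.1%), at optional recurrence or
detection targets on the mutant count, or at censoring caps (defaults: 1e6
days, 1e9 events, always recorded).

The SSA tracks each mutant-founding event as a lineage and reports the
rescue time as the birth time of the earliest lineage still alive when the
establishment threshold is crossed — the waiting time for the resistant
lineage that avoids extinction, which is the quantity the theory layer
predicts. Tau-leap runs do not track lineages and report the crossing time
itself. Replicate seeds derive from `(base_seed, index)` on a fixed Weyl
ring, so ensembles are bit-reproducible and machine-portable; no
stochastic code path runs without an explicit seed.

## Desk-scale experiments

The published operating points (`N` up to 1e10 with `v = 1e-7`) would need
on the order of 1e8 SSA events per replicate, so the experiment drivers
and tests default to *rescaled* instances: the mutation rate is raised
(1e-3 or 1e-4) and sizes lowered so that the dimensionless ratios `N/N*`
match the original regime while a replicate runs in milliseconds. The
analytic layer is evaluated at full scale — it is size-independent in
cost. Problem sizes used by the test suite: ensembles of 200–1000
replicates at `N` between 200 and ~4000, 300–400 trajectories for
mean-trajectory checks, 2000 conditioned draws for Monte-Carlo time
estimates, and a 1000-point random sweep for the oracle-equivalence check.

What the scaled instances emulate is the branching-process structure:
independence of lineages, the relative sizes of the two rescue routes, and
the establishment threshold. What they do not emulate is everything the
model itself omits — spatial structure, cell–cell interactions beyond the
logistic death term, immune pressure, karyotype identity (which chromosome
is gained), a fitness distribution across aneuploidies, and back-mutation
from aneuploidy to euploidy. Passing tests therefore validate the
implementation of this model, not those biological effects.

## Numerical choices

* Quadratic PGF roots use `2c / (b + sqrt(b^2 - 4ac))`, avoiding
  cancellation; the iterative oracle uses Steffensen acceleration in
  extended (80-bit) precision because near criticality the residual
  `g(q) - q` cancels below double precision and plain iteration slows
  arbitrarily.
* Exponential differences `(e^{r1 t} - e^{r2 t})/(r1 - r2)` switch to the
  `t e^{r t}` limit when `|r1 - r2| < 1e-12`; the stationary threshold
  branch handles `r_a = 0` exactly.
* Lineage Monte-Carlo crossing times are solved in closed form per draw on
  the log scale (log-sum-exp over lineage weights), so late arrivals do not
  underflow.
* Conditioned lineages grow deterministically as `(1/p_m) e^{r_m (t - t_i)}`.
  Replacing the random survivor amplitude `W` (mean `1/p_m`) by its mean
  shifts log-scale crossing times by about Euler–Mascheroni `gamma / r_m`;
  the SSA cross-validation test budgets for exactly this offset. At the
  preset scale the offset is ~58 days against means of 1e4 days.
* The small-tumor recurrence closed form `-1/r_s - 1/r_a + ln(p_m N)/r_m`
  is the *aneuploid-path-only* conditional mean. The lineage Monte-Carlo,
  which includes the ~10% of rescues that arrive through the much faster
  direct-mutation path and the occasional multiple lineage, sits a few
  percent below it (about 9,600 vs 11,176 days at `N = 1e6` for the
  melanoma preset). This is a real property of the mixture, not an
  estimator defect; the same estimator reproduces the large-tumor constant
  to a few per mille.
* Asymptotic branches switch at `N <= N*/10` and `N >= 10 Nm*`; in between
  the hazard integral (rescue time) or Monte-Carlo (recurrence) is used and
  tagged, so a caller always sees which approximation produced a number.
* `aneuploid_phenotype` cutoffs at `r_a T* = ±1` are deliberate hard edges;
  the raw condition values are all returned for stricter use.

## Limitations

Beyond the model-scope limits above: the tau-leap clamp biases totals near
extinction; the hazard construction treats the aneuploid compartment
deterministically and is therefore unavailable in stationary/resistant
regimes; recurrence and detection targets are counts of *mutant* cells
(the resistant clone is what regrows the tumor); and full-scale SSA runs
at `N >= 1e7` with `v = 1e-7` are out of desk reach by design — the
analytic layer is the instrument for that scale.
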