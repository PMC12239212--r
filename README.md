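# aneurescue

Tumors under anticancer drugs can escape extinction — *evolutionary
rescue* — either by a direct resistance mutation in a drug-sensitive cell
or by a two-step path in which chromosome missegregation first produces an
aneuploid cell that tolerates (or partially resists) the drug, and a
resistance mutation then arises on that aneuploid background. `aneurescue`
implements the three-genotype stochastic birth–death model of this
process, for researchers in cancer evolution and evolutionary rescue
theory who want to ask: *how large must a tumor be for rescue to become
likely, how much does aneuploidy lower that threshold, and how long until
the rescued tumor recurs?*

## The model

Sensitive (s), aneuploid (a) and mutant (m) cells divide and die at rates
λ<sub>k</sub>, μ<sub>k</sub> (per day; r<sub>k</sub> = λ<sub>k</sub> −
μ<sub>k</sub>, with r<sub>s</sub> < 0 < r<sub>m</sub>). Sensitive
divisions missegregate at probability *u* (per division) and mutate at
*v*; aneuploid divisions mutate at *v<sub>a</sub>*. Lineages are
independent (optionally logistic with capacity *K*), so multitype
branching-process theory gives the rescue probability of an *N*-cell tumor
as

  p<sub>rescue</sub> = 1 − q<sub>s</sub><sup>N</sup> ≈ 1 − e<sup>−N/N\*</sup>,

where q<sub>s</sub> is the single-lineage extinction probability (a PGF
fixed point) and N\* = 1/p<sub>s</sub> the threshold tumor size. Closed
forms cover the direct threshold N<sub>m</sub>\* =
(|r<sub>s</sub>|/(vλ<sub>s</sub>))·(λ<sub>m</sub>/r<sub>m</sub>), the
aneuploidy-mediated threshold N<sub>a</sub>\* (three branches — tolerant,
stationary, resistant — selected by r<sub>a</sub>T\*, where T\* is the
critical aneuploid-lineage survival time), standing-variation thresholds,
and mean rescue/recurrence/detection times; exact Gillespie and
tau-leaping simulators with replicate ensembles, bootstrap confidence
intervals and figure-level experiment drivers sit alongside.

## Worked example

```r
library(aneurescue)

p <- rescue_preset("melanoma_a375")   # A375 / vemurafenib parameter table
rescue_thresholds(p)
#> # A tibble: 1 × 8
#>   n_star_direct n_star_aneuploid n_star_standing ratio_aneuploid_direct ...
#> 1     40000000.         4449388.       77864294.                  0.111
```

A direct mutation needs a ~4×10⁷-cell tumor for likely rescue; tolerant
aneuploidy (at u = 10⁻², λ<sub>a</sub> = 0.0899) lowers the threshold to
~4.4×10⁶ cells — an 89% reduction (ratio 0.11) — so tumors between the two
thresholds depend on aneuploidy to survive treatment. Standing variation
(pre-existing aneuploid cells at fraction f = ũλ<sub>s</sub>/c ≈ 0.14%)
has a 17.5-fold higher threshold than the de novo path here, so
drug-induced missegregation dominates.

Simulation and theory agree at desk scale (mutation rate raised to 10⁻³,
N = 1000 so that N/N\* matches an intermediate operating point):

```r
ps <- rescue_preset("melanoma_a375", v = 1e-3, u = 0, n_init = 1000)
glance(run_replicates(ps, 200, base_seed = 7))
#>   n_replicates n_rescued n_extinct n_censored p_rescue ci_lo ci_hi ...
#> 1          200        52       148          0     0.26 0.199 0.321
rescue_probability(ps, 1000)
#> [1] 0.2205688
```

The simulated rescue fraction (0.26, CI 0.20–0.32) brackets the exact
branching-process value 0.22. Time scales, conditioned on rescue:

```r
time_summaries(p, n = 1e6, seed = 1)
#>   mean_rescue_time rescue_method   mean_recurrence_time recurrence_method ...
#> 1            8415. hazard_integral                9559. monte_carlo
```

For a 10⁶-cell melanoma the rescuing lineage arrives after ~8,400 days on
average (the tolerant aneuploid reservoir decays on the 1/|r<sub>a</sub>| =
10⁴-day scale), and the tumor regrows to its initial size ~9,600 days
after treatment starts; for large tumors (N ≫ N<sub>m</sub>\*) the mean
recurrence time instead converges to the N-independent constant
(1/r<sub>m</sub>)·ln((r<sub>m</sub>−r<sub>s</sub>)/(vλ<sub>s</sub>)) ≈
1,500 days. `autoplot()` methods draw trajectories, rescue-probability
curves and survival curves; a command-line wrapper lives at
`inst/cli/evorescue` (`evorescue theory --preset melanoma_a375 --quantity
thresholds`).

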