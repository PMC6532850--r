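# faoflux

Kinetic modelling of mitochondrial fatty-acid beta-oxidation (FAO) flux
from acylcarnitine time courses.

FAO shortens an even-numbered acyl chain by two carbons per cycle
(C16 → C14 → ... → C4 → C2). When expression of ACADS — the short-chain
acyl-CoA dehydrogenase catalysing the C4 → C2 step — is reduced, C4 species
accumulate; quantifying *which* reaction slowed, and by how much, requires a
dynamic model rather than per-metabolite statistics. faoflux is built for
that analysis: it fits acylcarnitine concentration time courses measured
after a fatty-acid load (e.g. in doxycycline-inducible ACADS-knockdown
hepatocytes) and turns them into per-reaction rate estimates with
uncertainty. Intended users are metabolomics and systems-biology analysts
working with flux-assay time courses.

## The model

The even-chain intermediates form a linear cascade of irreversible
first-order reactions with mass-action kinetics and optional zero-order
influx terms (substrate input into C16; entry of endogenous pools at C14,
C8, C4):

    dx_n/dt = k_{n+2} x_{n+2} − k_n x_n + b_n        (x in nmol/g protein,
                                                      k in 1/min)

i.e. a linear system dx/dt = A x + b with lower-bidiagonal A, solved exactly
via matrix exponentials. Measurements are compared to the model on log10
scale (log-normal error, single profiled sigma) and estimated by multi-start
maximum likelihood. On top of the fit sit:

* **profile-likelihood 95% CIs** (chi-square(1) threshold, bisection);
* **influx model selection** — backward elimination by likelihood-ratio
  test, chain rates never removed;
* **rate-ratio inference** — a joint two-condition model with per-rate
  ratios alpha_n = k_n(knockdown)/k_n(control), profile CIs and LRT
  p-values; alpha_4 < 1 with CI excluding 1 is the knockdown signature;
* the study's **descriptive layer**: per-time-point t-tests, baseline fold
  changes, C3/C4 acyl ratios, delta-delta-Ct with a reference-gene index,
  exact Mann–Whitney, Kruskal–Wallis/Dunn, two-way ANOVA contrasts;
* a **synthetic-data generator** emulating the knockdown experiment design
  (3 doxycycline conditions, 4 replicates, t = 0/7/14/21/28 min,
  sigma = 0.05 on log10 scale), so the whole pipeline is testable without
  any download.

## Worked example

```r
library(faoflux)

sc <- default_scenario(seed = 1)      # emulated knockdown experiment
ds <- generate_dataset(sc)            # long-format time-course table

cmp <- compare_rates(ds[ds$condition == "null", ],
                     ds[ds$condition == "max", ], sc$spec,
                     fit_options(n_starts = 5, seed = 1))
print(cmp)
```

```
Rate ratios alpha = k(B) / k(A) with profile-likelihood CIs and LRT p-values
 species   alpha   lower   upper  p_value significant
     C16 0.93370 0.85160 1.02200 1.36e-01       FALSE
     C14 0.97640 0.88930 1.07100 6.13e-01       FALSE
     C12 0.96700 0.86930 1.07300 5.28e-01       FALSE
     C10 0.95580 0.84350 1.07800 4.63e-01       FALSE
      C8 0.93030 0.80240 1.06900 3.13e-01       FALSE
      C6 0.89570 0.73420 1.07200 2.34e-01       FALSE
      C4 0.07037 0.05242 0.09128 2.56e-57        TRUE
      C2 0.92390 0.79020 1.07600 3.09e-01       FALSE
```

Reading: the C4 → C2 conversion rate in the maximal knockdown is an
estimated 7.0% of its control value (95% CI 5.2–9.1%), a significant
reduction — the generating truth for this dataset scaled k_4 by 0.07 — while
all other rate ratios straddle 1. Baseline statistics come from the same
table, e.g. `baseline_fold_change(ds, "C4", "max", "null")$fold` (the
knockdown's baseline C4 elevation, ≈2.4 on this draw).

The same stages are available from a shell via the launcher
(`Rscript inst/cli/faoflux.R synth|simulate|fit|select-model|compare|stats`);
each run writes CSV/JSON results plus a log with seed, version and
parameter echo.

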