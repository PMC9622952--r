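# strokecea

A decision-tree / Markov cohort model for the health-economic comparison of
two neuroprotective strategies in acute ischemic stroke — edaravone
dexborneol versus single-agent edaravone — from the Chinese healthcare
system's perspective. It is written for health economists and HTA analysts
who want the whole pipeline (base case, one-way sensitivity, probabilistic
sensitivity, acceptability curves) as tested, scriptable R functions rather
than a spreadsheet.

## The model

A short-term decision tree fixes each arm's day-90 outcome on the modified
Rankin Scale, banded as mRS 0–1 (no disability), mRS 2–3 (minor/moderate),
mRS 4–5 (severe) and mRS 6 (dead). The surviving cohort, entering at age
63, then moves through an annual-cycle Markov model over up to 30 years on
an expanded state space: three post-stroke states, three one-cycle
recurrent-stroke *tunnel* states, and death. Each year patients may

- suffer a recurrent stroke with probability `1 − exp(−r·g^(t−1))`, where
  `r = 0.12` per patient-year grows by `g = 1.019` per life year;
- die of the recurrence (probability 0.21) or of background causes, with
  age-specific background mortality multiplied onto the hazard scale by
  disability-specific hazard ratios (1.00 / 1.19 / 2.04);
- otherwise remain in their state.

Costs (2021 CNY: drug course, intravenous injections, one-time
hospitalization, annual post-hospitalization care, recurrence events) and
utilities accrue per cycle with half-cycle correction and 5 % annual
discounting. Strategies are compared by the incremental cost-effectiveness
ratio and net monetary benefit,

    ICER = Δcost / ΔQALY        NMB = QALY × WTP − cost

at a willingness-to-pay threshold of 121,464 CNY/QALY (1.5 × per-capita
GDP). One-way sensitivity analysis produces a tornado of INMB ranges;
probabilistic sensitivity analysis resamples every input (Dirichlet for the
day-90 multinomials, beta for probabilities and utilities, gamma for costs,
lognormal for ratios) and yields the probability of cost-effectiveness and
the acceptability curve.

Because the source evidence carries two mutually inconsistent utility sets,
the package ships both as named presets (`"table1"`: 0.80/0.58/0.28;
`"text"`: 0.84/0.78/0.36) and never silently picks one; see the methods
vignette (`vignettes/stroke-cea-methods.Rmd`).

## Worked example

```r
library(strokecea)
fit <- cea(default_parameters(utility_preset = "text"))
fit
#> Two-arm cost-effectiveness model: edaravone_dexborneol vs edaravone
#>   utility preset 'text', WTP 121,464 CNY/QALY
#>
#>   Horizon 1 y
#>     cost      26658.83 vs     24208.19  (delta    2450.63)
#>     QALY        0.7300 vs       0.7100  (delta     0.0199)
#>     ICER  122886.61 CNY/QALY
#>     INMB        -28.37 CNY
#>
#>   Horizon 5 y
#>     cost      65771.96 vs     64229.02  (delta    1542.94)
#>     QALY        3.0523 vs       2.9700  (delta     0.0823)
#>     ICER  18745.96 CNY/QALY
#>     INMB       8454.50 CNY
#>
#>   Horizon 30 y
#>     cost     153088.85 vs    153058.41  (delta      30.43)
#>     QALY        8.0655 vs       7.8369  (delta     0.2286)
#>     ICER  133.12 CNY/QALY
#>     INMB      27739.35 CNY
```

Read: at one year the combination therapy costs 2,450.63 CNY more and gains
0.02 QALYs, so it is borderline at the threshold; by 30 years the cost
difference has nearly vanished while the QALY gain has grown to 0.23, and
the incremental net monetary benefit is ≈ 27,739 CNY — clearly
cost-effective. Sensitivity analyses:

```r
tor <- owsa(default_parameters("table1"), horizon = 30)   # tornado entries
psa <- run_psa(default_parameters("table1"), n_iterations = 5000, seed = 1)
plot(psa)                                                  # CE plane + CEAC
```

From a shell:

```sh
inst/cli/strokecea run --utility-preset text --horizons 1,5,30 --out out/
inst/cli/strokecea psa --iterations 5000 --seed 1 --out out/
```

Every output directory receives a `manifest.json` sufficient to reproduce
it.

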