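# recolonize

Inference tools for plot-level community manipulation experiments in which
a treatment change opens previously closed plots to recolonization — the
setting of long-term exclosure studies where fenced plots excluding a
dominant competitor (here, kangaroo rats of genus *Dipodomys* in a desert
rodent community) are suddenly converted to controls, and the question is
how long the recolonizing populations take to become indistinguishable
from long-term control plots.

The package provides, as one tested pipeline:

* **Treatment-by-time GAMs** — exponential-family generalized additive
  models with log link,
  `g(mu_pt) = alpha_T + f_T(t) + b_p(t)`,
  one penalized cubic-spline smooth of time `f_T` per treatment and
  shrinkage-penalized plot-deviation smooths `b_p`; Poisson for counts,
  Tweedie (variance `phi * mu^p`, `1 < p < 2`) for community metabolic
  flux. Smoothing parameters are selected by GCV (REML optional) and every
  fit carries the Bayesian posterior covariance
  `V_beta = (X'WX + sum_j lambda_j S_j)^-1 * phi`.
* **Difference-of-smooths inference** — link-scale contrasts
  `d(t) = c(t)' beta` between treatment smooths with pointwise (default)
  or simultaneous credible intervals, and a convergence detector that
  reports the first month from which the interval contains zero in a
  sustained way, plus any later excursions.
* **Metabolic flux** — three-quarter-power scaling `E = m^(3/4)` summed
  over the seed-eating community per plot and census.
* **Multistate capture–recapture** — the Arnason–Schwarz likelihood
  (survive → move → detect per interval, latent strata marginalized by a
  forward recursion) for stratum-specific apparent survival `S`,
  recapture `p` and transition probabilities `Psi`, with AIC model
  selection and a new-individual influx tabulation. MARK-style `.inp`
  files are read and written.
* **Partial CCA** — chi-square-standardized correspondence analysis of
  plant composition constrained by treatment and conditioned on year, with
  reduced-model permutation tests (pseudo-F).
* **A seeded synthetic-data generator** emulating the whole experiment
  (10 plots in 3 treatments, 72 monthly censuses, treatment change at
  month 26, known recovery delays, stratum-dependent survival/movement,
  weak treatment signal in plant tables), so every stage is testable
  against known truth.

## Worked example

```r
library(recolonize)

layout <- experiment_layout()                     # 10 plots, change at month 26
counts <- simulate_counts(layout, trajectory_params(), seed = 1)
fit    <- fit_gam(counts)                         # Poisson, treatment + plot smooths
fit
#> Treatment-by-time GAM (poisson, log link)
#> deviance: 602.728  total edf: 76.74  scale: 1
#> smooth edf:
#>     s(time):control     s(time):kr_plus s(time):rodent_plus     s(time):plotP01
#>                0.00                7.90               18.82                6.50
#> ...

dc <- difference_smooth(fit, "control", "kr_plus")
detect_convergence(dc, intervention = 26, sustain = 6)
#> Convergence at month 47 ( 21 months after the intervention )

dc2 <- difference_smooth(fit, "control", "rodent_plus")
detect_convergence(dc2, intervention = 26, sustain = 6)
#> Convergence at month 27 ( 1 months after the intervention )
```

The flat control smooth (edf 0) and wiggly rodent_plus smooth (edf 18.8)
are the generator's truth showing through: controls sit at a constant mean
while plots that lacked any resident community recover immediately but
oscillate. The difference curves put the kangaroo-rat recovery delay on
plots with an established rodent community about 20 months behind the
empty plots, the experiment's central contrast.

`run_all(pipeline_config(seed = 1), output_dir = "out")` runs every stage
(three GAM metrics, difference curves and convergence reports, influx
table, multistate candidate set with AIC table, seasonal plant pCCA) and
writes CSV outputs plus a YAML run manifest.

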