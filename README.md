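# devilgrowth

Growth-law inference for untreated tumours measured in wildlife
mark–recapture studies.

Devil facial tumour disease (DFTD) — a transmissible cancer of Tasmanian
devils — is one of the very few systems where solid tumours grow in the
complete absence of treatment while being measured repeatedly in the wild.
The data such monitoring produces are statistically thorny: a handful of
calliper-derived volumes per tumour (often just one), captures ~90 days
apart, and no knowledge of when any tumour started growing. `devilgrowth`
is an R package for exactly this inference problem, for disease ecologists
and cancer modellers alike.

## What it does

* **Five classical growth laws** for volume $V(t)$ (cm³, days) with closed-form
  solutions: exponential ($dV/dt = rV$), logistic ($rV(1-V/K)$), Mendelsohn
  ($rV^b$), Gompertz ($rVe^{-\rho(t-t_0)}$), von Bertalanffy
  ($\alpha V^{2/3} - \beta V$).
* **Lognormal-error maximum likelihood with latent onsets**:
  $\ell = \sum_{i,j} \log N(\log V_{i,j};\, \log V(t_{i,j};\theta,t_{i,0}),\, \varepsilon)$,
  where each tumour's anchor time $t_{i,0}$ (the day it passed the
  reference volume $V_0 = 0.125$ cm³) is profiled out of the likelihood,
  as is the shared error variance $\varepsilon$.
* **AICc model selection** across cohort splits (ploidy, facial location,
  sex), $\mathrm{AICc} = 2k - 2\ell + 2k(k+1)/(n-k-1)$ with $n$ =
  measurements per split.
* **Bayesian credible intervals** from covariance-adaptive MCMC on a
  degrees-of-freedom-honest marginal posterior, and **permutation tests**
  for group differences in growth rate.
* **A synthetic cohort generator** reproducing the sampling design
  (quarterly captures, lognormal noise, detection floor, mortality
  censoring near maximum volume) with ground truth attached, so the whole
  pipeline is testable end to end.

Everything is tidyverse-shaped: measurement tables in, tibbles out,
`tidy()`/`glance()`/`augment()` on fitted objects, `autoplot()` everywhere.

## Worked example

Simulate a cohort under the default study world (62 tumours, ~1.4 captures
each, logistic growth with diploid-like and tetraploid-like groups), then
ask which law the data support:

```r
library(devilgrowth)

cohort <- simulate_cohort(cohort_config(), seed = 1)
cmp <- compare_growth_models(
  cohort,
  splits = list(all = list(), diploid = list(ploidy = "diploid"),
                tetraploid = list(ploidy = "tetraploid")),
  control = fit_control(multistart = 8, seed = 1))
aicc_wide(cmp)
#> # A tibble: 5 × 5
#>   model               k   all diploid tetraploid
#>   <fct>           <int> <dbl>   <dbl>      <dbl>
#> 1 exponential         1  23.5    23.5      61
#> 2 logistic            2   0       0         0
#> 3 mendelsohn          2  15.9    11.8       8.82
#> 4 gompertz            2  14.6    11.0       2.25
#> 5 von_bertalanffy     2 116.    108.       71.4
```

The generating (logistic) law has ΔAICc = 0 in every split; the
one-parameter exponential law pays 23.5 AICc points on the pooled data.
Fit the winning law to the diploid split and quantify uncertainty:

```r
fit <- fit_growth(filter_cohort(cohort, ploidy = "diploid"), "logistic",
                  control = fit_control(multistart = 8, seed = 1))
fit
#> <growth_fit> Logistic law, 43 measurements on 31 tumours
#>   theta:   r = 0.01605, K = 325
#>   epsilon: 0.004045   logLik: 57.459   AICc: -110.62

post <- sample_posterior(fit, n_steps = 1000, n_chains = 2, burn_in = 500,
                         seed = 2)
credible_interval(post)
#> # A tibble: 2 × 5
#>   parameter estimate    lower      upper level
#>   <chr>        <dbl>    <dbl>      <dbl> <dbl>
#> 1 r           0.0158   0.0141     0.0174  0.95
#> 2 K         425.     179.     13450.      0.95
```

The daily growth rate is recovered tightly (truth: 0.016/day). The
carrying capacity's upper credible limit is enormous — that is the
signature of mortality censoring: hosts die as tumours approach maximum
volume, so the plateau is barely observed. Finally, do the two karyotype
groups grow at different rates?

```r
permutation_test(cohort, "ploidy", model = "logistic", n_perm = 199,
                 seed = 3, control = fit_control(multistart = 3))
#> <perm_test> |r_diploid - r_tetraploid| under the logistic law
#>   observed = 0.0089376, p = 0.005 (199 permutations of 'ploidy' labels)
#>   diploid: r = 0.01605, K = 325
#>   tetraploid: r = 0.02498, K = 120.1
```

Here the generator truly gave the tetraploid-like group a faster rate
(0.026 vs 0.016/day), and the permutation test detects it.

Real data enter through `read_measurements("cohort.csv")` — long CSVs with
`tumour_id`, `day` (or ISO `date`), and either `volume_cm3` or the
calliper dimensions `length_cm`/`width_cm`/`depth_cm` (converted by the
rectangular product by default, `volume_convention = "ellipsoid"` for
π/6·LWD). A command-line wrapper (`inst/cli/devilgrowth.R`, or
`run_cli()`) exposes `simulate`, `fit`, `compare`, `ci` and `permtest`
subcommands.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

runs the installed package through the full pipeline — simulating a
default cohort from the given seed, comparing all five laws across ploidy
splits, fitting and sampling the posterior for the diploid group, and
permutation-testing the ploidy contrast — printing each stage's results,
and writes the JSON report to `--out`.

## Documentation

The methods vignette (`vignettes/growth-law-inference.Rmd`) describes the
statistical model, the latent-anchor convention and why the reference
volume is cosmetic, the posterior-target choice behind the credible
intervals, what the synthetic world does and does not emulate, and the
package's numerical conventions.
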