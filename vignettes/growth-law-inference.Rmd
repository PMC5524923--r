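---
title: "Growth-law inference for untreated tumours: models, likelihood, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Growth-law inference for untreated tumours}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(devilgrowth)
```

## The problem

How do solid tumours grow when nobody treats them? Devil facial tumour
disease (DFTD), a clonally transmissible cancer of Tasmanian devils, is one
of the few systems where that question can be answered with field data:
infected animals are trapped roughly quarterly in capture–mark–recapture
monitoring, their facial tumours are measured with callipers, and no
intervention ever occurs. The resulting data are long-format tables — one
row per capture with a tumour id, a day, and a volume in cm³ (from the
rectangular product of calliper length, width and depth), plus covariates
(host sex, tumour ploidy, facial location).

Two features make these series statistically awkward:

* **Sparseness.** Most tumours are seen once or twice; a cohort of ~60
  animals yields only ~90 measurements.
* **No common clock.** Nobody knows when a tumour was implanted. Each
  series has times relative to its own first capture, and tumours are first
  seen at wildly different stages of growth.

`devilgrowth` implements the full inference pipeline for such data: five
candidate growth laws, a lognormal-error likelihood with a latent
per-tumour anchor time, AICc model selection, MCMC credible intervals,
permutation tests for group differences, and a synthetic-cohort generator
that stands in for (unreleased) field data.

## Growth laws

Five classical one-dimensional laws for volume $V(t)$ are supported, each
with a closed-form solution through the anchor condition $V(t_0) = V_0$:

| law | $dV/dt$ | solution | $k$ |
|---|---|---|---|
| exponential | $rV$ | $V_0 e^{r(t-t_0)}$ | 1 |
| logistic | $rV(1-V/K)$ | $K/[1+(K/V_0-1)e^{-r(t-t_0)}]$ | 2 |
| Mendelsohn | $rV^b$ | $[(1-b)r(t-t_0)+V_0^{1-b}]^{1/(1-b)}$ | 2 |
| Gompertz | $rVe^{-\rho(t-t_0)}$ | $V_0\exp\{\tfrac{r}{\rho}(1-e^{-\rho(t-t_0)})\}$ | 2 |
| von Bertalanffy | $\alpha V^{2/3}-\beta V$ | $[\alpha/\beta-(\alpha/\beta-V_0^{1/3})e^{-\beta(t-t_0)/3}]^3$ | 2 |

Units are days and cm³ throughout. The Gompertz right-hand side is
time-inhomogeneous; its clock is anchored at the same per-tumour $t_0$ as
the solution, the only reading consistent with that closed form. The
Mendelsohn exponent is a free parameter on $(0,1)\cup(1,3]$ — $b = 1$ is
excluded because it reproduces the exponential law exactly — and with
$b > 1$ the solution blows up at a finite time, which the package treats
as a domain error reporting the boundary. Closed forms are verified against
adaptive Runge–Kutta integration of the defining ODEs in the test suite.

```{r}
growth_solution("logistic", c(r = 0.016, K = 364), t = c(0, 300, 600))
```

## The statistical model

Let tumour $i$ have volumes $V_{i,j}$ at times $t_{i,j}$ (days since its
first capture, so $t_{i,1} = 0$). Measurement error, short-term growth
fluctuations, and tumour-to-tumour variation are absorbed into a single
lognormal error:

$$\ell(\theta, \{t_{i,0}\}, \varepsilon) = \sum_{i,j}
  \log N\!\left(\log V_{i,j};\ \mu = \log V(t_{i,j}; \theta, t_{i,0}),\
  \sigma^2 = \varepsilon\right).$$

Because no baseline exists, each tumour carries a latent **anchor time**
$t_{i,0}$: the day (relative to first capture, possibly negative) when its
curve passed the reference volume $V_0 = 0.125$ cm³ — a 0.5 cm cube,
roughly the smallest detectable facial tumour. $V_0$ is purely cosmetic:
changing it translates every anchor by the same travel time and leaves the
maximised likelihood unchanged (an acceptance test refits with
$V_0 = 100$ cm³ and checks the log-likelihood moves by less than $10^{-6}$).

Fitting is nested. The outer optimiser (bounded quasi-Newton, log-scale
parameters, one data-driven start plus Latin-hypercube multistarts) searches
$\theta$; at each evaluation every $t_{i,0}$ is profiled by a 1-D grid +
golden-section search on $[-3000, 3000]$ days, and $\varepsilon$ by its
closed form $\hat\varepsilon = SS/n$ (floored at $10^{-8}$ so noise-free
fixtures stay finite). The profiling interval is generous on purpose: the
epidemic at the monitored site began in 2006, so no tumour can predate the
data by more than a decade.

Design choices worth stating explicitly:

* **Singletons stay in.** A single-capture tumour is fitted exactly by its
  anchor time, so it contributes no residual — only its observation count
  (which enters AICc's $n$). `fit_control(min_points = 2)` enables the
  stricter alternative.
* **$k$ counts structural parameters only** (1 for exponential, 2
  otherwise). The anchors and $\varepsilon$ are profiled nuisances; counting
  them would make AICc meaningless at these sample sizes.
* **Exponential sanity anchor.** Exponential growth with lognormal error is
  exactly a per-tumour-intercept linear model in log space; the generic
  optimiser is required (by test) to match that closed form to $10^{-6}$
  in $r$.

## Model selection

`compare_growth_models()` fits every law to every cohort split (all data;
diploid/tetraploid; mucosal/dermal; female/male — ploidy and location
splits drop tumours with unknown labels) and reports $\Delta$AICc within
each split, with $n$ = measurements in the split and ties broken toward
the smaller model. Failed cells are recorded as missing rather than
aborting the table.

```{r, eval = FALSE}
cohort <- simulate_cohort(cohort_config(), seed = 1)
compare_growth_models(cohort, splits = list(all = list(),
                                            diploid = list(ploidy = "diploid")))
```

## Uncertainty

**Credible intervals.** `sample_posterior()` runs adaptive random-walk
Metropolis chains over $\theta$ (log scale, covariance-adaptive proposals
during burn-in, split-chain $\hat R$ reported, warning above 1.05) under
independent log-uniform priors on each parameter's bounds — the defaults
are $r \in [10^{-4}, 1]$/day and $K \in [1, 10^5]$ cm³, broad enough to be
vague at these data scales.

The posterior *target* deserves a paragraph, because the obvious choice is
wrong. Plugging the profiled $\hat\varepsilon = SS/n$ into the likelihood
("`target = "profile"`", available as an option) ignores that the $m$
profiled anchors absorb roughly one residual degree of freedom each; with
~1.4 captures per tumour, $m$ is close to $n$ and the plug-in variance is
several-fold too small, so the target is far too sharp. In simulation its
nominal 95% intervals for $r$ covered the truth in only ~60% of replicate
cohorts. The default `target = "marginal"` instead integrates
$\varepsilon$ out under a Jeffreys prior and charges one degree of freedom
per anchor (a Laplace-style correction), giving
$\log p(\theta) \propto -\tfrac{\nu}{2}\log SS(\theta)$ with
$\nu = n - m$. The $\theta$-dependence of the anchors' Laplace curvature
factor is neglected. Coverage of the marginal target is checked in the
acceptance suite (28/30 on reduced cohorts at the time of writing) along
with a conjugate-normal closed-form check of the sampler itself.

**Permutation tests.** Group differences in growth rate are tested by
refitting the chosen law to each group and comparing
$|\hat r_A - \hat r_B|$ (the leading rate parameter; $\alpha$ for von
Bertalanffy) against the distribution obtained by permuting group labels
at the tumour level — a tumour's measurements always move together.
Permuted refits are warm-started from the observed group MLEs, the
observed statistic is computed through the identical warm-started path so
that a permutation reproducing the observed labelling ties it exactly, and
the p-value uses the add-one convention
$p = (1 + \#\{T^{perm} \ge T^{obs}\})/(1 + n_{perm})$, which cannot reach
zero. Type-I error at $\alpha = 0.05$ is verified by simulation in the
acceptance suite.

## The synthetic world

`simulate_cohort()` generates cohorts with the statistical structure the
analysis assumes, so every stage is testable without field data. Defaults
state that world once:

| setting | default | why |
|---|---|---|
| tumours | 62, one per host | cohort size of the monitored population |
| captures per tumour | $1+\mathrm{Geom}(1/1.4)$, mean 1.4 | ~87 measurements on 62 animals |
| capture gaps | 90 d ± 15 d SD, floored at 1 d | quarterly trapping with field jitter |
| groups | logistic $r=0.016, K=364$ (diploid-like); $r=0.026, K=172$ (tetraploid-like), equal mix | point estimates for the two karyotypes; the true mix is unpublished, so weights are equal |
| onset | $t_0 \sim U(-400, 0)$ d before first capture | tumours are first seen at various stages but within the epidemic's local history |
| noise | $\varepsilon = 0.04$ ($\pm 20\%$ volume) | calliper error plus growth fluctuation; unstated in the field study |
| censoring | observation stops once a volume exceeds $0.8K$ | host mortality as tumours approach maximum volume; `1` disables |
| detection floor | 0.125 cm³ | sub-reference tumours go unnoticed |

Mortality is a hard threshold, not a hazard — the generator reproduces the
*mechanism* (the upper end of the volume distribution is unobservable,
which is what makes the upper credible limit of $K$ explode), not a
survival model. Onset times are independent of capture schedules, tumours
within a host do not interact, and trapping detection is perfect; none of
these simplifications is believed to matter for the estimators under test,
but a green test here certifies recovery under *this* world, not under the
field's. Ground truth (per-tumour $\theta$, anchors, censoring counts)
rides along as an attribute for recovery tests.

## Numerical notes

* Solutions are evaluated on the log scale in compiled code, so scanning
  anchors across $\pm 3000$ days cannot overflow; out-of-domain predictions
  contribute a large finite penalty during profiling and $-\infty$ to the
  likelihood (a rejected point, not an exception).
* The anchor profile uses a 25-day grid scan before golden-section
  refinement; the likelihood surface in $t_0$ is smooth at the 60+ day
  width set by $1/r$, so the grid cannot skip optima at biologically
  plausible rates.
* Anchor estimates that hit the $\pm 3000$-day bracket are flagged and
  warned about rather than silently accepted.
* AICc ties (exact, to $10^{-9}$) break toward fewer parameters;
  comparisons that cannot be fitted at all (e.g. $n \le k+1$) are missing
  cells.
* All randomness is seeded: fits (start placement), the generator, the
  sampler, and the permutation test are bit-reproducible given their seeds.

## Limitations

Growth-rate heterogeneity between tumours is folded into the lognormal
error rather than modelled hierarchically; with ~90 measurements a
hierarchical onset-time prior is not estimable, and this package
deliberately stops short of it. The censoring mechanism is not part of the
likelihood, so $K$ estimates on heavily censored cohorts are wide and
right-skewed (the simulation studies quantify how much). The volume
convention for calliper dimensions (rectangular vs ellipsoid) is genuinely
ambiguous in field protocols; both are offered and every report records
which was used.
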