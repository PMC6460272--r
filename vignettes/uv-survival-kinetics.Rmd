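---
title: "UV survival kinetics from plate counts: model, estimators and design choices"
author: "uvkin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{UV survival kinetics from plate counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uvkin)
```

## The problem

Germicidal UV experiments on bacteria are usually read out as plate counts:
a broth culture is spread on agar, irradiated for increasing times, and the
colonies that grow afterwards are counted as colony-forming units (CFU).
For many vegetative cells the surviving population declines exponentially
with dose, and the whole experiment can be summarised by a single rate — the
survival constant — together with derived quantities such as the half-life
and the exposure needed to push the population below one viable cell.

`uvkin` implements this analysis end to end: the dose (fluence) model, the
log-linear estimator of the survival constant, the categorical tests usually
run alongside on isolate phenotype data, and a seeded generator of synthetic
experiments so every stage can be exercised without laboratory data.

## The model

Survival is modelled as first-order decay,

$$ N_t = N_0 \, e^{-k x(t)}, $$

where $N_0$ is the unirradiated control population, $N_t$ the population
after exposure $t$ (minutes), and $x(t)$ is either the exposure time itself
(**time mode**, $k$ in min$^{-1}$) or the total fluence (**fluence mode**).
The total fluence delivered through a culture of transmittance $T$ by a lamp
of intensity $H_0$ (W/m$^2$) and spectral bandwidth $b$ (nm) is taken
proportional to

$$ H(t) = T \, b \, H_0 \, t, $$

with the proportionality constant fixed at 1 (so the fluence unit is
W·m$^{-2}$·nm·min).  Nothing in the analysis depends on that constant: it
cancels between the two modes, and `fit_survival()` guarantees
$k_\mathrm{time} = k_\mathrm{fluence} \cdot T b H_0$ on any series.
Transmittance follows the Beer–Lambert convention $T = 10^{-\mathrm{OD}}$,
so a stationary culture at OD$_{600} = 1.2$ transmits 6.3% of the incident
light.

Two algebraic points are worth stating because published forms of the
pointwise solutions sometimes carry typographical errors: the inversions
implemented here are the consistent ones,

$$ k = -\frac{\ln(N_t/N_0)}{x(t)}, \qquad
   t = \frac{\ln(N_0/N_t)}{k} \ \ (\text{time mode}), $$

and the natural logarithm is used throughout, matching the $e$-base of the
decay law.

## Estimation

`fit_survival()` regresses $y_i = \ln(N_i/N_0)$ on $x_i$ by ordinary least
squares, fitting **both slope and intercept**.  Forcing the line through the
origin would use the control count twice (once in the ratio, once as a
constraint) and would change the meaning of the reported $R^2$; with a free
intercept, `r2` is the conventional coefficient of determination of the
log-linear fit.  The survival constant is $k = -\text{slope}$ (time mode) or
$-\text{slope}/(T b H_0)$ (fluence mode); the `slope` field is always in
natural-log units per minute.

Numerical and degenerate-input choices:

* **Zero counts** are excluded from the regression — their logarithm is
  undefined, and any substitution constant (0.5 CFU and the like) biases the
  slope in a dilution-dependent way.  Excluded times are surfaced in
  `excluded_zero_times` so the caller can see how much of the tail was lost.
* A fit needs at least two positive-count observations; otherwise a
  numerical error is raised.
* A **non-negative slope** (no kill, or growth) is not an error: the fit is
  returned with `non_decaying = TRUE` and `k`/`half_life_min` set to `NA`.
* A perfectly flat series has zero log-variance; its `r2` is reported as 1
  because the line reproduces the data exactly.
* If both an OD600 and an explicit transmittance are configured they must
  agree under $T = 10^{-\mathrm{OD}}$ to within $10^{-9}$; disagreement is
  an error, not a warning, because a silent choice between the two would
  change every fluence-mode constant.

Default fitting mode is `"time"`: the fluence factors are constant within an
experiment, so they are absorbed into $k$, and a per-minute constant is what
half-life and time-to-threshold questions need.  Fluence mode is provided to
re-express the same decay per unit dose.

The half-life is $\ln 2 / k$.  For $k = 0.035$/min this is 19.80 min, i.e.
0.33 **hours** — a value sometimes quoted with a minutes unit by slip; the
package reports both scales in its printed output.  `time_to_threshold()`
inverts the decay law and requires a strictly positive threshold: under
exponential decay the time to literally zero survivors is infinite, so
extinction questions should be posed as time to fewer than one CFU.

## The categorical battery

Phenotype data from isolate collections (site × morphology tables,
pigmentation × resistance tables) and treatment experiments are handled by
four classical tests behind typed, validated interfaces:

* `chisq_test()` — Pearson's chi-square with expected counts from the
  margins; the Yates continuity correction is applied only to 2×2 tables,
  its standard scope, even when requested on larger ones.  A zero row or
  column margin is a degenerate table and is rejected.
* `fisher_exact()` — two-sided exact test for 2×2 tables under the
  probability-mass ordering (the p-value sums the hypergeometric
  probabilities of all tables with the observed margins that are no more
  likely than the observed one).  Mid-p and tail-doubling variants exist;
  the probability-mass convention was chosen because it is the one used by
  the standard R implementation practitioners report.
* `kruskal_wallis()` — mid-ranks with the standard tie correction; an
  all-identical sample is reported as $H = 0$, $p = 1$ rather than an error.
* `two_way_anova()` — balanced two-factor design with interaction, the
  standard decomposition
  $SS_\mathrm{total} = SS_A + SS_B + SS_{AB} + SS_\mathrm{error}$ and F
  ratios against the error mean square.  Balance is enforced (the Type
  I/II/III distinction is then moot); unbalanced input is rejected with a
  message to balance or subsample.  With zero error variance, a factor with
  nonzero sum of squares is reported as $F = \infty$ and an all-constant
  grid as $F = 0$, both flagged with a note.

The computational kernels are the reference implementations in base R's
stats package; this module contributes the validation, the degenerate-case
contracts and the typed containers.  The test suite cross-checks every test
against independently hand-coded oracles (full hypergeometric enumeration,
brute-force sums of squares, textbook statistics).

## What the synthetic generator emulates

`simulate_survival_series()` draws, per replicate:

1. a control population $N_0$ uniform on a configurable range (default
   $1.5\times10^7$–$2.5\times10^7$ CFU — only the range is known for the
   experiments this emulates, so no tighter distribution is assumed);
2. expected plated counts $\mu_t = N_0 e^{-k t} \cdot d$ on the default
   exposure grid 0/15/30/45/60 min, where $d$ is a single multiplicative
   plated fraction (default $10^{-5}$, chosen so a $2\times10^7$ control
   plates about 200 colonies — inside the conventional 30–300 countable
   window; the true plated fraction of the emulated protocol is not
   recorded, so this is a package choice);
3. observed counts as independent Poisson draws around $\mu_t$, the
   standard counting model for plate counts.  Expectations above a
   configurable ceiling (default $10^9$) are returned as rounded means
   instead, guarding the Poisson sampler when an undiluted huge population
   is requested.

Seeding contract: one root seed, with a deterministic child stream per
replicate, so the same spec is byte-reproducible and *adding* replicates
never changes the earlier ones.

`simulate_isolate_table()` produces multinomial contingency tables whose
cell probabilities are the outer product of the marginals tilted by
$\exp(\theta u_i v_j)$ with centred integer scores; $\theta = 0$ gives exact
independence and serves as the null model for calibration tests.
`simulate_ae_grid()` draws balanced Poisson treatment × time grids for the
ANOVA.

What the generator deliberately does **not** model: serial-dilution
pipetting error, plating/spreading variability, lamp drift, shoulder or
tail phases of inactivation, photoreactivation, and spatial effects on the
plate (such as survivors accumulating at the dish edge).  Consequently
synthetic series are cleaner than real ones — their log-linear fits reach
$R^2 \approx 0.99$ where comparable laboratory series report values nearer
0.9 — and a passing recovery test demonstrates correctness of the
estimator under Poisson counting noise, not robustness to every source of
experimental error.

Problem sizes in the test and acceptance runs are the package's own
choices: 200 replicates for parameter recovery, 500 for calibration
properties, which put Monte-Carlo error comfortably below the tolerances
being asserted while keeping a full run in seconds.

## Pipeline and interfaces

CSV dialects are deliberately minimal: survival series as
`time_min,cfu` (the $t = 0$ row doubles as the control count unless `n0` is
configured), contingency tables with a label column and labelled header,
treatment grids long-format as `treatment,time_min,replicate,cfu`.  Configs
are YAML key-value files.  `run_pipeline()` chains simulate → read → fit →
stats and emits a versioned JSON report (`schema_version` is pinned so
downstream fixtures can detect format changes) whose provenance block
carries the seed, a config fingerprint, timestamp and package version; all
randomness flows from the single seed.  The `uvkin` command line
(`inst/scripts/uvkin.R`, a two-line wrapper over `cli_main()`) exposes
`fit`, `stats`, `simulate` and `run`, with exit codes 0 (success),
2 (parse), 3 (validation) and 4 (numerical failure).

## Worked example

```{r example}
series <- read_survival_csv(
  system.file("extdata", "blc01_survival_synthetic.csv", package = "uvkin"))
fit <- fit_survival(series)
fit
half_life(fit$k)
time_to_threshold(fit$k, n0 = 2e7, nt = 1)
```

## Known limitations

* Single-phase first-order kinetics only: no shoulder/tail, Weibull or
  log-logistic survival models, and no spore-specific kinetics.
* The exact test is restricted to 2×2 tables; no r×c exact test and no
  post-hoc multiple-comparison machinery.
* The ANOVA requires balance; it will not silently drop or weight cells.
* Zero-count exclusion means heavily-killed designs (expected counts below
  ~1 at late times) lose their tail and the estimator inherits a mild
  downward truncation bias; choose the plated fraction so that counts stay
  in the tens-to-hundreds across the grid.
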