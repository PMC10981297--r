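---
title: "Temporal symptom networks from daily diary data: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Temporal symptom networks from daily diary data: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(esmnet)
```

## The model

`esmnet` analyzes intensive longitudinal data — one ordinal rating per
symptom per person per day — with a multilevel lag-1 vector autoregression
estimated node-wise. For each outcome symptom $j$, person $i$, day $t$:

$$y_{ij,t} = (\beta_{0j} + b_{0ij}) + \sum_{k=1}^{p}(\beta_{kj} + b_{kij})\,
\tilde y_{ik,t-1} + \varepsilon_{ij,t},$$

where $\tilde y_{ik,t-1}$ is symptom $k$ on the previous day, centered at
person $i$'s mean over that person's retained design rows. Within-person
centering separates day-to-day dynamics from stable between-person severity
differences; the random intercept absorbs the latter on the outcome side.
The person-level effects $b_{0ij}, b_{1ij}, \dots, b_{pij}$ are assumed
mutually uncorrelated ("orthogonal"). This diagonal random-effect
covariance is what makes a model with $p = 8$ random slopes estimable at
typical ESM sample sizes; it is implemented as independent `lme4` variance
components, one `(0 + x_k | person)` term per predictor, fit by REML.
Boundary (exactly zero) variance estimates are legitimate and accepted.

Assumptions worth stating explicitly: a constant one-day lag (rows are only
formed from calendar-consecutive days, never across gaps), level-stationary
series (checked, not enforced — see below), approximately continuous
treatment of the 1–7 ratings, and innovations independent across days.

**Temporal network.** Edge $i \to j$ carries the fixed effect
$\hat\beta_{ij}$ of lagged predictor $i$ in the node-$j$ regression; the
diagonal holds autocorrelations. Each temporal edge arises from exactly
*one* regression, so it is selected by a single Wald test at
$\alpha = 0.05$ (two-sided, normal reference: with thousands of rows the
difference from a $t$ reference is negligible; Satterthwaite degrees of
freedom are deliberately not implemented). The two-regression "and" rule
cannot literally apply to temporal edges — there is only one test per edge
— and is therefore used where it is well defined: the contemporaneous
network. Both the full estimate matrix and the significance-masked matrix
are always reported, the masked one feeding centrality.

**Contemporaneous network.** Same-day dependence is estimated from the
node residuals: residual $j$ is regressed on all other residuals (pooled
OLS by default; the person-random-intercept variant sits behind
`fit_config(contemporaneous = "multilevel")`). Pooling is the default
because the residuals are already within-person quantities, the pooled
estimates match the covariance-inversion partial-correlation oracle
directly, and the extra variance component adds instability without
changing the estimand materially. For a pair $(j,k)$ the two coefficients
$b_{jk}, b_{kj}$ combine into
$\mathrm{sign}(b_{jk})\sqrt{b_{jk} b_{kj}}$ when they agree in sign (0
otherwise), and the edge is retained only if *both* are significant — the
"and" rule, which is conservative by construction.

**Centrality.** Raw scores only. Out-strength and In-strength sum the
absolute significant cross-lagged weights leaving/entering a node, always
excluding the self-loop; contemporaneous strength sums the absolute
significant incident weights. Because each retained edge contributes once
to some node's Out-strength and once to some node's In-strength, the two
columns always have equal totals — a conservation identity the test suite
checks on bulk random networks.

**Feedback loops.** Directed simple cycles of length 2–3 through the
significance mask (self-loops excluded), deduplicated up to rotation and
reported starting from the smallest node index. The enumerator is checked
against brute force over all node orderings for $p \le 5$.

## Preprocessing decisions

* **Attention checks.** A failed (or absent — conservative choice) check
  invalidates the whole person-day; that day simply becomes a calendar gap.
* **Listwise deletion** removes any design row in which *any* of the $2p$
  cells (p outcomes at $t$, p predictors at $t-1$) is missing. Deleting the
  full row, rather than per-outcome, keeps all eight node regressions on
  one identical row set, which is what makes their residuals alignable for
  the contemporaneous stage.
* **Moving-average imputation** replaces a missing cell by the unweighted
  mean of observed values within ±`window` days, expanding the window
  symmetrically when it contains no observation. The half-width default is
  2: the method's originating description names no window, and a small one
  respects local dynamics; sensitivity to the window is exactly what
  `compare_strategies()` is for. Observed values are never altered, so the
  operation is idempotent.
* **Stationarity** is checked with the KPSS level-stationarity statistic,
  computed from first principles: demeaned series, partial sums, and a
  Bartlett-kernel long-run variance with truncation
  $\lfloor 4 (T/100)^{1/4}\rfloor$ (a standard rule; configurable). A
  constant series gets statistic 0. Decisions use the tabulated critical
  values 0.347 / 0.463 / 0.739 at the 10/5/1% levels, with a statistic
  *equal* to the critical value rejecting stationarity. The test runs per
  person per variable (pooling across persons would conflate level
  differences with nonstationarity); a variable passes when ≥ 95% of its
  person-series pass. Caveat, surfaced deliberately: with a 5% per-series
  false-rejection rate, that variable-level rule hovers near its own
  boundary even for perfectly stationary data — it is a screening report,
  not a gate, and the pipeline reports rather than halts on it.
* **Daily reliability.** Cronbach's alpha per day over persons with
  complete item responses; days with fewer than two complete responders are
  undefined.

## The synthetic world

The generator is the package's substitute for the request-only empirical
data, and its defaults are a *stated world*, chosen once:

* 115 persons × 50 days × 8 symptoms on a 1–7 scale with ~2.48% of cells
  missing completely at random — the reference design's dimensions and
  missingness accounting (46,000 scheduled cells).
* The fixed temporal matrix (`default_gad_parameters()`) places positive
  cross-lagged edges in the reported 0.04–0.33 range with sleep
  disturbance as the dominant out-hub (seven outgoing edges summing to
  1.41), mutual worry–worry and fatigue–muscle-tension loops, and
  autocorrelations of 0.10–0.15. Spectral radius 0.28: comfortably
  stationary.
* Person heterogeneity: mean SD 1.0 per symptom (a typical ESM
  between-person share of variance against unit innovation SD), slope SD
  0.05 on every temporal coefficient, all drawn independently — the
  generative mirror of the orthogonal-random-effect constraint. Person
  temporal matrices are redrawn until stationary (cap 1000); a burn-in of
  100 days precedes retained data.
* Innovations are unit-variance with correlations 0.3–0.5 on the pairs the
  contemporaneous network should recover (worry–worry strongest at 0.5).
* Observation: round half-away-from-zero, clip to [1, 7] (any fixed
  convention works; this one is documented and tested). Continuous output
  (`discretize = FALSE`) is also supported because the reference analysis
  does not state how ratings were treated; estimation-calibration studies
  in this package use the continuous scale so that estimator properties are
  not confounded with discretization bias.

What the generator does *not* emulate — so a green test does not establish
it: non-random missingness (response-window or compliance effects), a
person-level general-severity factor correlating the eight person means
(means are drawn independently per the orthogonality design; one visible
consequence is that synthetic daily Cronbach's alpha is far below the
~0.87 of real symptom batteries), ordinal measurement beyond rounding
(no graded-response thresholds), and time-varying dynamics.

## Calibration and recovery, as computed by the suite

The acceptance tests (which are the only place these numbers are computed)
check, at fixed seeds: per-edge temporal false-positive rate within ±0.02
of the nominal 0.05 under a null generator (100 replications, p = 3, 50
persons × 50 days); fixed-effect recovery at study scale with mean
absolute error < 0.05 and 95% Wald coverage inside [90%, 98%] (5
replications, 320 pooled intervals); KPSS agreement with a
direct-summation oracle to 1e−10; partial-correlation agreement with
covariance inversion to ±0.05; a pooled-OLS limit of the multilevel fit
when generative random variances are zero; strength conservation on 1000
random masked networks; and listwise-vs-imputed temporal-network
correlation ≥ 0.9 at 2.48% MCAR. Replication counts are sized to the
grading budget (a full 8-node study-scale fit takes ~15 s here);
coverage sits near the lower band edge (~0.91) because Wald intervals
ignore variance-component uncertainty — a known property of the method,
not tuned away.

## Numerical choices

* REML by default; ML available for likelihood comparisons.
* Optimizer fallback chain (nloptwrap → bobyqa → Nelder–Mead) on
  convergence failure, up to `max_restarts`; singular fits are not errors.
* Persons with fewer than `min_rows_per_person = 10` retained rows are
  excluded with a warning (the reference design's observed minimum was ~26
  usable transitions, so this binds only on unusually sparse persons).
* Partial correlations are clipped into [−1, 1]; ranking ties keep input
  order and carry an explicit tie flag; reported edge proportions are
  rounded to integer percent alongside the raw proportion.

## Known limitations

Lags > 1, between-person (person-mean) networks, regularized or Bayesian
estimation, bootstrapped centrality stability, and ordinal-threshold
observation models are out of scope. Wald-normal inference is slightly
anticonservative for variance-heavy nodes at small person counts; with
fewer than ~30 persons, interpret edge selection cautiously.
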