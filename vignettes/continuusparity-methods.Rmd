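---
title: "Methods: demographic trajectories and the continuusparity cohort model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: demographic trajectories and the continuusparity cohort model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(continuusparity)
```

## The analysis problem

A cohort of single-queen ant colonies is censused once per week from
foundation until (and ~4 weeks past) the queen's death: eggs, worker
pupae, queen pupae, winged- and wingless-male pupae, and queen survival.
Three demographic questions drive the package:

1. **When does reproduction peak, and in what currency?** Total egg
   output peaks in mid-life, but the *relative* investment in sexuals
   (new queens and males) keeps rising and peaks late.
2. **How does mortality relate to reproduction?** Mean-standardized
   mortality stays below its average level until after the
   sexual-investment peak — selection is maintained into old age.
3. **How is investment split between castes and sexes**, and is the
   split robust to the assumed queen/worker biomass conversion?

## Life table and mortality measure

With weekly censuses and no losses to follow-up, deaths are
interval-censored to census weeks. At age $x$ the risk set $n(x)$ holds
every queen whose death week is $\ge x$; queens still alive at their
last census leave the risk set without a death. We report

* discrete hazard $q(x) = d(x)/n(x)$,
* central death rate $m(x) = d(x)/\left(n(x) - d(x)/2\right)$,
* survivorship by product-limit recursion $l(x+1) = l(x)(1-q(x))$.

**The mean-standardized mortality trajectory uses the central death
rate by default.** The standardization divides age-specific mortality by
its mean over all post-maturation ages; with complete mortality the last
observed age always carries $q = 1$, and more generally $q$ is bounded
by 1 while the underlying mortality *rate* is not. That bound compresses
the terminal rise so strongly that the relative hazard crosses 1 around
the 60th percentile of the death distribution for essentially any
lifespan distribution with realistic spread. The central death rate — the
standard discrete approximation of the continuous mortality rate, with
terminal value 2 — preserves the late rise, and the crossing then falls
where the shape of the data puts it (around week 29–30 under the default
model, versus week ~26 for the hazard). The hazard remains available via
`mean_standardize(lt, measure = "hazard")`.

## Standardization and trimming

`mean_standardize()` divides values by their mean over the retained
post-maturation ages, so the retained relative values average exactly 1
(the suite asserts this to $10^{-9}$). Maturation defaults to the first
age with positive cohort fecundity; it is overridable because
"maturation" is a biological, not a statistical, notion. By default the
whole life range until the last death is retained; `trim = 0.05` drops
ages where survivorship has fallen below 5%, the usual sensitivity check
for whether conclusions hinge on the noisy terminal ages (on simulated
cohorts the peak landmarks move by at most ~1 week; the suite checks the
median shift across cohorts).

## Smoothing and landmark extraction

`loess_smooth()` is written as explicit per-point tricube weighted least
squares: for each grid point, the `floor(span * n)` nearest neighbours
get tricube weights scaled by the neighbourhood radius and a local
polynomial is fitted. Degree 1 is the default and is what the
equivalence tests pin against an independently coded per-`lm()` oracle
(agreement $\le 10^{-8}$) and against `stats::loess(surface =
"direct")`.

**Landmark extraction smooths at degree 2 with observation weights.**
Two practical findings drove this:

* A span-0.75 *linear* local fit over a 45–50-point age axis is nearly a
  global line; a rise-then-plateau trajectory smooths into a saturating
  ramp whose argmax lands wherever noise puts the last uptick. A local
  *quadratic* at the same span represents rise-then-fall and localizes
  the peak; it also matches the default degree of the figure smoothers
  in the R environment such analyses are usually run in.
* Points at old ages average over very few surviving queens (often 1–5
  of 99). Weighting the local fits by the number of queens alive (for
  fecundity) or at risk (for mortality) is the standard
  inverse-variance-flavoured remedy and removes the tail's outsized pull
  on the smoothed curve.

The mortality crossing is the first age at which the smoothed relative
mortality exceeds 1 and stays above it for ≥ 2 consecutive ages
(single-week blips are noise at these risk-set sizes); ties in peak
detection resolve to the earliest age.

## Investment statistics

Lifetime totals per colony include the post-death window: brood laid
before death is allowed to develop and enters the final counts. The
caste ratio converts queens into worker-equivalent cost units,
$Q c / (Q c + W)$ with $c = (w_Q/w_W)^k$; dry weights are inputs (the
defaults, ratio 2, are placeholders and the pipeline says so loudly) and
`k_sweep()` recomputes the per-colony ratios from raw totals over
$k \in [0.6, 1]$ — the monotonicity of $c$ in $k$ makes the cohort
medians monotone, so the scientific content of the sweep is whether the
*ranking* of treatments changes (it does not, in simulation). Sex ratios
pool winged and wingless males; colonies without sexuals are excluded
from medians rather than imputed.

## The generative cohort model

The simulator's defaults *are* the study conditions: 99 colonies in
three worker-number treatments (31/34/34 at 10/20/30 workers), queen
lifespans with mean 25 weeks and CV 32.2%, cohort egg laying peaking at
~16 weeks with ~25 eggs/week at peak, reproductive death once laying
falls below ~10 eggs/week, an age-increasing queen bias among pupae,
~86% of pupae workers, a queen-biased sex ratio among sexuals (~0.85),
rare winged males (~0.36 per lifetime, median 0), and development lags
of 5/3/3 weeks (queen/male/worker pupae).

Structure, per queen $i$:

* **Lifespan** $D_i \sim \mathrm{round}\,\Gamma(\text{mean }25,
  \text{CV }0.322)$ (shape $1/\mathrm{CV}^2$, scale
  $\text{mean}\cdot\mathrm{CV}^2$): positive, two-parameter, and it puts
  the relative-mortality crossing where the data-analysis pipeline finds
  it (~week 30 at the study's sample size).
* **Reproductive timescale** $z_i = (D_i - L_i)/u_{10}$, where $u_{10}$
  is the age at which the standard egg schedule falls to the 10
  eggs/week threshold and $L_i = 1 + \mathrm{Pois}(1.5)$ weeks is a
  terminal *lethargy* phase. Her expected egg rate is the shared
  gamma-density kernel evaluated in physiological age $a/z_i$, so her
  laying falls below the threshold exactly at lethargy onset; during
  lethargy the rate additionally decays ×0.3 per week. This couples
  schedule and death the way reproductive death demands: laying
  collapses below ~10 eggs/week and the queen dies within days to a few
  weeks. Slow queens ($z>1$) lay proportionally less per week
  (amplitude $\propto 1/z$): pure time-stretching would leave every
  long-lived queen producing at full rate just before her late death,
  and the cohort's sexual-investment trajectory would never decline.
* **Counts**: weekly eggs are Poisson; each egg pupates with
  probability 0.5; caste follows the logistic allocation (asymptotic
  sexual share 0.32, midpoint 16 physiological weeks, scale 2 weeks);
  sexuals are queens with probability 0.87; males are winged with
  probability 0.10; pupae appear after the class lag. The 10-worker
  treatment rears a queen-destined pupa with probability 0.5 —
  treatments affect queen pupae only, leaving eggs and worker pupae
  untouched.

The kernel shape (6) is the one genuinely structural constant: in a
scale family the ratio between threshold-crossing age and peak age
depends only on shape, and shape 6 makes a cohort whose mean lifespan is
25 weeks peak in fecundity at ~16 weeks. Allocation midpoint/scale,
asymptote, the queen probability and the winged probability were
calibrated once, by forward simulation, so the *observed* cohort
statistics land on the study conditions (sexual-investment peak ~27–28
weeks, worker fraction ~0.86, observed median sex ratio ~0.85 under
treatment thinning, winged-male mean ~0.36), and then frozen.
`true_landmarks()` computes the model-implied landmark ages by
deterministic expectation over the lifespan and lethargy distributions
— including the finite-cohort window (median maximum lifespan of an
$n$-queen cohort) and the terminal all-remaining-die census age — so
parameter-recovery tests compare estimates against an honestly derived
truth rather than against the estimator's own average.

Determinism: colony $i$ runs under seed
$(s \cdot 1000003 + i) \bmod (2^{31}-1)$, so identical seeds give
byte-identical tables and enlarging a cohort never perturbs existing
colonies; the caller's RNG state is saved and restored.

**What the model does not emulate.** Egg-counting error (eggs develop
over ~8 days and cluster in piles, so field egg counts are noisy and
double-counted; an optional `egg_double_count_frac` adds carry-over, off
by default) — consequently the simulated egg–pupae Kendall correlations
(~0.85/0.5/0.85) are stronger than field values (~0.70/0.59/0.73), and
tests assert strong positive association rather than those magnitudes.
No worker behaviour, nest space, sperm depletion, or any
molecular/transcriptomic layer; no treatment effect on lifespan or egg
totals (the reference design found none); lifespans are drawn, not
mechanistically caused by an energetic model. Passing recovery tests
therefore show the *pipeline* recovers known demographic structure at
the study's scale — not that the biological model is true.

## Numerical conventions and degenerate inputs

* Quantiles are type 7 (linear interpolation), the convention of the
  environment the reference analyses used; configurable.
* CV uses the $n-1$ standard deviation; undefined for $n<2$ or zero
  mean (error, not NA).
* τ-b is computed from exhaustive pair counts; zero variance in either
  vector yields NA with a warning. The optional p-value is a normal
  approximation, documented as approximate under ties.
* Ratios with empty denominators (caste ratio with $Q=W=0$, sex ratio
  with no sexuals) are NA and excluded from aggregates, never 0.
* Census validation rejects negative or missing counts, duplicated
  (colony, week) keys, and queens that return from the dead; week gaps
  warn by default and abort in strict mode — gaps are flagged, never
  imputed.
* Empty cohorts, all-zero schedules, and zero post-maturation means are
  errors with typed condition classes (`cp_validation_error`,
  `cp_format_error`, `cp_config_error`, `cp_io_error`).

## Problem sizes

The test suite simulates 99-colony cohorts (the study design) — about 20
of them for the recovery and ordering checks — plus one 2000-colony
cohort for moment convergence; the acceptance script uses one 99-colony
cohort for production statistics and 20 for landmark medians. These
sizes make every distributional claim in the suite a property of the
study-scale estimator, not of an asymptotic limit.

## Known limitations

* The two late landmarks are close together (~1.5–2 weeks apart in the
  model) while their per-cohort estimators carry 1–2 weeks of sampling
  noise at $n=99$; the *median* landmark sequence across cohorts
  reproduces fecundity peak < mean lifespan < sexual peak < mortality
  crossing, but any single cohort orders the last two correctly only
  ~60–70% of the time. A single observed cohort (including a real one)
  is weak evidence for that pairwise order on its own.
* The crossing age depends on the standardization window: longer-lived
  outliers extend the age axis, raise the post-maturation mean mortality
  and delay the crossing. This is a property of the method, shared with
  the published analyses, not of the implementation.
* Fecundity is attributed to the census age at which offspring are
  *observed* (pupae lag laying by development time), matching the
  reference convention; no lag-back correction is applied.
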