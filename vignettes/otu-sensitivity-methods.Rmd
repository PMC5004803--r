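---
title: "Methods: per-OTU dose-response modelling and OTU sensitivity distributions"
author: "otuSD"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: per-OTU dose-response modelling and OTU sensitivity distributions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(otuSD)
```

# Scope and model

`otuSD` estimates community-level toxicity thresholds for a soil toxicant
(developed around silver: Ag⁺, AgNPs and sulfidised Ag₂S-NPs) by treating
every OTU in a 16S amplicon dose series as its own test organism. The chain
is: read counts → absolute genome-equivalent abundance → per-OTU
dose-response fit → EC20 → Burr Type III OTU sensitivity distribution →
hazardous concentrations HCx with bootstrap confidence intervals. A
parallel branch handles scalar functional endpoints (net nitrate
production, functional-gene copies).

## Dose-response models

Two nested models are fitted to every eligible series, with dose $x$ in
mg kg$^{-1}$ soil and response $y$ in single-copy (genome-equivalent) 16S
abundance, or percent of control for functional endpoints:

$$y = c + \frac{d - c}{1 + (x/e)^b} \qquad \text{(log-logistic, 4 par.)}$$

$$y = c + \frac{d - c + f x}{1 + (x/e)^b} \qquad \text{(Brain–Cousens, 5 par.)}$$

In the log-logistic model $d$ is the control-level response, $c$ the lower
asymptote, $e$ the inflection dose (the EC50 of the $d-c$ span), and $b>0$
describes inhibition. The Brain–Cousens term $f x$ allows low-dose
stimulation (hormesis); under it $b$ and $e$ lose their slope/inflection
interpretation. At $f = 0$ the models coincide identically — a property the
test suite asserts to $10^{-12}$ over random parameter grids.

Assumptions worth making explicit: observations across doses are treated
as independent with homoscedastic errors (ordinary least squares, no
weighting); one observation per dose is sufficient and replicates, when
present, simply enter as extra observations; the control's measured
background concentration (0.1 mg kg$^{-1}$ by default) is used as its dose
value so that $(x/e)^b$ and log-dose axes are well defined — a literal zero
dose is still accepted by the evaluators.

## Acceptance rules and model selection

A fit is accepted only when all of: (1) $b > 0$; (2) $e$ below the maximum
spiking concentration; (3) $R^2 > 0.65$ (strict), with
$R^2 = 1 - SS_{res}/SS_{tot}$ about the response mean and no adjustment.
Failed optimizations are recorded as `fit_failed`, never raised as errors —
essential when fitting thousands of OTUs unattended.

Two deliberate choices here were genuinely open:

* **Criterion (2) under hormesis.** Although $e$ has no clean
  interpretation in the Brain–Cousens model, the bound is applied to both
  models so that the same three rules govern every fit; the hormesis flag
  is carried separately so users can audit the consequences.
* **Selection.** If both models are accepted, the hormesis model wins.
  This is the conservative choice for the per-OTU branch: stimulation at
  low doses steepens the later decline, so hormesis-model EC20s are
  typically lower. Significance of $f$ is *not* required for selection in
  the OTU branch — it is metadata. The functional-endpoint branch inverts
  this: there the sigmoidal model is used unless hormesis is statistically
  significant, matching how nitrification dose-response data are usually
  handled. The two branches intentionally differ.

Hormesis significance is a Wald interval: significant iff
$f \pm t_{n-5,\,0.975}\,SE(f)$ excludes zero. A numerical guard declares
non-significance outright when the stimulation term is negligible relative
to the fitted span ($|f| e < 10^{-8} (d-c)$), because zero-residual fits
otherwise produce 0/0-shaped $t$ statistics. The test suite checks the
size of this test empirically (false-positive rate within 3–7% at
$\alpha = 0.05$ over 500 null simulations) and its power against strong
stimulation.

## ECx referencing

`computeEcx()` supports two reference levels:

* `upper_asymptote` (default): the dose where the fitted curve equals
  $(1 - p/100)\,d$. This is the package's primary definition — the EC20 of
  an OTU is the dose cutting its fitted control-level abundance by 20%.
  Closed form for the log-logistic model; for hormesis the crossing on the
  descending limb is bracketed between the curve maximum and ten times the
  maximum dose and solved by `uniroot`.
* `span`: the classical $EC_p = e\,(p/(100-p))^{1/b}$, referenced to the
  $d - c$ span, provided for comparability with standard dose-response
  software.

A consequence of upper-asymptote referencing is that extremely sensitive
OTUs can yield EC20s below the background concentration. These are
retained but flagged `below_background` (a numerical artefact of immediate
responders; no tested dose is "safe" for them), and a configuration switch
can exclude them from the OSD.

Delta-method 95% CIs propagate the parameter covariance
$s^2 (J^\top J)^{-1}$ (analytic Jacobian in natural parameters) through the
ECx gradient — analytic for the span mode of the log-logistic model,
central differences otherwise; the lower bound is floored at zero.

## Preprocessing constants

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| low-count filter | total ≤ 2 | reads | removes singletons/doubletons, the conventional error guard |
| rarefaction depth | 9,000 | reads/sample | equalizes sequencing effort; samples below depth are dropped (not scaled) |
| copy-number fallback | mean of map | copies/genome | convention of copy-number correction tools for unmapped OTUs |
| eligibility | ≥ 6 | samples with nonzero abundance per arm | degrees of freedom for 4–5 parameter fits |
| $R^2$ threshold | 0.65 | — | acceptance criterion (3) |
| EC level | 20 | % reduction | per-OTU toxicity value feeding the OSD |
| protection levels | 5, 10, 20, 80 | % affected | HC5/HC10/HC20 protective thresholds; HC80 delimits the insensitive tail |
| bootstrap resamples | 1,000 | — | pipeline default; CI stability at the 2.5/97.5 percentiles |

The preprocessing order raw → filtered → rarefied → absolute is enforced by
the `OtuExperiment` stage marker; calling a step out of order is an error,
and rarefied tables must have exactly equal column sums. Rarefaction draws
without replacement (multivariate hypergeometric) with a per-sample RNG
stream derived deterministically from the seed and the sample id, so
results do not depend on sample order.

The copy-number convention divides read relative abundance by the per-OTU
16S copy number and scales by the sample's qPCR total — genome equivalents,
conserving total 16S copies ($\sum_i A_{is} CN_i = T_s$ exactly). The
alternative of renormalizing corrected fractions to sum to one is
intentionally not used: it would break that conservation property and the
link to the absolute qPCR scale.

## Burr Type III OSD

The OSD parameterization is fixed to the convention
$F(x) = (1 + (b/x)^c)^{-k}$, $x > 0$, with all three parameters strictly
positive. Parameterizations of this family differ across the SSD
literature, so the package states its choice prominently and uses it
everywhere (CDF, quantile, MLE, HCx).

Fitting is by maximum likelihood with parameters on the log scale,
analytic gradient, and three moment-style starts (the $k = 1$ special case
gives $b \approx$ median and $c \approx \pi/(\mathrm{sd}(\log x)\sqrt 3)$);
the best converged optimum is kept. At least 8 EC20 values are required —
below that the heavy-tailed three-parameter family is not identifiable and
the error message points users toward small-sample methods, which are out
of scope here. Degenerate (zero-variance) inputs are rejected explicitly.

HCx is the $x/100$ quantile. Confidence intervals are a nonparametric
percentile bootstrap over EC20 records (resample, refit, requantile);
failed resamples are dropped and counted, with a warning above 10% and an
error above 50% failures. Treatments are compared by 95% CI overlap — the
rule is symmetric and consistent with superscript-letter tables in the
ecotoxicology literature; a formal bootstrap difference test would be a
natural extension but is not implemented. Compact letters are assigned
greedily over estimates sorted by value, which is exact for the small
numbers of arms in practice.

## Synthetic data: what it does and does not emulate

`generateTruth()` draws a community of OTUs in three response classes —
insensitive (flat), log-logistic decliners, and hormetic responders —
with: $e \sim$ lognormal (median 20 mg kg$^{-1}$, sdlog 1.2, so most
decliners have their inflection inside the dose range);
$b \sim U(0.8, 4)$; lower-asymptote fraction $c/d \sim U(0, 0.2)$;
hormetic $f$ sized numerically so peak stimulation is 10–50% of control;
base abundances lognormal (sdlog 1.5) normalized to one — a realistically
uneven community; 16S copy numbers uniform on 1–10. The default dose grid
is 14 geometric levels from 0.1 (background) to 5590 mg kg$^{-1}$, one
sample per dose, and the control 16S pool is $10^8$ copies.

`simulateObserved()` then draws reads multinomially at the sequencing
depth (default 20,000, rarefied to 9,000 downstream) from the
copy-number-weighted pool shares, and qPCR totals lognormally around the
true pool (CV 2% by default). A Dirichlet-multinomial overdispersion knob
and a replicate option exist for robustness and power studies but are off
by default, mirroring a pooled-DNA, one-sample-per-dose design.

What this emulates well: compositionality (reads are shares of a shrinking
pool as sensitive OTUs decline), copy-number distortion, counting noise at
realistic depth, and qPCR measurement error. What it does not emulate:
taxonomic structure, spatial/temporal autocorrelation, overdispersion
beyond the optional knob, PCR/primer bias, or OTU-picking artifacts.
Passing recovery tests therefore demonstrates correctness of the
estimators under the stated noise model — not robustness to every failure
mode of real amplicon data.

A practical fact the acceptance script quantifies (as
`median_ec20_recovery_error_pct`): per-OTU EC20 recovery at a 9,000-read
depth is limited by each OTU's read budget. For a realistically uneven
500-OTU community most fitted OTUs receive only tens of reads per sample,
and the median EC20 error is then dominated by multinomial counting noise
rather than by the estimator; abundant OTUs recover substantially better.
Parameter-level claims in the test suite are therefore framed per read
budget, and noise-free recovery is exact to $10^{-4}$ relative or better.

## Numerical choices

* Nonlinear least squares: Levenberg–Marquardt (`minpack.lm::nls.lm`),
  $e$ fitted as $\log e$ (positivity structural), tolerances
  $10^{-10}$, at most $10^4$ function evaluations. Starting values:
  $d$ = mean response at the two lowest doses, $c = \min(0, \min y)$,
  $e$ = geometric mean of positive doses, $b = 1$, $f = 0$; three
  perturbed restarts on failure, then `fit_failed`.
* Flat response series (zero variance) short-circuit to `fit_failed`
  rather than producing an undefined $R^2$.
* Singular Jacobians leave the covariance `NULL`; downstream consumers
  (hormesis test, ECx CIs) degrade to warnings, never crashes.
* Burr III likelihood is evaluated via `log1p(exp(w))` with an overflow
  guard at $w > 35$, and $u/(1+u)$ via the logistic function, keeping the
  MLE stable for extreme shape parameters.
* Hormesis ECx root finding targets the descending limb only, bracketing
  from the curve maximum; the no-crossing condition (target not attained
  within ten times the maximum dose) is a typed error telling the caller
  that this OTU/endpoint cannot yield the requested ECx.

## Problem sizes used in validation

The test suite validates at sizes chosen to exercise the estimators
meaningfully: 200 random parameter draws for oracle agreement; 500 null
and 200 alternative simulations for the hormesis test; a 500-OTU community
at depth 9,000 for end-to-end recovery; 100 replicates at $n = 400$ for
Burr III recovery; and 200 replicates with 200 bootstrap resamples (scaled
down from the 1,000-resample pipeline default) for HC5 interval coverage.

## Known limitations

* EC20s below the background dose are artefacts of upper-asymptote
  referencing for immediately affected OTUs; they are flagged, kept by
  default, and excludable.
* The Wald interval on $f$ is a large-sample approximation; with ~14
  observations and 5 parameters its size is adequate (verified
  empirically) but profile-likelihood intervals would be preferable at
  smaller $n$.
* CI non-overlap is a conservative significance rule: it can miss
  differences a direct bootstrap test would detect.
* Burr III small-sample fallback distributions (log-logistic,
  inverse-Weibull) are not implemented; below 8 EC20s the OSD step
  refuses rather than guesses.
* Results are conditional on the community analysed; OSDs from one soil
  do not transfer to soils with different communities or chemistry.
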