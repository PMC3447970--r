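---
title: "Expected-gain analysis of reaching around a costly obstacle"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Expected-gain analysis of reaching around a costly obstacle}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reachgain)
```

## The task and the decision-theoretic model

A subject makes speeded reaches to a vertical target strip on a screen
while an invisible virtual obstacle — a half-plane with a vertical left
edge — sits at the halfway depth of the reach. Touching the target earns
$V_T = +2$ points; passing right of the obstacle edge costs
$V_O \in \{-1, -2, -5\}$ points. Because target and obstacle are elongated
vertically, only the horizontal coordinates matter: the *excursion* $x_1$
where the fingertip crosses the obstacle plane (measured from the obstacle
edge, negative = left of it) and the *endpoint error* $x_2$ where it lands
on the screen (measured from the target centre). Three target positions
(0, 38, 75 mm right of screen centre) crossed with the three costs give
nine conditions; the obstacle edge is always 6.6 mm right of the target
centre and the target strip is $w = 6.5$ mm wide.

Choosing a movement plan fixes a bivariate Gaussian distribution over
$(x_1, x_2)$ with mean at the planned crossing coordinates and standard
deviations $\sigma_1, \sigma_2$ set by motor noise. The expected gain of a
plan with planned excursion $e$ is

$$
\mathrm{EG}(e) \;=\; V_T\,P\!\left(|x_2| \le w/2\right) \;+\;
V_O\,P\!\left(x_1 > 0\right)
\;=\; V_T\!\left[\Phi\!\Big(\tfrac{w/2-\mu_2}{\sigma_2}\Big) -
\Phi\!\Big(\tfrac{-w/2-\mu_2}{\sigma_2}\Big)\right] +
V_O\,\Phi\!\Big(\tfrac{e}{\sigma_1}\Big).
$$

Gain is additive over the two indicator events, so it depends only on the
marginals and is invariant to the cross-plane correlation $\rho$. The data
do show a small positive $\rho$ (a common component of trajectory
variation detectable at both planes); the generator can produce it and the
summaries estimate it, but all expected-gain computation sets $\rho = 0$.
Joint four-outcome probabilities (hit both, target only, obstacle only,
neither) are products of marginals when $\rho = 0$ and otherwise come from
adaptive 1-D quadrature over the conditional normal of $x_2 \mid x_1$
(`stats::integrate`, relative tolerance $10^{-10}$); they are checked
against each other and against Monte-Carlo sampling in the tests.

Boundary conventions, which matter only for classifying discrete samples:
an obstacle hit requires strictly $x_1 > 0$; a target hit is inclusive,
$|x_2| \le w/2$. All APIs reject non-finite coordinates. Units are mm and
points throughout; screen-absolute coordinates exist only in the condition
table.

## The empirical noise model

Motor noise grows with the size of the detour. For each obstacle location
the package fits two straight lines — one per plane — relating the
per-condition sample SD of the crossings to the condition's mean excursion,
giving six lines in all. Locations are deliberately *not* pooled into one
two-variable model: noise may grow differently around near and far
obstacles, and pooling would buy generality only at the cost of extra
assumptions.

The fit is weighted least squares with weights $1/\mathrm{SE}^2$ of each SD
estimate, where $\mathrm{SE}(\hat\sigma) = \hat\sigma/\sqrt{2(n-1)}$ (the
Gaussian sampling error of a sample SD). The precise weighting scheme is a
package choice — any reasonable weighting gives near-identical lines here
because the three design points per line have similar precision. Lines are
parameterized on signed mean excursion (negative leftward), so slopes are
typically negative: predicted $\sigma$ grows as reaches detour further.
`predict_sigma()` refuses non-positive predictions, and the optimizer's
search range is restricted to excursions where both planes' predicted
$\sigma$ exceeds 0.05 mm.

Pooled condition summaries centre each subject's trials on that subject's
own condition mean before pooling second moments (mirroring value diagrams
drawn centred on the pooled mean), and use the $n-1$ denominator. With
seven subjects this under-counts the centring by six degrees of freedom —
a bias below 0.4% at 840 trials per condition, noted rather than
corrected.

## Optimal planning and the MEG excursion

Substituting the fitted lines into $\mathrm{EG}(e)$ gives an expected-gain
curve over any theoretical non-positive planned excursion, with the planned
endpoint fixed at the condition's observed mean endpoint error (endpoint
bias varies with target position but not with excursion, so it is treated
as given, not optimized). The maximizer $e^*$ — the maximum-expected-gain
(MEG) excursion — is located by a 0.5 mm grid sweep over
$[-40, 0]\,\mathrm{mm}$ intersected with the $\sigma$-positive range,
followed by bounded golden-section refinement (`stats::optimize`,
tolerance $10^{-6}$). Flat maxima resolve toward the smallest $|e^*|$, a
minimal-deviation convention. The tests require agreement with an
exhaustive 0.01 mm grid within 0.05 mm on all nine conditions, and
$|e^*|$ is verified to be non-decreasing in cost magnitude at every
location.

## The Dominance Test and its margin

Optimality cannot be tested against the space of *all* strategies — no
model of that space exists — but it can be tested against strategies the
subject demonstrably produces. The gain matrix $G[i,j]$ evaluates, under
condition $i$'s costs, noise lines and mean endpoint, the mean excursion
actually observed in condition $j$ (strategies transfer as
obstacle-relative excursions). If some $G[i,j]$ exceeds $G[i,i]$, the
strategy chosen in condition $i$ is *dominated*: a demonstrated, available
strategy would have earned more. Excursions outside a row's
$\sigma$-positive range are marked not-evaluable and excluded, never
extrapolated.

`dominance_test()` itself is a pure function of the matrix with a
numerical-noise margin of $10^{-6}$ points. For headline reporting the
pipeline uses a larger, data-driven margin: the *gain resolution* of the
experiment, the largest per-condition standard error of mean realized gain
(about 0.04 points at this design). The reason is specificity. The fitted
noise lines rest on three design points per location whose SD estimates
carry a ~2.4% sampling CV; propagated through the flat expected-gain
maxima this moves the fitted optimum by roughly a millimetre, which is the
same order as the spacing between neighbouring observed strategies. With a
near-zero margin, an agent playing the *exactly* optimal strategy in every
condition is therefore flagged in most replicates — the test would have
essentially no specificity at this sample size. Gain differences below the
precision with which mean gain is even measurable cannot evidence
suboptimality, so they are reported (the raw margins are kept in the
output) but not flagged. A bootstrap over trials
(`dominance_bootstrap()`) is available as an auxiliary stability check of
the flags.

## Evidence for the unity line

If subjects plan optimally, observed mean excursions equal the MEG
predictions and the nine $(\hat e^*, \bar e)$ pairs lie on the identity
line. The package scores this with a Bayesian model comparison. Under
$M_0$ (optimal planning) the observed means are Gaussian around the
identity line with their per-condition standard errors; $M_0$ has no free
parameters. Under $M_1$ a free line with slope $a$ and intercept $b$
replaces the identity, with independent uniform priors $a \in [0, 2]$ and
$b \in [-20, 20]$ mm — weakly informative and centred on $M_0$, so that
$M_0$ is nested at the prior's centre of mass. These prior ranges are a
documented package choice (they are configurable); wider priors favour
$M_0$ through the Occam factor, narrower ones favour $M_1$. The marginal
likelihood of $M_1$ is a 2-D trapezoid-grid integral (401 points per
dimension by default) computed in log space with log-sum-exp; the weighted
residual sum of squares is expanded once as a quadratic form in $(a, b)$,
so the grid costs one outer product. Evidence is reported in decibels,
$10\log_{10}$ of the posterior odds for $M_0$ at equal prior model odds;
3 dB is about 2:1, and a degenerate prior that pins $M_1$ to slope 1 and
intercept 0 yields exactly 0 dB.

Calibration (run in the acceptance suite): data generated on the identity
line give positive evidence in essentially all replicates; data generated
with slope 0.5 give negative evidence. Note that the test treats the
predictions as known. With the default homogeneous-subject generator the
across-subject SEs are a few tenths of a millimetre, so a single
experiment's correlated ~1 mm estimation error in $\hat e^*$ is itself
resolvable and the single-run evidence for an optimal agent is usually
negative; the informative comparisons are across agents (a
stop-80%-of-the-way agent is rejected orders of magnitude more strongly)
and under the calibration construction above. With realistic
between-subject heterogeneity switched on, the SEs grow roughly tenfold
and this stringency disappears.

## Stationarity, autocorrelation, Gaussianity

Three diagnostics check the modelling assumptions. The within-block
profile removes each block's mean excursion and averages the centred
values at each of the 30 within-block positions; a homing-in strategy
would show a trend, and the slope of a line fit to the profile is reported
with its standard error. Sample autocorrelations per subject and block up
to lag 15 use the biased ($1/n$) normalization, for which the usual
$\pm 1.96/\sqrt{n}$ white-noise band applies; at block length 30 the
band's exceedance is near its nominal 5% at lag 1 and lower at high lags,
where the biased estimator's variance shrinks. The QQ diagnostic
standardizes a sample, pairs its order statistics with standard-normal
quantiles at plotting positions $(i-0.5)/n$ (the common midpoint rule;
$i/(n+1)$ is available behind a flag), and reports the correlation of the
pairs as a linearity coefficient.

## What the generator emulates — and what it does not

The generator reproduces the study design exactly: 7 subjects, 9
conditions, 4 blocks of 30 reaches per condition (1080 reaches per
subject), randomized block order per subject, target reward +2, obstacle
costs −1/−2/−5, edge offset 6.6 mm, strip width 6.5 mm. Its behavioural
policy plays each condition's MEG excursion (`optimal`), a fixed fraction
of it (`scaled`, e.g. the classic stop-80%-of-the-way agent), or
user-supplied excursions (`fixed`); planned endpoints carry a small
per-target-position bias (0.5/−0.5/−1.5 mm) independent of excursion.

The ground-truth noise lines are necessarily synthetic — no numeric
coefficients exist to copy — and were fixed once on three grounds: noise
grows with excursion magnitude (obstacle-plane $\sigma$ roughly doubles
over a 20 mm detour) and with obstacle distance from screen centre;
intercepts of 3.0/3.8/4.6 mm (obstacle plane) put the optimal agent's MEG
excursions between about −5 and −19 mm, the scale of detours this task
elicits; and the implied slopes are four to five times their sampling
error under the design, so the six-line fit is well identified and
slope-sign artifacts (which would send the optimizer to the search
boundary) do not occur. Shallower, location-independent noise (e.g. all
intercepts 1.5 mm) compresses all nine MEG excursions into under 2 mm,
below the design's own estimation error — under such a regime neither the
unity-line comparison nor the Dominance Test can resolve anything, which
is a statement about experiment design, not about the estimator.

Deliberate idealizations: crossings are exactly bivariate Gaussian, so
the QQ diagnostic's pass is a calibration, not a discovery; trials are
independent within blocks (an AR(1) switch exists solely to exercise the
autocorrelation diagnostic); subjects are identical by default
(`between_subject_sd_mm` adds policy jitter when heterogeneity matters);
there are no timeout trials, practice phases, vertical coordinates, or
kinematics between the two planes. Passing tests on this generator
therefore show that the estimators recover a data-generating process *of
the assumed form* at the study's scale — not that real reach data satisfy
those assumptions; the diagnostics exist to check the assumptions on real
data.

## Numerical choices and problem sizes

Monte-Carlo cross-checks use $10^6$ draws with 3-binomial-SE bands (a
20-point parameter sweep); replicated properties use 50–200 full synthetic
experiments (7560 reaches each) — sizes chosen so every stochastic
check's sampling error is several times smaller than the tolerance it
enforces while the whole suite stays quick. All randomness flows from
explicit seeds; the sampler uses the Cholesky construction
$x_2 = \mu_2 + \sigma_2(\rho z_1 + \sqrt{1-\rho^2} z_2)$ so the same seed
reproduces experiments byte-identically.

## Known limitations

The plug-in $\hat e^*$ has a per-replicate correlated error of about 1 mm
(conditions within a location share a fitted line), and a small
attenuation (~5%) appears in the observed-on-predicted regression slope
from errors in the predictions. The pooled-SD denominator ignores the
subject-centring degrees of freedom. The evidence model's decibel values
depend on the chosen prior box — there is no canonical choice — though its
calibration properties (sign behaviour) are insensitive to it. The Dominance Test pools across subjects; it does not
test individual subjects.
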