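---
title: "Correcting sampling bias in gridded occurrence data: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Correcting sampling bias in gridded occurrence data: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Citizen-science occurrence databases record where volunteers went at least as
much as where a species lives. When presence-only point records are aggregated
to counts per grid cell ("pseudo-abundance"), unsurveyed cells become zeros
that are indistinguishable, at face value, from true absences. A model fitted
naively to such data learns the geography of recorder effort. `biastree`
implements the standard corrective toolkit around that problem — spatial
filtering of records, manipulation of pseudo-absence backgrounds, bias-surface
weighting, and zero-inflated (ZI) count regression — together with the
machinery needed to judge the corrections: internal cross-validation,
simulated stratified field surveys, and calibration of model predictions
against effort-adjusted field densities to produce a landscape-wide population
total.

Everything runs against a synthetic landscape generator with known truth, so
each correction can be scored against the quantity real studies never have:
the true abundance in every cell.

## The zero-inflated model

Observed counts per cell are modelled as a two-component mixture. With
probability $\pi_i = \mathrm{logit}^{-1}(z_i^\top\gamma)$ cell $i$ yields an
*excess zero* (it was never effectively surveyed); otherwise the count follows
a Poisson or negative-binomial (NB) distribution with mean
$\mu_i = \exp(x_i^\top\beta)$. The NB dispersion $\theta > 0$ gives variance
$\mu + \mu^2/\theta$ and is estimated on the log scale. The log-likelihood

$$\ell(\beta,\gamma,\theta) = \sum_i \log\left[\pi_i\,\mathbf 1(y_i = 0) +
(1-\pi_i)\,f(y_i;\mu_i,\theta)\right]$$

is maximized by BFGS with the analytic score, warm-started from a plain count
GLM on the positive cells (count component) and a logistic regression on the
zero indicator (zero component). Convergence requires the gradient norm to
fall below $10^{-6}$ relative to the objective within 500 iterations;
non-convergence is flagged on the returned object, never hidden. Standard
errors come from the inverse observed information.

A fitted ZI model yields three prediction types:

* **count**: $\hat\mu_i$ — abundance free of the zero-generating process;
* **zero**: $\hat\pi_i$ — the probability that a zero is an excess zero, a
  map of suspected under-recording;
* **whole**: $(1-\hat\pi_i)\hat\mu_i$ — the expected *observed* count.

When excess zeros are produced by non-sampling, the count prediction is the
better estimate of true abundance and the whole-model prediction tracks the
biased data. One caveat the synthetic experiments make precise: this
superiority is stated here in mean absolute error, and it holds cleanly for
Poisson-like dispersion. Under extreme NB dispersion (e.g. $\theta \approx
0.4$) the count distribution is so right-skewed that the *shrunken*
whole-model prediction can sit closer to most realized abundances in absolute
error even though the count prediction is the unbiased estimate of their
mean — absolute-error loss favours medians, and the NB median lies far below
the mean at small $\theta$. Conclusions about which prediction "is more
accurate" therefore depend on the loss function as much as on the bias
mechanism.

Poisson and NB fits are compared with a Vuong statistic on the pointwise
log-likelihood differences $m_i$, $Z = (\sum_i m_i - C)/(\sqrt n\,
\mathrm{sd}(m))$, with $C$ an AIC- or AICc-style complexity correction;
negative $Z$ favours the second model. Identical pointwise likelihoods leave
$Z$ undefined (0/0) and raise an error rather than reporting 0.

## Presence-background modelling

The conventional presence-only corrections need a presence-background model to
act on. `biastree` uses penalized logistic regression of presences against
background points: presence-background logistic regression estimates the same
relative suitability surface as an inhomogeneous-Poisson-process or
maximum-entropy model, while keeping the likelihood, the penalty and the
parameter count explicit. Candidate fits across a ridge-penalty grid (and
optionally quadratic features) are ranked by
$\mathrm{AICc} = -2\ell + 2k + 2k(k+1)/(n-k-1)$ with $k$ the raw coefficient
count, ties broken toward the smaller model.

The corrections themselves:

* **Systematic filtering** — one random record per coarse cell (2–10 km).
  Coarse grids are anchored at the landscape origin; anchoring affects
  membership only at boundaries and is configurable.
* **Cluster filtering** — one random record per single-linkage component of
  the graph joining records closer than the link distance (default 1 km).
* **Weighted-distance filtering** — nearest-neighbour distances min–max
  rescaled to $[0,1]$ and used as selection weights for a without-replacement
  draw, favouring isolated records. Records at weight zero become selectable
  only after every positive-weight record is taken.
* **Buffer-restricted backgrounds** — pseudo-absences confined to the union
  of disks around records (rejection sampling from the union's bounding box).
* **Bias surfaces** — per-cell weights from a Gaussian kernel density of
  source points (recorder homes, towns), or min–max rescaled rasters
  (altitude, record density), steering pseudo-absence placement toward
  heavily recorded areas. The kernel is Gaussian with a default bandwidth of
  five cell sizes; the surface's shape, not the kernel family, is what drives
  the method. For distance-type sources the direction of the rescaling
  (nearness vs. farness attracting pseudo-absences) is an explicit parameter
  rather than a guess.

Background sampling draws cells with probability proportional to weight,
with replacement across draws, then places a uniform point in each drawn
cell; presence cells are not excluded, matching common presence-background
practice.

## The synthetic landscape

`generate_landscape()` smooths white noise with a separable Gaussian kernel
(scale = `correlation_length`, default 5 km on a 1-km grid) as a cheap
Gaussian-process surrogate, then centres and scales each numeric covariate;
categorical covariates threshold an independent smoothed latent field at
quantiles, giving spatially coherent classes. True abundance is NB in the
covariates; the excess-zero process is logistic in the same covariates; an
optional binomial detection probability thins counts inside sampled cells
(default 1 — the bias regime studied is zero-generating, not thinning).
Records are scattered uniformly within their cells, and recorder home bases
claim records with probability decaying as $\exp(-d/\text{activity decay})$ —
a free modelling choice, since real recorder activity ranges are not
characterized.

Default study conditions (frozen in `default_pipeline_config()`): a 50×50
grid, three numeric and one three-level categorical covariate,
$\beta = (0.5, 0.8, -0.4, 0.3, 0.3, -0.3)$, $\theta = 0.4$,
$\gamma = (1.2, -0.9, 0.6, 0, 0.4, 0)$. These give roughly 14% of cells a
positive observed count and variance:mean ratios of 20–45 — the same regime
(heavy zero inflation, strong overdispersion) as a national ancient-tree
inventory aggregated to 1-km cells, at desk scale. What the generator does
*not* emulate: real GIS predictor sets, road/path accessibility structure,
multi-species target-group effects, and recorder sociology; passing tests
show the algorithms behave as specified under the stated generative
assumptions, not that any particular real dataset satisfies them.

Truth (true $N$, excess-zero flags) is quarantined: fitting code receives
only the observed cell table, and the flags exist solely for oracle tests and
diagnostics.

## Field surveys, calibration and the landscape total

Survey squares follow the 50 + 4×10 design: 50 cells at random, then 10 per
stratum from the four cells classes built by crossing record presence with
predicted abundance (low/high at the mean zero prediction). Inaccessible
squares (configurable probability, default 4/90) are redrawn within their
stratum; incomplete campaigns are simulated with a per-square completion
probability (default 52/90), and calibration uses completed squares only.
Surveyors observe $\mathrm{Binomial}(N, c\cdot d)$ of the truth at coverage
$c$; the effort-adjusted density $y/(c \cdot \text{area})$ is unbiased for
$N/\text{area}$ at $d = 1$.

Calibration regresses the field metric (raw count, or density) on the model
prediction by OLS over surveyed squares, then applies $a + b\,p_i$ to every
cell and sums — density estimates are multiplied by the cell area
($10^6\,\mathrm m^2$) first, the unit-consistent reading of "summing
per-square estimates". Negative per-cell estimates are kept by default (no
clipping is part of the published procedure); a `clip_negative` flag exists
because a large negative intercept can otherwise produce absurd per-cell
values, and both behaviours are reported when it matters. Field
presence–absence comparisons binarize abundance predictions at the median
over the *selected* square set (not just the completed ones — the reference
set is an explicit argument), because the completed subset is a biased
subsample of the design.

At the default desk scale the calibrated total $T$ is roughly centred on the
true $\sum_i N_i$ but wide (its replicate distribution spans roughly half to
double the truth with ~50 completed squares of 2,500 cells); the acceptance
test derives that spread from 100 fresh pipeline replicates at run time
rather than freezing an interval.

## Numerical and design notes

* Cells are half-open squares $[x,x+s)\times[y,y+s)$, so boundary points have
  exactly one home; aggregation is exactly conservative and idempotent.
* The mixture likelihood is evaluated with log-sum-exp stabilisation; the
  analytic score is verified against central finite differences at random
  parameter points.
* Neighbour searches (cluster filtering, nearest-neighbour distances) use
  grid binning for average-case linear behaviour; correctness is defined by
  brute-force pairwise oracles in the test suite, never by the index.
* Thresholding abundance to presence–absence uses a strict `>` at the
  boundary (the convention had to be fixed somewhere; constant predictions
  are therefore all-absent).
* Cross-validation assigns cells to folds uniformly at random — no spatial
  blocking, matching the workflow this package operationalizes, which found
  geographic splits less effective.
* k for AICc of ridge-penalized fits is the raw coefficient count by default;
  an effective-degrees-of-freedom variant was considered and rejected as
  harder to compare across the candidate grid.
* All randomness flows through named, stage-derived seeds; identical configs
  reproduce bit-identical artifacts.

## Problem sizes

The shipped tests and the acceptance script use a 50×50-cell landscape for
pipeline-level checks, 30×30 for replicate simulations, and $n = 5000$
observations for parameter-recovery and model-comparison benchmarks, with
25–100 replicates per property — sizes chosen so the full validation suite
documents the method's behaviour in minutes while keeping Monte-Carlo error
well inside the asserted tolerances.

## Limitations

The ZI model assumes the excess-zero process is fully covariate-driven;
spatially autocorrelated unexplained effort is not modelled (no spatial random
effects), only diagnosed via residual–coordinate correlations. The
presence-background stand-in shares MaxEnt's suitability-surface estimand but
not its feature classes or regularization path, so no numerical equivalence
with MaxEnt outputs should be expected. Calibration extrapolates a linear
field–prediction relationship from few surveyed squares to the whole
landscape; with heavy-tailed abundance this is the dominant source of
variance in the landscape total, exactly as in the real workflow.
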