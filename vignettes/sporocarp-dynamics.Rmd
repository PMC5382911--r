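---
title: "Models and methods: scales of variation in sporocarp surveys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: scales of variation in sporocarp surveys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`sporoscale` analyses multi-year surveys of epigeous fungal fruiting bodies
(sporocarps) collected weekly on permanent plots. This vignette documents
the statistical models, the choices behind their implementation, and what
the synthetic-data generator does and does not emulate — the information a
user needs to judge when the package's guarantees transfer to their own
data.

## The analysis table

The unit of analysis is the plot-year. Weekly records (plot, date, taxon,
trophic guild, sporocarp count, fresh mass in g) are aggregated by
`aggregate_plot_year()`:

* biomass in kg fresh weight per hectare,
  `(sum of g / 1000) * (10000 / plot area in m^2)`;
* richness S, the number of distinct taxa with positive annual biomass
  (morphotaxa resolved only to genus count as distinct taxa — richness is
  an "at least" count);
* Pielou's evenness `J = -sum(p_i log p_i) / log S`, where `p_i` are the
  annual biomass shares. Natural logarithms are used throughout, the
  ecological convention for Shannon-based indices.

J is undefined for S <= 1 (log S = 0) and is propagated as `NA` rather
than coerced to 0 or 1; downstream fits drop those rows and report the
count. Observed evenness in real surveys spans most of (0, 1), which a
0/1 coercion would distort. Plot-years that were sampled but yielded
nothing are retained with biomass 0 and S = 0 (a `drop_empty` switch
exists): sampling effort without collections carries information about bad
years, and removing it would bias temporal trends upward.

Climate enters through the late-summer/early-autumn (LSEA) window that
controls Mediterranean fruiting: accumulated August–October precipitation
(mm) and the unweighted mean of the three monthly mean temperatures (°C),
per plot and year. Climate is keyed per plot (each plot carries its
nearest station's series); a locality-keyed table can be broadcast to
member plots. A missing month inside the window is a hard error — silently
imputing part of a three-month accumulation would corrupt the covariate
and is easy to fix upstream.

Responses are transformed before Gaussian modelling: square root for
biomass, log(1+x) for richness in the variance decomposition,
arcsin(sqrt(x)) for evenness in trend models. "Arcsine transformed" is
implemented as the proportion variance-stabiliser arcsin(sqrt(x)); a plain
arcsin(x) variant is selectable where a user's convention differs.

## Variance components (`fit_varcomp`)

The null model is

y = mu + u_year + u_locality + u_plot(locality) + eps,

all random terms independent zero-mean Gaussians. A subtlety: with one
observation per plot-year, a *year-specific* plot effect is confounded
with the residual, so "plots nested within localities nested within years"
is not estimable as worded. The package therefore models plot effects as
persistent across years (plot within locality) *crossed* with a year main
effect — the only specification in which the plot and error variances are
both identifiable — and this is what the reported plot vs error shares
mean.

Estimation is REML. The mean and error variance are profiled out
analytically; the three log variance-ratios are maximised by Nelder-Mead
with two starting points (a moment-based guess and equal ratios) plus a
restart from the incumbent, relative tolerance 1e-10 on the deviance.
Working on the log scale enforces non-negativity by construction — no
post-hoc truncation touches the objective. Each deviance evaluation
reduces to a q x q Cholesky (q = total random-effect levels, 31 at the
default design) through the Woodbury identity, so bootstraps are cheap.
Degenerate input with literally constant response is reported by
convention as all components 0 with the error share 100. Designs with one
plot per locality everywhere raise an identifiability error naming the
confounded terms.

Confidence intervals are percentile 95% intervals over 199 case-bootstrap
resamples. The resampling unit is two-stage: years with replacement, then
plots (whole time series) within localities with replacement — both random
dimensions of the design are resampled, and locality labels stay fixed
because four localities are too few to resample meaningfully. A parametric
bootstrap from the fitted model is available (`type = "parametric"`).
Resamples that fail to converge are dropped and counted; more than 20%
failures warns, or errors under `strict = TRUE`. Percentile intervals were
chosen over basic/BCa for transparency. With only 8 year clusters to
resample, the year-share intervals are wide and their coverage sits
slightly below the nominal 95% — a standard cluster-bootstrap effect at
small cluster counts, compounded by the mild downward bias of an
estimated share (a ratio) of a component estimated from 8 levels. When
calibrated coverage matters more than design-faithful resampling, use
`type = "parametric"`, whose intervals are closer to nominal in the
package's simulations.

## Penalized-spline mixed models (`fit_pgamm`)

Trend models combine, in one penalized regression:

* a P-spline smooth — cubic B-splines on equally spaced knots with a
  second-order difference penalty `t(D) %*% D`. The default basis
  dimension is k = 5 for the year smooth: with 8 distinct years, 5 basis
  functions leave the fit flexible (up to ~4 effective df) while keeping
  the penalized problem well conditioned. B-splines with difference
  penalties were preferred to thin-plate bases for their closed-form,
  sparse penalty and exact polynomial null space;
* linear fixed terms (elevation, LSEA precipitation and temperature, or a
  linear year term). Covariates are standardized internally for
  conditioning; the fixed-term table reports estimates back per data unit;
* random intercepts for locality and plot within locality, entering as
  ridge-penalized indicator blocks (the mixed-model representation,
  ridge weight = scale / variance). If the locality variance collapses it
  is reported as 0, never dropped;
* an AR(1) correlation between successive years of the same plot, handled
  by exact whitening (gaps bridged with rho^lag).

The smooth is made identifiable against the intercept by a sum-to-zero
constraint and then rotated into the penalty eigenbasis, so the penalty is
diagonal with exact zeros on its null space; this keeps the unpenalized
(linear-trend) directions numerically clean even when the smoothing
parameter is forced to infinity — the fit then reproduces the GLS/OLS
line, a limit the tests exercise at 1e-6.

All variance-structure parameters — log smoothing parameter, log ridge
weights, atanh(rho) — are selected *jointly* by maximising the restricted
likelihood (scale profiled out), with Nelder-Mead plus a restart (Brent
when one-dimensional). An alternating scheme (update beta given rho,
then rho given residuals, iterate) reaches the same optimum but has a
fiddlier convergence analysis; joint optimisation of the same REML
criterion was preferred. Non-finite trial deviances are rejected with a
large value rather than crashing the search. |rho| approaching 1 triggers
a boundary warning.

Poisson richness uses penalized quasi-likelihood: working responses and
weights are iterated around the same Gaussian core (weights fold into the
whitening as W^(1/2) before the AR(1) transform), to a 1e-7 tolerance on
the linear predictor. PQL is an approximation — small counts bias
variance components somewhat low — but keeps one core for both families;
on large counts it agrees with the Gaussian log-count fit, which is
tested.

The fixed-term table reports estimate, SE, Wald statistic (t with
residual df = n - total edf for Gaussian, z for Poisson), raw two-sided
p-values (no multiple-testing correction) and significance stars at
0.05/0.01/0.001. The "yearly elevational changes" specification
(`pgamm_year_elevation`) is implemented as year-as-factor main effects
plus one linear elevation slope per year, so each year's slope appears
with its own SE and p — elevational trends are allowed to appear, vanish
or reverse between years. The linear-year row of `pgamm_climate` is the
"Year" effect summary; the smooth model (`pgamm_time`) answers the same
question non-parametrically, and both are exposed because either reading
of a "year effect" is defensible.

## Fruiting pulses (`first_derivative`)

The derivative of the fitted trend is computed by finite differences on a
grid of 100 equally spaced time points: fitted values at t ± eps/2 are
differenced and divided by eps (eps defaults to range/1000; "slight" shift
is otherwise unquantified, and results are insensitive to eps across two
orders of magnitude — a tested invariant). The difference is centred, and
the extended knot sequence keeps the basis defined eps/2 beyond the
boundary, so boundary estimates do not drift with eps. Standard errors use
the delta method on the coefficient covariance (the Bayesian covariance of
the penalized fit); intervals are pointwise 95% with the normal quantile
1.96, not simultaneous bands — each grid point is tested at its own level,
so isolated false flags at a ~5% pointwise rate are expected under a flat
truth. Maximal runs of same-direction significant points are reported as
increase/decrease periods; a single significant point is kept as a
zero-length period rather than discarded.

## Elevational variability (`elevation_variance_regression`)

Each plot's between-year variability is summarised by the sample variance
(divisor n-1) of its transformed annual series. With one observation per
plot-year, a per-plot "year variance component" from a mixed model is
confounded with residual noise; the sample variance is the identifiable
estimand and is the default, while a two-component REML estimator sits
behind `method = "reml"` for data with within-year replicates. Evenness
series use the defined years only, with `n_years` recorded; plots with
fewer than two usable years are excluded with a message. The variances are
regressed on elevation by OLS (`linear_regression()`), reporting slope ±
SE, the t-based p (n-2 df) and R².

## The synthetic survey generator (`generate_survey`)

The generator's defaults *are* the emulated study conditions, chosen once:

* 19 permanent 10 x 10 m plots in 4 localities (4/5/5/5), locality bands
  centred near 785/1180/1422/1604 m, gradient endpoints pinned exactly at
  684 and 1615 m; 8 consecutive years (2007–2014), weekly sampling
  September–December;
* variance components on the sqrt-biomass scale
  (sigma2 year/locality/plot/error = 4.2/1.7/3.4/0.7, i.e. shares
  42/17/34/7) — year and plot dominating, a small error share;
* the latent plot-year mean is intercept (8, i.e. 64 kg/ha) + trend +
  standardized-LSEA climate effects (beta_precip = 2, beta_temp = 0.5,
  precipitation dominant) + the random effects; sqrt-biomass is truncated
  at zero and squared back. Truncation affects ~0.4% of plot-years at the
  defaults, a negligible distortion of the recovered shares;
* trend shapes: flat, linear, or a half-sine hump (rise then fall), on
  the sqrt scale;
* LSEA precipitation increases with elevation (0.075 mm per m over a
  138 mm base) with a shared lognormal inter-annual anomaly, calibrated so
  the 8-year cumulative LSEA precipitation runs from roughly 1100 mm at
  the bottom of the gradient to roughly 1660 mm at the top; temperature
  declines with elevation at 5.5 °C/km with a seasonal cycle;
* a 349/231 mycorrhizal/saprotrophic species pool; the mycorrhizal guild
  takes a Beta-distributed share of biomass with mean 0.94, and
  mycorrhizal sporocarps are heavier (12 vs 4 g mean fresh mass);
* richness per guild is Poisson with log mean linear in the same latent
  predictor — Gaussian-on-sqrt biomass plus Poisson richness makes
  parameter recovery well-posed for both model families;
* guild biomass is split among species by lognormal abundance weights
  (log-sd 1) and across weeks by a seasonal multinomial peaked in late
  October. No mechanistic species-abundance model is claimed; the
  lognormal choice is isolated in one config knob;
* `year_sd_elev_gradient` optionally scales the year-effect and residual
  SD linearly in elevation (0 = homoscedastic), the constructed truth for
  the elevational-variability analysis;
* `ar1_rho` gives the residual a stationary within-plot AR(1) structure.

Four independent random substreams (climate, effects, species split, week
split) mean that changing, say, the species-abundance shape perturbs
nothing in the latent biomass — a tested invariant, as is bit-identical
regeneration under a fixed seed. `detail = "plot_year"` stops at the
latent analysis table (no species/week expansion; evenness is `NA` on
this path), which is what the Monte-Carlo studies use.

What the generator does **not** emulate: within-season phenological
structure beyond a fixed seasonal kernel; species identity persistence
across years (species are redrawn each plot-year, so community turnover
is unrealistically high and evenness dynamics are optimistic); spatial
autocorrelation between neighbouring plots beyond the locality intercept;
climate measurement error or station-to-plot mismatch; and taxonomic
uncertainty. Passing recovery tests on these surveys therefore
demonstrates correctness of the estimators under the declared model, not
robustness to those real-data features.

## Validation scenarios and problem sizes

Recovery studies align the generating model with the fitted model, as
parameter recovery requires:

* variance-component recovery: 200 surveys at the default design with
  components (4, 1.5, 3, 0.6), flat trend and zero climate effects (the
  null model the decomposition fits); mean recovered shares within 5
  points of the analytic ones;
* bootstrap coverage: 100 outer replicates, 199 resamples each; the year
  share's 95% interval must cover the truth 88–99 times;
* AR(1) recovery (rho = 0.6, 200 replicates) is run without a shared year
  random effect, since the trend model does not contain one and a shared
  year shock would masquerade as (and bias) within-plot autocorrelation;
* flat-truth derivative calibration likewise sets the year-effect
  variance to zero so the true conditional mean is constant in time
  (200 replicates; at most 10% of grid points flagged on average);
* pulse detection uses a strong hump (amplitude 6, small year variance):
  exactly one significant rise then one fall, overlapping the true
  monotone phases;
* the elevational-variance sign test uses `year_sd_elev_gradient = 1`
  (SD doubling across the gradient), recovering a positive slope in at
  least 90% of 200 replicates.

The acceptance script (`scripts/acceptance.R`) re-runs the same studies at
40–60 replicates — sizes chosen so the whole script completes in a couple
of minutes while keeping Monte-Carlo error well inside the margins being
checked — and writes every quantity it computes to JSON.

## Known limitations

* PQL is approximate for small Poisson counts; no Laplace/quadrature
  refinement is offered, nor quasi-Poisson/negative-binomial families.
* Pointwise (not simultaneous) derivative intervals: interpreting many
  grid points jointly inflates the family-wise rate.
* The case bootstrap treats the 4 localities as fixed; locality-share
  intervals are accordingly conditional on the observed localities.
* One observation per plot-year makes several textbook specifications
  (year-specific plot effects; per-plot year variance components)
  unidentifiable; the package implements the identifiable versions and
  says so rather than silently re-parameterising.
* Smooths are univariate; no tensor products, model-selection tables or
  rarefaction/Hill-number diversity machinery.
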