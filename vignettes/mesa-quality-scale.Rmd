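---
title: "Measuring meal quality with an unfolding item response model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring meal quality with an unfolding item response model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mesascale)
```

## The measurement problem

A child's daily meals differ in quality: some are built on unprocessed or
minimally processed foods (MPF), others on ultra-processed foods (UPF).
`mesascale` treats *meal quality* as a latent trait measured by eighteen
binary indicators — did the child consume at least one MPF, processed food
(PF), or UPF at each of six daily eating occasions (breakfast, morning
snack, lunch, afternoon snack, dinner, evening snack)? Foods come from a
closed 32-icon recall vocabulary and are mapped to NOVA processing classes
(`default_nova_map()`). Higher trait values mean a larger share of
ultra-processed foods across the day's meals.

## The unfolding response model

Consumption of a given food class at a given occasion is not monotone in
meal quality: a child with very low (very healthy) meal quality skips
breakfast UPF *and* a child with very unhealthy meals may skip breakfast
MPF. The natural model is therefore an ideal-point ("unfolding") model: the
generalized graded unfolding model (GGUM). For a dichotomous item with
discrimination $\alpha_i$, location $\delta_i$ and threshold $\tau_{i1}$
(with $\tau_{i0} \equiv 0$, $H = 1$, $M = 2H + 1 = 3$), the probability of
observing category $z$ is

$$
P(Z_i = z \mid \theta_j) \;=\;
\frac{e^{\alpha_i\left[z(\theta_j-\delta_i)-\sum_{k=0}^{z}\tau_{ik}\right]}
     +e^{\alpha_i\left[(M-z)(\theta_j-\delta_i)-\sum_{k=0}^{z}\tau_{ik}\right]}}
 {\sum_{v=0}^{H}\left(
   e^{\alpha_i\left[v(\theta_j-\delta_i)-\sum_{k=0}^{v}\tau_{ik}\right]}
  +e^{\alpha_i\left[(M-v)(\theta_j-\delta_i)-\sum_{k=0}^{v}\tau_{ik}\right]}\right)}.
$$

The consumption curve $P(Z=1\mid\theta)$ is unimodal, peaks at
$\theta = \delta_i$ (where it reduces to the logistic form
$e^{-\alpha_i\tau_{i1}}/(1+e^{-\alpha_i\tau_{i1}})$), and is exactly
symmetric about $\delta_i$. When $\tau_{i1} < 0$ the peak exceeds one half
and the curve crosses $P = 0.5$ at two points symmetric about $\delta_i$
(`crossing_points()`); when $\tau_{i1} \ge 0$ the non-consumption curve
dominates everywhere. Published item sets typically report $\alpha$ and
$\delta$ but not $\tau$; `solve_tau()` recovers it from a printed curve
feature (a 0.5-crossing or the peak probability).

## Estimation

**Item parameters** are estimated by marginal maximum likelihood
(`fit_ggum_mml()`): the trait is fixed at $N(0,1)$ for identification (the
calibration scale *is* the respondent distribution) and integrated out on a
quadrature grid — 61 equally spaced nodes on $[-4, 4]$ whose normal-density
weights carry composite Simpson coefficients before renormalization. The
correction matters: plain density weights converge only first-order in the
grid step (endpoint error ~$10^{-4}$ in a log-likelihood), while the Simpson
rule leaves log-likelihoods stable to below $10^{-6}$ when the node count is
doubled, which the test suite verifies against $10^4$-node dense grids. An EM algorithm
alternates posterior node weights per (collapsed) response pattern with a
bounded quasi-Newton improvement of each item's expected complete-data
log-likelihood — a generalized EM, so the marginal log-likelihood is
monotone non-decreasing (asserted every iteration). Convergence requires a
relative log-likelihood change below $10^{-6}$ *and* a maximum parameter
change below $10^{-4}$, within 500 iterations; parameter boxes are
$\alpha \in (0.05, 5]$, $\delta \in [-4, 4]$, $\tau \in [-4, 2]$, and an
estimate landing on a box edge flags the item.

Two numerical facts shaped the design:

* **Reflection invariance.** The marginal likelihood is *exactly* invariant
  under jointly negating every $\delta_i$ (the mirrored scale, with the
  symmetric trait prior, fits identically). A "try both signs and keep the
  better likelihood" rule therefore cannot select an orientation; instead
  the fit accepts an explicit `orientation` convention (anchor item plus
  sign). The pipeline anchors the breakfast-MPF item negative, which encodes
  the scale's substantive direction — higher scores, more ultra-processed
  meals.
* **Edge items are weakly identified.** For an item whose 0.5-crossings lie
  outside the region where the population has mass, $(\delta, \tau)$ move
  along a near-ridge and their standard errors blow up. Well-conditioned
  recovery needs items whose consumption region is actually observed; the
  published 11-item set satisfies this.

Starting values: $\alpha = 1$, $\tau = -1$, and $\delta$ from a
principal-component heuristic (endorsers of an item sit near its location,
so the mean component score of endorsers ranks the locations).

**Person scores** are expected a posteriori means (`eap_scores()`) on the
same grid, with posterior SDs; identical response patterns get identical
scores. Standard errors for item parameters come from the observed
information of the marginal likelihood (numerical Hessian, `se = "hessian"`)
or from a nonparametric respondent bootstrap (`bootstrap_se()`), with each
refit reflected to the full-data orientation before aggregation.

## The reporting scale and levels

Calibrated quantities are mapped to a mean-100, SD-10 reporting scale
(`to_reporting_scale()`: $\pm1.8$ on the trait scale is 82–118). Scores
below 95 are *healthy*, above 101 *unhealthy*, and the closed interval
[95, 101] — both boundaries included — *mixed* (`assign_level()`); on the
calibration scale these cut-offs sit at $-0.5$ and $0.1$. The cut-offs were
set by expert judgement in the source study and are configuration here, not
something the package rediscovers. `scale_table()` places items and levels
on one continuum, reporting each item's transformed location, its crossing
region, and the modal response at a representative score per level (the
mixed band's midpoint; for the open-ended outer levels, the midpoint
between the adjacent cut-off and the 82/118 edge of the accurately measured
region). Reliability is summarized by the test information curve
(`test_information()`); `accurate_range()` reports the contiguous trait
interval meeting an *explicit* accuracy criterion — the notion of "accurate
enough" is deliberately not defaulted.

## Dimensionality and item retention

Unidimensionality is screened by limited-information factor analysis:
pairwise tetrachoric correlations (`tetrachoric_matrix()`, latent
bivariate-normal ML with PSD repair) followed by minimum-residual factoring
(`factor_analysis()`), with quartimin (oblimin) rotation when two or more
factors are extracted. A dominant factor is declared when its share of
total variance — sum of squared unrotated loadings over the number of
items — exceeds 20%. The retention rule keeps an item when (loading
$\ge 0.3$ *or* communality $\ge 0.2$) *and* discrimination $\ge 0.7$
(`retention_filter()`).

A structural caveat the package makes explicit: on data *generated from*
the unfolding model, linear factor methods understate the latent structure.
Unfolding items are non-monotone in $\theta$, so items located on opposite
ends correlate weakly or negatively even though a single trait drives
everything. Computing the exact population tetrachoric matrix implied by
the reference model (common $\tau = -1$) and factoring it gives a dominant
share of about 0.10 — far below the 20% screen, and varying the common
threshold over $[-3, -0.6]$ never lifts it past 0.14. The 27%-type
dominance reported for real recall data reflects strong monotone structure
in actual consumption behaviour that unfolding-generated synthetic data do
not possess. Consequently: passing the dominance screen on synthetic data
is *not* expected, the synthetic-data tests validate the dimensionality
machinery against constructions with known factor structure (planted
loadings, bivariate-normal oracles, maximum-likelihood cross-checks), and
on synthetic cohorts the retention filter prunes items mainly through the
discrimination rule.

## Differential item functioning

Construct validity is probed by likelihood-ratio DIF tests (`dif_test()`):
for each studied item, a two-group fit constraining the item's parameters
equal across groups is compared against a fit freeing its $\alpha$,
$\delta$, $\tau$ in one group, both groups sharing the $N(0,1)$ metric
through the anchor items (all-other anchoring by default, with iterative
purification available via `anchor_select()`). The statistic is twice the
marginal log-likelihood gain, referred to $\chi^2_3$; all three parameters
are tested jointly because "behaves differently" is not further
differentiated in the source instrument. p-values are Benjamini–Hochberg
adjusted across items at level 0.05 (both configurable). Simulation under
the null (20 replicates of two groups of ~3,000) holds the size and the
statistics track $\chi^2_3$ (QQ slope within [0.8, 1.2]); a planted
location shift of 0.5 is detected in well over 80% of replicates.

## The synthetic cohort generator

`simulation_config()` fixes the study conditions as defaults: 6,399
children, $\theta \sim N(0,1)$, responses drawn from the published 11-item
parameter sets. Design choices where the source is silent:

* **Threshold $\tau = -1$ for all items.** The source reports no
  thresholds; $-1$ gives every item a consumption region with
  0.5-crossings, the shape most published item curves display. Items whose
  curves never cross 0.5 can be emulated with a small positive threshold.
* **The seven non-retained items** are Bernoulli nuisance items (default
  rate 0.5), emulating foods such as bread whose consumption varies little
  with meal quality; the source publishes no parameters for them.
* **Foods per positive cell**: one to three distinct foods, uniform within
  the class vocabulary — only presence/absence matters downstream, so
  richer co-occurrence structure is deliberately out of scope.
* **Implausible reporters** (3 and 60 foods/day) and **occasion skipping**
  are opt-in knobs so the cleaning rules and reporting-rate patterns can be
  exercised. The analysis cohort uses the implausible reporters but *not*
  occasion skipping: a skipped occasion zeroes all three of its items at
  once, an occasion-level dependence that violates local independence and
  contaminates calibration — whereas the fitted model treats non-report as
  non-consumption.

Rebuilding items from generated records reproduces the generating matrix
exactly for every child who reports at least one food; a child whose row is
all zero reports nothing and is absent from the records by construction.
All generation is seed-deterministic and restores the caller's RNG state.

What the generator does **not** emulate: real food co-occurrence, portion
sizes, day-of-week effects, and — as discussed above — the monotone
response structure that real recall data superimpose on the unfolding
signal. Green synthetic-data tests therefore certify the estimation and
reporting machinery, not distributional fidelity to any real cohort.

## Survey estimation

Level prevalence uses weighted proportions with confidence intervals from a
stratified cluster bootstrap (default 1,000 replicates): clusters —
classes, the actual sampling units — are resampled with replacement within
year-school strata. This replaces the Taylor-linearized survey estimator of
the source analysis with an assumption-light equivalent; single-cluster
strata are collapsed into a pooled stratum with a warning, since they carry
no within-stratum resampling information.

## Problem sizes and reproducibility

The test suite and the acceptance script regenerate everything they check:
parameter recovery runs 20 cohorts of 6,399; DIF size and power use 20
null and 20 shifted replicates of 6,000; dense-grid oracles use $10^4$
nodes; bootstrap comparisons use 40–60 replicates at 1,200–4,800
respondents. Every random step takes an explicit integer seed, and
`analysis/01_simulate_cohort.R` through `analysis/07_apply.R` rerun the
whole development sequence deterministically.

## Known limitations

* Only dichotomous items are calibrated; the response function itself is
  implemented for the general polytomous case, but polytomous M-steps and
  scales are out of scope.
* The three-item binary case is formally underidentified (9 parameters
  versus 7 pattern frequencies); fitting requires at least four — in
  practice five or more — items.
* Exact numerical replication of estimates produced by other GGUM software
  on real data is not claimed; recovery is demonstrated within published
  standard errors on synthetic data.
* The 95/101 level cut-offs are taken as given; no cut-point discovery is
  attempted.
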