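---
title: "Methods: permutation statistics for sleep-stage functional connectivity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: permutation statistics for sleep-stage functional connectivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sleepfc)
```

## Scope and data model

`sleepfc` analyses inter-network functional connectivity (FC) across the
sleep-wake cycle at the *edge* level. The unit of data is an
`edge_fc_dataset`: for each of the stages wake, NREM2, SWS and REM, a
subjects × edges matrix of Fisher r-to-z transformed full correlations
between resting-state network (RSN) node time series. The pipeline starts
at node pseudo time series (or directly at edge-FC values); volumetric
image processing, artifact correction and sleep staging are upstream of
this package and out of scope.

A `node_partition` labels each node `higher_order` (multimodal/executive
networks: default-mode, executive-control, fronto-parietal, dorsal
attention components), `sensory`, or `other`, and flags the DMN /
fronto-parietal subset. The default 14-node partition has 7 higher-order
nodes of which 4 are DMN/F-P, which fixes the three edge universes used
throughout: all 91 edges, the 70 edges touching a higher-order node, and
the 46 edges touching a DMN/F-P node. Only the counts of higher-order and
DMN/F-P nodes matter for these subset sizes (91 − C(7,2) = 70 and
91 − C(10,2) = 46); the two non-higher-order, non-sensory labels in the
default partition are placeholders for nodes whose functional class is
genuinely ambiguous at this model order.

## From time series to edges

`compute_edge_fc()` computes the full (pairwise Pearson) correlation
between every node pair and applies the Fisher transform `z = atanh(r)`.
Because BOLD-derived pseudo time series are autocorrelated, the nominal
sample size T overstates the information content of each correlation.
With `df_correction = "bartlett"` the variance-stabilised statistic
`z_std = atanh(r) √(df_eff − 3)` uses the Bartlett effective sample size

$$\mathrm{df}_{\mathrm{eff}} = \frac{T}{1 + 2\sum_{k=1}^{\lfloor T/5\rfloor}
\hat\rho_a(k)\,\hat\rho_b(k)},$$

where the sums run over sample autocorrelations of the two series. The lag
cutoff at ⌊T/5⌋ is the conventional compromise between bias (too few lags)
and variance (noisy high-lag autocorrelations); `df_eff` is floored at 8 so
that a pathological negative autocorrelation sum cannot produce a
non-positive effective sample size. On AR(1) pairs with coefficient 0.5 and
T = 150 the uncorrected `z_std` has variance ≈ 1.7 under the null while the
Bartlett-corrected statistic is within a few percent of unit variance (the
test suite verifies both). The unstandardised `z` is the FC value carried
through the rest of the pipeline.

`regress_out_confounds()` removes noise-component time courses by ordinary
least squares (with an intercept) before edge FC is computed, and
`truncate_epochs()` harmonises epoch lengths for direct two-stage
comparisons by truncating the longer epoch to the shorter one's length.
The initial volumes are kept — the choice of segment is not identifiable
from the analysis design, and keeping the head of the epoch is the simplest
deterministic rule.

## Trajectory classification

`stage_code()` assigns x = 1, 2, 3, 4 to wake, NREM2, SWS, REM and pools
every subject's FC value for one edge. `fit_edge_trajectories()` then fits
polynomials of order 1–3 by least squares and tests each order's
R² against a permutation null: FC values are randomly reassigned to stages
*preserving the observed group sizes* (the default design is strongly
unbalanced: 33/24/9/6), R² is recomputed, and

$$p = \frac{1 + \#\{R^2_{\mathrm{perm}} \ge R^2_{\mathrm{obs}}\}}{1 + n_{\mathrm{iter}}}.$$

When the number of distinct relabelings is small (at most
`exact_limit`, default 10\,000) the full enumeration replaces Monte-Carlo
sampling and the p-value is exact. The R² statistic is inherently
one-sided: only large R² values indicate departure from a horizontal line.

### Selecting the best-fitting class

The classification rules are: (1) if only one order is significant, it
names the class; (2) if several are, the best fit among them is selected;
(3) if none is, the edge is flat. Rule (2) hides a genuine degeneracy:
least-squares R² is monotone in polynomial order, and whenever an edge has
any real stage structure, *every* order's overall-R² permutation p collapses
to the add-one floor. A literal "highest R² among significant fits" rule
therefore always selects the cubic — it cannot recover a quadratic or
linear truth at any signal-to-noise ratio. Adjusted R² does not rescue the
rule either: for a truly quadratic edge the cubic term's incremental F
exceeds 1 with probability ≈ 0.32, so adjusted-R² selection tops out near
68% quadratic recovery.

The package's default (`selection = "nested"`) therefore supplements the
overall test with an incremental one: order o ∈ {2, 3} is *supported* only
when its overall R² permutation p is below α **and** the permutation p of
its incremental F over order o − 1 (computed on the same relabelings) is
below α; the highest supported order wins, and no supported order means
flat. On planted archetypes at the default group sizes this recovers
linear, quadratic and cubic truths in ≥ 90% of replicates (the residual
errors are the α-level false-positive increments, e.g. a quadratic edge is
called cubic about 5% of the time). The literal rule (`"max_r2"`) and the
adjusted-R² variant (`"adjusted_r2"`) remain available for comparison.

A related subtlety affects archetype design: four stage means determine a
cubic interpolant, so "quadratic-looking" means with unequal second
differences contain a genuine cubic component that a consistent classifier
*should* detect. The default quadratic archetypes therefore place their
stage means exactly on parabolas (`archetype_from_poly()`), and the
archetype constructor checks curvature-sign consistency rather than exact
quadraticity.

Quadratic edges are categorised convex/concave by the sign of the leading
coefficient, and flagged *opposite-direction* when the fitted curve moves
toward reversed polarity during NREM — formally, with the vertex location
clamped to the NREM code range [2, 3] as x\*, when
sign(f(x\*) − f(1)) = −sign(f(1)) and |f(4) − f(1)| < |f(x\*) − f(1)|.
Movement *toward* zero counts: an edge can head for reversed polarity by
shrinking in magnitude without crossing zero.

Family-wise correction uses the Holm–Bonferroni step-down over the
selected-fit p-values of **all** edges (flat edges contribute their
smallest per-order p). This is the conservative reading of a family that
could also be restricted to the significant edges only;
`holm_family = "significant"` provides the alternative. The class
distribution over non-flat edges is tested against uniformity with a
one-variable chi-square on 2 degrees of freedom
(`chi_square_fit_distribution()`).

## Angular-distance permutational MANOVA

Each subject in each stage contributes a vector of edge-FC values; the
dissimilarity of two vectors is the angular distance
`arccos(cosine similarity)/π` ∈ [0, 1] — scale-invariant, so it measures
the *pattern* of connectivity, not its overall magnitude. Stage
differences are tested with the distance-based pseudo-F

$$F = \frac{SS_A/(a-1)}{SS_W/(N-a)}, \qquad
SS_T = \frac{1}{N}\sum_{i<j} d_{ij}^2, \qquad
SS_W = \sum_g \frac{1}{n_g} \sum_{i<j \in g} d_{ij}^2,$$

with SS_A = SS_T − SS_W and significance from relabeling subjects to
stages. **Squared** distances in the sums of squares are the single most
consequential interpretation choice in this module: the non-parametric
MANOVA literature this statistic comes from squares the distances, and the
squared form is required for SS_A = SS_T − SS_W to be non-negative in
general. The test suite cross-checks the pseudo-F against an independent
distance-based MANOVA implementation (`vegan::adonis2`) on the same
distance matrix.

Post-hoc pairwise comparisons restrict to one stage pair, report
t = √F of the two-group decomposition, draw the null from pair-restricted
relabelings, and apply Bonferroni (not Holm) correction across the six
stage pairs. Degree equivalents (distance × 180) are reported for
interpretability. If a relabeling makes SS_W = 0 with SS_A > 0 the
pseudo-F is infinite; the result is flagged degenerate and the permutation
p-value is still well defined (infinite observed F is matched only by
equally separable relabelings).

## Directional wake-to-NREM transitions

For each edge and each NREM stage, three permutation tests are run: a
Welch two-sample t between wake and NREM values, and two one-sample
t-statistics (wake against 0; NREM against 0) whose nulls are built by
relabeling the pooled values of the two stages and recomputing the target
group's statistic, as the between-stage exchange scheme prescribes (a
sign-flip null is available as an option). Categories are assigned
reversal-first:

* **reversal** — both one-sample tests significant with opposite signs;
* **increase** — two-sample significant, same sign, larger NREM magnitude;
* **reduction** — two-sample significant, smaller magnitude (sign-crossed
  cases that fail the reversal criterion are also reductions: FC moved
  toward and past zero without significant opposite connectivity);
* **none** otherwise.

The reversal-first precedence means no call is simultaneously a reversal
and an increase/reduction, and the rules depend on signs only relatively —
a global sign flip of all FC values leaves every category unchanged. Under
a null with identical wake and NREM distributions, reversals require two
independent significances and so occur at roughly α² ≪ α.

The counting unit for summaries is the (edge, NREM stage) pair — an edge
may reduce in one NREM stage and reverse in the other, and both calls
count. Summary rows split edges into higher-order–higher-order,
higher-order–sensory and sensory–sensory (non-higher-order nodes are
grouped with sensory so the three rows sum exactly to the all-edges row),
plus an overlapping DMN/F-P row. Holm–Bonferroni correction is applied
within each test family — the two-sample family, and one one-sample family
per stage; the family boundaries are configurable because they are not
uniquely determined by the design. The composition of categories is tested
with an exact one-sided binomial test of increases + reversals against
reductions at success probability 0.5. (Note the exact upper-tail p for
34 successes of 55 is ≈ 0.053, not the ≈ 0.03 sometimes quoted for this
proportion; the package reports the exact value.)

## The synthetic generator

`generate_edge_dataset()` draws, for every edge and stage, group-size many
subject values as archetype stage mean + independent Gaussian noise. The
defaults are the study conditions: 14 nodes, group sizes 33/24/9/6, and a
demonstration archetype profile of 49 flat, 5 linear, 36 quadratic
(18 convex / 18 concave, a subset dipping across zero) and 1 cubic edge.
Per-edge noise defaults to 0.2 Fisher-z — a plausible between-subject
spread for inter-network FC, chosen once as a convention since per-edge
variances are not part of the reported design. Each edge consumes its own
child RNG stream derived from the root seed by a counter scheme, so edge
values are reproducible regardless of edge order or subsetting; identical
configurations are byte-identical on disk.

What the generator deliberately does **not** emulate: between-edge
correlation beyond an optional shared per-subject latent factor
(default loading 0), matched subjects across stages (the permutation
schemes assume free exchangeability of stage labels, so independent groups
are the matching null model), hemodynamics, motion or scanner artifacts.
Passing tests on this generator therefore validate the *statistics* —
calibration, exactness, recovery — not robustness to the artifact
structure of real EEG-fMRI data.

`generate_node_timeseries()` produces stationary AR(1) node series driven
by equicorrelated innovations; with a common AR coefficient the stationary
cross-correlation equals the innovation correlation, giving a known ground
truth for validating the Bartlett correction.

## Numerical choices and problem sizes

* Add-one Monte-Carlo p-values bound p away from 0 at 1/(n_iter + 1);
  exact enumeration (used whenever the relabeling count is at most
  `exact_limit`) reports the plain proportion over all relabelings.
* Permutation-statistic comparisons use a 1e-12 slack so that exact ties
  (e.g. duplicated values) count as exceedances.
* Cosines within 1e-12 of ±1 are snapped before arccos so identical
  vectors give exactly zero distance.
* R² ties in the literal selection rule break toward the lower order
  (parsimony).
* Degenerate inputs are first-class: all-equal responses give R² = 0 with
  a degenerate flag and p = 1; zero vectors are rejected in the angular
  module; zero-variance groups produce signed-infinite t sentinels whose
  permutation ranks remain well defined.

The shipped test suite calibrates each permutation test at α = 0.05 over
500 null replicates at 500 iterations, verifies Monte-Carlo/enumeration
agreement on 20-relabeling instances, and runs archetype recovery at
100 (quadratic) and 50 (linear, cubic) seeded replicates with 1000
iterations — sizes chosen to give 3-standard-error resolution around the
quantities being checked while keeping the default run in the minutes
range. Production analyses should use the 10\,000-iteration default of
`perm_config()`; with fewer than ~4\,000 iterations the add-one floor sits
above the Holm threshold for a 91-edge family, and no edge can survive
correction.

## Known limitations

* The trajectory model is a polynomial in an ordinal stage code; the codes
  impose equal spacing between consecutive stages, which is a modelling
  convention, not a physiological scale.
* With 4 stages a cubic saturates the stage means, so cubic fits absorb
  any non-quadratic stage-mean pattern; interpret cubic calls accordingly.
* The wake-REM comparison inherits the design's very small REM group
  (6 subjects); at this size the angular post-hoc test has limited power,
  and a non-significant wake-REM difference is weak evidence of
  equivalence.
* Subjects are treated as independent between stages. If the same
  subjects contribute to several stages, the permutation nulls are
  approximate.
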