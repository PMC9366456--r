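---
title: "Quantifying rates and constraint of discrete morphological evolution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying rates and constraint of discrete morphological evolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Discrete character-state matrices — taxa scored for hundreds of
morphological characters — are the main quantitative record of anatomical
evolution in fossil groups such as Paleozoic amniotes.  Two complementary
questions can be asked of such data on a time-calibrated phylogeny:

* **How fast** did morphology evolve, and how did the rate change through
  time and between clades?
* **How constrained** was that evolution: did lineages keep exploring new
  character states, or did they recycle a limited state space
  (homoplasy), so that further change stopped producing new morphological
  disparity?

`charsat` implements both analyses, together with Mk modelling of a
discrete covariate (body-size category) and a synthetic-data module that
generates fully ground-truthed datasets with the same statistical
structure, so that every stage of the pipeline can be validated without
any external data.

## Dissimilarity, patristic distance and saturation

Morphological dissimilarity between two taxa is the **MORD** (maximum
observable rescaled distance): the mean per-character difference over the
characters scored in *both* taxa.  An unordered character contributes 0
when the two state sets intersect (so polymorphisms match on any shared
state) and 1 otherwise; an ordered character contributes the minimum
absolute state difference between the sets, rescaled by that character's
observed state range.  Cells that are missing (`?`) or inapplicable
(`-`) are both treated as "not scored": the two tokens are kept distinct
in the data model, but the dissimilarity computation does not
distinguish them, because no published convention does so for this
metric and imputing structure into inapplicable scores would be
arbitrary.  Pairs with no comparable characters are undefined and are
excluded from curve fitting rather than imputed.

Evolutionary change separating a pair of taxa is their **patristic
morphological distance**: the sum of branch lengths on the path
connecting them in a tree whose branch lengths are expected
character-state changes per character (such trees are typically inferred
under an Mk/Mkv model with the topology fixed; `charsat` consumes them as
input and checks topological congruence with the dated tree).

Under unconstrained evolution dissimilarity grows with patristic
distance; under a finite accessible state space homoplasy accumulates
and the relationship **saturates**.  The saturation level is estimated by
nonlinear least squares as the asymptote $V_{\max}$ of a
Michaelis–Menten curve

$$D = \frac{V_{\max}\,P}{K + P},$$

with $K$ the half-saturation constant in patristic-distance units.  The
fit uses Levenberg–Marquardt with an analytic Jacobian and both
parameters bounded below at zero; three deterministic starting points
guard against bad starts.  An 84% confidence interval on $V_{\max}$ is
computed from the asymptotic covariance of the least-squares estimate,
$V_{\max} \pm z_{0.92}\,\mathrm{SE}(V_{\max})$ with
$z_{0.92} \approx 1.4051$.  A fit is *untestable* (never an error) when
fewer than `min_pairs = 6` usable pairs or fewer than 3 distinct
patristic distances are available — below that a two-parameter fit with
an asymptotic interval is meaningless.  Degenerate flat data (all $D$
equal) return that value as the asymptote with a zero-width interval.
The CI method is isolated behind `fit_michaelis_menten()` so a
profile-likelihood variant could be swapped in.

## The equal-rates null and the 84% decision rule

Whether an observed asymptote is unusually low (strengthened constraint)
or high (relaxed constraint) is judged against matrices simulated under
a uniform, equal-rates null: each character evolves independently under
a $k$-state equal-rates Markov process along the changes tree, where $k$
is that character's observed state count (invariant characters are
simulated with $k = 2$, since $k = 1$ admits no change and the branch
lengths being emulated condition on variability), the expected number of
changes per branch equals the branch length, the root state is uniform,
and missing/inapplicable scores are copied into exactly the empirical
cells.  Each simulated matrix is paired with the *same* empirical
patristic distances and refitted; the converged asymptotes form the null
distribution (non-converged fits are dropped with their count recorded —
dropping preserves the distribution's shape better than imputing).

The decision rule: constraint is **relaxed** when the observed 84% CI
lies entirely above the null band, **strengthened** when entirely below,
and **none** otherwise.  Two 84% intervals of statistically identical
estimators overlap about 95% of the time (and two 95% intervals about
99% of the time), so the 84% level gives a conventional ~0.05 error rate
without the excess false negatives of 95% intervals;
`ci_overlap_calibration()` reproduces these frequencies by Monte-Carlo
simulation.  The null band is read as the *central* 84% interval of the
null asymptotes (8th–92nd percentiles), which makes the relaxed and
strengthened tests symmetric — the two-sided test being applied requires
a symmetric band.  A one-sided reading (84th percentile upward, 16th
downward) is exposed via `null_band = "onesided"` for sensitivity
analysis.

`scan_all_nodes()` applies the test to every internal node using only
the tip pairs descending from that node (optionally restricted to a
divergence-time window), sharing a single set of simulated matrices
across nodes.  No multiple-testing correction is applied across nodes —
the scan is a descriptive screen, and with the 84% rule roughly up to
16% of testable nodes are expected to show spurious signal on fully
null data (the observed estimate falls outside the null's central 84%
band about 16% of the time when the CI is narrow).  Tip pairs also share
path segments, so they are not independent observations; the fitting
procedure ignores this, as is standard for this analysis, and the
intervals should be read as descriptive rather than exact.

## Rates through time

Per-branch relative rates (typically posterior mean rates from a dated
Bayesian analysis, carried as MrBayes-style `[&rate=...]` annotations
and treated as relative — medians and log displays are invariant to the
unit constant) are summarised by slicing the tree at regular intervals,
by default 1 Myr.  A branch with parent age $p$ and child age $c$
crosses slice $t$ iff $c \le t < p$; the half-open rule ensures a branch
ending exactly at a slice is not double-counted with its child, and a
branch contributes its rate once to every slice it crosses.  The
per-slice median is the trend statistic (medians are computed on raw
rates; any log transformation is display-only), and a Loess curve
(default span 0.75, degree 2, exact direct surface) smooths the medians.
Group-wise series assign each branch to the clade containing *all* its
descendant tips — so a clade's stem branch belongs to the clade — and
exclude branches spanning several groups; with monophyletic groups
covering all tips this partitions every branch, and the per-slice group
multisets sum exactly to the ungrouped multiset.

## Mk models of body-size categories

Body size is modelled as a 4-category ordered-label trait (small < 1 kg,
medium 1–10 kg, large 10–100 kg, very large 100–1000 kg) under
continuous-time Markov (Mk) models on the dated tree.  The candidate set
crosses one/two regimes with equal-rates (ER) versus all-rates-different
(ARD) parameterisations; regimes are painted on branches by clade
membership, the stem branch of each named clade taking that clade's
regime and the backbone a declared background regime.  ARD places a free
rate on every ordered state pair (12 per regime for 4 states) with no
ordering restriction, so transitions between non-adjacent categories are
estimable.  The likelihood uses Felsenstein pruning with per-branch
propagators $e^{Q t}$ computed by eigendecomposition (dense
scaling-and-squaring fallback when the eigenbasis is ill-conditioned)
and a uniform root state distribution — the convention matching the Mkv
framing used for the trees being consumed; stationary or fixed root
options exist in the simulator.

Fitting maximises the likelihood over log-rates with L-BFGS-B in bounds
$[10^{-8}, 10^3]$ per Myr and multiple starts (ARD surfaces are
multimodal).  `fit_mk_model_set()` warm-starts each richer model from
its nested neighbour (ER → ARD, single → multi), which guarantees in
practice that a superset model never reports a worse likelihood than its
nested counterpart.  Model support uses $AIC = 2k - 2\log L$ with $k$
the *full* free-rate count (1, 12, 2 or 24 here) and Akaike weights
$w_i \propto e^{-\Delta AIC_i/2}$.  Note that some software reports
effective parameter counts that drop rates attached to transitions never
realised in the data, which yields smaller $k$ and different AIC values
for the same fit; `charsat` deliberately uses the definitional count.
Marginal ancestral states combine the post-order (subtree) and pre-order
(rest-of-tree) passes under the fitted model; each node's probability
vector sums to 1 within $10^{-9}$.

## The synthetic-data module

The generator produces datasets with the statistical structure the
analyses assume, plus the ground truth needed to score every downstream
call.  Its defaults describe the study conditions being emulated and are
fixed once:

* **Tree**: forward birth–death simulation from a crown root at 320 Ma
  (birth 0.025, death 0.015 per Myr), extinct lineages retained as
  fossil tips.  Exactly `n_tips` (default 80) tips are obtained by
  uniform taxon sampling from a complete simulation with at least that
  many tips — mirroring the incomplete sampling of real fossil datasets —
  always keeping both root subclades, and requiring each subclade to
  hold at least a quarter of the tips (both primary lineages of the
  emulated system are diverse).  Conditioning is by rejection with an
  explicit failure after a maximum number of attempts.
* **Characters** (default 300, unordered): equal-rates Mk with a
  *restricted accessible state space* inside one constrained clade
  (default $k = 2$) and a wider space elsewhere ($k = 6$).  Constraint
  is operationalised this way because the constraint concept being
  tested is defined behaviourally via saturation: a small accessible
  space forces homoplasy and a low asymptote.  Change events per branch
  are Poisson with mean equal to the integral of the rate profile
  (default: exponential decline, base 0.02 changes/character/Myr at the
  root, half-life 100 Myr — rates decline ~9-fold across the tree while
  still accumulating enough change for deep pairs to saturate), times a
  per-character gamma multiplier (shape 2, mean 1) for among-character
  rate variation.  The per-branch expected change counts, averaged over
  characters, are recorded as the true changes tree; an optional
  lognormal noise multiplier emulates branch-length estimation error, so
  tests need no external inference software.  Missingness (default 25%
  of cells) is applied last, completely at random, with an optional
  taxon-biased mode.
* **Size trait**: 4 states under a two-regime ARD model.  The
  "synapsid-style" regime is upper-triangular — transitions only toward
  larger categories, every large-to-small rate exactly zero — as an
  adjacent-step ladder (default 0.015/Myr).  The "reptile-style" regime
  is bidirectional and fast, with downward rates exceeding upward ones
  (defaults 0.06 up, 0.18 down per Myr), so reversals are common.  This
  contrast (directional ladder versus fast downward-biased mixing) is
  what makes the generating model identifiable: the fast regime
  decorrelates related tips, so a single shared rate matrix cannot
  simultaneously explain one clade climbing to large sizes and the other
  remaining small, while the strong rate asymmetry separates ARD from
  ER.  Even so, a 24-free-rate model must overcome a 24-unit AIC
  handicap against the 12-rate single-regime model: at ~100 tips the
  true multi-regime model is usually *not* selectable (phylogenetic
  correlation caps the attainable log-likelihood contrast), and
  model-recovery checks therefore use trees of ~250 tips.  This is an
  honest small-sample limit of AIC selection for richly parameterised
  Mk models, not a failure of the fitter.

What the generator does *not* emulate: correlations between characters,
non-uniform state frequencies at the root, character-specific
missingness linked to anatomy, or preservation/collection biases.
Passing tests therefore demonstrate the correctness and calibration of
the computations under the stated model, not robustness to every
property of real matrices.

## Numerical choices and test scale

* Random streams: every stochastic routine takes one integer seed;
  internal replicate seeds derive from it by a fixed published rule
  (`split_seed()`), making all outputs bit-reproducible.
* Michaelis–Menten: LM with analytic Jacobian, maximum 200 iterations,
  parameters bounded at zero; asymptotic SE from $(J^TJ)^{-1}$, declared
  non-converged if that matrix is singular.
* Propagators: eigendecomposition with condition-number guard, else
  scaling-and-squaring; probability rows renormalised after clamping
  tiny negatives.
* The packaged test-suite exercises the pipeline at deliberately modest
  problem sizes — trees of 25–300 tips, 80–500 characters, 100 null
  simulations per scan, 3–20 replicates per power check — chosen so the
  full suite completes in minutes while each check retains enough power
  to detect the planted effect; the reference analysis scale
  (98 taxa × 366 characters, 1000 null iterations) runs unchanged
  through the same functions.

## Known limitations

* Taxon pairs share tree paths; the least-squares fit and its CI treat
  them as independent.  The null-simulation comparison inherits the same
  structure on both sides, which is why the calibration holds in
  practice, but the CIs are descriptive.
* The equal-rates null has no among-character rate variation.  Empirical
  matrices (and the default synthetic matrices) do; strong rate
  heterogeneity shifts observed asymptotes relative to the null and can
  inflate apparent signal.  The false-positive calibration reported by
  the tests therefore uses homogeneous-rate null data.
* The asymptotic 84% CI can be optimistic for nodes with few pairs;
  `min_pairs` guards the worst cases only.
* Ancestral-state and rate-through-time summaries condition on a single
  (point-estimate) tree; posterior tree uncertainty is out of scope.
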