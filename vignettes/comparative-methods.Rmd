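---
title: "Comparative phylogenetics of yeast cell size and fermentation versatility: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative phylogenetics of yeast cell size and fermentation versatility}
  %\VignetteEncoding{UTF-8}
---

# The problem

Budding yeasts (Saccharomycotina) vary in two traits of putative ecological
relevance: the size of the cell and the number of simple sugars a species can
ferment. If fermentation was an ecological innovation that triggered an
adaptive radiation, theory predicts early bursts — high speciation and trait
diversification near the base of the clade, slowing toward the present — and
possibly correlated evolution between fermentative capacity and the cell
machinery that supports it. `phyloferm` implements the full chain of
comparative analyses needed to test these predictions on a time-calibrated
phylogeny with per-species trait data: phylogenetic signal, trait-evolution
model selection, disparity through time, diversification-rate estimation, and
phylogenetic regression. A first-class synthetic-data generator reproduces the
statistical structure of such a dataset at the study's own dimensions
(77 species, 150-million-year root), so every stage is testable without any
external files.

# Data encoding

**Fermentation versatility** is an ordinal count over seven commonly scored
sugars (glucose, galactose, sucrose, maltose, lactose, raffinose, trehalose).
A sugar counts when its test code is positive (`+`), slow (`s`) or weak (`w`);
variable responses (`±`, `v`), negatives and unreported tests count zero.
Unreported tests are treated as negative deliberately — the conservative
choice, since an unscored sugar cannot support a claimed capacity — and the
species are logged. The raw count lives on 0–7; seven sugars are scored but
no observed species ferments all seven, so the observed scale is 0–6 and the
pipeline simply reports the observed maximum rather than hard-coding a 0–6
cap.

**Cell size** is the midpoint of the reported range of the *lower* diameter
axis (yeast cells are asymmetric; the lower axis is the comparable one), in
micrometres, analysed on the natural-log scale. The phylogenetic regression
uses a configurable transform chain for the response; the default is the
double log, `log(log(cell size))`, with plain `log` as the documented
alternative, and every report states which chain was used. The double log
requires cell sizes above 1 µm, which holds for all yeasts in this size
range.

# The statistics

## Phylogenetic signal

*Discrete trait.* The statistic is the minimum number of character-state
changes on the tree (unordered states, unit cost), computed by Sankoff
dynamic programming so polytomies need no special-casing; on binary trees it
equals Fitch parsimony, and the test suite verifies it against exhaustive
enumeration and an independent implementation. The null shuffles tip states
uniformly without replacement R times (default R = 1000); signal is inferred
when the observed count falls below the null median, with
p = (1 + #{null ≤ observed}) / (R + 1). Versatility is treated as unordered
for this test — no ordering is assumed by the procedure being emulated — but
an ordered-cost matrix can be supplied through the `cost` argument of
`parsimony_transitions()`.

*Continuous trait.* Blomberg's K compares the observed ratio of the
non-phylogenetic to the phylogenetically corrected mean squared error with
its Brownian-motion expectation on the same tree:

    a      = (1'C⁻¹x) / (1'C⁻¹1)
    MSE0   = (x−a)'(x−a) / (n−1)
    MSE    = (x−a)'C⁻¹(x−a) / (n−1)
    E[MSE0/MSE] = (tr C − n/(1'C⁻¹1)) / (n−1)
    K      = (MSE0/MSE) / E[MSE0/MSE]

K = 1 matches Brownian motion; K < 1 means relatives resemble each other
less than BM predicts. K is exactly invariant to affine transforms of the
trait and to uniform branch-length rescaling (both property-tested).
Significance uses the variance of standardized independent contrasts under
tip shuffling: signal compresses contrasts, so the observed variance is
compared one-sided against the lower tail. Because contrasts are linear in
the trait, the permutation null is computed as one matrix product with a
precomputed contrast operator rather than n−1 recursions per shuffle.

All permutation p-values use the +1 finite-sample correction and count ties
toward significance (≤, not <): conservative, and consistent with the
one-sided "fewer than the null median" direction of both tests. At R = 199
this makes the test exactly nominal at α = 0.05, which the acceptance suite
checks against the binomial interval.

## Trait-evolution models

All single-regime models are Gaussian processes on the tree, so the data are
one draw from a multivariate normal with covariance σ²R(φ) and constant mean.
With C the phylogenetic variance–covariance matrix (shared root-to-MRCA path
lengths), T its height, t_a the MRCA depth and d_ij the patristic distance:

| model | R(φ) entry (i,j) | shape φ | k |
|-------|------------------|---------|---|
| BM    | C_ij             | —       | 2 |
| OU    | e^{−α d_ij}(1 − e^{−2α t_a})/(2α) | α ≥ 0 | 3 |
| EB    | (e^{a C_ij} − 1)/a | a < 0 | 3 |
| delta | T(C_ij/T)^δ      | δ > 0   | 3 |
| WN    | 1{i=j}           | —       | 2 |

k counts include σ² and the root state. The OU form is the non-stationary
process rooted at the optimum on an ultrametric tree (OU and EB therefore
require a calibrated tree and error otherwise); `expm1` keeps the OU and EB
entries exact in the BM limit, and the identities "delta(δ=1) ≡ BM" and
"EB(a→0⁻) → BM" are tested. The default EB box is decelerating,
a ∈ [log(10⁻⁵)/T, −10⁻⁶]; an accelerating box (upper bound 5) is available
via `bounds`. The delta box defaults to (10⁻³, 3).

Both σ² and the mean are profiled in closed form (GLS), so each fit is at
most a one-dimensional search over the shape parameter. That search is a
deterministic 41-point grid scan followed by bounded quasi-Newton refinement
(tolerance 1e−8) from the best grid point. A grid-plus-refine scheme was
chosen over random multistart because the profiled objectives are
one-dimensional and occasionally multimodal in α: the grid cannot miss a
basin wider than its spacing, and the result is bit-reproducible without any
seed.

Models are ranked by AICc, −2lnL + 2k + 2k(k+1)/(n−k−1), with Akaike weights
w_i = exp(−Δ_i/2)/Σ exp(−Δ_j/2).

*Multi-regime models* ask whether a painted clade (here, the clade that
underwent whole-genome duplication) evolved differently from the background.
BM1 and OU1 ignore the painting. BMS gives each regime its own Brownian rate:
each branch contributes its length times its regime's rate, so the
covariance is Σ_r σ²_r C_r with C_r the per-regime shared-path matrices; the
base rate is profiled and the rate ratio optimized. OUM shares α and σ² but
gives each regime its own optimum θ_r: the expected tip value is the
exposure-weighted mixture of optima along the root-to-tip path, with the
root stationary at its regime's optimum, and the θ vector drops out by GLS.
The free-parameter counts are k = 1 + (number of regimes) for BMS and
k = 2 + (number of regimes) for OUM — the counting used by the standard
multi-regime tooling, and the one under which the AICc identity reproduces
published model tables from their log-likelihoods. The clade's stem branch
is painted with the clade regime by default (`include_stem` toggles this;
the convention is not settled in the literature). Degenerate paintings are
honest special cases: a single-regime painting makes OUM collapse to OU1 and
BMS to BM1 exactly, which the tests assert.

## Disparity through time and the MDI

Disparity of a set of values is the mean pairwise distance (computed in
O(m log m) from the sorted values). Walking the ultrametric tree from the
root, at each divergence event the curve records the mean, over all lineages
alive at that instant (the just-split node included, its children not yet),
of the subclade disparity each lineage subtends divided by the whole-clade
disparity; single-tip lineages contribute 0, the root point is 1, and the
curve closes at (1, 0). Times are rescaled to [0, 1]. Relative disparities
are invariant to affine trait transforms, so the whole curve is
scale-free — which also means the Brownian null needs no rate matching in
principle; the simulation rate is nonetheless estimated from the observed
contrasts (REML) so that the null is conditioned on the observed scale.

The MDI is the trapezoid-rule area between the observed curve and the
pointwise median of S Brownian simulations (default S = 999), positive when
observed disparity sits above the null median late in time (constant or
accelerating trait diversification), negative for early bursts. For the
p-value each simulated curve's own MDI is measured against the median of the
*other* S − 1 curves — computed exactly from order statistics, not
approximated — giving an exchangeable null; the one-sided p follows the sign
of the observed MDI and a two-sided p on |MDI| is reported alongside, since
the emulated procedure reports a p-value without defining its convention.

## Diversification

The lineage-through-time series lists branching times and lineage counts
(polytomies add children − 1 lineages). The pure-birth rate conditioned on
the reconstructed tree is λ̂ = (n−2)/X with X the total tree length,
se = λ̂/√(n−2), lnL = (n−2)log λ̂ − λ̂X; the unconditioned (n−1)/X variant is a
flag. No rate-shift detection is attempted — the constant-rate fit plus the
LTT series is the supported evidence surface — and the Pybus–Harvey γ is
provided as a clearly labelled descriptive extra.

## Phylogenetic regression

PGLS errors follow the phylogenetic correlation with off-diagonals scaled by
Pagel's λ ∈ [0, 1], estimated by profile ML (golden-section over [0, 1] with
explicit endpoint checks, tolerance 1e−8; coefficients and error variance
profiled in closed form). The non-phylogenetic comparison is OLS fitted
through the same machinery so AICc values are directly comparable; degrees
of freedom are fixed at 4 (intercept, slope, variance, λ) versus 3. Because
the "R²" of a GLS fit is not uniquely defined, both variants are always
computed: the generalized 1 − (e'C⁻¹e)/((y−ȳ)'C⁻¹(y−ȳ)) with ȳ the GLS grand
mean, and the ordinary 1 − RSS/TSS on the raw residuals.

# Tree machinery and calibration

Trees are `ape` "phylo" objects throughout; Newick I/O, the VCV, contrasts,
pruning and polytomy resolution are thin validating wrappers over `ape`
(`read.tree`/`write.tree`, `vcv.phylo`, `pic`, `keep.tip`,
`multi2di(random = FALSE)`), with the package adding the error contracts the
pipeline needs: character offsets for malformed Newick, a hard error for
missing branch lengths, deterministic (never randomized) polytomy
resolution with zero-length edges — which leaves the VCV unchanged — and a
1e−8 × height perturbation of zero-length terminal branches when a matrix
must be inverted (below any reporting precision). Time calibration is
penalized-likelihood rate smoothing (`ape::chronopl`, smoothing parameter
defaulting to 1), with calibrated nodes specified as MRCAs of tip pairs in a
YAML config and infeasible age orderings rejected before optimization. One
practical constraint discovered in testing: the Poisson rate likelihood is
nearly flat when branch lengths are far below ~0.1 expected substitutions,
and the optimizer then stalls at its initialization, so genetic-distance
inputs should be on a realistic substitutions scale (the synthetic generator
uses a mean rate of 0.01 substitutions/Myr, giving exact recovery of
clock-like inputs).

Which tree — genetic-distance or calibrated — feeds the signal and
model-selection stages is genuinely ambiguous in the emulated workflow (the
analyses were run "with the original phylogeny" yet OU/EB and dtt need an
ultrametric one). The pipeline therefore accepts either per stage
(`tree_mode`), records the choice in every report, and the stages that
mathematically require an ultrametric tree refuse to run otherwise.

# What the synthetic generator emulates — and what it does not

`make_paperlike_dataset()` reproduces the dimensions and generating
structure the analyses assume: a 77-tip Yule tree (λ = 0.024/Myr) rescaled
to a 150-MYA root; log cell-size under OU with optimum log(3.5) µm,
stationary SD 0.35 and α = 0.02/Myr (α × height = 3, eroding signal to the
K ≈ 0.3 regime); versatility under an equal-rates Mk chain on states 0–6
from root state 2, with the pair rate (0.002/Myr) set so the expected number
of changes (~40) matches the parsimony-count scale of a real
77-species dataset; a correlated pair in which the double-log cell-size
response equals 0.5 × versatility plus Brownian error (tip SD 1); and a
genetic-distance tree with branchwise lognormal rate noise (CV ≈ 0.3) plus
three true node-age calibrations. The manifest records every parameter and
the seed, and regeneration is bit-identical.

Deliberate non-realism, hence what passing tests do *not* show about real
data: the tree is exactly ultrametric with no topological error; traits are
measured without error (the emulated analysis makes the same assumption);
the Mk chain is equal-rates, so the versatility marginal drifts toward
uniform rather than holding a mode at 2 the way real yeasts do; fermentation
codes are generated deterministically from the count rather than from sugar
identities; and taxon sampling is complete by construction. Calibration
accuracy on the synthetic genetic distances (~7% median node-age error at
rate CV 0.3) says nothing about the systematic uncertainty of real fossil or
event-based calibrations.

# Test and calibration-suite sizes

The randomized suites run at the following problem sizes, chosen to make the
Monte-Carlo error comfortably smaller than each acceptance band: Blomberg-K
calibration, 500 BM simulations on the 77-tip fixture (mean K required in
[0.9, 1.1]); test size, 400 i.i.d. datasets at R = 199 against the exact
binomial interval; MDI null, a 299-simulation shared null median with 200 BM
replicates (|mean MDI| < 0.05) plus 20 early-burst and 20 white-noise draws
for the sign checks; dual-implementation oracles at 100 (likelihood) and
1000 (parsimony) random 6-tip instances; OU parameter and PGLS slope
recovery at 200 replicates each (medians within 20% and 10% of truth);
pure-birth coverage at 500 trees (λ̂ within 2 se of truth in ≥ 90%).

# Known limitations

Likelihoods are evaluated through dense Cholesky factorizations of the n × n
VCV — transparent and exact, and entirely adequate at n ≈ 10², but the wrong
tool for trees of 10⁴ tips, where pruning-style O(n) algorithms would be
needed. OU fitting assumes an ultrametric tree (the non-ultrametric OU
likelihood is not implemented). The multi-regime machinery supports one α
for OUM (no per-regime α or σ² variants), mirroring the four-model set it
reproduces. Measurement error is not modelled anywhere. The MDI p-value
convention is a documented choice, not a community standard; both one- and
two-sided values are always reported so the choice is auditable.
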