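---
title: "Methods: from guide counts to drug-sensitization estimates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from guide counts to drug-sensitization estimates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

A pooled CRISPR knockout screen run in drug- versus vehicle-treated cell
lines asks, for every targeted gene, whether knocking it out makes cells
more (or less) sensitive to an anchor drug. The readout is the relative
abundance of each guide RNA in the drug arm compared with the matched
vehicle arm: a guide whose cells die faster under drug is depleted, so a
negative log2 fold change (LFC) marks a *sensitizer*. Run across a panel of
case (here, neuroblastoma) and outgroup cell lines and several anchor
drugs, such a screen nominates drug combinations: a sensitizing knockout
points to a drug against that gene product as a combination partner.

chemosens implements the analysis layer of such a screen: guide-level
quality filtering, gene-level aggregation with uncertainty, a robust
hierarchical Bayesian measurement-error model for per-drug, case-vs-outgroup
and cross-drug shared effects, an empirical-null gene-set test, ZIP synergy
scoring for follow-up dense drug-drug matrices, and a synthetic-screen
generator that makes every stage testable against known ground truth.

# Preprocessing: from counts to gene-level estimates

**Normalization.** The package uses median-ratio size factors (the
reference for each guide is its geometric mean across samples, computed
over guides with all-nonzero counts; each sample's factor is the median
ratio to that reference). This is robust to the composition shifts caused
by strong dropout of essential or sensitized guides, which total-count
scaling is not. For very small matrices (< 100 all-nonzero guides) the
method falls back to total-count scaling with geometric-mean-1 factors.

**Guide LFCs.** For each drug sample and its matched vehicle,
`lfc = log2((n_drug + c) / (n_vehicle + c))` on the normalized scale with
pseudocount `c = 1`. The base-2 logarithm and unit pseudocount are
conventions, not estimates; the pseudocount keeps zero-count guides finite
while shrinking only the least-informative values.

**Low-count filter.** Guides with raw counts below 5 in *both* arms are
flagged: their ratios are dominated by sampling noise. A guide that is rare
in only one arm is kept — one-sided collapse is exactly the signal the
screen is looking for.

**Dixon outlier filter.** Within each gene x cell line x drug group
(typically 6 guides), a single guide can misbehave — off-target activity,
cloning artifacts — and distort the gene mean. The filter computes Dixon's
r10 ("Q") statistic, the gap between the most extreme value and its nearest
neighbor divided by the range, and flags the extreme guide only if (a) its
two-sided p-value is below 0.05 and (b) its LFC disagrees in sign with the
mean of the other guides. The directionality rule is essential: a guide
that is merely *stronger* in the same direction as its siblings is
evidence, not artifact. p-values are obtained by linear interpolation in
alpha between the published two-sided critical values for n = 3-10; beyond
the tables the p-value is clamped (0.001 / 1). Only the accept/reject
decision at 0.05 is consequential; the interpolated p is reported for
transparency. At most one guide per group can be flagged, by construction
of the r10 statistic.

**Filter order.** Low-count removal runs before the Dixon test, so the
outlier test only sees stable estimates. The two filters interact only when
a low-count guide is also the extreme value; a `dixon_first` switch is
provided for the opposite order, and both orders are exercised in the
tests.

**Aggregation.** The gene-level estimate is the mean of kept guide LFCs,
`y`, with squared standard error `se2 = var/n`. Genes reduced to a single
kept guide are dropped (with a log of what was dropped) rather than
imputed: the downstream model requires a finite standard error, and
imputing a library-median SE would manufacture precision.

# The measurement-error model

Gene-level estimates arrive with heterogeneous, *known* uncertainty — a
gene measured by 6 concordant guides is far more reliable than one reduced
to 2 discordant ones. The model treats `se2` as known and adds a shared
residual:

$$y_i \mid d_i, x_i \sim t\!\left(\nu,\; \alpha_{d_i} + \beta_{d_i} x_i,\;
  \sqrt{SE^2_{y_i} + \sigma^2_{d_i}}\right)$$

with cell lines indexed by `i`, drugs by `d`, and `x = 0` for case
(neuroblastoma) lines, `x = 1` for the outgroup. So `alpha` is the
sensitizing potency in the case group and `beta` is the outgroup-minus-case
shift. Because sensitization is a *negative* fold change, a positive `beta`
means the case group is more sensitized; `selectivity_table()` reports
`+beta` as the "differential" so that positive values always read as
case-selective sensitization.

The Student-t likelihood with `nu ~ Gamma(2, 0.1)` makes the fit robust to
occasional wild fold changes without discarding them; as the data
concentrate, `nu` grows and the model approaches a Gaussian. Location
parameters get weakly informative Normal(0, sd 5) priors — fold changes
beyond +-10 are physically implausible, so these priors are vague on the
relevant scale. Scale parameters get the positive half of the same prior.
Whether the prior's "5" is an sd or a variance is a representation choice;
sd is used here (the more diffuse reading).

Three variants are exposed:

* `per_drug` — one drug, `alpha + beta x`, priors directly on the
  parameters (no hierarchy);
* `overall` — drops `beta`: the general sensitizing effect of a knockout
  irrespective of group, usable with a single group of lines;
* `joint_shared` — for a set of related drugs (e.g. the six DNA-damaging
  agents), per-drug `alpha_d, beta_d` are drawn from shared Normal
  distributions whose means `mu_alpha`, `mu_beta` are the knockout's shared
  effect across the whole drug class. The hierarchy shrinks noisy per-drug
  estimates toward the class mean, which the tests verify directly.

**Sampling.** The models are written as JAGS programs (shipped under
`inst/jags/`) and sampled by Gibbs/slice MCMC via rjags. Defaults are 4
chains x 1000 warmup + 1000 draws with a convergence gate of R-hat <= 1.01;
a failing fit is retried once with doubled draws and otherwise emitted with
a `converged = FALSE` flag, never dropped. Divergence counts — an
HMC-specific diagnostic — are reported as `NA`. Chain RNGs are derived from
the user seed, and `fit_gene()` canonicalizes record order, so results are
exactly reproducible and invariant to input row order. Any sampler meeting
the convergence gate would be conformant; the posterior, not the algorithm,
is the contract.

**Summaries.** Per parameter: posterior mean, sd, central 95% interval,
`p_neg = P(theta < 0 | data)` and
`p_nonzero = 2 max(p_neg, 1 - p_neg) - 1`, a symmetric index that is 0 for
a posterior centered on zero and approaches 1 as the posterior mass leaves
zero — the quantity used for volcano-style displays and ranking.

# Gene-set analysis against an empirical null

Rather than assuming a parametric null, the 400 non-targeting control
guides — which match the targeting guides in every respect except genomic
activity — are randomly grouped into 66 pseudo-genes of 6 guides (the 4
leftovers are discarded) and pushed through the *identical* preprocessing
and model path. A gene set is then compared against these null genes with a
two-sided Wilcoxon rank-sum test (exact when both samples are <= 25 and
tie-free, normal approximation with continuity correction otherwise), and
the effect size reported is the median set effect minus the median null
effect. p-values are BH-adjusted within each collection. Sets overlapping
the library in fewer than 5 genes are emitted with a `skipped` flag — a
655-gene targeted library simply cannot power smaller overlaps. Whether
raw aggregated fold changes or posterior means feed the test is a config
switch (`effect_source`), defaulting to posterior means.

The calibration of this machinery is checked empirically: random subsets of
null genes tested against the remaining null genes reject at the nominal
5% rate (the acceptance suite runs 2,000 such draws).

# ZIP synergy for dense drug-drug matrices

Follow-up screens measure a 10 x 10 dose matrix (1:3 dilution, 0-dose
anchors) of two drugs. Raw signal is normalized to fractional cytotoxicity
by the plate's own vehicle (0%) and kill-control (100%) wells. Monotherapy
rows are fit with a four-parameter logistic on log-dose, with bounded
parameters and a fixed grid of starting values so the least-squares fit is
deterministic; non-convergent or wrong-way (decreasing) responses fall back
to a flagged flat curve.

The zero-interaction-potency expectation at combination dose `(a, b)` is
the Bliss-style surface of the *fitted* monotherapy curves,
`y1(a) + y2(b) - y1(a) y2(b)`, and the synergy score is
`delta = observed - expected`, reported x100 on the percent scale. This is
a deliberate variant of the original ZIP formulation, which refits
logistic curves along every row and column of the matrix; the
fitted-monotherapy version captures the same zero-interaction surface, is
deterministic and cheap, and its recovery properties (exact zero on
additive surfaces, exact recovery of a planted constant interaction) are
what the tests assert. Numeric parity with any particular external
implementation is not claimed. The "region of maximum synergy" is the
highest-mean contiguous 3 x 3 dose window (size configurable), and groups
of combinations are compared by the same rank-sum machinery as the
gene-set test.

# The synthetic-screen generator

The generator's defaults reproduce the reference study design: 655
druggable genes x 6 guides, 400 non-targeting guides, 55 pan-essential
genes (326 guides), 10 case + 8 outgroup cell lines, 8 drugs (6
DNA-damaging) plus vehicle — 162 samples. Counts are negative binomial
(dispersion 0.05, the typical scale for pooled-screen sequencing) around a
depth-scaled log-normal baseline abundance (sdlog 0.5, mean depth 500
reads/guide); the count model is the package's own choice, since a
fold-change-level analysis never states one. Planted effects multiply the
drug-arm mean by `2^delta`; pan-essential dropout multiplies both arms;
non-targeting guides are never shifted (their true delta is identically
zero, which the tests assert). An optional fraction of targeting guides is
planted as opposite-sign outliers to exercise the Dixon filter.

What the generator does *not* emulate: PCR jackpotting, guide-efficacy
heterogeneity beyond the single outlier mechanism, dose-response of the
anchor drug (delta is the net effect at the screened dose), or time-course
dynamics. Passing tests therefore demonstrate correctness of the
*analysis* under a plausible count model, not robustness to every artifact
of real screens.

Dose-matrix fixtures use monotherapy curves with maximum inhibition around
0.5-0.6 so that the Bliss surface plus a planted interaction of 0.15 stays
inside [0, 1]; otherwise the clip to the response scale would bias the
recovered interaction downward.

# Problem sizes and numerical choices

The validation studies (also run by `scripts/acceptance.R`) use sizes
chosen to make the checks sharp but cheap: 50 replicates for posterior
coverage of (alpha, beta) at the generative truth (-1, 0.5, sigma 0.1,
nu 10, 18 lines); 2,000 subset draws for gene-set calibration; and a
200-gene screen with 10 planted sensitizers (delta -1, depth 500x, 6 case
lines, 66 null pseudo-genes) for end-to-end ranking, scored as the
fraction of planted genes whose sensitization evidence exceeds the null
genes' 95th percentile. Test fits use 2 chains with shorter warmup than
the 4 x 1000 defaults; the convergence gate applies regardless.

Other numerical details: size-factor fallback threshold of 100 all-nonzero
guides; Dixon restricted to n = 3-10 (the r10 statistic's intended range;
larger groups are left untested rather than mis-tested); 4PL bounds
min, max in [0, 1], EC50 within the dose range widened 100x each way, Hill
slope in (0, 10]; ties in gene rankings broken alphabetically for
stability; permutation p-values use the add-one rule so they are never
zero.

# Known limitations

* The model assumes `se2` is known; with 6 guides it is itself an estimate,
  and genes reduced to 2 guides have noisy standard errors. The shared
  `sigma` partially absorbs this.
* The joint hierarchy shares information across drugs but not across genes;
  gene-gene covariance (co-functional modules) is out of scope.
* RRA-style rank aggregation scores are accepted as an input column for
  hit counting but never computed here.
* The ZIP variant is documented above; scores from other implementations
  will differ in the second digit, not in sign or ordering.
* The Wilcoxon gene-set test compares gene-level estimates; guide-level
  alternatives would change power but are not implemented.
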