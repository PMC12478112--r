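---
title: "Modelling activity-dependent synaptic pruning after NMDAR-dependent LTD"
author: "synaprune"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling activity-dependent synaptic pruning after NMDAR-dependent LTD}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synaprune)
```

## The biological problem

Bath application of NMDA to cultured hippocampal neurons induces chemical
long-term depression (LTD): synaptic currents drop by roughly 30% within
half an hour. Over the following hours a fraction of the depressed
synapses is not re-potentiated but eliminated outright — pre- and
post-synaptic components disappear together (synaptic pruning). Under
normal network activity about 30% of synapses are lost by 3 h; silencing
the network with TTX after LTD induction raises the loss to about 70%,
blocking AMPA receptors raises it to roughly 47%, and raising network
activity (GABA-A block or high extracellular calcium) abolishes pruning
almost completely. The synapses that are lost are not a random draw: they
tend to have low presynaptic activity (scored by synaptotagmin-antibody
uptake), to sit far from their nearest neighbors, and to be contacted by a
single "en-passant" bouton of a dedicated axon rather than sharing an axon
with nearby synapses.

`synaprune` packages the analysis chain behind those observations
(puncta densities, mEPSC/sEPSC event analysis, spine-fate covariates) and
a generative model of the pruning rules, together with synthetic-data
generators that stand in for the microscopy and patch-clamp recordings.

## The pruning model

Pruning is modelled as a single Bernoulli decision per synapse over the
3-h horizon. This one-shot treatment reflects the experimental design:
densities measured at 3, 6 and 12 h plateau after 3 h, so the 3-h state
is treated as absorbing, and each comparison in the source experiments
uses a single post-induction timepoint.

1. Upon induction, synapse $i$ expresses LTD with probability
   $p_\mathrm{LTD}$ (default 0.70), independently of its covariates.
   Synapses that do not express LTD are never pruned — survivors of the
   TTX experiment show no residual depression, so non-LTD synapses must
   be unconditionally safe.
2. An LTD-expressing synapse survives with probability equal to its
   protection signal

   $$P_i = \mathrm{clamp}_{[0,1]}\!\Big[\, g \cdot \big( w_\mathrm{self}\,\sigma(a_i)
     + w_\mathrm{nbr}\,\sigma(\bar a_i)\,\mathbf{1}\{N_i \neq \emptyset\}
     + w_\mathrm{axon}\,\mathbf{1}\{\text{multi-contact axon}\} \big) \Big],
     \qquad \sigma(a) = \frac{a}{a + a_{1/2}},$$

   where $a_i$ is the synapse's own activity (a.u., synaptotagmin-uptake
   scale), $\bar a_i$ the mean activity of its neighbors within 5 μm,
   $N_i$ that neighbor set, and $g$ a global network-activity multiplier.
   It is pruned with probability $1 - P_i$.

The saturating $\sigma$ (rather than a linear activity term) bounds the
protection a single highly active synapse can accrue and encodes the
observation that a small subset of highly active synapses is essentially
immune to loss. The three weighted terms mirror the three experimentally
identified protective factors: own activity, neighborhood activity within
the 5-μm cooperation range, and shared-axon multi-contact wiring.

No functional form for protection is given in the source experiments;
this weighted saturating sum is the package's modelling choice, validated
only by reproducing the printed pruned fractions and the qualitative
orderings (below). That caveat should be kept in mind when interpreting
simulated covariate effects quantitatively.

### Condition presets

Pharmacological conditions act through $g$ and the weights
(`prune_conditions()`):

| condition | meaning | setting |
|---|---|---|
| `control` | normal network activity | $g = 1$ |
| `ttx` | action-potential block | $g = 0$ |
| `high_activity` | GABA-A block / 4 mM Ca²⁺ | $g = 8$ |
| `ampar_block` | AMPAR antagonist | $g = 0.55$ |
| `l_type_block` | L-type Ca²⁺ channel block | $w_\mathrm{self}, w_\mathrm{nbr} \times 0.7$ |

Under TTX the pruned fraction equals $p_\mathrm{LTD}$ exactly in
expectation — a closed-form anchor that fixes $p_\mathrm{LTD} = 0.70$
from the ~70% TTX loss. The AMPAR-block multiplier is the residual,
depolarization-independent fraction of the maintenance drive; it is not
identifiable a priori and is treated as a calibration parameter
(`g_ampar_block`, fitted value 0.55). The high-activity multiplier only
needs to be large enough to saturate protection for essentially every
synapse; the calibrated default is 8. L-type channel block scales the two
calcium-dependent terms rather than $g$, because the maintenance signal
is AMPAR-depolarization → L-type calcium entry: blocking the channel
removes the calcium-dependent protection while network activity per se
continues.

### Calibration

`calibrate_prune_model()` fits free parameters by exhaustive grid search
against target pruned fractions. Maps are generated once from fixed seeds
and held fixed across the grid; on each map the objective uses the exact
expectation of the pruned fraction over the Bernoulli draws,
$\frac{1}{n}\sum_i p_\mathrm{LTD}(1 - P_i)$, so the search is
deterministic and free of Monte-Carlo noise. The shipped defaults
($w_\mathrm{self} = 1.5$, $w_\mathrm{nbr} = 2.2$, $w_\mathrm{axon} = 0.2$,
$a_{1/2} = 9\times10^4$ a.u., $g_\mathrm{AMPAR} = 0.55$) come from such a
search against control = 30%, TTX = 70%, AMPAR block = 47% and
high activity = 0%, and were selected among statistically equivalent
optima for reproducing all three qualitative fate orderings (pruned
spines: lower activity, larger nearest-neighbor distance, higher
en-passant fraction). The large $a_{1/2}$ means $\sigma$ operates in its
near-linear range over the bulk of the activity distribution, which gives
the activity terms real discriminating power between spines.

## What the synthetic data emulate

**Spine maps** (`gen_spine_map()`). Positions are 1-D arclengths along
the dendrite, matching how inter-spine distances are measured at the
dendritic shaft; 2-D image coordinates are derived by laying the dendrite
along the image row. Spines arise from a Poisson cluster process plus an
isolated Poisson process. The defaults (600 μm, cluster rate 0.025/μm
with on average 4 spines per cluster spread 0.8 μm, isolated rate
0.08/μm) represent the visible-spine substrate of two-timepoint live
imaging — one map stands for the pooled dendrite portions of one neuron,
about 90 spines, with ~80% of spines having a nearest neighbor within
4 μm and ~18% spatially isolated beyond 5 μm. This is deliberately
sparser than fixed-immunostaining PSD-95 puncta (≈0.96/μm on 25-μm
segments), which the image generator emulates separately.

Activities are lognormal with mean 14,000 a.u. and CV 0.5, so that the
±2000/±1000 a.u. matched-control windows operate at a realistic scale.
Spines of a cluster share a latent activity factor (intra-class
correlation 0.65 on the log scale; marginals unchanged) — neighboring
synapses show coordinated activity. Axon wiring assigns each spine an
en-passant (single-contact) axon with marginal probability 0.35;
spatially isolated spines are proportionally more likely (×2.2, with the
clustered spines' probability lowered to preserve the marginal) to carry
a dedicated axon, reflecting that multi-bouton contacts form between an
axon and a run of neighboring spines.

**Puncta images** (`gen_puncta_image()`). Isotropic Gaussian spots
(σ = 1.5 px at 0.1 μm/px) on a constant background with white Gaussian
readout noise; density-placed puncta respect a 0.6-μm hard-core minimum
separation emulating the physical exclusion between spine heads.
Z-projection is emulated directly in 2-D; there is no 3-D stack, no
deconvolution and no spine-morphology classing.

**Current traces** (`gen_trace()`). Difference-of-exponentials unitary
events (τ_rise 1 ms, τ_decay 8 ms at 10 kHz) scaled to lognormal
amplitudes (mean 12 pA, matching pre-LTD mini amplitudes near 11.9 pA),
Poisson mini arrivals, and poly-synaptic bursts of 10 unitary events
jittered within 4 ms. The burst size is chosen so compound responses
carry mean currents above the 10^1.5 ≈ 32 pA boundary, reproducing the
empirically bimodal log₁₀(area/duration) distribution with the mono/poly
cutoff at 1.5. Noise is white Gaussian (the recordings' noise spectrum is
not characterized); series-resistance effects and rise-time kinetics
fitting are out of scope.

Passing tests on these fixtures demonstrate correctness of the
algorithms against known ground truth; they do not certify performance
on real microscopy or recordings, where backgrounds are structured,
noise is non-white, and spine identification is manual.

## Numerical and design choices

* **Thresholding**: Otsu's method on the within-mask histogram is the
  default (parameter-free, invariant to positive rescaling); an absolute
  `median + 4·MAD` rule is available. Touching puncta are split by
  watershed at intensity saddles deeper than 3× the masked MAD; spots
  without distinct maxima (e.g. 1 px apart) stay merged, and that
  behavior is documented rather than "fixed".
* **Coordinates**: pixel coordinates are 0-based; μm = (px + 0.5) ×
  pixel size (pixel-center convention).
* **Mini detection**: baseline level and SD are median/MAD over the
  leading window (robust to event contamination); detection runs on a
  1-ms moving average, which suppresses single-sample noise excursions
  (at 3·SD a raw-sample rule would fire constantly at 10 kHz), and peak
  amplitudes are read from the same smoothed trace because a raw
  single-sample peak is biased upward by the noise maximum. Events
  closer than one decay constant (8 ms) are merged; the merge window is
  a parameter because no value is prescribed experimentally.
* **Durations** are threshold-to-threshold at k·SD, tie-broken to the
  earlier sample; `event_statistic()` refuses non-positive areas or
  durations rather than returning infinities.
* **Boundary rule**: s = 1.5 exactly classifies as poly (the mono class
  is defined by strict `<`).
* **Tracking**: greedy one-to-one nearest-position matching within
  0.5 μm, ties toward the lower spine ID; a spine displaced beyond the
  tolerance is deliberately counted pruned-plus-new.
* **Cluster radius**: the neighbor-count analyses are reported at both
  5 μm (the "vicinity" radius) and 20 μm (the cluster radius named in
  the running text of the source experiments); the two source statements
  conflict, so both columns are always computed.
* **Matched-control windows**: the activity window (±2000 a.u.) is
  centered on the mean of the pruned spines that enter the neighbor
  comparison (those with a neighbor within 5 μm), which makes the
  selection idempotent.
* **Normality**: the D'Agostino–Pearson omnibus K² is implemented from
  the standard skewness/kurtosis transforms and requires n ≥ 8; smaller
  samples are flagged untested rather than silently passed, and an
  untested group alone does not force the rank-based path.
* **Two-group default**: Welch correction (equal variances are never
  assumed).
* **Seeds**: every stochastic function takes an explicit seed; nothing
  uses global random state implicitly.

## Problem sizes used in the shipped checks

The package's own test battery runs at desk scale: condition panels use
20 replicate maps (~100 spines each for the headline fractions, ~2000
spines per map for the calibration check), detector performance uses
30–60-s traces at 10 kHz and 64×250-px images, the type-I-error
simulation uses 2000 replicates, and the fate-ordering check uses 50
replicate experiments each pooling a cohort of 5 simulated neurons —
the orderings are population statements about an experiment's pooled
spines, not about single ~90-spine segments, whose small pruned samples
make mean comparisons noisier than anything reported at the bench.

## Known limitations

* The protection function is phenomenological; only its reproduced
  fractions and orderings are validated, not its form.
* LTD expression is independent of covariates; any real correlation
  between depression depth and activity is not modelled.
* Neighbor relations are same-dendrite only and 1-D; inter-dendrite
  interactions and branch geometry are out of scope.
* The simulator has no re-potentiation/recovery dynamics and no
  biophysical calcium handling — the outcome is a binary fate.
* The synaptotagmin-uptake background-subtraction scheme is exposed as a
  parameter (`background`) rather than fixed, since no scheme is
  prescribed; ROI intensities are clamped at zero and flagged.
* d-STORM single-molecule counting is consumed as tabular input
  elsewhere and is not recomputed here.
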