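---
title: "Methods: biophysical modelling and circular analysis of CA1 theta phase-locking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: biophysical modelling and circular analysis of CA1 theta phase-locking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`ca1theta` models how CA1 pyramidal cells time their spikes relative to the
hippocampal theta rhythm (4-12 Hz), and how that timing depends on the cell's
morphology, its intrinsic conductances, and the balance of its synaptic input
pathways -- in particular the complementary perisomatic inhibition that PV+
and CCK+ basket cells deliver to deep versus superficial pyramidal cells. The
package contains a compartmental Hodgkin-Huxley simulator driven by
theta-modulated pathway inputs, a genetic algorithm that fits conductance
multipliers to target response features, the in-silico sublayer and
interneuron manipulation experiments, and the downstream analysis stack:
circular phase statistics with surrogate nulls, unsupervised classification
of theta cycles by their nested spectral components, a rank-order test for
repeating multi-unit sequences, and a multinomial regression attributing
phase preference to cell features. Synthetic-data generators stand in for
recordings and reconstructions, so every stage is testable offline.

# The cell model

## Compartments and passive rules

A morphology is a tree of cylindrical compartments (soma, basal dendrites,
apical trunk, apical/tuft branches) with path distance `z` measured along
the tree from the soma centroid. Passive membrane properties follow fixed
rules:

* axial resistivity 100 Ohm cm, scaled by its GA factor;
* specific capacitance 5 uF/cm2 at the soma and `1.8 x 5 x SS` elsewhere,
  where the spine factor `SS` accounts for the membrane area of dendritic
  spines (2.51 for basal dendrites; a decision table on thickness and
  distance for apical dendrites, see `spine_correction()`);
* leak conductance given by a sigmoid of somatodendritic distance,
  `g_pas(z) = 0.001 / (80 + (0.4 - 80)/(1 + exp((225 - z)/30)))` S/cm2,
  multiplied by `SS` outside the soma. This makes the distal membrane very
  leaky (`Rm` falls from 80 to 0.4 kOhm cm2), which dominates how far tuft
  input can spread.

The diameter thresholds of the spine table are half-open intervals closed on
the lower bound, and `z = 350` um exactly follows the proximal rule; the
source material leaves both boundaries undefined, so a deterministic
convention was chosen.

## Channels: 18 state equations per compartment

Each compartment integrates membrane potential, an intracellular calcium
pool, and 16 gating states -- 18 coupled equations in total. The allocation
is: Na with four states (fast activation m, fast inactivation h and two slow
inactivation states), delayed rectifier with activation plus slow
inactivation, A-type K (a, b), M-type K, fast Ca- and voltage-dependent K
(two states), slow AHP K, L-type Ca (activation plus Ca-dependent
inactivation), and HCN split into fast and slow components. The published
total (18) does not come with a printed per-channel breakdown, so this
allocation is a documented convention; all rate-function parameters
(`default_kinetics()`) are plain Boltzmann half-voltages, slopes and time
constants that can be replaced wholesale with values from an archived model.

Maximal conductances follow linear-in-z profiles (`default_gmax_profiles()`):
Na and KDR concentrate perisomatically so that spikes initiate near the
soma (this is what lets perisomatic inhibition gate the output), while
A-type K, HCN and L-type Ca increase with distance; the rising CaL profile
provides the dendritic amplification of distal (entorhinal) input that, in
the modelled cell class, would otherwise involve NMDA receptors -- which are
deliberately excluded.

## Numerical integration

The integrator uses operator splitting at fixed `dt`: gating states advance
by exponential Euler against the current voltage; the voltage step is a
backward (implicit) Euler solve of the cable equation, performed directly on
the tree with a Hines-ordered elimination, so the scheme is unconditionally
stable. Boltzmann steady states come from a voltage lookup table
(0.05 mV resolution, linear interpolation). Synapses are double-exponential
conductances advanced analytically by two decay states per
(compartment x kinetics) group; each presynaptic event increments both
states by a weight normalized so a single event peaks exactly at its
`gmax`. Integration aborts with a diagnostic if any |V| exceeds 200 mV.

The default step is `dt = 0.025` ms. Population experiments run at 0.05 ms:
the contract is the convergence test (halving `dt` changes the terminal
potential by far less than 0.1 mV), not the step size itself. Spike
detection high-passes the somatic trace above 300 Hz (zero-phase FIR),
takes suprathreshold excursions of the raw potential (threshold 0 mV) that
carry high-frequency energy, and merges events within a 2 ms refractory
window.

# Synaptic pathways and theta drive

Twelve input populations are modelled (CA3, CA2, ECIII, ECII glutamatergic;
axo-axonic, bistratified, CCK and PV basket, Ivy, neurogliaform, OLM and
Schaffer-associated GABAergic). For each pathway `default_pathways()` fixes
a target band in signed somatodendritic distance, bouton count, kinetics,
peak conductance, presynaptic rate, preferred theta phase and a
Beta-function phase dispersion. Event times are sampled per cycle (Poisson
counts at `rate/theta_freq`) with phases drawn from a Beta(b1, b2) law
mapped onto the full cycle around the pathway's preferred phase.

Phase convention: the theta reference is a sinusoid with the trough at
0/360 degrees and the peak at 180; the wave therefore rises over (0, 180)
and falls over (180, 360). Pathway phases follow the physiology of the
modelled circuit: CA3/CA2/ECII drive near the trough, ECIII at the peak,
CCK basket cells at the peak, PV basket cells on the falling phase
(default 250 degrees), OLM and bistratified cells near the trough.

The per-pathway table is a stand-in for unavailable experimental
parameterizations, with three deliberate choices:

* Bouton counts are desk-scale (tens to ~1200), so per-contact conductances
  are *effective* values absorbing the much larger real synapse numbers;
  the distal ECIII conductance additionally absorbs the dendritic
  amplification lost by excluding NMDA.
* CA3 (Schaffer) synapses target the apical-trunk band (50-350 um), the
  stratum-radiatum territory, rather than the perisomatic/basal region;
  placing them perisomatically makes trough drive insensitive to the
  basket-cell manipulations and erases the deep/superficial contrast.
* Values were calibrated once so that default synthetic cells fire within
  the realistic 0.01-8 Hz band and both glutamatergic windows (trough-CA3,
  peak-ECIII) can drive spiking -- the regime the modelled experiments
  describe -- and are not adjusted per experiment.

`apply_manipulation()` rescales bouton counts (rounded half-up) or
presynaptic rates; the sublayer profiles are deep = 30% CCK / 100% PV and
superficial = 100% CCK / 30% PV on the perisomatic boutons, and full PV
removal is the rate-mode fraction 0.

# GA fitting

`evolve()` implements the generational scheme: individuals are vectors of
dimensionless GA factors (one per conductance class plus the axial
resistivity), scored by an integer error = number of measured response
features outside their acceptance intervals (boundaries count as inside;
diverging simulations are invalid). Successful individuals survive with
probability 0.4, unsuccessful ones with 0.2, vacancies are refilled
uniformly within bounds, and 40% of individuals then have exactly one
randomly chosen factor redrawn. The survival probabilities are interpreted
per individual; a per-value variant sits behind the `per_value` flag because
the source phrasing is ambiguous. Default runs last 100 generations with a
population of 64 (population size is a convention). The intrinsic feature
set is resting potential, input resistance, sag ratio, step spike count and
spike peak from somatic current steps; `cross_morphology_validate()`
re-scores sampled error-0 individuals on every morphology and replaces
failures from the pool.

# Circular statistics

Spike phases use the trough-0/peak-180 convention throughout; simulations
read phases off the sinusoidal reference, LFP analyses off the detected
cycle boundaries. `mean_vector()`, `rayleigh_test()` (with the standard
finite-sample series correction), `watson_williams()` and
`harrison_kanji()` follow the classical circular-ANOVA formulas, with the
high-concentration F table used when the pooled kappa exceeds 2 and the
chi-squared approximation otherwise. Both ANOVAs are mildly conservative
for very small samples; their type-I calibration in the test suite uses 20+
observations per group/cell, the regime the approximations are designed
for.

The trough-peak index is `TP = (n_trough - n_peak)/n` with trough window
[270, 360) + [0, 90) and peak window [90, 270) -- bounded in [-1, 1],
antisymmetric under a half-cycle shift, positive for trough-preferring
(superficial-like) and negative for peak-preferring (deep-like) firing. The
formula is a convention (no closed form is published) and is kept in one
place so it can be replaced.

The surrogate modulation test randomizes the cell's firing rate across
cycles: per-cycle spike counts are permuted over cycle identities and spike
phases are redrawn uniformly within each cycle (default), or resampled from
the cell's own pooled phases (`permute_counts`, which preserves the phase
marginal and is therefore conservative for R -- it isolates pure
rate-structure effects). Significance compares the observed mean vector
length with the 95th percentile of 1000 surrogates.

# Theta-cycle classification

`detect_theta_cycles()` band-filters at 4-12 Hz with a forward-backward FIR
(zero phase), finds troughs, and validates them by flanking peaks of at
least half the trough magnitude within 0.6 spectral periods, plus a
scale-invariant amplitude floor (half the raw signal's SD) that rejects the
pseudo-oscillations any narrowband filter produces from broadband noise.
Cycles run trough-to-trough and must have 4-12 Hz instantaneous frequency.

Classification embeds each cycle by PCA retaining >90% variance and
clusters with an online-trained self-organizing map whose codebook is
grouped by hierarchical clustering; the cluster count minimizes the
Davies-Bouldin index over a candidate range, with a degenerate single-
cluster guard when no partition reaches an acceptable index. By default the
PCA operates on each cycle's wavelet time-frequency signature (Morlet,
10-100 Hz log-spaced, 16 coarse time bins, log power) rather than on raw
samples: nested bursts are phase-coupled to theta with cycle-to-cycle
jitter of a few milliseconds, which decorrelates 50-90 Hz bursts at the
sample level while leaving their spectral signatures intact. The raw-sample
embedding remains available (`features = "waveform"`).

Cluster labels come from the wavelet map of each cluster's mean waveform
after regressing out the theta fundamental: dominant residual energy below
20 Hz at the peak is tSC1, 30-40 Hz on the falling phase tSC2, 50-60 Hz at
the peak tSC3, 70-90 Hz at the peak tSC4; anything else stays unlabeled.

# Rank-order test

Within each included cycle (at least four participating units), the first
spike of each unit is ranked and normalized to [0, 1]. A cycle's statistic
is the number of other cycles whose rank vectors correlate above 0.8
(Pearson, over at least four shared units); its null is built from 500
within-cycle order shuffles. Because the count statistic is a small integer
with heavy ties under the shuffle null, the per-cycle p-value uses the
mid-p rule; without it the realized size sits near 1% instead of the
nominal 5%. A mean-correlation statistic is available behind a flag.

# Determinants of phase preference

`fit_multinomial()` regresses the 30-degree-binned preferred phase of a
population of synthetic cells on standardized features with a multinomial
logistic model (quasi-Newton optimizer) under a ridge penalty
(`decay = 0.1`): the 12-bin x ~95-feature model is near-saturated at the
reference scale (731 cells), and the analysis family this follows
regularizes by default. Coefficients are re-expressed under the sum-to-zero
softmax normalization as a full 12 x p phase-bin map.

Feature significance is the Mardia circular-linear correlation between the
feature and the per-cell preferred phase (`n R^2` against chi-squared with
2 df). An earlier design -- permuting each feature's 12 bin coefficients --
cannot resolve the required p < 0.001: twelve exchangeable values floor the
permutation p near 1/n_perm and adjacent dominant weights recur by chance.
The per-cell correlation has full resolution and a clean null; the
positive-coefficient resultant is retained as the descriptive phase
attribution of each significant feature.

Per-bin variance explained is permutation importance on the multinomial
deviance: each feature's column is permuted (8 draws averaged) and the
per-bin deviance increase is expressed as a fraction of the permuted-model
deviance in that bin. A feature-direction (up = positive coefficients,
down = negative) is a selected contributor when this fraction reaches 20%
in at least three consecutive bins (circular adjacency) where the direction
is active, among features passing significance.

# Synthetic data: what it emulates, and what it does not

The LFP generator produces a `-cos` theta carrier with per-cycle
Gaussian-windowed bursts at the four tSC signatures over 1/f noise; spike
generators draw per-cycle Poisson counts with von Mises phases (kappa = 0
uniform); the feature-table generator plants effects as phase shifts linear
in standard-normal features with von Mises response noise (kappa = 16,
shifts of a few tens of degrees per SD -- strong but unaliased effects;
shifts approaching 90 degrees/SD wrap the response around the circle and
destroy identifiability for any phase-binned model). Every generator is a
pure function of its seed.

These generators emulate stationary theta with fixed class proportions,
unimodal per-unit locking, and independent Gaussian features. Real
recordings have non-stationary theta frequency and amplitude, correlated
features, asymmetric cycle waveforms, movement artifacts, and spike-sorting
errors; passing the planted-recovery tests shows that each analysis is
implemented correctly and calibrated under its own assumptions, not that it
is robust to all of those complications.

# Problem sizes

Tests and the acceptance script run desk-scale versions of the reference
protocol by choice: morphologies of 40-60 compartments (configurable to the
200-300 of full reconstructions), panels of 8 synthetic cells at 200 theta
cycles (the reference protocol is 1000 cycles per cell), GA populations of
24 with early stopping for recovery checks, 2000-replicate nulls for the
calibration checks, and the full 731 x 95 scale for the regression
analysis. The qualitative contrasts these sizes support -- the sign of the
deep/superficial TP separation, the direction of the PV-removal shift,
planted-structure recovery -- are the quantities asserted.

# Known limitations

* Gating kinetics, synaptic parameter tables and GA acceptance intervals
  are literature-informed conventions, not fitted reproductions of an
  archived model; absolute firing rates and phase values should be read as
  qualitative.
* No NMDA receptors, no short-term plasticity, no presynaptic network
  dynamics (inputs are inhomogeneous point processes), no temperature
  dependence, and no full-network simulation.
* The Watson-Williams and Harrison-Kanji approximations degrade for very
  small or very dispersed samples; the package warns when the pooled
  resultant is low.
* The TP index formula, the surrogate construction, and the per-bin
  variance-explained definition are documented conventions standing in for
  unpublished details; each is isolated behind one function so alternative
  readings can be swapped in.
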