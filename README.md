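# ca1theta

Biophysical modelling and circular analysis of theta phase-locking in CA1
pyramidal cells.

Hippocampal CA1 pyramidal cells fire at preferred phases of the 4–12 Hz
theta rhythm, and the population splits into trough-preferring
(superficial-sublayer-like) and peak-preferring (deep-sublayer-like) cells.
`ca1theta` is a research compendium for studying the mechanisms behind that
bimodality in silico: it combines a multicompartment Hodgkin–Huxley cell
simulator with theta-modulated synaptic input pathways, genetic-algorithm
conductance fitting, the sublayer/interneuron manipulation experiments, and
the statistical machinery used to analyze phase-locking in both simulated
and recorded data. It is aimed at computational neuroscientists and
electrophysiologists who want a self-contained, testable implementation of
this analysis stack in R.

## What is inside

**Cell model.** Compartmental morphologies (generated binary trees or SWC
reconstructions) with the passive rules of the modelled cell class: axial
resistivity 100 Ω·cm, somatic capacitance 5 µF/cm², dendritic capacitance
`1.8 × 5 × SS` with per-compartment spine factors, and a sigmoidal leak
profile `g_pas(z) = 0.001 / (80 + (0.4 − 80)/(1 + e^{(225−z)/30}))` S/cm².
Nine conductances plus an intracellular calcium pool give 18 coupled state
equations per compartment (`I = g(V,t)·(V − V_rev)` for every current, with
`g = Gmax · GA_factor`). Integration is backward-Euler on the dendritic
tree (Hines solve) with exponential-Euler gating, in C++.

**Inputs and experiments.** Twelve pathway populations (CA3, CA2, ECIII,
ECII and eight interneuron classes) with Beta-distributed theta phase
tuning; event-driven double-exponential synapses; manipulation operators
for bouton-count or rate scaling. The sublayer profiles (deep = 30 % CCK /
100 % PV perisomatic boutons, superficial = 100 % CCK / 30 % PV), full PV
removal, and glutamatergic input scans reproduce the package's core
in-silico experiments.

**Analysis stack.** Mean vector length and Rayleigh test, trough–peak (TP)
index, Watson–Williams and Harrison–Kanji circular ANOVAs, a 1000-surrogate
modulation test, theta-cycle detection (zero-phase FIR, trough validation),
PCA + self-organizing-map classification of cycles into theta-nested
spectral components (tSC1–4) with Davies–Bouldin model selection, a
500-shuffle rank-order sequence test, and a multinomial logistic-regression
analysis attributing 30°-binned phase preference to ~95 morphological,
intrinsic and synaptic features.

**Synthetic data.** Seed-deterministic generators for LFP with planted
theta/tSC structure, von Mises phase-locked spike trains, and feature
tables with planted feature→phase effects, so the full pipeline runs and is
tested without any recordings.

## Worked example

```r
library(ca1theta)

# a panel of synthetic cells: generated morphologies plus jittered
# intrinsic GA factors
cells <- build_cell_panel(n_cells = 4, seed = 2)
print(cells[[1]]$morphology)
#> CA1 pyramidal-cell morphology
#>   compartments: 45 (total length 1341 um)
#>   terminal branches: 4 basal, 6 apical (10 total)
#>   max path distance: 602 um

# one cell, 200 theta cycles under the deep perisomatic profile
run <- run_theta(cells[[1]],
                 experiment_config(n_cycles = 200, profile = "deep",
                                   seed = 11001))
print(run)
#> theta_run: 108 spikes over 200 cycles (4.32 Hz)
#>   R = 0.91, preferred phase = 125 deg, TP = -0.87

# deep vs superficial profiles across the panel
ex <- sublayer_experiment(cells, n_cycles = 200, seed = 11)
print(round(ex$tp, 2))
#>   cell  deep superficial
#> 1    1 -1.00       -0.41
#> 2    2 -0.50        0.22
#> 3    3 -0.65        0.21
#> 4    4 -0.44        0.47
```

The cell fires at 4.3 Hz (within the realistic 0.01–8 Hz band), is strongly
phase-locked (mean vector length R = 0.91), and under the deep profile
prefers the theta peak (TP = −0.87; the TP index is +1 for pure trough
firing and −1 for pure peak firing). Across the panel, the deep profile
pushes every cell toward peak firing and the superficial profile toward the
trough — the sublayer contrast the modelled experiments demonstrate; with 8
cells the paired permutation test on this contrast is significant
(p < 0.05).

The methods vignette (`vignettes/ca1-theta-methods.Rmd`) documents the
model, the conventions (TP index, surrogate construction, tSC labeling),
the numerical choices and the generators' limitations.

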