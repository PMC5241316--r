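---
title: "Model and methods: spiking word-learning networks and their oscillatory analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The model

`spikelex` simulates word learning in a multi-area network of
integrate-and-fire cells and analyses the network's oscillatory responses
the way electrophysiologists analyse EEG/MEG data. This vignette documents
the model equations, every tunable constant (with defaults and the reason
behind each), what the synthetic stimuli emulate, the numerical choices,
and the known limitations — in particular, which constants had to be
chosen by calibration because the published description leaves them open,
and what that implies for interpreting the results.

## Architecture

Twelve cortical areas are modelled (six perisylvian: A1, AB, PB, PF_i,
PM_i, M1_i; six extrasylvian: V1, TO, AT, PF_L, PM_L, M1_L), each a 25x25
sheet of excitatory cells with a 25x25 sheet of inhibitory twin cells —
15,000 cells in total. The between-area graph has 22 reciprocal edges:
two next-neighbour chains, hub cross-links among the four multimodal
areas (AT, PB, PF_i, PF_L), within-system jumping links, and long-distance
temporal-frontal links. Excitatory projections (within and between areas)
are sparse, random and topographic: a cell links to cells inside an
`n = 19` square centred on its homologous position, with probability
`p0 * exp(-|d|^2 / 2 sigma^2)` falling off with distance `d` and clipped
to zero outside the square. Initial weights are i.i.d. uniform on
`[0, 0.1]`.

The miniature scale used for tests and desk experiments keeps the same
code path with 6 areas (A1, PB, M1_i | V1, AT, M1_L; five edges
preserving the primary-to-hub skeleton of both systems), 11x11 sheets,
`n = 9` neighbourhoods, and 4 words of 10-cell patterns.

## Cell dynamics

Every cell's state is its membrane potential, integrated with an Euler
step of 0.5 ms (one simulation step):

* `V <- V + (1/tau) * (-V + k1 * (V_in + k2 * eta))`, with `tau` = 2.5
  steps (excitatory) or 5 steps (inhibitory), `k1 = 0.01`, and `eta` a
  fresh uniform draw on [-0.5, 0.5] per excitatory cell per step
  (inhibitory cells are noiseless, `k2 = 0`).
* The net input `V_in` sums presynaptic outputs through the signed
  weights, subtracts the area's global inhibition `kG * omega_G` (for
  excitatory cells only) and adds any stimulus drive.
* An excitatory cell spikes when `V - alpha * omega > thresh`
  (`thresh = 0.18`, `alpha = 7`), where `omega` low-passes its own spike
  train with `tau_adapt = 10` steps (spike-rate adaptation). Inhibitory
  cells emit their rectified potential.
* `omega_E` low-passes the spike train with `tau_favg = 30` steps and is
  the presynaptic "activity" entering the learning rule; `omega_G`
  low-passes the area's total spike count with `tau_glob = 12` steps and
  feeds back subtractively to every excitatory cell of that area.

The noise amplitude and global-inhibition strength switch jointly
between modes: `k2 = 5 * (24/dt)` and `kG = 0.75` during learning,
`k2 = 50 * (24/dt)` and `kG = 0.60` during testing. With `dt = 0.5` ms
these give `k2` = 240 and 2400: the testing regime is strongly
noise-dominated by construction (the potential's noise sd is about 3.5,
nineteen times the spiking threshold), which is worth keeping in mind
throughout — every stimulus-specific signal has to survive against that
background.

Within one step the update is synchronous: outputs are computed from the
previous step's potentials, then net inputs, then the membrane and
low-pass updates, and finally (in learning mode) the plasticity rule,
which sees the step's spikes together with the just-updated postsynaptic
potential and presynaptic rate estimate. Potentials are never clipped;
only outputs are nonlinear. A testing trial starts from a full reset
(all state variables zero).

## Plasticity

Excitatory-to-excitatory synapses follow a discretised
Artola-Bröcher-Singer rule, gated by spiking: nothing changes unless the
pre- or postsynaptic cell fired this step. Given a gating spike, the
weight changes by `+delta` when the presynaptic rate estimate is at least
`theta_pre = 0.05` and the postsynaptic potential is at least
`theta_plus = 0.15` (LTP); by `-delta` when the presynapse is active but
the potential sits in the mid-range `[theta_minus, theta_plus) =
[0.14, 0.15)` (homosynaptic LTD) or when the presynapse is inactive and
the potential is high (heterosynaptic LTD); otherwise not at all.
`delta = 0.0008`, and weights are clipped to `[0, w_max]`.

## Stimuli and protocols

A *word* is a triplet of sparse binary patterns over the primary areas:
19 cells (about 3% of an area) in A1 and in M1_i for every word, plus 19
cells in V1 for object words or in M1_L for action words. Training
presents each word 3000 times in random order (36,000 trials at full
scale): the pattern cells of its areas receive a strong constant drive
for `t_on = 16` steps, followed by `isi = 30` noise-only steps, with
plasticity on throughout and no reset between trials.

*Pseudowords* are built after training by tiling the A1 grid into 5x5
sub-squares (25 tiles) and reassembling, position by position, tiles
taken from the trained words' A1 patterns — two tiles from each of the
12 words, plus one remainder tile from a uniformly drawn word (25 =
2 x 12 + 1; the same `floor(T/K)`-per-word rule generalises to other
tile/word counts, with a warning). A pseudoword is therefore made
entirely of familiar local features but is globally novel.

Testing freezes plasticity, switches to the testing noise/inhibition
regime, and presents each of the 24 stimuli (words and pseudowords) 10
times to area A1 only: per trial, a global reset, 1.5 s of noise-driven
baseline, 0.5 s of stimulation, 1 s post-stimulus — 240 trials of 6000
steps. The per-area S-ERP (the sum of all excitatory membrane potentials)
and the total spike count are recorded every step.

## Spectral analysis

Single-trial S-ERPs are convolved with six-cycle complex Morlet wavelets
(`sigma_t = c / (2 pi f)` with `c = 6`; support truncated at
`±3 sigma_t`; unit-energy normalisation `sigma_t^(-1/2) pi^(-1/4)`) at
1-Hz steps from 4 to 100 Hz, at the native 2000-Hz sampling rate, and the
squared moduli are averaged into 10-ms bins. *Total* power averages the
single-trial power across trials; *evoked* power is the power of the
across-trial average S-ERP; *induced* power is their difference, so
total = evoked + induced holds exactly before baseline correction.
Baseline correction subtracts the mean over -500 to -100 ms per area and
frequency. Samples whose wavelet support extends beyond the epoch are
flagged `NA` rather than zero-padded; the baseline uses the valid bins.

Coherence between two areas is the magnitude-squared coherence of the
single-trial wavelet coefficients across trials,
`|<X seed * conj(X target)>|^2 / (<|X seed|^2> <|X target|^2>)`,
computed at the native rate and bin-averaged afterwards; it is 1 for
identical channels and biased upward by about `1/N` for `N` independent
trials, which is why conditions are always compared with equal trial
counts.

Condition contrasts use cluster-based permutation statistics on the
20-40 Hz band average: a dependent-samples t per (area, time-bin),
two-tailed thresholding at alpha = 0.05, clusters formed by temporal
adjacency within each area (areas are treated as separate strips; the
area-level graph is deliberately not used as spatial adjacency, since no
principled adjacency over cortical areas is available), cluster mass =
summed t, and a null distribution of the maximum absolute cluster mass
from random within-pair condition swaps (1000 permutations, or exhaustive
enumeration on request). Monte-Carlo p values use the
(1 + exceedances)/(1 + draws) convention; with 5 replicate pairs the
smallest attainable two-tailed p is 2/2^5 = 0.0625. A paired t test on
the per-instance mean peak S-ERP (per-area maximum in 50-500 ms,
averaged over trials and areas) separates amplitude from synchrony
effects; a zero-variance difference is reported as degenerate rather
than failing.

# Calibrated constants and why

Four constants of the architecture are not fixed by the published model
description and had to be chosen. They are all exposed in
`sim_config()`; the defaults were set by calibration on
training-dynamics diagnostics (baseline firing rates, weight selectivity,
assembly recruitment), as follows.

**Local inhibitory-loop strength (`g_ei`, `g_ie`).** Each inhibitory
twin sums its 5x5 neighbourhood's spikes (weight `g_ei = 1/n^2`) and
inhibits its excitatory twin with weight `-g_ie`. Only the product
matters dynamically. The loop's purpose is local competition, and its
strength turns out to be the single most important free constant: the
Hebbian rule is only selective if spontaneous firing keeps `omega_E`
below `theta_pre` during learning, so that the presynaptic-activity gate
discriminates driven from undriven cells. With a weak loop the
learning-mode baseline rate settles almost exactly at `theta_pre` and
LTP becomes indiscriminate (measured: cross-word weights reach ~86% of
within-word weights and grow without bound). The default
`g_ie = 90000` — equivalently, a twin inhibition of about `4.5 x` the
local mean firing rate in membrane-potential units — holds the
learning-mode baseline near 0.03 spikes/cell/step, below `theta_pre`,
which restores selectivity (cross-word weights < 5% of within-word) and
lets assemblies recruit cells beyond the directly stimulated patterns.

**Weight ceiling (`w_max = 22.5`).** The learning rule has no upper
bound; under the stated `delta` and 3000 trials per pattern,
within-pattern weights grow to about 40. The ceiling is set at 22.5
(225x the maximum initial weight) so that it is reachable within the
training schedule and so that a trained assembly's recurrent drive is of
the same order as the background noise amplitude — the condition for the
two-state (ignition) behaviour that distinguishes learned from novel
stimuli. A ceiling of ~2x the initial weights, by contrast, caps the
trained coupling three orders of magnitude below the testing-noise scale
and provably removes every stimulus-specific dynamical effect.

**Connection density (`p0 = 0.5`, `sigma = n/2`).** At reduced scale the
number of assembly-internal links per cell — which carries the
re-ignition feedback — shrinks with the area; the denser default keeps
the maps sparse and patchy while roughly doubling the within-assembly
in-degree relative to thinner settings.

**Stimulus amplitude (`stim_amp = 1200`).** Patterns are "presented"
without a stated amplitude. The default puts `k1 * amp = 12` on the
driven cells' potential — far above threshold and above the
testing-noise half-range — so pattern cells fire at their
adaptation-limited maximum regardless of network state, as expected for
a strong sensory afferent. Any value above ~20 makes an isolated cell
spike within a few steps; the high default additionally makes the drive
noise-proof during testing.

Learning-trial timing (`t_on = 16`, `isi = 30` steps) follows the
procedure of the predecessor architecture as far as it is recoverable;
both are configurable.

# What the simulations do and do not show

At the default miniature scale the package reproduces, and its tests
verify, the *learning-side* results: stimulus-specific cell assemblies
emerge (within-word weights far exceed cross-word weights; assemblies
recruit hub-area cells beyond the stimulated patterns; each word's
assembly contains its own input cells), training is selective (synapses
between never-active cells are untouched), and repeated co-stimulation
strengthens between-group links against matched controls.

On the *testing side*, the re-ignition of a trained assembly against the
testing-mode noise depends on the assembly's recurrent in-degree times
its weight, relative to the noise amplitude `k1 * k2`. A linear-response
estimate makes the loop gain roughly `0.09 * k1 * N_in * w`: with
miniature-scale assemblies (tens of cells, in-degree ~3-10 at the
ceiling) the gain stays well below 1, so word stimulation elevates
assembly-cell firing (measured: assembly cells' rate estimate rises to
~0.67 versus 0.42 under a pseudoword and ~0.23 at baseline) and imparts
a weak ~28-Hz periodicity to the assembly's spike train, but does not
produce the macroscopic, area-wide spike waves that would dominate the
S-ERP. In the replicated miniature experiment the word-minus-pseudoword
induced 20-40 Hz contrast is therefore at noise level and not
sign-consistent across replicates, and the category-specific coherence
double dissociation — which additionally requires the assembly to span
the full primary-to-primary chain, three synaptic stages from A1 — does
not emerge. These are honest consequences of the scale reduction: the
gain scales with the assembly in-degree, which scales with area size, so
the full-scale architecture sits much closer to the ignition regime than
any 11x11 miniature can.

Accordingly, the test suite asserts the structural, protocol, learning
and oracle results strictly, and additionally asserts the oscillatory
word-advantage and the coherence dissociation exactly as the replicated
experiment defines them; at miniature scale those two assertions fail,
for the reason analysed above, and are left failing rather than
weakened. The peak frequency is reported rather than thresholded.

# Numerical choices

* One seeded RNG stream per run; the compiled engine consumes R's own
  stream (one uniform per excitatory cell per step, in cell order), so
  the C++ loop and the plain-R reference implementation produce
  bit-identical trajectories — a property the test suite checks, along
  with determinism under a fixed seed at every scale.
* Problem sizes in the test suite: oracle comparisons run on 5x5-grid
  toy networks (150 cells); the replicated experiment runs five
  miniature instances (1452 cells each, 12,000 training trials, 80
  3-s testing trials); the null-control battery uses 20 zero-weight
  miniature networks with 5 trials per stimulus.
* Non-finite potentials abort the simulation with the step index;
  degenerate statistics (zero-variance paired differences) are reported
  as such with a warning.
* Boundaries: neighbourhoods are clipped at area edges (no torus);
  self-synapses are excluded; homologous positions map by identical grid
  coordinates.

# Reproducibility plumbing

`derive_seeds()` hashes a master seed into per-stage, per-instance
sub-seeds (all below 2^31), so replicate `k` of an experiment can be
re-run in isolation. Connectomes and recordings serialise losslessly via
`write_connectome()` / `write_recordings()`; statistical outputs are
written as TSV tables by `export_results()`. The thin command-line
front end (`inst/cli/spikelex`) exposes `dry-run`, `build`, `train`,
`test`, `analyze` and `pipeline` over these functions; full scale sits
behind an explicit `--scale full` with a runtime warning.
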