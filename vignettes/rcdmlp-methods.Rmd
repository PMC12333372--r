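---
title: "Range-corrected Delta-MLPs: models, training, and free-energy analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Range-corrected Delta-MLPs: models, training, and free-energy analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Hybrid QM/MM free-energy simulations of reactions such as phosphoryl
transfer are limited by the cost of the target level of theory: an ab
initio QM/MM potential is orders of magnitude more expensive than a
semiempirical one, yet the semiempirical surface can be qualitatively
wrong — in the reactions this package's surrogate emulates, the cheap
base potential shows a single barrier along the phosphoryl-transfer
coordinate while the target shows a metastable pentacoordinate
intermediate flanked by two barriers.

A Delta machine learning potential (Delta-MLP) bridges the gap: a neural
correction trained to reproduce the *difference* between target and base
energies and forces, added on top of the base potential during sampling.
`rcdmlp` implements the full desk-scale stack: the range-corrected graph
topology, two correction-model architectures, committee training with
iterative data selection, a synthetic two-basin reaction surrogate with
Langevin umbrella sampling, and the free-energy machinery (MBAR, wTP,
gwTP, reweighting entropy, density-of-states smoothing) needed to carry
sampling from the corrected potential to the target surface.

# Range correction

The correction must not perturb the MM subsystem on its own: as solvent
molecules diffuse across any finite interaction cutoff, the total energy
must stay continuous, and MM-MM physics is already handled by the base
force field.  Three structural rules enforce this:

* **graph restriction** — edges exist only for atom pairs within the
  radial cutoff (6 A by default) that contain at least one QM atom;
  MM-MM pairs never enter the graph (`build_edges()`);
* **species remapping** — MM atoms are coded as atomic number + 50
  (`map_species()`), so an MM oxygen (code 58) can carry network
  parameters distinct from a QM oxygen (code 8);
* **zero MM biases** — the per-species energy offsets that persist for
  isolated atoms are structurally pinned to zero for all MM codes, so an
  MM atom leaving the last QM cutoff contributes exactly nothing.

Every distance-dependent feature is built from Bessel radial functions
under a polynomial envelope of order 5 (`radial_features()`), which takes
the features and their first derivatives smoothly to zero at the cutoff.
The acceptance tests scan an MM atom across the cutoff in 1e-4 A steps
and require energy continuity at the 1e-8 eV level.

# Correction-model architectures

Two architectures share one contract (`init_model()`, `site_energies()`,
`delta_energy_forces()`): total energy is a sum of atomic site energies
over the restricted graph, forces are exact analytic gradients, and both
obey the range-correction rules above.

**MACE-like many-body model.**  Per layer, an atomic basis
`A[i, k, lm]` is assembled from channel-mixed radial features times real
spherical harmonics (up to `l_max = 3`) summed over graph neighbors,
weighted by sender node states.  Rotation-invariant features are scalar
contractions of `A`: the `l = 0` component (correlation order 1), per-`l`
power sums (order 2), and their products with the scalar channel (order
3), giving body orders up to `nu + 1`.  With `T = 2` message-passing
layers the receptive field extends two hops — but only through QM atoms,
because MM-MM edges do not exist.  The hyperparameter `L` controls the
angular order of features *communicated between layers*: with `L = 1`
the `l = 1` components of `A` are carried as equivariant vector features
and re-enter the next layer through invariant contractions with the edge
direction; with `L = 0` only scalars are passed.  The final layer is
read out through a 16-channel perceptron gated by the sigmoid-linear
unit, intermediate layers through linear readouts.

**DP-like two-body baseline.**  Per atom, each neighbor contributes a
smooth scalar weight `s(r) = f_env(r)/r` and a coordinate-matrix row
`s(r) (1, x/r, y/r, z/r)`; species-specific embedding networks map
`s(r)` to an embedding vector, and the feature matrix is the
contraction of the embedding matrix with the coordinate matrix and its
first `axis_filters = 12` rows (the DeepPot-SE construction), fed to a
fitting network.

**Trainable-parameter layout.**  In both architectures the nonlinear
feature machinery (radial mixing, embeddings, node updates, gate/hidden
weights) is *fixed at seed-controlled random values*, and training
adjusts the readout weights and QM species biases.  Site energies are
therefore linear in the trainable vector, in the tradition of linear
atomic-cluster-expansion potentials with randomized nonlinear features.
This buys three things at desk scale: per-sample design quantities
(energy features and their position Jacobians) are computed once and
reused across all optimization steps; the training loss is exactly
quadratic, so Adam behaves predictably and committee-seed variation is
honest (different random features *and* different starts); and analytic
forces come from a single reverse sweep.  The cost is expressiveness:
the function class is the span of a finite random feature set, which is
ample for the smooth corrections studied here but would need wider
channels (`N`) for rugged targets.  Paper-scale widths (`N = 128`,
240-neuron fitting layers) remain configurable; the desk defaults are
`N = 16` and 24-neuron layers.

Forces use hand-coded reverse-mode differentiation through the full
layer recursion (including the node-state and vector-feature chains);
the training design uses a forward sensitivity sweep that yields the
Jacobian of every feature at once.  The two routes are checked against
each other and against central finite differences (1e-5 eV/A) in the
test suite, and microcanonical dynamics with the correction conserves
energy to a relative drift below 1e-4 over 10,000 steps of 0.15 fs.

# Training protocol

The loss per sample is `p_e(t) dE^2 + p_f <|dF|^2>` with the energy
weight ramping exponentially from 1 to 100 eV^-2 over training and the
force weight fixed at 100 A^2 eV^-2; the learning rate decays
exponentially from 1e-3 to 1e-5 (`lr_schedule()`; 400,000 steps at paper
scale, 2,000 by default here — the quadratic loss plateaus well before
that).  Training repeats over 4 seeds to give a committee.

The **simplify** data-selection workflow (`simplify_workflow()`) trains
round 1 on a random 50% of the database, applies the committee to the
test remainder, and *discards* samples whose maximum member force RMSE is
below 0.08 eV/A (the committee already agrees on them); later rounds
restart the optimization from the previous parameters on the surviving
samples capped at 25% of the original database.  Partition sizes use
ceilings of the fractions so that 50% + 2 x 25% always covers the
database — this is what makes the 3-round termination bound hold for
every database size, including small ones.

**End-state augmentation** (`augment_endstates()`) extends the training
set 10%: selected frames get every QM heavy atom displaced up to 0.15 A
in a random direction and every QM hydrogen moved along its covalent
bond to a length uniform in [0.7, 1.2] A.  That range is read as the
*new bond length* (not an increment): adding 0.7-1.2 A to a ~1 A X-H
bond would be unphysical, while resampling the bond length in that range
matches the stated purpose of perturbing the local environment.

# The synthetic surrogate

`toysim` stands in for the solvated QM/MM systems: a collinear
O-P-O triatomic with a tethered QM hydrogen (QM region) surrounded by
soft-sphere MM particles confined to a droplet around the QM centroid.
The reaction coordinate is the distance difference
`xi = |R_A - R_P| - |R_P - R_B|`.  The base potential is a two-basin
quartic profile in xi (barrier 0.40 eV, basins at +/-1.6 A) plus a
bond-sum restraint, soft repulsions, and a repulsive QM/MM pair shell.
The target adds

* a Gaussian well of depth 0.20 eV and width 0.27 A *in each P-O bond
  distance*, centered at 1.8 A — the bond length both bonds reach
  simultaneously near xi = 0.  Along the reaction path this creates a
  metastable intermediate ~3 kT below its flanking barriers while
  leaving the end basins intact.  Crucially, the end states sample each
  bond at ~1.0 A *and* ~2.6 A, so recovering the well is smooth
  *interpolation* in the bond distance, not extrapolation — the same
  transferability mechanism the Delta-MLP relies on in the real systems;
* a modified QM/MM pair term inside the 6 A cutoff (a Gaussian shell
  scaled per QM species under the polynomial envelope), so the
  correction also has a genuine solvent-coupled short-range component;
* a small tilt change emulating reactant/product asymmetry shifts.

Six named variants (2 nucleophile analogs x 3 leaving-group analogs)
differ in tilt, pair-correction amplitude, and hydrogen tether length.
What the surrogate does *not* emulate: electrostatics and polarization
(the real driver of QM/MM coupling), water structure, periodic boundary
conditions, and chemical anharmonicity.  Passing tests on the surrogate
therefore demonstrate the *workflow* — graph contracts, training
mechanics, estimator correctness, end-state transferability of a smooth
correction — not chemical accuracy on real systems.

Sampling uses BAOAB-split Langevin dynamics at 298 K with a 5 ps^-1
collision frequency and 0.5 fs steps (the toy system has no fast X-H
stretch above ~14 fs period; hydrogen carries 2 amu).  The umbrella
bias is `k/2 (xi - xi0)^2`.  A note on window spacing: with the
production-scale k = 300 kcal mol^-1 A^-2 the biased xi fluctuation is
~0.044 A, which is why that force constant pairs with 0.1 A spacing;
the desk schedule (0.25 A spacing) pairs with k = 40 so that adjacent
windows keep ~2 sigma overlap — MBAR needs overlapping neighbors.

# Free-energy analysis

`mbar_solve()` minimizes the convex MBAR objective with BFGS using the
analytic gradient, then polishes with self-consistent iteration to a
1e-10 relative tolerance on the dimensionless free energies (anchored at
state 1).  Surfaces are histograms on a grid aligned with the window
centers (0.1 A bins at paper scale, 0.25 A at desk scale):
`F(b) = -kT log sum w`, anchored so the occupied minimum is zero;
unoccupied bins are reported as missing and never interpolated.

**wTP** reweights the samples of one reference model to the target:
`w_n proportional to exp(-beta U_target(x_n)) / D_n` with `D_n` the MBAR
denominator.  **gwTP** pools the samples of several reference models
into one MBAR over all (model, window) states and applies the same
formula; with a single reference it reduces to wTP exactly, which the
tests assert bit-for-bit.

**Reweighting entropy** quantifies per-bin reliability: the weights in a
bin are normalized and scored by `-sum w log w / log n`, which is 1 for
uniform weights and near 0 when a few samples dominate.  The weights
entering the diagnostic are the *perturbation factors*
`exp(-beta (U_target - U_ref,own))` of the samples relative to their own
generating reference: with target == reference they are uniform and the
entropy is exactly 1, which pins down the normalization.  Surfaces with
bins below ~0.6 should be treated as unreliable.

**Density-of-states smoothing** histograms the perturbation energies of
a spatial bin into 0.2 kT energy bins and gives every sample of an
energy bin the identical factor — the bin *average* of `exp(-dU)`.  The
averaged form is chosen over sharing `exp(-mean dU)` deliberately:
averaging weights preserves each energy bin's total mass and can only
increase the bin's entropy, matching the method's purpose (damping
outlier weights within a spatial bin) and the observed behavior that
smoothing slightly raises reweighting entropies; the `exp(-mean dU)`
variant can decrease them marginally (Jensen's inequality shrinks the
non-outlier bins' mass).

# The end-state transferability experiment

`endstate_transfer_experiment()` chains everything: base-potential
sampling of only the two end-state windows (xi = -1.5 and +1.5 A, 100
frames each, +10% augmentation), simplify-workflow training of a
4-member committee, base+Delta-MLP umbrella sampling over the full
17-window ladder, pooled gwTP to the target, and comparison with direct
target-potential umbrella sampling.  At the desk defaults (seed 1) the
gwTP estimate deviates from the direct-target surface by ~0.3 kT mean
absolute deviation over occupied bins and recovers the intermediate well
at ~3 kT depth — although no training data came from the transition
region.  The acceptance suite requires < 2 kT and a well at least 1 kT
deep.

# Numerical choices and degenerate inputs

* Real spherical harmonics use the orthonormal Cartesian-polynomial
  convention without the Condon-Shortley phase; tests only rely on
  invariance, not the convention.
* Atoms with no graph neighbors short-circuit to their species bias (the
  silu readout subtracts its zero-feature value so empty environments
  contribute exactly the bias, hence exactly 0 for MM atoms).
* Window-center matching uses a 1e-9 A tolerance; xi histogram bins snap
  to the nearest grid multiple.
* Degenerate schedules (`xi_min == xi_max`) yield a single window;
  stride selection anchors at the most negative center, reproducing the
  printed S:n subsets (64/32/16/8 windows ending at 3.0/2.9/2.7/2.3 A).
* Checkpoints are versioned single-file JSON archives with full double
  precision; datasets are extended-XYZ text with 15 significant digits
  (byte-stable round trips).
* All simulation RNG flows through per-(variant, member, window) seeds
  derived from one master seed; repeated runs are bit-identical.

# Problem sizes

Desk defaults were chosen so the full validation suite — including the
end-state transferability pipeline — runs on a single CPU core in
minutes: 12-atom systems (4 QM + 8 MM), 17 umbrella windows, 50-100
saved frames per window, committees of 4, 2,000 optimization steps.
Paper-scale settings (64 windows at k = 300 with 0.1 A spacing, 500
frames, N = 128 channels, 400,000 steps) are reachable through the same
interfaces and configuration files.

# Known limitations

* No electrostatic embedding: the correction is strictly short-ranged
  and nonelectrostatic by design; long-range polarization response is
  out of scope.
* The trainable set excludes the internal feature weights; systems whose
  correction is not well captured in the random-feature span need wider
  channels rather than deeper optimization.
* Neighbor search is brute-force O(N^2) — appropriate for clusters of
  tens of atoms, not condensed-phase boxes.
* The equivariant message pathway implements L <= 1; higher-order
  tensor messages (L >= 2) are not supported.
* MM nodes do emit (bias-free) site energies when they have QM
  neighbors; the alternative reading — MM atoms contributing only
  through messages into QM sites — satisfies the same contracts, and
  the choice is interpretive.
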