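---
title: "Approximating collective variables with small neural networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Approximating collective variables with small neural networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cvnet)
```

## Why approximate a collective variable?

Biased molecular simulations need collective variables (CVs) that are cheap
to evaluate from Cartesian coordinates and differentiable with respect to
them.  Descriptors that violate either requirement — non-linear embeddings
with no out-of-sample formula, or surface areas whose analytic derivatives
are impractical inside an MD engine — can still be *approximated* by a small
regression model trained on an ensemble of structures with precomputed CV
values.  A feed-forward network is a natural choice because the same
backpropagation machinery that trains it also yields exact input gradients,
which is precisely what converting a force on the CV into atomic forces
requires.

`cvnet` implements that train–export–verify loop: fit the network on
superposed, box-scaled coordinates, write it out as a PLUMED input file in
which every neuron is one expression line, and re-evaluate that file along
the training trajectory as a self-check.

## The model and its assumptions

Given F frames of N analysis atoms, each frame is rigidly superposed onto a
reference structure and scaled into the unit cube:

* **Superposition.** The Kabsch least-squares fit (SVD of the 3×3 coordinate
  covariance, equal atom weights, determinant guard so only proper rotations
  are returned).  Equal weights are used because nothing in the method
  requires masses; the exported `FIT_TO_TEMPLATE ... TYPE=OPTIMAL` line
  performs the same least-squares fit inside PLUMED.
* **Scaling.** The reference must sit in a box with one corner at the origin
  and the diagonal corner at (l_x, l_y, l_z) nm.  After fitting, x/y/z are
  divided by l_x/l_y/l_z.  If any fitted coordinate leaves [0, 1] the box is
  too small for that conformation and the pipeline stops with the frame,
  atom and axis named — silently clipping would corrupt the features.
* **Network.** 3N inputs, one to three hidden layers, a single output.
  Deeper architectures are deliberately out of scope: the network must stay
  cheap enough to evaluate (and differentiate) every MD step once inlined
  into PLUMED text expressions.
* **Targets.** The CV values are min–max scaled to [0, 1].  The output
  activation is linear; the exported file applies
  `cv_min + (cv_max − cv_min) · out` so the CV that PLUMED computes is in
  original units (nm² for a surface area, dimensionless for an embedding),
  which keeps published hill widths meaningful.  Bounding the output by the
  training-set range is a real, documented extrapolation limit — see below.

The implicit physical assumptions: the analysis atoms fully determine the
CV; conformations in production runs resemble those in the training
ensemble (the training set must contain every basin you hope to visit); and
the molecule is whole, not broken across periodic boundaries (the package
validates box membership but performs no PBC repair).

## Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| hidden layers | 1 | — | one layer suffices for smooth geometric CVs |
| neurons/layer | 64 | — | generous for 3N ≲ 500 inputs at negligible cost |
| activations | sigmoid | — | smooth, bounded, renders compactly as `1/(1+exp(-u))` |
| optimizer | adam (1e-3, β₁ 0.9, β₂ 0.999, ε 1e-8) | — | robust default; SGD (0.01) and RMSprop (1e-3, ρ 0.9) available |
| loss | mean squared error | scaled CV² | the natural regression loss; MAE offered for outlier-heavy tables |
| epochs | 1000 | — | fixed count, no early stopping; history lets users judge convergence |
| batch size | 256 | frames | sized for 10⁵–10⁶-frame sets; use ~64 for 10³-frame sets so the optimizer gets enough updates |
| test fraction | 0.1 | — | conventional held-out share; at least one frame is always held out |
| weight digits in export | 9 | significant digits | keeps the file↔memory round trip below 1e-6 in CV units (tested; 3 digits demonstrably fails) |

Weights initialise from a seeded uniform ±√(6/fan-in) draw with zero biases.
All randomness — the weight draw, the TR/TE permutation, minibatch order —
derives from one user seed, and identical seeds give bit-identical trained
networks and byte-identical exported files.

## The synthetic ensembles

`generate_conformers()` supplies study conditions without external data:

* **chain-dihedral** — an N-bead chain with 0.15 nm bonds and 109.47° bond
  angles whose dihedrals are drawn uniformly per frame; this emulates the
  conformational variety of a flexible ring or short chain.  A candidate
  conformer is accepted only if, once superposed onto the reference, it lies
  inside the box — the same admissibility the pipeline later enforces — and
  rejected conformers are redrawn (an error after 500 failures signals a
  genuinely undersized box).
* **gaussian-cloud** — the reference plus isotropic noise, for cheap
  ensembles where conformational realism is irrelevant (round-trip sweeps,
  parser fuzzing).

Every frame then receives a random proper rotation and translation so the
fitting step is genuinely exercised.  Oracle CVs are tabulated alongside:
radius of gyration, Shrake–Rupley SASA (deterministic golden-spiral sphere
points, default 0.15 nm radii and 0.14 nm water-like probe), and a linear
probe for exact-recovery tests.

What these fixtures do *not* emulate: Boltzmann-weighted sampling, solvent,
force-field energetics, atom-type heterogeneity, or the multi-basin
structure of real free-energy landscapes.  A high held-out correlation on
these ensembles demonstrates that the pipeline is implemented correctly —
fitting, scaling, training, export and gradients all agree — not that a
32-neuron network will approximate an arbitrary CV of a real protein.

## Numerical choices

* Kabsch reflection guard: when the covariance determinant is negative the
  smallest singular direction is flipped, so det(R) = +1 always; collinear
  point sets trigger a warning (the in-plane rotation is then not unique)
  and a best-effort transform.
* Box membership uses a 1e-9 nm tolerance so PDB round-tripping (1e-4 nm
  resolution) never trips the check on boundary atoms.
* Without shuffling, the test set is the trailing block of frames — the
  natural "held-out end of trajectory" reading; with shuffling it is a
  seeded permutation of ⌊fraction·F⌋ frames (minimum 1).
* The exported dialect uses only `+ - * / exp tanh max`; softsign and elu
  are rewritten with `max` (|u| = max(u, −u); min(u, 0) = −max(−u, 0)), and
  the companion parser rejects anything outside this set, forward
  references, duplicate labels and unknown directives, so a file that
  parses is a file the evaluator fully understands.
* Degenerate inputs fail loudly: constant CV tables (no min–max scaling
  possible), zero-variance correlations, non-finite losses (reported with
  the epoch index) and frame/atom-count mismatches are all errors, not
  warnings.

## Design decisions that were genuinely open

* **Output scaling.** Instead of a bounded output activation, targets are
  min–max scaled and the inverse map is serialized into the PLUMED file.
  This keeps the output layer linear (benign gradients) and the exported CV
  in original units.
* **Trajectory formats.** Multi-model PDB, DCD and GROMACS TRR are read;
  TRR and DCD writers are included so fixtures exercise the binary path
  (the TRR layout is validated against an independent reader in the test
  suite).  XTC is rejected with a pointer to `gmx trjconv`: its compressed
  coordinate codec is a large dependency for no testing benefit.
* **Recovery experiment sizes.** The standing verification experiments use
  a 24-bead chain (2,000 frames, 32 sigmoid neurons, 500 epochs, batch 64)
  for radius of gyration and a 10-bead ensemble for SASA; at these sizes
  the whole loop runs in well under a minute while leaving the held-out
  correlation thresholds (0.98 / 0.95) a comfortable margin.  Batch 64
  rather than the 256 default reflects the small frame count.
* **No bias directives.** The exporter writes the CV definition only;
  adding `METAD` or other bias blocks is left to the user, since hill
  parameters are system-specific judgement calls.

## Limitations

* The network only interpolates: structures outside the training
  distribution (unseen basins, unfolded states if only folded ones were
  trained on) get unreliable CV values, and the min–max rescaling pins
  predictions to the training range.  This is inherent to the approach, not
  an implementation artifact.
* RMSD-fit-free featurisations (interatomic distances, contact maps) are
  not supported; the input is always superposed Cartesian coordinates.
* The internal evaluator covers exactly the emitted dialect.  It is a
  verification harness, not a PLUMED replacement; behaviour on arbitrary
  third-party PLUMED files is out of contract.
* Training is single-threaded dense linear algebra; it is comfortable for
  10³–10⁵ frames and a few hundred inputs, but a million-frame ensemble is
  an overnight job, not an interactive one.

## A compact end-to-end run

```{r example, eval = FALSE}
box <- box_spec(1, 1, 1)
ens <- generate_conformers(24, 2000, box, seed = 11, cv = "rgyr")
paths <- write_ensemble(ens, tempfile("demo"), traj_format = "trr")
fit <- approximate_cv(paths$reference, paths$trajectory, paths$cv_table,
                      box = box, column_index = 2, hidden = 32, seed = 11,
                      config = training_config(epochs = 500, batch_size = 64),
                      plumed_path = "plumed.dat")
fit$report          # Pearson r on TR and TE, in original CV units
g <- parse_plumed("plumed.dat")
plumed_driver(g, ens$trajectory, fit$reference)[1:5]  # driver-style check
```
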