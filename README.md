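# cvnet

Neural-network approximation of collective variables, exported to PLUMED.

## The problem

Biased molecular simulations (metadynamics, umbrella sampling, ...) steer a
system along a few *collective variables* (CVs) — low-dimensional functions
s(**x**) of the atomic Cartesian coordinates.  A CV is only usable for
biasing if (i) it can be evaluated at every MD step from coordinates alone
and (ii) its derivatives ∂s/∂**x** are available, so a force on the CV can
be turned into forces on atoms.  Many attractive descriptors fail one or
both tests: non-linear embeddings (Isomap and friends) have no closed form
for out-of-sample structures, and quantities like the solvent-accessible
surface area (SASA) are closed-form but far too slow to evaluate and
differentiate every step.

`cvnet` addresses this the way a structural-bioinformatics practitioner
would: train a small feed-forward network ŝ(**x**) on an ensemble of
structures with precomputed CV values, then serialize the trained network
into a PLUMED input file.  PLUMED evaluates the resulting expression lines
natively — including their derivatives — so the approximated CV can be
monitored or biased in any MD engine PLUMED plugs into.

## The model

Each frame is superposed onto a reference structure (Kabsch least-squares
fit, removing rotation and translation), its coordinates are divided by the
box edges (l_x, l_y, l_z) so every input lies in [0, 1], and the flattened
3N-vector feeds a multilayer perceptron

  ŝ = f_out( W_out · f_k( ... f_1(W_1 **x** + b_1) ... ) + b_out )

with 1–3 hidden layers, per-layer activations (sigmoid by default; tanh,
linear, relu, softsign, elu supported), a linear output, and min–max scaled
targets.  Training is minibatch gradient descent (Adam by default; SGD and
RMSprop available) on mean-squared (or mean-absolute) error, with a held-out
test set (10 % of frames by default) whose Pearson correlation r(ŝ, s)
is the headline quality metric.  Input gradients ∂ŝ/∂**x** come from an
analytic backward pass.

The exported PLUMED file contains a `FIT_TO_TEMPLATE` line reproducing the
Kabsch fit, one `POSITION` line per analysis atom (original serial numbers),
scaled-input lines, one `CUSTOM` expression per neuron with inlined weights,
and a final line mapping the output back to original CV units.  An internal
evaluator for exactly this dialect (`parse_plumed()` / `plumed_driver()`)
recomputes the CV along a trajectory, standing in for the usual
`plumed driver` self-check.

## Worked example

Everything below runs with no external data: the package generates a
24-bead chain ensemble, tabulates its radius of gyration as the target CV,
trains, and verifies the export.

```r
library(cvnet)

box <- box_spec(1, 1, 1)                         # nm
ens <- generate_conformers(24, 2000, box, seed = 11, cv = "rgyr")
paths <- write_ensemble(ens, "demo", traj_format = "trr")

fit <- approximate_cv(paths$reference, paths$trajectory, paths$cv_table,
                      box = box, column_index = 2, hidden = 32,
                      seed = 11,
                      config = training_config(epochs = 500, batch_size = 64),
                      corr_path = "corr.txt", plumed_path = "plumed.dat",
                      template_path = "template.pdb", quiet = FALSE)
#> loaded 2000 frames x 24 atoms; CV range [0.1961, 0.453766]; seed 11
#> training 72-32-1 network: 500 epochs, batch 64, adam/mean_squared_error
#> Pearson r: TR 0.9929, TE 0.9903
#> wrote plumed.dat and template.pdb

# the plumed-driver style self-check: re-evaluate the exported file
g <- parse_plumed("plumed.dat")
cv <- plumed_driver(g, load_trajectory(paths$trajectory, fit$reference),
                    fit$reference)
max(abs(cv - fit$predicted))
#> [1] 3.836458e-10
```

`corr.txt` holds one row per frame — predicted value, original value, and
whether the frame was in the training (`TR`) or test (`TE`) set — the
conventional scatter-plot input for judging the approximation.  A Pearson
r(TE) of 0.99 here means the network explains ~98 % of the held-out CV
variance; the 3e-9 round-trip error confirms the text file encodes the
trained network faithfully.

The same pipeline is available from the shell
(`inst/scripts/cvnet`, flags mirroring the R arguments):

```sh
cvnet -i traj.trr -p reference.pdb -c cv_table.txt -col 2 \
      -boxx 1 -boxy 1 -boxz 1 -layers 1 -layer1 32 -epochs 500 \
      -batch 64 -o corr.txt -plumed plumed.dat
```

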