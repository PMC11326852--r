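# xtalformer

Crystallographic diffraction experiments measure structure-factor
amplitudes |F(h,k,l)| but lose the phases φ(h,k,l) — the *phase problem*.
The Patterson map,

    p(u,v,w) = (1/V) Σ_hkl |F(h,k,l)|² exp(−2πi(hu + kv + lw)),

is computable from the measured amplitudes alone (all phases set to zero)
and equals the autocorrelation of the electron density. **xtalformer**
poses phase recovery as supervised learning on that map: a hybrid
3D-CNN/transformer regresses the electron density grid e ∈ R^(N1×N2×N3)
directly from the Patterson grid p, optionally conditioned on
standardized per-residue "partial structure" density maps u_j through a
one-way attention mechanism — Patterson tokens attend to partial-structure
tokens, never the reverse, and the partial tokens are embedded once and
reused by every layer.

The package is aimed at structural-bioinformatics researchers who want a
self-contained, CPU-scale laboratory for this problem: it generates
random peptide fragments with idealized geometry, builds crystalline
training examples in P1 orthorhombic cells under explicit dataset rules
(minimum intermolecular contact ≥ 2.75 Å via iterative cell expansion,
axis reindexing to a ≥ b ≥ c, center-of-mass centering, maps to a
resolution limit normalized into [−1, 1], tensor-size binning), trains
the model with the weighted loss

    L = 0.9999 · MSE(e′, e) + 1e−4 · (−PC(e′, e)),

where PC is the voxel Pearson correlation, and evaluates predictions by
map correlation and mean phase error in equal-count resolution shells
(fraction of well-phased examples, error < 60°, included). The
transformer, its 3D convolutions and full backpropagation are implemented
in base R on BLAS primitives and verified against finite differences.

## Worked example

Generate eight synthetic dipeptide examples, fit the model, and inspect
it:

```r
library(xtalformer)

gen <- generator_config(n_residues = 2, seed = 11)
ds  <- generate_dataset(10, gen, d_min = 2.0, oversampling = 2.0,
                        mode = "fixed", fixed_cell = unit_cell(14, 14, 14),
                        patch_dims = c(4, 4, 4), min_batch = 1)
exs <- ds$examples[1:8]

fit <- xtalformer(exs,
                  model    = model_config(grid_dims = c(16, 16, 16),
                                          patch_dims = c(4, 4, 4)),
                  training = train_config(epochs = 500, batch_size = 8,
                                          lr = 1e-3, beta2 = 0.9,
                                          seed = 1))
print(fit)
#> Patterson-to-density transformer fit
#> model config: grid 16x16x16, patch 4x4x4 -> S=64 tokens, d_t=64 (4 heads x 16), L=2, c=8, ff=128, in_ch=1
#> trained 500 epochs on 8 examples
#> final train loss 0.000307, mean PC 0.9562
```

The final mean Pearson correlation above 0.9 shows the network has the
capacity to invert the Patterson autocorrelation on maps it has seen —
the overfitting sanity check for this architecture. Evaluation adds the
phase-error view:

```r
summary(fit, exs)
#> evaluation over 8 examples
#>   mean PC:           0.9568
#>   mean phase error:  8.03 deg
#>   examples < 60 deg: 100.0%
#> per-shell mean phase error (deg):
#>  shell  d_max d_min mean_error frac_examples_below_60
#>      1 14.000 4.427      5.151                      1
#>      2  4.427 3.395      6.817                      1
#>      ...
#>     10  2.087 2.000     13.780                      1
```

A mean phase error of ~8° on the training examples (well under the 60°
convention for a well-phased set) means the predicted maps would be good
starting points for conventional refinement; predictions can be exported
with `write_ccp4_map()` for external model-building programs. Held-out
accuracy requires training at dataset scales beyond a desk machine and is
out of scope here.

Lower-level entry points mirror the pipeline stages:
`generate_fragment()`, `build_example()`, `calc_structure_factors()`,
`density_from_sf()`, `patterson_from_sf()`, `phase_error()`,
`train_model()`, `recycle_train()`, `evaluate_model()`, and
`run_pipeline()` (YAML-configurable; also exposed by the thin CLI script
in `inst/exec/xtalformer`).

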