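---
title: "Predicting electron density from Patterson maps: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting electron density from Patterson maps: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(xtalformer)
```

## The problem

X-ray diffraction measures the amplitudes $|F(h,k,l)|$ of a crystal's
structure factors but not their phases $\varphi(h,k,l)$; without phases the
electron density cannot be reconstructed directly. The Patterson function
sidesteps the missing phases by squaring all amplitudes and setting all
phases to zero,

$$p(u,v,w) = \frac{1}{V}\sum_{h,k,l} |F(h,k,l)|^2 \, e^{-2\pi i (hu+kv+lw)},$$

which is computable from raw data alone and equals the autocorrelation of
the density: a map of interatomic vectors rather than atoms. This package
treats recovery of the density from the Patterson map as a supervised
regression problem on small crystalline peptide fragments in space group
P1 with orthorhombic cells: a hybrid 3D-CNN/transformer maps a Patterson
grid to a density grid, optionally conditioned on standardized
"partial structure" maps, one per residue present in the fragment.

Everything needed to study the task is generated in code: random
peptide-like fragments, their cells, structure factors, density and
Patterson maps, and the per-residue conditioning maps. No downloads or
external programs are involved.

## Crystallographic conventions

All Fourier machinery lives behind a small set of fixed conventions; the
equalities asserted in the test suite hold under exactly these.

* **Grids.** A map of a cell $a \times b \times c$ on an
  $N_1 \times N_2 \times N_3$ grid samples fractional coordinates $i/N$
  (origin at voxel 0). `build_grid()` chooses the smallest even $N_i$
  covering each edge at the nominal spacing
  $\Delta = d_{\min} / \text{oversampling}$; at the production settings
  (1.5 Å resolution, oversampling 3.0) this is 0.5 Å. Even dimensions keep
  Friedel placement in the frequency grid unambiguous.
* **Synthesis.** `density_from_sf()` places the Friedel-expanded
  coefficients into a complex frequency grid at indices $h \bmod N$ and
  applies the discrete transform with kernel $e^{-2\pi i hn/N}$, scaled by
  $1/V$; the imaginary residue is asserted to vanish. The Patterson map
  uses $|F|^2$ with zero phases. `patterson_from_density()` computes the
  same map as $\mathrm{Re}\,\mathcal{F}(|\mathcal{F}^{-1}(e)|^2)$ — the
  "inverse-shifted" copy of the density in the autocorrelation appears as
  complex conjugation in frequency space. Both routes agree to machine
  precision for band-limited maps, and the test suite asserts this
  route-equivalence on randomly generated fragments.
* **Scattering.** Atoms are point scatterers with $f$ = electron count by
  default, making the analytic test oracles exact; 4-term Cromer–Mann
  Gaussian form factors for H, C, N, O, S are available behind
  `scattering = "gaussian"`. B-factors default to 0 and occupancies to 1;
  both are honored when set. Whether hydrogens are present is a property
  of the input structure, not an assumption of the code (the built-in
  generator emits none).

## Dataset rules

`build_example()` turns a fragment into a training triple (Patterson map,
density map, per-residue partials):

1. **Cell assignment.** In `variable` mode the cell starts at the
   fragment's per-axis coordinate ranges and all three edges grow by 0.25 Å
   per iteration until the minimum intermolecular contact — the smallest
   distance from the central copy to any of its 26 periodic images —
   reaches 2.75 Å (at most 100 iterations, then the example is discarded).
   Growth is isotropic so fragment-to-cell proportions are preserved, and
   the step is below the grid spacing so cells stay tight. In `fixed` mode
   the fragment is placed in a given cell (41 × 30 × 24 Å by default) and
   discarded if the contact rule fails there.
2. **Reindexing.** Axes are permuted so $a \ge b \ge c$ (stable under
   ties), making map orientation canonical.
3. **Centering.** One common translation puts the mass-weighted centroid
   at the cell center. Because the Patterson map is invariant to
   translation of the whole density, centering removes the origin
   ambiguity; predictions and truths can then be compared voxel-by-voxel
   and phase-by-phase without an origin search, which is deliberately not
   implemented.
4. **Maps.** Structure factors to $d_{\min}$, density and Patterson
   synthesis, then max-abs normalization into $[-1, 1]$. Max-abs (rather
   than min–max) preserves the physically meaningful zero level and the
   sign pattern, matching the sign-symmetric tanh output of the model.
5. **Binning.** Examples are grouped by exact grid dimensions; bins
   thinner than the minimum batch size are dropped, since training batches
   must be drawn within one tensor-size bin.

**Partial structures.** Each residue contributes the density of an
idealized, example-independent template of its type (built from internal
coordinates in a fixed conformer), centered at the cell center. Centering
rather than placing the template at the residue's true position avoids
leaking the answer into the conditioning input; placement at the true
centroid is available behind `placement = "true"` for ablations. Because
templates are standardized, two examples sharing a residue type on the
same grid receive bit-identical partial maps.

**Grid padding.** When the model's patch dimensions are known at build
time, grid dimensions are rounded up to patch multiples by sampling the
same cell more densely rather than by zero-padding: a zero margin would
break the periodicity the Fourier synthesis assumes, while denser sampling
keeps every grid a true map of its cell.

## The model

The network follows the tokenization-with-conditioning design: with grid
$N_1 \times N_2 \times N_3$ and patches $d_1 \times d_2 \times d_3$, the
token count is $S = N_1 N_2 N_3 / (d_1 d_2 d_3)$.

* A stem of two 3×3×3 convolutions (stride 1, same padding, a leaky ReLU
  with slope 0.01 between) expands the Patterson input to $c$ channels
  while preserving spatial dims; partial-structure maps pass through a
  separate stem with its own weights. The leaky slope — also used in the
  patch MLPs and the decoder CNN, though not in the attention
  feed-forward blocks — keeps stem units trainable after large early
  updates, which plain ReLUs do not survive at aggressive learning
  rates in this small-data regime.
* The channel volume is partitioned into $S$ patches in raster order,
  each flattened to length $c\,d_1 d_2 d_3$ and projected by a two-layer
  MLP to token width $d_t$; a learned positional embedding is added. The
  Patterson and partial branches have separate embedding tables, and the
  partial table is shared across residues $j$ — this sharing is what makes
  the forward pass invariant to permuting the residue order, a property
  the tests assert.
* $L$ layers of **one-way attention**: queries come only from the
  Patterson tokens $X_\ell$; keys and values are the concatenation of
  projected Patterson tokens and projected partial tokens
  $U \in \mathbb{R}^{SJ \times d_t}$, so each attention row spans
  $S + SJ$ keys. $U$ is embedded once and never updated — the partials
  serve as a stable reference in every layer. Scores are scaled by
  $1/\sqrt{d_h}$ (omitted in compact statements of the block but required
  for trainable softmax attention), heads are concatenated through an
  output projection, and a ReLU feed-forward follows. Residual connections
  with pre-norm layer normalization wire both sub-blocks; pre-norm was
  chosen for stability at small data scale. With $J = 0$ the layer reduces
  exactly to a standard self-attention block, which the tests check
  against an independent implementation.
* The decoder maps final tokens through a two-layer MLP back to patch
  width, un-partitions to the $c$-channel volume, and applies a two-layer
  3D CNN down to one channel followed by tanh, so predictions live
  strictly in $(-1, 1)$, matching the normalized targets.

$d_t = H \cdot d_h$ is tied (standard multi-head convention; the output
projection is square). Initialization is truncated normal (He scaling for
convolutions, $1/\sqrt{\text{fan-in}}$ for projections, 0.02 for embedding
tables), all biases zero; everything derives from one seed. The
entire forward/backward pass is written in base R against BLAS matrix
primitives: convolutions via precomputed gather ("im2col") indices, patch
partitioning via a precomputed index bijection, and analytic gradients for
every block, verified against central finite differences in the test
suite.

## Loss and training

The loss is the weighted sum used for map-to-map regression,

$$\mathcal{L} = 0.9999 \cdot \mathrm{MSE}(e', e) \;+\; 10^{-4} \cdot
\bigl(-\mathrm{PC}(e', e)\bigr),$$

where PC is the Pearson correlation over voxels with a small
$\epsilon = 10^{-8}$ inside each root of the denominator,

$$\mathrm{PC}(e,e') = \frac{\sum (e'-\bar e')(e-\bar e)}
{\sqrt{\sum (e'-\bar e')^2+\epsilon}\cdot\sqrt{\sum (e-\bar e)^2+\epsilon}}.$$

Printed statements of this quantity sometimes garble the denominator into
a sum of the two root terms; the product form is used here because the
correlation of a map with itself must be 1, which only the product
satisfies. At a perfect prediction the loss is exactly $-10^{-4}$.

Optimization is Adam (the generic adaptive choice when none is
prescribed), learning rate $10^{-3}$ for the desk-scale configurations,
mini-batches drawn within one tensor-size bin and shuffled by the seed.
The second-moment decay matters far more here than its canonical default
suggests: with eight examples per batch the gradient is nearly
deterministic, and $\beta_2 = 0.999$ adapts the per-parameter scale so
slowly that training crawls through a long plateau; $\beta_2 = 0.9$
roughly halves the steps needed to overfit the desk-scale set and is
used for those runs ($\beta_2 = 0.999$ remains the constructor default).
An optional global gradient-norm clip is available as a stability guard.
Training is bit-reproducible given the seed, and a non-finite loss aborts
with the last stable parameters attached. **Recycling** retrains a freshly
initialized model whose stem receives two channels — the Patterson map and
the previous model's prediction for the same example, in that fixed order
— for training and evaluation alike.

## Evaluation

`evaluate_model()` reports, per example, the Pearson correlation between
prediction and truth and the mean phase error: structure factors of both
maps are recovered by forward transform to the example's build resolution,
phases are compared reflection-by-reflection (F(0,0,0) excluded), wrapped
into $[0°, 180°]$, and averaged — unweighted by default, with an
amplitude-weighted variant alongside since conventional phase-comparison
tools weight by amplitude and the convention is rarely stated. Reflections
are split into equal-count resolution shells from low to high resolution;
the report includes per-shell means and the fraction of examples whose
error stays below 60°, the conventional threshold for a well-phased set.

## What the synthetic generator does and does not emulate

`generate_fragment()` builds chains of idealized residues (peptide bonds
C–N 1.33 Å, N–CA 1.46 Å, CA–C 1.52 Å) with backbone torsions drawn
uniformly or with a helical bias, rejection-sampled until no non-bonded
pair is closer than 1.8 Å. Templates cover GLY, ALA, SER, CYS, VAL, THR,
LEU, ASP and ASN; additional types can be supplied as plain-text
coordinate files. The generator reproduces the *structural* statistics the
pipeline needs — realistic atom counts, bond geometry, fragment extents,
packing behavior under the contact rule — but deliberately not
Ramachandran statistics, rotamer variability, or sequence realism. Tests
passing on generated data therefore demonstrate the correctness of the
crystallographic math and the learnability of the map-to-map task at desk
scale; they say nothing about accuracy on real PDB-derived fragments at
scale.

## Problem sizes and numerical choices in the tests

The desk-scale study conditions used throughout the tests and the
acceptance script: dipeptides over a GLY/ALA/SER alphabet; a fixed
14 × 14 × 14 Å cell with maps at 2.0 Å resolution, oversampling 2.0
(16³ grids after patch rounding); the toy model of 4³ patches
($S = 64$), $c = 8$, $d_t = 64$, 4 heads, 2 layers, feed-forward width
128; full-batch Adam at $10^{-3}$ with $\beta_2 = 0.9$ for 500 steps on
8 examples. These sizes
keep each map triple well-resolved while letting the whole pipeline —
generation, building, training to high train correlation, evaluation — run
on a single CPU. Degenerate inputs are handled explicitly: all-zero maps
normalize to themselves, $J = 0$ reduces the model to plain
self-attention, coincident atoms only affect intramolecular (not image)
contacts, and Friedel-inconsistent coefficient sets are rejected rather
than silently truncated.

## Known limitations

* P1 orthorhombic cells only; no other space groups, non-90° angles,
  anomalous scattering, or bulk solvent.
* No origin search in map comparison: the pipeline's centering step is
  what licenses direct voxel and phase comparison, so maps from other
  sources must be centered the same way.
* Exact attention only; token counts grow linearly in residue count, so
  very long fragments become expensive.
* The residue template library is a subset of the 20 standard types,
  extensible via text files.
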