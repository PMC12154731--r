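---
title: "Detecting substrate activation from Laplacian electron-density maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting substrate activation from Laplacian electron-density maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lapnet)
```

## The problem

Hydrolases initiate catalysis by a nucleophilic attack on the carbonyl
carbon of their substrate. Along a molecular-dynamics trajectory of the
enzyme-substrate complex, individual frames differ in whether the carbonyl
carbon is *activated*: susceptible to that attack. In the quantum theory of
atoms in molecules, activation is visible in the Laplacian of the electron
density, $\nabla^2\rho(\mathbf r)$. The valence shell of an atom appears as
a closed envelope of charge concentration ($\nabla^2\rho < 0$); a frame is
reactive when a charge-depletion region ($\nabla^2\rho > 0$) breaks that
envelope on the attack side of the carbonyl carbon, exposing an
electrophilic site. A non-reactive frame keeps the concentration envelope
unbroken. The fraction of reactive frames over a trajectory quantifies how
efficiently the active site activates a given substrate.

`lapnet` implements the full per-frame decision pipeline:

1. **wavefunction input** — closed-shell Gaussian-basis wavefunctions in
   Molden format (`read_molden()`, `write_molden()`);
2. **field evaluation** — analytic $\rho$ and $\nabla^2\rho$ on the plane
   through the carbonyl C, the carbonyl O and the nucleophile atom
   (`plane_from_atoms()`, `sample_map()`);
3. **image reduction** — the single zero-isovalue contour, rendered to a
   fixed 960 x 720 canvas and cropped to a 550 x 720 carbonyl-only image
   (`zero_contour()`, `render_map()`, `crop_carbonyl()`);
4. **classification** — a small convolutional network trained with early
   stopping (`cnn_train()`, `cnn_predict()`), cross-checkable against a
   rule-based geometric probe (`classify_map()`);
5. **trajectory statistics** — reactive fraction, run-length and
   randomness analysis of state alternation, confidence summaries, and
   normal-mixture decomposition of nucleophilic-attack distances
   (`reactive_fraction()`, `runs_test()`, `fit_distance_mixture()`).

A synthetic-data module (`make_promolecule()`, `generate_dataset()`)
provides labeled inputs for every stage, so the whole pipeline is testable
without a QM/MM engine.

## Field evaluation

Molecular orbitals are expanded in Cartesian Gaussians
$x^a y^b z^c e^{-\alpha r^2}$ with $a+b+c \le 2$ (s, p and d shells;
spherical d sets are expanded to the Cartesian six on load). Both the
density $\rho = \sum_i n_i \phi_i^2$ and its Laplacian

$$\nabla^2\rho = \sum_i n_i \left( 2\,\phi_i \nabla^2\phi_i
  + 2\,|\nabla\phi_i|^2 \right)$$

use analytic derivatives of the Gaussian product form; no numerical
differentiation occurs in production paths (finite differences appear only
as an independent oracle in the test suite, where the analytic Laplacian
must agree to a relative $10^{-5}$ at non-nuclear points).

Shell normalization differs between wavefunction generators, so shells are
renormalized on load to make every expanded basis function have unit
self-overlap; the test suite pins this convention by integrating the
density of a deliberately unnormalized contraction back to its electron
count.

The evaluation plane is canonical: origin at the carbonyl carbon, the
$u$ axis toward the carbonyl oxygen, and the nucleophile at $v \ge 0$.
This fixes the orientation of every rendered image, which the downstream
image classifier implicitly requires. The default grid spacing is 0.05
bohr (20 points/bohr) with 4 bohr padding; the synthetic-data generator
uses 10 points/bohr, which resolves the valence-shell contour structure at
a quarter of the cost and is the resolution at which all shipped
classifier results are produced.

## Rendering conventions

The renderer is a deterministic array rasterizer with a fixed
plane-to-pixel mapping (60 px/bohr; canvas window $u \in [-6, 6)$,
$v \in [-6, 10)$ bohr), so identical in-plane geometry yields bit-identical
PNG payloads — a property the test suite asserts on reruns and that makes
dataset generation reproducible byte-for-byte. Images show a two-tone fill
by the sign of $\nabla^2\rho$ plus the zero contour line and small atom
discs; a line-only monochrome style is available
(`render_style(fill = FALSE)`). The carbonyl crop keeps the full 720-pixel
height and anchors the C–O midpoint column at a fixed offset, which places
the nucleophile (always on the $v > 0$ side) outside the 550-pixel window;
cropping verifies this and fails loudly otherwise.

## The geometric probe rule

Reference labels come from a formalization of the visual criterion used
when classifying such maps by eye: sample $\nabla^2\rho$ along rays from
the carbonyl carbon toward the nucleophile, fanned $\pm 15^\circ$ (the
depletion pocket can sit slightly off-axis), at radii 0.5–1.3 bohr. After
discarding a leading positive stretch (the tail of the inner
core-depletion annulus), a ray is *broken* when a positive stretch occurs
strictly inside the window before the field re-enters the outer positive
region — or when no concentration stretch remains at all. Any broken ray
makes the frame reactive. The rule is deterministic, auditable (per-ray
sign patterns are returned), and independent of the CNN, so the two
classifiers cross-validate each other.

## Synthetic data: what it emulates, and what it does not

The physical tier builds *promolecular* wavefunctions: atom-centered
spherical Gaussian shells whose parameters are fixed in-code constants
chosen so each atom shows the core-depletion / valence-concentration /
outer-depletion radial topology. Activation is emulated by sp-hybridizing
the carbon valence orbitals away from the nucleophile,
$\phi = \sqrt{1-\lambda}\, s + \sqrt{\lambda}\, p_{\mathrm{away}}$, which
depletes density on the attack side while conserving the electron count
exactly (s and p on one center are orthonormal) and keeping the density
non-negative by construction. The depletion response is monotone in
$\lambda$ on the admissible range $[0, 0.3]$; beyond it the $p^2$ term
starts refilling the attack side, so larger mixings are rejected. Classes
are drawn from disjoint ranges ($\lambda \in [0, 0.04]$ non-reactive,
$[0.12, 0.25]$ reactive, straddling the probe threshold near 0.05), with
0.05 Å geometry jitter, $\pm 10^\circ$ attack-direction jitter and attack
distances uniform in 2.7–3.1 Å — thermal-scale frame-to-frame variability.
Every generated label is checked against the geometric probe on the
underlying map and regenerated on disagreement (above 5% regeneration the
generator aborts; in practice the rate is ~0).

What this does *not* emulate: real QM/MM densities have anisotropic bonding
features, environment polarization, and borderline frames with small or
ambiguous depletion areas. Passing tests on synthetic data therefore
demonstrate that the pipeline machinery is correct and self-consistent,
not that the shipped CNN weights transfer to real enzyme systems — on real
systems the network should be retrained on manually curated maps.

A second, graphical tier draws parametric valence-shell contours (closed
oval vs. oval with an attack-side gap) directly in image space for cheap
classifier tests; both tiers share the same dataset contract.

## The classifier

The network is deliberately small: three valid 3 x 3 convolution blocks
(8/16/32 filters, ReLU, 2 x 2 max-pool), a 32-unit dense layer and one
sigmoid output; binary cross-entropy, Adam at $10^{-3}$, batch 32. Inputs
are the 720 x 550 crops block-averaged by a factor of 10 to 72 x 55 — the
contour topology that separates the classes survives this downscaling, and
it keeps single-CPU training of a 2500-image dataset in the minutes range.
All of these are configurable (`cnn_spec()`).

Training monitors the validation loss with an early-stopping callback:
improvements smaller than `min_delta` (default $10^{-3}$) do not reset the
patience counter (default 5 epochs, 30 epochs maximum), and the returned
weights are always those of the minimal-validation-loss epoch. On cleanly
separable synthetic data the validation loss decreases essentially
forever, so a pure no-improvement rule would never halt; `min_delta`
encodes "has stopped improving materially". Reported scores follow the
conventions: reactive iff the sigmoid output is $\ge 0.5$ (ties reactive),
confidence $= \max(p, 1-p)$.

Layers are implemented as vectorized matrix operations (im2col gathers
with precomputed indices, BLAS products, sparse scatter for the
convolution backward pass); gradients are verified against finite
differences in the test suite.

## Trajectory statistics

* `reactive_fraction()` is the activation efficiency: the mean of the
  per-frame binary labels.
* `runs_test()` formalizes the qualitative claim that reactive and
  non-reactive episodes alternate without regularity: a Wald–Wolfowitz
  runs test conditioned on the state counts. For up to 200 frames the
  exact conditional distribution is used (closed-form combinatorics,
  verified against full enumeration), with a minimum-likelihood two-sided
  p-value; longer series use the normal approximation with continuity
  correction. The empirical type-I error at the 5% level is checked to be
  within 3–7% over 2000 simulated series.
* `fit_distance_mixture()` decomposes nucleophilic-attack-distance
  distributions into $k$ normal components ($k$ is user-chosen; flexible
  complexes need at least three). The EM implementation keeps the best of
  10 seeded restarts, returns the per-iteration log-likelihood trace
  (asserted non-decreasing), prunes degenerate components, and reports
  components sorted by mean; `mixture_bic()` gives BIC guidance over
  candidate $k$. An independent mixture implementation serves as a
  cross-check in the tests.

## Numerical choices and edge cases

* Ties at a raw score of exactly 0.5 classify as reactive.
* Uniformly signed Laplacian maps give an empty contour set, not an error.
* Max-pool ties resolve to the first window slot, keeping training
  bit-reproducible under a fixed seed.
* EM convergence: relative log-likelihood change below $10^{-8}$ or 500
  iterations; components with vanishing variance or weight are pruned and
  flagged rather than crashing the fit.
* Collinear or coincident C/O/Nu atoms are geometry errors; probe rays
  that leave the sampled grid are truncated to it.
* Nuclear-cusp regions (within 0.05 bohr of a nucleus) are excluded from
  finite-difference comparisons, which are ill-conditioned there.

## Study conditions and problem sizes

The shipped acceptance analysis generates a balanced 2500-image synthetic
dataset, splits it 4:1 stratified into 2000 training and 500 validation
images, trains the default network, and evaluates validation accuracy; a
further 500 held-out frames quantify CNN/probe agreement. Mixture recovery
uses 50 replicates of 5000 draws from the three-population attack-distance
mixture (means 2.71/2.88/3.05 Å, weights 0.29/0.42/0.29, common standard
deviation 0.06 Å — the standard deviation is this package's choice, as
component spreads are not part of the published summary).

## Known limitations

* The promolecular generator is topologically realistic, not physically
  realistic: no claim is made that its densities resemble DFT densities
  beyond the zero-contour structure the classifier consumes.
* With components 0.17 Å apart and 0.06 Å wide (2.8 sigma separation),
  mixture *weights* are weakly identified: the maximum-likelihood
  estimator itself has a replicate-to-replicate spread of up to ~0.08 in
  the component weights at $n = 5000$, even though the means recover to
  within 0.02 Å. Tolerances on weight recovery should respect that spread;
  demanding better than ~0.1 from any estimator at these conditions will
  fail for a sizeable fraction of replicates.
* Basis support stops at d shells; f and higher angular momenta are
  rejected explicitly.
* The "on-the-fly" coupling to a running MD engine is an extension point
  (the CLI processes files as they appear); no live engine integration is
  included.
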