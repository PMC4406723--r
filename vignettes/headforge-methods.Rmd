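---
title: "headforge: models, methods, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{headforge: models, methods, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# What this package models

`headforge` is a desk-scale re-implementation of the computational chain
used to build and validate detailed volumetric head models for
electromagnetic simulation: multi-contrast images are co-registered,
segmented into tissue masks, fused across raters into a consensus ground
truth with quantified rater performance, turned into conformal surfaces,
enriched with diffusion-tensor-derived anisotropic conductivity, and used
in quasi-static transcranial-stimulation field simulations.

Real subject MRI is replaced throughout by a synthetic head phantom with
exactly known ground truth. That substitution is the central design
decision: every downstream algorithm can then be validated against exact
expectations instead of against other software.

# The synthetic phantom

`default_head_spec()` describes a toy head of nested ellipsoids — skin,
three skull layers (outer table, diploe, inner table), CSF, grey matter,
white matter, ventricles, and two anterior eye globes. Voxel assignment is
last-writer-wins from outermost to innermost solid, so inner tissues carve
into outer ones; the toy orbits are deliberately carved into the anterior
skull so that they sit beneath a frontal electrode. All geometry is
analytic, which keeps label ground truth exact and removes any dependence
on downloadable data.

Image contrasts (`render_contrast()`) follow
`I(x) = mu(label) * b(x) + e(x)` with a low-order multiplicative bias
field `b` (sum of three low-frequency cosines, amplitude 0 by default —
bias is modelled only so registration can be stressed with it) and
additive Gaussian noise. Rician noise is intentionally not modelled: none
of the pipeline contracts depend on the noise family, and Gaussian noise
admits exact binomial/Gaussian expectations in the tests. The default
noise level (sigma = 3.5 intensity units against tissue means of 70–110)
corresponds to SNR of roughly 20, a conventional value for structural MRI;
the source imaging protocols do not publish their noise statistics, so a
convention was chosen once and kept.

Simulated raters (`simulate_rater()`) implement the exact generative
model that STAPLE assumes in mode A: each true-foreground voxel is marked
with probability `p` (sensitivity) and each background voxel left blank
with probability `q` (specificity), independently. Mode B
(`boundary_jitter_mm > 0`) first displaces the boundary by a smooth random
field, modelling the spatially correlated errors human raters actually
make; it exists to probe robustness, but parameter-recovery targets use
mode A because that is the model STAPLE estimates.

White-matter diffusion tensors (`make_tensor_field()`) are cigar-shaped
(`lambda = (1.4, 0.35, 0.35) x 1e-3 mm^2/s`, FA ~ 0.71) with principal
axes tangent to arcs around the anterior-posterior axis — a toy
corpus-callosum-like arching family. CSF and grey matter are isotropic at
3.0e-3 and 0.8e-3 mm^2/s. Synthetic diffusion-weighted volumes follow the
monoexponential signal equation `S = S0 exp(-b g' D g)` on a 32-direction
spherical-Fibonacci shell at b = 800 s/mm^2 plus one b = 0 volume.

# Segmentation primitives

The segmentation module provides the classic semi-automatic toolbox:
separable Gaussian smoothing with a millimetre kernel width (interpreted
as FWHM by default; the convention in the source tooling is ambiguous, so
`kind = "sd"` is available), Otsu thresholding evaluated exhaustively over
the observed intensity values (threshold placed at the smallest value of
the upper class, which makes the mask invariant under increasing affine
intensity rescaling), 6-connected region growing, 1-D Lloyd k-means on
intensities with ascending-mean relabeling for determinism, morphology
with exact Euclidean-ball structuring elements (computed via the distance
transform), and inter-slice interpolation by linear blending of signed
Euclidean distance fields — endpoints are reproduced exactly and topology
is free to change between slices, which is the property that makes the
interpolation "topologically flexible". Foreground connectivity is
6-connected everywhere; a single consistent topology keeps the surface
module's conformality guarantees simple. A marker-based watershed on the
gradient magnitude is included but flagged experimental: the interactive
original publishes no parameters.

# Registration

`register_affine()` maximizes Studholme normalized mutual information
`(H(A)+H(B))/H(A,B)` over a 12-parameter affine transform
(`T . R . Sh . Sc` about the fixed-image centre; rotations applied
`Rz Ry Rx`). Sixty-four histogram bins span the 1st–99th intensity
percentiles; the similarity is evaluated over a filled and dilated Otsu
head mask — background air carries no alignment information, and leaving
it in both wastes time and dilutes the statistic.

The optimizer is derivative-free and staged, because NMI under linear
interpolation is only piecewise smooth and the nearly axis-symmetric head
creates rotation local minima: a deterministic grid over coarse rotations
is scored at half resolution, the best starts are refined rigidly and
then affinely, and full resolution runs a cyclic coordinate descent whose
line searches combine a bracketing scan (to step over local dips) with
Brent refinement, followed by a Nelder–Mead polish. All stages are
deterministic given the seed.

Registration validation uses `registration_phantom_spec()`, which adds
four small asymmetric intra-cranial marker ellipsoids: nested ellipsoids
alone leave scale and shear weakly constrained, and real heads do contain
asymmetric internal landmarks. The simulated second acquisition is
rendered on the warped label grid (`render_moving_acquisition()`) rather
than interpolated from the first rendering — interpolating would imprint
pose-correlated smoothness that biases any intensity-based similarity.

# STAPLE consensus

`staple()` is the binary expectation-maximization estimator: the E-step
posterior uses the current sensitivities/specificities and a prevalence
prior in log space, the M-step re-estimates `(p_j, q_j)` from the
posterior, and the observed-data log-likelihood trace is checked to be
non-decreasing on every run. Initialization is the classic
`p = q = 0.9999`; estimates are clipped to `[1e-5, 1 - 1e-5]`. Ties at
`W = 0.5` go to foreground, which keeps the consensus mask deterministic.

The prior deserves a note. The default is a fixed global prevalence equal
to the mean foreground fraction across raters. When raters have low
specificity over a large volume, that fraction overestimates the true
prevalence and biases the recovered sensitivities by a few percent;
`prior_mode = "estimated"` re-estimates the prevalence each iteration and
recovers the generative parameters essentially unbiasedly, so
parameter-recovery studies use it. A mean-field spatial option (the prior
replaced by a locally averaged posterior) realizes the "spatial
homogeneity" idea mentioned for the original consensus runs, whose exact
formulation is unpublished; it is off by default and both options are
declared alternatives, not reconstructions.

# Validation metrics and statistics

Dice is `2|A n B| / (|A| + |B|)`. The modified Hausdorff distance is the
maximum of the two directed mean nearest-neighbour distances between
boundary voxel centres, in mm; boundary voxels (those with an exposed
face, 6-neighbourhood) are used because the distance is explicitly a
boundary-matching measure, with a full-mask variant behind a flag for
sensitivity analysis. Whether the original comparisons used 2D in-plane
or 3D distances is unstated; both are supported and the tests pin the 3D
boundary default. Kruskal–Wallis uses midranks with tie correction and a
chi-square approximation (an exact permutation null is available for
total n <= 10); Lilliefors computes the KS statistic against a normal
with estimated moments and takes its p-value from a seeded Monte-Carlo
null. No multiple-testing correction is applied anywhere, matching the
original analysis. `variability_study()` assembles the
structures-by-raters Dice/MHD table against the STAPLE ground truth, the
machine-readable analogue of the published inter-operator tables.

# Surfaces

`extract_interfaces()` replaces the original Delaunay-refinement front
end with direct voxel-interface extraction: two triangles per voxel face
separating different labels, vertices on the voxel-corner lattice shared
across all regions. Conformality is therefore structural — an interface
triangle exists once, tagged with its (inside, outside) label pair — and
each region's surface is closed by construction. Taubin smoothing
(lambda = 0.5, mu = -0.53, 10 iterations; the classic non-shrinking pair,
the original publishes no parameters) moves the single shared vertex set,
so interfaces cannot separate. Simplification collapses short edges
(volume-preserving collapse placement in the interior of an interface
patch; junction-curve vertices only absorb less-constrained neighbours)
and flips diagonals when the minimum angle improves, rejecting any
operation that would flip a normal, create a degenerate triangle, break
tag consistency, open the surface, or introduce a self-intersection
(exact triangle–triangle tests on spatial-hash candidate pairs). Adaptive
sizing scales the local target edge by the region thickness recorded at
extraction time (`min(target, 0.5 x thickness)`), the declared realization
of a "non-uniform sizing field". The audit reports watertightness,
orientation consistency, Euler characteristic, signed volume,
self-intersection count and triangle quality, and is asserted after every
stage in the tests.

One honesty note on "watertight": voxel-face extraction of a shell only
one voxel thick necessarily produces pinched non-manifold edges wherever
same-label voxels touch diagonally (four faces share one lattice edge).
This is a property of voxel boundaries, not of the processing. The audit
therefore distinguishes strict 2-manifold watertightness (every edge on
exactly two triangles — guaranteed for pinch-free, thick regions) from the
weaker `closed` property (every boundary is a boundaryless,
orientation-balanced 2-cycle — guaranteed for every region and preserved
by smoothing and simplification). Shell regions also have Euler
characteristic 2k for k nested boundary components, not 2; only ball-like
regions are topological spheres.

# Diffusion tensors and conductivity

Tensor fitting is plain log-linear least squares of
`ln S = ln S0 - b g' D g` (7 unknowns per voxel); voxels with
non-positive signals are dropped, and negative eigenvalues are clamped to
1e-6 mm^2/s with a conditioning flag. No weighted or robust variants are
offered: the basic estimator keeps the noiseless round trip with the DWI
synthesizer exact to machine precision, which is the module's primary
oracle.

Conductivity mapping is the standard linear eigenvalue scaling
`sigma = k D` with `k = 0.844 S s/mm^3` (the literature coefficient; the
source only states that a linear relationship was used, so `k` is
configurable). Units matter: `k D` is in S/mm, and a `unit_gain` of 1000
converts to S/m. Eigenvalues are clipped to `(0, 1.8]` S/m — the CSF
conductivity cap — applied to eigenvalues rather than components so
positive-definiteness survives; eigenvectors are untouched. With these
defaults CSF diffusivity maps above the cap and is clipped exactly to the
CSF value, which is the behaviour that motivated the cap in the first
place. Voxels outside the DTI mask receive per-tissue scalar fallbacks.

# Quasi-static solvers

At 10 Hz the quasi-static approximation holds and conductivities are
purely real. Two discretizations mirror the two solver families used with
full head models:

* `solve_voxel()` — 7-point finite volumes, face conductance
  `harmonic_mean(sigma_i, sigma_j) x area / distance`, Dirichlet electrode
  voxels, zero-flux outer boundary. Scalar and diagonal tensors only.
* `solve_fem()` — each voxel split into 6 Kuhn tetrahedra (conformal
  across faces), linear elements, element stiffness `V G' sigma G` with
  the tensor sampled at element centroids; full anisotropic tensors.
  First-order elements replace the original second-order cells — a
  declared desk-scale accuracy trade-off, covered by the refinement
  convergence test.

Both reduced systems are SPD and solved by incomplete-Cholesky
preconditioned conjugate gradients (C++ core) to a relative residual of
1e-8; the true residual is recomputed and asserted. The sparse direct
factorizations available in this environment proved orders of magnitude
slower on these 3D grids, so the conjugate-gradient design was kept and
the tolerance contract checked explicitly. Electrode currents come from
discrete flux sums (finite volumes) or nodal reactions (FEM), and global
current conservation holds to solver precision. Electrodes are
potential-controlled Dirichlet patches; current-controlled stimulation is
a post-hoc rescaling by linearity. Montage presets place angular patches
about 10-20-like directions on the phantom scalp (Fpz-Cz: two large
25-degree patches; Cz-ring: five small 12-degree patches); real
10-20 digitization is out of scope.

Two numerical subtleties are worth recording. First, the FEM fixes all
corner nodes of electrode voxels, so a bar of `nz` voxels has the same
effective plate gap as a finite-volume bar of `nz - 1` voxels; the
cross-solver agreement test matches geometries accordingly. Second, a
two-layer bar whose interface lies on a voxel face is solved exactly by
the harmonic-mean scheme at any resolution, which would make a
"refinement decreases the error" check vacuous; the convergence test
therefore places the interface strictly inside a voxel so a genuine O(h)
error exists and shrinks under 2x and 4x refinement.

# What a green test establishes — and what it does not

The phantom is analytic and the raters follow STAPLE's own generative
model, so green tests establish that the algorithms are implemented
correctly and recover known ground truth under their stated assumptions.
They do not establish anatomical realism, nor do they reproduce the
published inter-operator agreement numbers or the ~25% anisotropic field
reduction: those quantities are properties of three specific human
raters' outlines and of a full-resolution subject model, neither of which
is available at desk scale. The end-to-end tests instead mirror the
qualitative findings — equal raters are statistically indistinguishable,
the frontal montage drives more current through the eyes than the ring
montage, and anisotropic brain conductivity changes the predicted brain
field (weakening it on this phantom).

# Known limitations

* The phantom's tissues are smooth ellipsoids; algorithms whose failure
  modes need thin, folded, or fragmentary geometry (cortical folds, dura)
  are only exercised by their guard rails, not stressed.
* Registration accuracy is quoted for the marker-bearing phantom; a
  featureless nested-ellipsoid head genuinely under-constrains scale and
  shear and will register worse.
* The voxel solver rejects non-diagonal tensors rather than
  approximating them; that split of responsibilities is intentional.
* Multi-category STAPLE, deformable registration, eddy-current
  correction, tractography, and atlas-based segmentation of deep nuclei
  are out of scope.
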