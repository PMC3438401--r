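---
title: "Validating micro-FE models of cement-augmented trabecular structures by deformed-morphology comparison"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating micro-FE models of cement-augmented trabecular structures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Micro-finite-element (micro-FE) models built from micro-CT images resolve
individual trabeculae and, in cement-augmented bone, the interdigitated
cement-bone composite at the interface. Validating such models is hard:
surface meshes are irregular, classical strain-field registration does not
apply directly, and specimen-level stiffness alone says little about whether
the *local* deformation is right. `trabevalid` implements a complete,
testable version of a validation methodology built around one idea: image the
specimen in the loaded state, rasterize the FE-predicted deformed geometry
back into image space, and compare the two *pixel by pixel*.

For a pixel inside the registered comparison region,

* model solid, scan background → **false positive** (FP),
* model background, scan solid → **false negative** (FN),

and the total error is the sum of FP and FN pixels as a fraction of the solid
(trabecular and cement) pixel count. Because no public micro-CT data set of
cement-augmented foam specimens exists, the package includes a first-class
synthetic specimen generator and imaging emulator, so every stage of the
pipeline runs against a known ground truth.

## Synthetic specimens

`generate_foam_lattice()` emulates the open-cell rigid polyurethane foam used
as an osteoporotic-bone surrogate: cylinders of ~6 mm diameter and ~12 mm
height, porosity above 95%, cell size 1.5–2.5 mm, strut thickness
0.15–0.3 mm. The lattice is the edge skeleton of a Poisson–Voronoi
tessellation:

1. Seed points with mean spacing drawn once per specimen from the cell-size
   range are scattered in and around the cylinder (the margin guarantees that
   struts cross the end planes, so the network is loadable).
2. Nearest-seed labels are computed at scan resolution through a Euclidean
   feature transform; grid corners where three or more Voronoi cells meet
   form the strut centrelines, four or more marking cell vertices.
3. Each strut (identified by its cell triple) is dilated to its own thickness
   drawn from the strut-thickness range, stamped half a voxel thin to
   compensate the ~1-voxel width of the discrete centreline tube.

Two numerical choices matter here. First, thickness sampling is
*pre-narrowed*: a trial stamping at the thinnest strut measures how much edge
length the draw produced, and the upper end of the sampling range is lowered
so the expected solid fraction is about 4.6%. Sampling the full range and
shrinking afterwards would, for small-cell draws, require a global shrink far
below the nominal thickness range; the narrowing keeps the correction small.
Second, porosity is enforced exactly: solid voxels carry the ratio
`distance / strut radius`, so the minimal global shrink that reaches the
porosity bound is an order statistic of those ratios, not an iterative
search. The shrink refuses to push strut radii below one voxel. Finally, only
the dominant connected component is kept (clipping at the cylinder wall can
strand a few voxels) and the generator errors if it fails to touch both end
planes.

The generator is a pure function of its parameters and seed; every operation
downstream inherits that determinism.

## Imaging emulator

`emulate_uct()` maps labels to class mean intensities, blurs with an
isotropic Gaussian point-spread function and adds per-class Gaussian noise.
The defaults (background/bone/cement/marker means 25/105/155/230, noise SDs
6/8/8/5 on an arbitrary 8-bit-like scale, PSF sigma 15 µm at 25 µm voxels)
were chosen once to reproduce the qualitative behaviour of foam-and-PMMA
scans: the bone and cement gray-level distributions overlap visibly (the
histogram valley between the two material modes stays a few percent of the
peaks), yet a two-threshold segmentation of a default scan still recovers the
ground truth with Dice ≥ 0.90 for bone and ≥ 0.95 for cement. What the
emulator deliberately does **not** model: beam hardening, ring artifacts, and
reconstruction noise correlations. Passing tests therefore demonstrate the
pipeline's behaviour under partial-volume blur and additive noise, not under
scanner-specific artifacts.

## Segmentation

Scans are converted to model resolution by block-mean downsampling
(`downsample_mean()`, 25 µm → 50 µm by default), which preserves the
partial-volume information that thresholding acts on; the thresholds
themselves come from three-class between-class-variance maximization
(`auto_thresholds()`, a multi-level Otsu) and are always overridable.
Intensity equal to a threshold goes to the upper class. Manual slice-by-slice
refinement of the segmentation is out of scope; its automated stand-in is
`connectivity_filter()`, which removes solid components below a voxel-count
floor and refuses to proceed if that would delete more than 20% of the solid
phase (a symptom of bad thresholds). The known cost of automated
segmentation is local: peak von Mises stress is sensitive to the sharp
corners that manual editing would smooth, so reported stress maxima should be
read with that caveat; stiffness and morphology are far less affected.

## Boundary conditions

Loading is displacement-controlled compression. The displacement of each
specimen end is estimated exactly as an operator would from the images: at
least five landmark points per end, matched by index between the unloaded
and loaded scans, and averaged componentwise (`compute_end_displacements()`).
The signed componentwise mean (rather than a mean of magnitudes) is the
package's documented choice. Platen twist is not estimated. The nominal
strain recorded by `build_boundary_conditions()` is the relative axial end
displacement over the specimen height; load increments default to ~3%, ~5%
and ~15%.

## The micro-FE model

`build_mesh()` converts a 50 µm label volume into one 8-node hexahedral
element per solid voxel — the standard micro-FE discretization — with
cement-bone interface faces enumerated. Smoothed tetrahedral meshes are the
common alternative at this scale; voxel hexahedra give uniform element
stiffness templates and a matrix-free solver, and the unloaded-state
calibration absorbs the geometric difference between the mesh and the scan
either way. Materials are homogeneous and linearly elastic, E = 280 MPa (foam)
and 2280 MPa (PMMA), Poisson's ratio 0.3 for both.

* **Constraints.** Both end faces get all three displacement components
  prescribed ("clamped", the default — the ends are embedded in cement
  against the platens). An "axial" mode (z only, plus minimal lateral
  rigid-body pins chosen to be consistent with uniform uniaxial stress) is
  reserved for verification problems such as the EA/L and springs-in-series
  checks; marker voxels isolated in background are excluded from the mesh,
  and free-floating solid components are dropped with a message.
* **Interfaces.** `tied` shares nodes across the cement-bone boundary.
  `frictionless_penalty` duplicates interface nodes and couples only the
  face-normal component of each duplicated pair with penalty springs
  (default 100 · E_cement · h per face), a linearization of small-sliding
  frictionless contact; tangential sliding stays free, so the penalty limit
  closes the normal gap but is not the tied solution. Coulomb friction is a
  non-goal (nonlinear).
* **Solver.** Jacobi-preconditioned conjugate gradients with element-by-element
  matrix-free products; deterministic ordering. The iteration starts from the
  affine interpolation of the end displacements, which satisfies the
  constraints exactly and leaves only the strut-scale deviation to the
  solver. The default tolerance is 1e-8 (relative residual); pipelines use
  1e-6, at which the energy-based stiffness is converged to ~0.02% on the
  desk-scale specimen.
* **Outputs.** Centroid stresses (the centroid strain-displacement matrix,
  equal by symmetry to the 2×2×2 Gauss average), element von Mises stress
  with the element layers adjacent to the Dirichlet faces excluded from the
  reported maximum (constraint singularities), end reactions, and the
  apparent stiffness. Two stiffness estimates are reported: the axial
  reaction over the relative end displacement, and the work identity
  `k = uᵀKu / Δu²`, which is variational and far less sensitive to the
  residual; pipelines report the latter.

Solutions are linear in the boundary data, so pipelines solve once per
interface model at the first non-zero increment and scale; the test suite
verifies that solutions at ~3% and ~5% strain are scalar multiples to 1e-8.

## Deformed-morphology validation

`warp_labels()` carries every solid voxel's hexahedron through its eight
nodal displacements, splits it into six tetrahedra sharing the main diagonal,
and rasterizes into the scan-resolution grid with 2× supersampled pixel
centres: a pixel is solid when at least half its sample points fall inside
the deformed solid, cement taking priority over bone on overlap. Inverted
(negative-volume) tetrahedra raise a warning naming the first affected
elements — the signal that the applied field exceeds what linear kinematics
can represent. Fiducial markers are warped alongside and re-painted on top.

Comparisons run at three sagittal stations (`slice_plan()`): the x-positions
of the three marker centroids when markers are present, or 25/50/75% of the
specimen width otherwise, each a single-pixel slice at the nearest voxel
plane, restricted to the cylinder-chord region mask. Marker pixels are
excluded from all counts. The denominator is the solid pixel count *of the
scan slice* within the region, so errors are expressed relative to the
observed structure (which image supplies the denominator is a genuinely
open convention; the scan-side denominator is this package's documented
choice).
`calibrate_unloaded()` applies the identical machinery to the unloaded model
and scan, measuring the baseline error of model generation (segmentation +
downsampling + voxel remeshing) before any load.

## The closed loop, and what it shows

With no deposited scans of loaded specimens, the package validates itself in
a closed loop: the loaded "experimental" scan is synthesized by warping the
*ground-truth* labels through the solved displacement field (extended off the
mesh by nearest-node lookup and trilinearly resampled to the scan grid),
imaging them with fresh noise, and segmenting with the unloaded thresholds.
The comparison between the FE-predicted deformed slices and these scans then
carries every real error source this pipeline has — segmentation noise,
model-vs-truth geometry differences, rasterization — except one: the physical
specimen always deforms exactly as the elastic model predicts. Inelastic
reality is emulated separately by `collapse_field()`, a sigmoidal crush band
added to the experimental side only, whose amplitude grows with strain; the
tests require the morphology error to then increase strictly across
increments, reproducing the qualitative degradation expected once foam
struts yield.

Passing the closed loop therefore demonstrates that model generation,
solving, rasterization and the metric are mutually consistent at realistic
noise levels — not that a linear elastic model tracks a real specimen at 15%
strain (it does not; that is precisely what the metric is designed to
expose).

## Problem sizes and defaults

The shipped study conditions use a 4 mm × 8 mm scaled specimen (cement caps
4/3 mm deep at each end, scan at 25 µm, model at 50 µm), giving roughly
300 000 elements and one million degrees of freedom — large enough for the
caps, the interdigitated composite and a free trabecular mid-section to all
exist, small enough for a single-CPU workstation run in minutes. The
generator sweep for the porosity bound uses the full 6 mm × 12 mm specimen.
Landmark picking noise defaults to 12.5 µm (half a scan voxel) with 8 points
per end.

## Known limitations

* Linear, small-strain kinematics: the ~15% increment is outside the model's
  validity by design, and inverted-tetrahedron warnings should be expected
  there.
* The frictionless interface is a penalty linearization; Coulomb friction
  and true contact search are out of scope.
* The imaging emulator does not model reconstruction artifacts; thresholds
  transfer from the unloaded scan to loaded scans, which assumes stable gray
  levels across increments.
* Peak stress depends on segmentation sharpness far more than stiffness or
  morphology; automated segmentation can overestimate local maxima.
* The synthetic foam is a Voronoi strut lattice: real Sawbone foam has
  plate-like elements and thickness variation along struts that the
  generator does not reproduce.
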