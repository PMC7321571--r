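---
title: "Measuring full-field strain at the cartilage-bone interface: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring full-field strain at the cartilage-bone interface: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The measurement problem

Digital volume correlation (DVC) estimates the internal displacement field
between two three-dimensional grayscale images of the same specimen — here,
micro-CT volumes of osteochondral (cartilage-bone) plugs — by tracking the
gray-level pattern of small cubic sub-volumes from one image to the other.
Differentiating the displacement field yields the full-field strain tensor,
which is the quantity of biomechanical interest: how load applied at the
articular surface is transferred through articular cartilage and the
calcified interface into subchondral bone.

Because DVC measures pattern motion, its precision depends entirely on the
quality of the trackable texture (chondrocyte and osteocyte lacunae,
trabecular structure) relative to the noise. Any DVC result therefore needs
an accompanying *uncertainty analysis*: correlating image pairs whose true
strain is known (zero, or an imposed virtual deformation) and summarizing
the apparent strain as error statistics. This package implements the full
chain — phantom generation, preprocessing, the correlation engine, strain
computation, the two error protocols, and micro-indentation reductions —
in one coherent toolkit.

# The correlation engine

## Model

For each node of a cubic grid, a sub-volume of edge $s$ voxels from the
reference image is matched in the deformed image by zero-normalized
cross-correlation (ZNCC)

$$
C(\mathbf{o}) \;=\;
\frac{\sum_{\mathbf{x}} \bigl(f(\mathbf{x}) - \bar f\bigr)
      \bigl(g(\mathbf{x}+\mathbf{o}) - \bar g_{\mathbf{o}}\bigr)}
     {\sqrt{\sum_{\mathbf{x}} \bigl(f(\mathbf{x}) - \bar f\bigr)^2}\;
      \sqrt{\sum_{\mathbf{x}} \bigl(g(\mathbf{x}+\mathbf{o}) -
            \bar g_{\mathbf{o}}\bigr)^2}},
$$

evaluated for all integer offsets $\mathbf{o}$ inside a search window. The
numerator is computed spectrally (`fft`), the local window sums by
integral images, so a full correlation map costs three FFTs per node. The
integer peak is then refined per axis by a three-point Gaussian fit on the
correlation values $(C_{-1}, C_0, C_{+1})$,

$$
\delta = \frac{\ln C_{-1} - \ln C_{+1}}
              {2(\ln C_{-1} + \ln C_{+1} - 2 \ln C_0)},
$$

with an ordinary parabola as fallback when a neighbor is non-positive.
This rigid-sub-volume, local-approach formulation is the standard
equivalent of commercial local DVC codes; no attempt is made to replicate
any proprietary weighting or outlier replacement.

## Multipass predictor scheme

`dvc()` runs a sequence of strictly decreasing sub-volume sizes (default
80-72-64-56-48 voxels). Each pass seeds the next by trilinear
interpolation of its displacement field onto the finer node layout, so
the later, smaller sub-volumes only search a ±4-voxel neighborhood around
an already good prediction. The first pass, having no predictor, searches
±half its sub-volume size. The uncertainty protocols call single-pass DVC
with a fixed ±8-voxel window instead: their inputs are registered pairs
(zero strain) or sub-voxel synthetic deformations, so displacements are
bounded by a few voxels and a half-sub-volume search would only waste
time and admit spurious distant peaks.

## Validity rules

A node is invalid (excluded from all statistics, never interpolated
silently) when any of the following holds:

* the reference sub-volume is flat: its contrast (standard deviation)
  falls below $10^{-4}$ of the local gray level, a floor below which
  "texture" is indistinguishable from arithmetic ripple;
* the correlation peak lies on the border of the *requested* search
  range, where the true peak may be outside (a peak pressed against the
  *image* boundary, by contrast, is the physical measurement limit and is
  kept, with sub-voxel refinement skipped on that side);
* the peak correlation coefficient is below `cc_min` (default 0.1);
* the sub-volume overlaps voxels flagged as resampled from outside the
  image domain (see the synthetic-deformation protocol below).

Two numerical guards matter in practice. First, window sums are computed
on the mean-subtracted window, and correlation values are clamped to
$[-1, 1]$: with gray levels near 200 and near-flat windows, naive
integral-image variances suffer catastrophic cancellation and can push
$C$ above 1. Second, when the integer peak is numerically perfect
($C_0 \ge 1 - 10^{-9}$), sub-voxel refinement is skipped: a perfect match
has zero residual offset by definition, and fitting a Gaussian through
the asymmetric round-off of the neighbors would inject spurious sub-voxel
noise. This guard is what makes the zero-strain identity protocol return
exactly zero. Ties between equal integer peaks are broken toward the
smallest displacement magnitude, then lexicographically.

# Strain and the von Mises equivalent

`compute_strain()` differentiates the nodal displacements by central
differences on the node grid (one-sided at grid borders and beside
invalid nodes), forming the small-strain tensor
$\varepsilon_{ij} = \tfrac12(\partial_j u_i + \partial_i u_j)$ in
microstrain (µε, strain × 10⁶; compression negative). Central differences
are exact for affine displacement fields, which is what makes the
synthetic-deformation protocol a closed-loop check. The choice of a
finite-difference scheme (rather than, say, local shape-function fits) is
an assumption of this implementation; the commercial chain never states
its scheme.

The scalar summary is the von Mises equivalent strain computed from the
deviatoric normal components and engineering shears:

$$
e_{xx} = \tfrac23\varepsilon_{xx} - \tfrac13\varepsilon_{yy}
       - \tfrac13\varepsilon_{zz}, \qquad
\gamma_{ij} = 2\varepsilon_{ij},
$$

$$
\varepsilon_{eq} = \frac{2}{3}
 \sqrt{\frac{3\,(e_{xx}^2 + e_{yy}^2 + e_{zz}^2)}{2}
     + \frac{3\,(\gamma_{xy}^2 + \gamma_{xz}^2 + \gamma_{yz}^2)}{4}}.
$$

$\varepsilon_{eq}$ is nonnegative, insensitive to hydrostatic offsets,
and scales linearly with the tensor; `equivalent_strain(c(0, 0, -10000,
0, 0, 0))` returns 6666.7 µε and a pure shear $\gamma_{xy}$ of 1000 µε
returns $1000/\sqrt3 \approx 577.35$ µε — both asserted to $10^{-6}$
relative in the tests.

# Uncertainty protocols

Both protocols summarize a strain field per tissue region and sub-volume
size with the error statistics used throughout the DVC literature: per
valid node $k$ the scalar

$$
a_k = \frac16 \sum_{c \in \{xx,yy,zz,xy,xz,yz\}}
      \lvert \varepsilon_c(k) - \varepsilon_c^{true}(k) \rvert ,
$$

then $\mathrm{MAER} = \operatorname{mean}_k a_k$ and
$\mathrm{SDER} = \operatorname{SD}_k a_k$. This "average of the absolute
values of the six components per point, mean and SD over points"
convention is the single most important interpretation fixed by this
package, since the originating literature names the quantities without
writing them.

* **Zero-strain** (`zero_strain_test()`): two repeated acquisitions of an
  undeformed specimen, $\varepsilon^{true} \equiv 0$; any output is
  measurement error.
* **Synthetic deformation** (`make_synthetic_pair()` +
  `synthetic_deformation_test()`): the second volume is virtually
  compressed along z by the affine map $\mathrm{diag}(1, 1, 1-s)$ about
  the image center (default $s = 0.01$, i.e. −10 000 µε) and resampled
  with a Lanczos kernel of order $a = 3$ (the interpolant is named in the
  protocol, the order is this package's choice of the common default).
  Voxels whose source point falls outside the image are zeroed and
  flagged, and the correlation engine masks any sub-volume overlapping
  them — correlating tissue texture against padding would otherwise
  corrupt the outermost node layers. The analytic truth
  $\varepsilon_{zz} = -s$ makes MAER/SDER meaningful and lets the
  protocol also report the mean recovered $\varepsilon_{zz}$ per region.

Regions are defined by strict inclusion: a node counts toward articular
cartilage (or mineralized tissue) only when its entire sub-volume lies in
voxels of that label, so interface-straddling nodes belong to neither.
Per-region entries at a size with no valid node are reported as absent
(NA), never as zero. The size sweep runs each size as an independent
single-pass analysis by default — whether the original protocol used
multipass at every size is not documented; single-pass is the cleaner
probe of size dependence, and the multipass configuration is used for the
final strain maps. Equivalent-strain distributions are summarized by
`strain_histogram()` with a default bin width of 100 µε (binning is
unstated in the source protocol; 100 µε resolves the reported peak
locations without starving the bins).

# The synthetic phantom: what it emulates, and what it does not

`generate_phantom()` builds a deterministic stand-in for a cartilage-bone
micro-CT scan (no real scans are distributed): a two-region slab with

* a rough interface — a smooth random relief (SD 10 µm) on the nominal
  cut at `interface_z_fraction` (default 0.5) of the height, with z the
  compression axis;
* dark ellipsoidal lacunae in both regions, drawn as a Poisson process:
  defaults of 5 × 10⁴ mm⁻³ in cartilage (chondrocyte lacunae) and
  4 × 10⁴ mm⁻³ in mineralized tissue (osteocyte / hypertrophic
  chondrocyte lacunae), semi-axes uniform in 2–6 µm with random
  orientation, clipped to their host region. These are literature-scale
  values for adult bovine tissue, stated as assumptions: the source
  imaging study shows but never quantifies lacunar density, size or
  contrast;
* gray levels (background 20, cartilage 90, mineralized 180, lacunae 40
  on an 8-bit-like scale), an isotropic Gaussian detector point-spread
  function (`psf_sigma`, default 0.7 voxels) applied to the noiseless
  structure, then additive Gaussian acquisition noise (default SD 5).
  The PSF is essential, not cosmetic: real tomograms are band-limited by
  the source spot, detector and reconstruction kernel, and a voxel-sharp
  binary phantom exhibits aliasing-driven peak-locking that no real scan
  shows;
* optional edge-enhancement fringes (amplitude ×
  z-derivative of the Gaussian-blurred mineralized-phase indicator),
  mimicking the bright/dark banding of propagation-based phase contrast.
  This is a phenomenological surrogate — no Fresnel propagation,
  polychromatic beam or reconstruction-artifact physics is simulated.

The voxel size defaults to 2 µm, matching the imaging conditions the
protocol targets. Not modeled: depth-dependent chondrocyte organization,
trabecular architecture below the subchondral plate, ring or
beam-hardening artifacts, and the spatial noise correlation of filtered
back projection. Consequently, passing tests on phantoms demonstrates
that the *pipeline* is correct and that its error protocols behave as
expected (errors shrink with sub-volume size, synthetic error exceeds
zero-strain error); they do not predict the absolute uncertainty of any
particular scanner or tissue, which is precisely why the error protocols
exist to be run per dataset.

# Preprocessing choices

* **Rigid registration** (`register_rigid()`) maximizes normalized mutual
  information, NMI $= (H_1 + H_2)/H_{12}$, on a 64-bin *partial-volume*
  joint histogram (each sample linearly weighted into adjacent bins) —
  with hard binning the metric is too jagged for sub-voxel refinement.
  The optimizer is an FFT cross-correlation for the integer-translation
  start, followed by multi-start Nelder-Mead over translation and
  rotation on a two-level pyramid. Near-integer solutions (within 0.1
  voxel and 0.06°) are snapped to the grid when NMI is within 5%: on
  low-entropy (quasi-binary) images, interpolation mixing can inflate
  NMI by around a percent *off* grid even though the exact alignment is
  correct, and the 0.1-voxel gate bounds the snap error regardless. That pathology is also this metric's
  main limitation: sub-voxel NMI registration is reliable on volumes with
  continuous gray histograms (noise, texture), and accurate to ~0.1 voxel
  and ~0.2° there, but degrades on noiseless piecewise-constant data.
* **Denoising** (`denoise_anisotropic_diffusion()`) is conservative
  (flux-form) Perona-Malik diffusion with the exponential conductance
  $g(d) = e^{-(d/\kappa)^2}$; the mean gray value is conserved exactly
  and edges move by less than a voxel over the default 10 iterations.
  $\kappa$ (gray units) and the step (stability bound $\lambda \le 1/6$
  in 3D) are exposed because the original chain documents none of them.
* **Labeling** (`segment_regions()`) floods the gradient-magnitude image
  with a marker-controlled watershed (priority-flood, 6-connectivity,
  written for this package as no installed 3D marker-controlled
  implementation was available). Markers default to the cores of
  multi-level Otsu classes — voxels between a class mean and halfway to
  the neighboring threshold — and explicit markers always win. The
  pipeline order (register → denoise → segment) follows the narrative
  order of the original post-processing description.
* **Marrow zeroing and VOI cropping** are exact index operations;
  cropping centers with the floor convention (`start = floor((dim -
  side)/2) + 1`).

# Indentation metrics

Flat-punch load-displacement records are segmented into loading / hold /
unloading by a plateau band (default 1% of maximum load). Contact
stiffness is the least-squares slope $S = dP/dh$ over the top fraction of
the unloading load range; "initial stage of the unloading" is quantified
as the top 20% by default — a choice this package makes explicit because
the protocol gives no fraction. Hardness is maximum force over contact
area in MPa, with the nominal flat-punch base area (50 µm × 50 µm =
2500 µm²) as default. Note the area-definition sensitivity: 45 mN over
the nominal base area gives 18 MPa, an order of magnitude above
hardnesses reported for hydrated articular cartilage with effective
(calibrated) contact areas; the contact area is therefore a user-supplied
parameter, not something this package can infer. Unconfined-compression
records reduce to nominal stress $F/(\pi d^2/4)$ and strain
(displacement over cartilage thickness), with stress relaxation measured
across the displacement hold.

# Numerical and scale choices in the tests

Voxel coordinates are 1-based (R convention) with the image center at
$(\mathrm{dim}+1)/2$; all reported quantities (displacements, strains)
are origin-independent. The test suite exercises the full
synthetic-deformation protocol on a 240³-voxel phantom (the smallest
volume that gives a 5×5×5 node grid at the final 48-voxel sub-volume with
a clean interior), the zero-strain identity sweep on 160×160×240, and the
error-trend comparison at sub-volume sizes 16 and 80 on the 240³ phantom
with independent noise realizations. Unit tests run on 32³–128³ volumes.
Under these conditions the multipass pipeline recovers the imposed
−10 000 µε axial strain within a few percent, with MAER against the
analytic truth of order 100 µε at the 48-voxel sub-volume.

# Known limitations

* Rigid sub-volume tracking assumes the pattern moves as a block; where
  the displacement varies within a window (strain gradients, or windows
  containing the fixed plane of the virtual compression) the recovered
  displacement is biased toward the locally dominant integer shift.
  Multipass reduces, but does not remove, this bias; shape-function DVC
  (affine windows) would, and is out of scope.
* The Gaussian three-point sub-voxel estimator has a small residual
  S-curve (peak-locking) bias, about 0.02 voxels on the default phantom
  texture.
* NMI registration degrades on noiseless quasi-binary volumes (above).
* The phantom's realism limits are listed in its own section; absolute
  MAER/SDER values on phantoms do not transfer to any particular scanner.
* No finite-strain (Green-Lagrange) formulation, no stress computation,
  no GPU path, and no deformable registration.
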