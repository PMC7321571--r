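# cartidvc

Full-field strain measurement and uncertainty quantification for
cartilage-bone volumetric image pairs.

Digital volume correlation (DVC) tracks the natural gray-level texture of
micro-CT volumes — chondrocyte and osteocyte lacunae, trabecular
structure — between two acquisitions of the same specimen, yielding the
internal 3D displacement field and, by differentiation, the full strain
tensor field. At the cartilage-bone interface this is the only way to
observe how load applied to the articular surface is transferred through
the calcified cartilage into subchondral bone. Because the measurement
rides on image texture, every DVC study needs an uncertainty analysis on
image pairs whose true strain is known; this package implements both the
measurement chain and those error protocols, for imaging scientists and
biomechanics researchers working with lab or synchrotron micro-CT.

## What it computes

* **Local multipass DVC** (`dvc()`): cubic sub-volumes matched by
  FFT-accelerated zero-normalized cross-correlation with three-point
  Gaussian sub-voxel refinement; a descending size chain
  (80-72-64-56 → 48 voxels by default) in which each pass seeds the next.
  Returns a fitted object with `print`, `summary`, `plot`, `predict` and
  `residuals` methods.
* **Strain tensor and von Mises equivalent strain** (`strain()`,
  `equivalent_strain()`): central differences on the node grid, then

  ε_eq = (2/3) √( 3(e²ₓₓ+e²ᵧᵧ+e²_zz)/2 + 3(γ²ₓᵧ+γ²ₓz+γ²ᵧz)/4 ),

  with deviatoric components e_ii = (2/3)ε_ii − (1/3)ε_jj − (1/3)ε_kk and
  engineering shears γ_ij = 2ε_ij, reported in microstrain (µε).
* **Uncertainty protocols** (`zero_strain_test()`,
  `synthetic_deformation_test()`): MAER/SDER per tissue region per
  sub-volume size, where per node a = mean |six strain components −
  truth|; zero-strain pairs have truth 0, synthetic pairs are created by
  `make_synthetic_pair()` as a virtual 1% axial compression
  (diag(1, 1, 0.99) about the image center, Lanczos resampling) with
  analytic ground truth.
* **Preprocessing**: NMI rigid registration (`register_rigid()`),
  Perona-Malik denoising (`denoise_anisotropic_diffusion()`),
  marker-controlled watershed labeling of cartilage vs mineralized tissue
  (`segment_regions()`), marrow zeroing and VOI cropping.
* **Synthetic cartilage-bone phantom** (`generate_phantom()`): two-region
  slab with rough interface, ellipsoidal lacunae in both tissues,
  detector PSF, acquisition noise and optional phase-contrast-like edge
  fringes — a deterministic, seedable stand-in for scans that cannot be
  distributed.
* **Micro-indentation** (`contact_stiffness()`, `hardness()`,
  `summarize_locations()`, `compression_stress_strain()`): flat-punch
  unloading stiffness S = dP/dh, hardness, triplicate-by-location
  summaries, unconfined-compression stress-strain with relaxation.
* **I/O**: multi-page TIFF stacks with plain-text sidecars, CSV and
  legacy-ASCII VTK exports, JSON reports, a plain-text pipeline config
  (`run_pipeline()`) and a CLI wrapper in `inst/cli/cartidvc.R`.

## Worked example

Generate a phantom, impose a known 1% axial compression, and measure it
back:

```r
library(cartidvc)

ph   <- generate_phantom(phantom_spec(shape = c(160, 160, 160), seed = 11))
pair <- make_synthetic_pair(ph$volume, strain_level = 0.01)
fit  <- dvc(pair$reference, pair$deformed, sizes = c(80, 64, 48),
            overlap = 0.5, truth = pair$deformation)
summary(fit)
```

```
Multipass DVC fit
  sizes: 80-64-48 (valid nodes per pass: 9-32-125)
  final grid: 125 nodes, 125 valid
  mean displacement (vox): -0.0005941, -0.0007265, -0.004216
  correlation coefficient:
   Min. 1st Qu.  Median    Mean 3rd Qu.    Max. 
 0.7567  0.9028  0.9858  0.9349  0.9922  0.9997 
Strain field: 125/125 valid nodes
       exx   eyy      ezz   exy   exz   eyz
mean  77.3 -44.6 -10113.9  14.3  -0.9 -35.5
sd   437.5 248.3   1885.4 185.8 329.9 245.9
eps_eq mean 6779.8, max 9166.3 microstrain
```

The imposed strain is ε_zz = −10 000 µε: the fit recovers a mean ε_zz of
−10 114 µε with the other components near zero, and the mean von Mises
equivalent strain sits near the closed-form value for uniaxial
compression (2/3 × 10 000 ≈ 6 667 µε). Strain errors against the
analytic truth, over the interior nodes:

```r
st  <- strain(fit)
ok  <- interior_nodes(st) & st$valid
err <- sweep(st$eps[ok, ], 2, affine_strain(pair$deformation) * 1e6)
mean(rowMeans(abs(err)))   # MAER vs truth, microstrain
#> [1] 340.0224
```

A zero-strain error sweep on a noisy repeated-acquisition pair, per
tissue region:

```r
base <- generate_phantom(phantom_spec(shape = c(160, 160, 160),
                                      noise_sd = 0, seed = 11))
rep  <- zero_strain_test(add_noise(base$volume, 5, seed = 1),
                         add_noise(base$volume, 5, seed = 2),
                         base$labels, sizes = c(16, 32, 48))
print(rep)
```

```
Strain uncertainty report (zero_strain protocol)
 region_name size    MAER    SDER n_valid
   cartilage   16 21761.5 31116.0     285
 mineralized   16 10719.0 13782.3     332
   cartilage   32   834.5   346.0      50
 mineralized   32   449.1   364.5      50
   cartilage   48   476.2   230.4       9
 mineralized   48   214.5    92.5       9
```

MAER falls steeply with sub-volume size — the averaging behavior the
error protocols exist to verify — and the mineralized region, with its
denser texture, tracks better than articular cartilage at small windows.

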