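---
title: "From off-axis holograms to cell volume: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From off-axis holograms to cell volume: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(holovol)
```

`holovol` measures cell volume from off-axis digital holographic microscopy
(DHM). This vignette is the package's account of the science it implements:
the forward model behind the simulator, each reconstruction stage and its
assumptions, the parameters that matter and why their defaults are what they
are, the numerical decisions taken where the method leaves room, and what
the synthetic validation does and does not establish about real data.

## 1. The forward model (what the simulator renders)

An off-axis hologram records the interference of a unit-amplitude object
wave $O = e^{i\varphi(x,y)}$ with a tilted plane reference $R$:

$$I = |O + R|^2 = |O|^2 + |R|^2 + O R^{*} + O^{*} R .$$

The two cross terms are conjugate sidebands riding on the carrier frequency
set by the reference tilt; everything the method recovers lives in one of
them. The simulator renders this intensity exactly, with four controllable
departures from the ideal:

* **Defocus.** The object wave can be propagated away from focus by the
  angular-spectrum method before interference, so autofocus has a ground
  truth to find.
* **Background aberration.** A Zernike phase surface (OSA/ANSI single-index
  ordering, orthonormal over the unit disk inscribed in the raster) can be
  multiplied onto the object beam. Injection and compensation share one
  basis convention by construction.
* **Detector noise.** Additive Gaussian noise on intensity, specified
  relative to the mean intensity (default $\sigma = 0.01$), clipped at
  zero. A seed is mandatory whenever noise is on: the same arguments must
  produce bit-identical holograms.
* **Reference amplitude.** Equal to the mean object amplitude (fringe
  contrast near 1). Beam-ratio engineering is out of scope.

The phase object itself comes from a thickness map through
$\varphi = 2\pi\,(\Delta n - n_0)\,h/\lambda$, with $\Delta n$ the object's
refractive index and $n_0$ the medium's. All geometry is expressed in
object-plane micrometres; the sampling is the camera pitch divided by the
magnification, $3.45/60 = 0.0575\ \mu m$ per pixel at the defaults, since
microscope calibration beyond pitch and magnification is not modelled.

### Phantoms

Three ground-truthed phantom families cover the morphologies of interest:

* `sphere` — the chord function $h(r) = 2\sqrt{(d/2)^2 - r^2}$ of a solid
  sphere (default 10 µm), the standard calibration target whose analytic
  volume $\tfrac{4}{3}\pi r^3 = 523.60\ \mu m^3$ anchors the whole chain;
* `spherical_cap` — a hemi-ellipsoidal cap (height 0.8 × footprint radius),
  the smooth dome of a resting adherent cell;
* `pancake_pseudopodia` — a flat cap (height 0.3 × footprint radius) with
  five tapered radial protrusions placed with seeded angular jitter, the
  spread morphology of an activated cell.

Two constructions make the ground truth exact rather than approximate.
First, the raw map is smoothed with a Gaussian of $\sigma = 2$ px *before*
anything else is derived from it: sphere and cap rims otherwise have
unbounded thickness gradients, the rendered phase would change by more than
$\pi$ between pixels, and unwrapping would be ill-posed at the rim. The
declared ground-truth volume is the pixel sum of the *blurred* map, so the
oracle matches what is actually rendered. Second, the blurred map is zeroed
below 0.2% of its maximum (a Gaussian skirt is never exactly zero), making
the support mask finite and the identity
$V = \text{px}^2 \sum h$ over the mask exact to machine precision. Scaling
to a target volume is linear, so targets are hit exactly. Phantoms must fit
their grid with a 10% margin per side; violations are errors that name the
required grid size.

## 2. Reconstruction

**Sideband isolation.** The spectrum is centred, the magnitude-maximal bin
outside a DC exclusion disk (default radius 10% of the Nyquist bin radius)
is taken as the carrier, restricted to the upper half-plane — the two
sidebands are conjugate mirror images, so a deterministic choice is needed;
ties break lexicographically by bin index. If no bin outside the exclusion
disk exceeds 3× the median spectral magnitude, there is no sideband and the
call errors rather than guessing. A circular mask (default radius 0.5 of
the DC-to-sideband distance, with a 3-bin raised-cosine rim to suppress
ringing) selects the +1 order; the spectrum is then rolled so the carrier
bin lands on DC. This demodulation-by-shift is exactly invertible on the
grid, at the cost of leaving any sub-bin carrier remainder as a small tilt
— which the Zernike stage removes anyway. The filter radius must not touch
the exclusion disk; the error message reports the maximal admissible
`radius_frac` for the located carrier.

**Propagation.** The angular-spectrum transfer function
$\exp(i 2\pi d/\lambda \sqrt{1-(\lambda f_1)^2-(\lambda f_2)^2})$ is exact
scalar diffraction for propagating components; where the radicand is
negative (evanescent waves) the transfer function is zeroed, preventing
exponential blow-up and making propagation unitary on the propagating band.
$d = 0$ short-circuits to the identity.

**Autofocus.** The focus metric is the high-frequency energy ratio of the
amplitude image: the energy of the amplitude's spectrum outside a disk of
radius 1/8 Nyquist, over total energy. One direction choice deserves
explanation: for an *amplitude* object this ratio peaks at focus, but the
specimens here are *phase* objects — in focus their amplitude is flat, and
defocus converts phase structure into amplitude diffraction fringes. The
metric is therefore **minimized** over the scanned distances. The scan is
coarse-to-fine: evaluate on the grid, then golden-section refine within one
step of the best point, giving sub-step accuracy at bounded cost. A field
with no object yields a constant metric; the scan then returns the range
minimum with a warning rather than an arbitrary interior point.

## 3. Phase processing

**Quality-guided unwrapping.** Pixel reliability is
$q = 1/(1 + v)$ with $v$ the variance of the wrapped phase gradients over
the pixel's 3×3 neighbourhood — near 1 on smooth regions, low at noise and
discontinuities. Unwrapping flood-fills from the global quality maximum
(ties: lexicographic by row, then column), visiting pixels through a
priority queue in descending quality and adding the multiple of $2\pi$ that
brings each within $\pi$ of its already-unwrapped predecessor. Errors are
thereby confined to low-quality regions instead of propagating along scan
lines. The implementation is compiled (a binary heap in C++); every output
pixel is congruent to its input modulo $2\pi$ by construction, and the test
suite asserts this to $10^{-9}$.

**Background compensation** is two-stage, global then local:

1. *Zernike fit* up to radial order 4 (15 terms — tilt, defocus,
   astigmatism, coma, spherical: the standard description of smooth
   microscope aberrations; higher orders start absorbing the cell itself).
   The fit runs over all non-excluded pixels with coordinates normalized to
   the inscribed unit disk. Corner pixels (normalized radius > 1)
   *participate in the fit* rather than being extrapolated: polynomial
   extrapolation outside a fitted disk amplifies coefficient error as
   $\rho^4$ and was the single largest failure mode in development testing.
2. *Median residual removal.* The Zernike-subtracted map, with object
   pixels replaced by their nearest background value (BFS inpainting, so
   the cell cannot leak into its own background estimate), is median
   filtered with a wide kernel — default 51 px ≈ 2.9 µm, wider than
   pseudopodia, narrower than field curvature — and the result subtracted.

The object-exclusion mask matters more than any other detail here: if the
cell is treated as background, the median stage subtracts the cell itself.
Two complementary detectors are used. The *phase rule* — pixels above
background median + 3 MAD, dilated 5 px — uses a one-sided MAD (spread
estimated from the background-dominated lower half, since cells are
positive-phase) and is iterated against the fitted background residual
until stable; it is exact when the background is mild, regardless of how
large the object is. The *amplitude rule* exploits a physical signature:
band-limited reconstruction of a phase object leaves amplitude dips along
the object rim where edge gradients exceed the filter passband; thresholding
the dips, dilating, and filling the enclosed region yields a mask that is
independent of the phase background — robust under aberrations strong
enough to defeat any phase threshold. The pipeline feeds the amplitude mask
into the phase rule as a known-object augmentation; either alone has a
failure regime (the amplitude rim vanishes for smooth objects whose edges
stay inside the passband; the phase rule cannot separate a large centred
dome from order-4 curvature), and the union covers both.

## 4. Segmentation and morphometry

Segmentation is dual-threshold with morphological reconstruction, on the
thickness map: a seed mask at 50% of the maximal thickness marks cell
cores; a boundary mask at the robust noise floor (background median +
3 MAD of thickness, floored at machine epsilon so a noise-free map's
boundary is the support) captures the full extent including pseudopodia
plus whatever noise passes the low threshold; only boundary components
touching a seed survive. Area opening (default 64 px) removes specks,
closing with a 5 px disk fills micro-holes. Connectivity is 8-connected
throughout — thin diagonal pseudopodia must not disconnect — which required
a dedicated compiled labelling kernel (the available library routine is
4-connected). Touching-cell splitting is deliberately not implemented;
fields are assumed single-cell or well separated, and each surviving
component is reported separately.

Volume is a plain Riemann sum over the mask, $V = \text{px}^2 \sum h$ —
exactly linear in thickness and exactly additive over disjoint components,
properties the tests assert exactly. Negative compensated phase inside the
mask clips to zero with a logged count rather than erroring: background
noise dips below zero routinely and the induced volume bias is negligible
at the default noise.

Circularity is $4\pi A / P^2$ on the top-view mask. The perimeter $P$ uses
a coarea (total-variation) estimate: the summed gradient magnitude of the
$\sigma = 1$ px Gaussian-smoothed mask indicator. Classical chain-code and
Crofton estimators were evaluated and rejected — on a large digitized
square, 4-direction Crofton biases circularity to 0.88 and a
corner-corrected chain to 0.84, where the closed form is $\pi/4 \approx
0.785$; the TV estimate is within about 1% on digitized disks, squares and
star shapes alike. Sphericity is Wadell's
$\pi^{1/3}(6V)^{2/3}/A_{surf}$ with the surface area taken as the
gradient-corrected upper surface of the thickness map plus the base.
Components under 16 px are degenerate for shape work and reported as `NA`.

Time series are analyzed by nearest-centroid association between
consecutive frames within a 10 µm radius — ambiguity (two candidates in
radius) is an error naming the candidates, not a silent guess. Per-interval
slopes $\Delta V/\Delta t$ are labelled `rapid` when $|dV/dt|$ exceeds 1.5×
the track's median $|dV/dt|$, else `slow`; the magnitude comparison (rather
than signed) lets the same rule stage both growth and decay series. Tracks
also carry a monotone-decrease flag (death-like) and the first
positive-to-negative slope change (division-like peak).

## 5. Parameter summary

| Parameter | Default | Units | Why |
|---|---|---|---|
| `wavelength_um` | 0.633 | µm | HeNe line of the modelled instrument |
| `n_object` / `n_medium` | 1.38 / 1.33 (cells), 1.46 / 1.34 (silica) | — | typical mammalian-cell and calibration values |
| magnification, camera pitch | 60×, 3.45 µm | — | gives 0.0575 µm/px object sampling |
| carrier | 1/8 of sampling frequency, both axes | cycles/µm | separability vs. fringe-sampling compromise; must stay under half Nyquist |
| `radius_frac` | 0.5 | of DC–sideband distance | safe margin to both DC and the conjugate order |
| `noise_sigma` | 0.01 | of mean intensity | low-noise laboratory conditions; controllable |
| edge blur | 2 | px | keeps rim phase gradients under π/px |
| Zernike order | 4 | — | 15 terms: the standard smooth-aberration set |
| median kernel | 51 | px | ≈ 2.9 µm: above pseudopod width, below curvature scale |
| `high_frac` | 0.5 | of max thickness | scale-free core seed across morphologies |
| `low_thresh_um` | median + 3 MAD | µm | robust noise floor; exposed as config |
| `min_area_px`, closing radius | 64, 5 | px | speck and micro-hole scales |
| association radius | 10 | µm | sub-cell-diameter frame-to-frame motion |
| rapid-stage factor | 1.5 | × median slope magnitude | reproducible slow/rapid rule |

## 6. Numerical contracts and degenerate inputs

Determinism is a contract throughout: seeded renders are bit-identical;
unwrapping, autofocus and sideband choice have explicit tie-breaks; two
pipeline runs on identical inputs produce byte-identical CSVs, and the run
manifest records every auto-chosen parameter (carrier bin, filter radius,
focus distance, thresholds, clipped-pixel counts) needed to re-run a result.
Degenerate inputs error early and specifically: sub-pixel spheres,
non-positive volumes, phantoms exceeding their grid, carriers past the
separability limit, zero-radius filters, filters touching the DC disk,
empty focus ranges, all-zero thickness fields, seeds not contained in
boundaries, exclusion masks leaving under 20% background, median kernels
exceeding the raster.

Raster files are written as 32-bit TIFF. The TIFF library available to R
stores [0,1] data as 32-bit integers, so rasters are scaled into [0,1]
(power-of-two scale factors where the data allow, which are exact in binary
floating point) with the affine transform in a JSON sidecar; a write-read
cycle is exact to one part in $2^{32}$ of the range — tighter than 32-bit
float storage would be, but not bit-identical, and documented as such.

Problem sizes in the test suite are chosen to exercise each property at the
smallest scale where it is meaningful: most unit tests run 256² rasters
(the 10 µm sphere spans 174 px there); the microsphere validation and the
phenotype recoveries run at the full 1024² / 0.0575 µm/px; seeded
repetition batteries (volume ordering, autofocus, monitoring) run at 512²
with a 2×-binned camera (6.9 µm pitch), which halves linear size while
keeping the optics physical. Background-compensation recovery uses
cell-scale objects on 256–512² grids where an order-4 surface and the
object are identifiable from one another.

## 7. What the synthetic validation does and does not show

The simulator is faithful to coherent off-axis recording of pure phase
objects with smooth aberrations and Gaussian intensity noise. Passing the
phantom batteries therefore establishes that reconstruction, unwrapping,
flattening, segmentation and integration are correct and stable under the
modelled physics — recovered volumes land within a fraction of a percent of
ground truth at default settings, and the error budget (edge blur, filter
band-limiting, threshold skirt loss) is characterized.

Real specimens add physics the simulator deliberately omits: intracellular
refractive-index heterogeneity (volumes are *effective optical volumes*
under a constant-contrast assumption; decoupling needs dual-wavelength or
tomographic hardware), partial coherence and speckle, the objective's
NA-limited pupil, camera quantization and fixed-pattern noise, phase halos
around steep structures, and touching or overlapping cells. Agreement on
phantoms bounds algorithmic error, not these modelling errors; absolute
volumes from real data inherit the constant-index caveat, while relative
changes over time — the dV/dt staging the monitoring module targets — are
considerably more robust to it.
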