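---
title: "Simulating and correcting illumination aberrations in a synthetic-aperture holographic microscope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and correcting illumination aberrations in a synthetic-aperture holographic microscope}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

A digital holographic microscope (DHM) records both amplitude and phase of
the field diffracted by a sample, by interfering it with a reference beam.
Like any microscope it trades resolution against field of view (the
spatial-bandwidth product). A synthetic-aperture DHM (SA-DHM) breaks this
trade by scanning the illumination angle: each tilted plane-wave
illumination shifts a different region of the sample's spatial-frequency
spectrum into the fixed numerical aperture (NA) of the objective, and the
regions are stitched in the Fourier domain into a synthetic aperture much
wider than the objective's own passband.

The catch is the illumination itself. Steep illumination angles are
produced by real condenser optics whose wavefront error grows with the
steering angle; those aberrations ride on every measurement and scramble
the stitched spectrum. Worse, most useful illuminations are *dark-field*:
the un-diffracted beam falls outside the objective NA, so the illumination
wavefront can never be measured directly at the camera. This package
implements, end to end in simulation, a strategy for that regime: estimate
the illumination's Zernike aberration coefficients with a convolutional
regressor from the diffraction pattern that a circular aperture casts
through the system — three intensity images that *are* observable even in
dark field — then divide the estimated aberration phase out of each
recovered field before synthesis.

## Wavefront model

Aberrations are parameterized by the ten lowest Zernike terms in a
non-normalized convention (no radial normalization factors): piston
($Z_0 = 1$), the two tilts ($Z_1 = \rho\sin\phi$, $Z_2 = \rho\cos\phi$),
astigmatisms ($\rho^2\sin2\phi$, $\rho^2\cos2\phi$), defocus
($2\rho^2 - 1$), trefoils ($\rho^3\sin3\phi$, $\rho^3\cos3\phi$) and comas
($(3\rho^3-2\rho)\sin\phi$, $(3\rho^3-2\rho)\cos\phi$). Coefficients are
phase in radians at the rim of the circular aperture that defines the unit
disk ($\rho = 1$ at the rim). The azimuth is measured counter-clockwise
from the +x (column) axis with y up; this matters because the sin/cos
terms swap under axis flips. Because the basis is not orthonormalized,
coefficient values are *not* comparable across conventions term by term;
everything in this package (sampling ranges, network targets,
compensation) consistently uses the convention above.

The two tilt terms are not aberrations: a tilt of $c$ radians at the rim
of an aperture of radius $R$ pixels is a carrier of spatial frequency
$c/(2\pi R)$ cycles/px, i.e. it sets *where* in the Fourier domain the
measurement lands. Orders 3..9 distort the image; the piston $c_0$ is
invisible in any intensity and only matters as a tile-to-tile phase
inconsistency at synthesis time.

## The simulated instrument

The simulated layout is a 4-f imaging chain sampled on a single square
grid (default 2240 px at 1 µm pitch, wavelength 0.532 µm): a circular
aperture (default radius a quarter of the grid) carries the illumination
phase map; an objective (f1 = 10 mm) forms its Fourier transform, where a
224-px-diameter mask realizes the objective NA

$$\mathrm{NA} = \lambda \frac{d/2}{N\,\Delta} = 0.532\,\mu m \cdot \frac{112}{2240\,\mu m} = 0.0266,$$

while the full grid corresponds to NA 0.266; a tube lens (f2 = 200 mm)
forms the image on the camera. Two design choices keep the arithmetic
honest:

* **All planes share one grid.** The tube-lens transform is taken in the
  inverse direction, so the camera field lives in sample-referred
  coordinates and the magnification $-f_2/f_1$ is pure bookkeeping. A tile
  of the synthesized spectrum is then literally a masked region of the
  sample's own DFT — synthesis is index arithmetic, with no resampling.
* **The out-of-focus plane is propagated on that same grid.** The third
  observation channel is the camera field propagated d = 10 mm by the
  band-limited angular-spectrum method (exact transfer function, with the
  sampled-transfer-function band limit to suppress wrap-around). Treating
  d as an image-space distance at magnification 20 would defocus by about
  one pixel and carry no information; on the sample-referred grid it
  produces the strongly defocused third channel the estimator needs.

Free-space propagation uses the band-limited angular spectrum rather than
a Fresnel kernel because the default throw (10 mm at 1 µm pitch) is well
inside the angular-spectrum validity and adds no approximation error. The
aperture is treated as the front focal plane of the objective, giving the
exact Fourier relation.

### Holographic recording

Each camera-plane field is recorded as four phase-shifted interferograms
$I_n = |A_o|^2 + A_r^2 + 2A_oA_r\cos(\theta_o - n\pi/2)$, $n = 1..4$
(a polarization camera acquires these in one shot in hardware; the
simulation produces the four maps directly, with a spatially uniform
reference). The quadrature combination $(I_1-I_3) + j(I_2-I_4)$ then
equals $-4j\,A_rA_o e^{j\theta_o}$ *exactly*; multiplying by $j$ gives
$4A_r$ times the object field. The package fixes the phase-step sign to
$-n\pi/2$ and the constant to $j$ once, so that the round trip
`recover_field(make_holograms(U, Ar)) / (4 Ar)` is the identity to machine
precision — with the opposite step sign the same combination yields the
conjugate field, which `recover_field(shift_sign = +1)` undoes with one
conjugation. That recovery exactness is the operational content of the
phase-shifting equations, and is what the test suite pins down.

## Training data

One training sample is the response of the *empty* system (aperture only,
no sample) to one random aberration: three intensity images — the masked
Fourier plane cropped to the mask's bounding square (so the mask rim is
the image border), the focal plane, and the out-of-focus plane, each
independently min-max normalized — stacked as a 3-channel raster with the
10 coefficients as the regression target. Coefficients are drawn uniformly:
piston on $[-\pi, \pi]$, tilts on $[-1200, 1200]$ rad, orders 3..9 on
$[-48, 48]$ rad at full scale. The tilt bound sits below the aliasing
limit of the default aperture ($\pi R = 1759$ rad), and the range
validator enforces exactly that at configuration time. An optional mode
scales the high orders in proportion to the carrier magnitude (steeper
illuminations are worse-aberrated, which is how the reconstruction
experiments draw their aberrations); the fixed range is the default for
training data.

With these ranges the overwhelming majority of draws are dark-field: the
carrier displacement $\lVert(c_1,c_2)\rVert N/(2\pi R)$ exceeds the
112-px mask radius unless the tilt magnitude falls below about 176 rad,
an event of probability $\approx \pi\,176^2/(4\cdot1200^2) \approx 1.7\%$.
The bright/dark flag stored with every sample is this analytic criterion,
and the tests verify it against a brute-force Fourier peak search.

Per-channel min-max normalization deliberately discards the global
intensity scale. Together with the intensity-only recording this makes the
piston term carry *no* signal at all — a global phase changes none of the
three channels — which is why the piston must be handled at synthesis
time instead of being regressed.

### Scaled presets

Everything above is dimensionless enough to shrink. A scaled preset with
$N$ pixels keeps the mask at $N/10$, the aperture at $N/4$, the pitch and
wavelength fixed, and scales the out-of-focus distance as
$d = 10\,\mathrm{mm}\cdot N/2240$ so the defocus spread stays the same
fraction of the field of view. The sampling ranges scale too: the tilt
bound as $1200\,N/2240$ (same carrier-to-mask geometry, same dark-field
fraction) and the high-order bound as $48\,N/2240$ — the dimensionless
quantity that controls how an aberration distorts a spectral tile is its
phase *gradient* relative to the mask radius, which goes as $c/R$, not the
coefficient itself. Under this scaling a 280-px preset reproduces the
full-scale geometry tile for tile at 64× less work, which is what makes
CPU-scale training and testing meaningful rather than merely fast.

## The estimator

The regressor is a residual convolutional network ending in a 10-unit
linear head. Two architectures are built from the same primitives: a
bottleneck residual network with stage depths (3, 4, 6, 3) for full-scale
runs, and the default `resnet_small` — a 3-stage residual CNN
(16/32/64 channels, batch norm) on 32-px inputs — sized so that the
complete generate-train-evaluate cycle runs on one CPU in minutes.
Convolutions are im2col + GEMM in C++; gradients are verified against
numerical differentiation in the test suite.

One head detail matters for this task. Classification CNNs end in global
average pooling, which makes the features translation-invariant; but two
of the ten regression targets are the carrier tilts — literally the
*position* of the diffraction evidence in the Fourier channel (and, in
dark field, the orientation and curvature of the aperture-diffraction
ring tails passing through the NA window). Average pooling discards
position by construction, and with it most of the tilt signal. The small
network therefore flattens its final $4\times4\times64$ feature map into
the linear head instead of pooling it; decoupled weight decay
($3\times10^{-4}$) keeps the extra head capacity from overfitting.

A second input detail follows from the dark-field physics. In the Fourier
channel the evidence of a dark-field carrier is the tail of the aperture's
diffraction rings sweeping through the NA window, and those tails span
several decades of intensity; after min-max normalization they occupy the
bottom few percent of the linear range. The estimator therefore remaps
that channel by $\log(1 + a x)/\log(1 + a)$ (default $a = 10^3$) before
the network — the standard logarithmic display of Fourier magnitudes,
applied as model-input preprocessing. The triplet files themselves stay
linear min-max, so the transform is part of the model artifact, not the
dataset.

Targets are scaled per coefficient by their sampling half-ranges before
the MSE loss, otherwise the tilt terms (hundreds of radians) would
outweigh the high orders (tens) by roughly $600\times$ in the gradient.
The optimizer is Adam (learning rate $2\times10^{-3}$, step decay at 60%
and 85% of the epochs, batch 32); inputs stay in [0, 1] with no
statistics-based normalization (only the fixed log remap of the Fourier
channel above). Training records the validation loss before the first
epoch as the untrained baseline, so learning can be quantified as a
reduction factor per coefficient.

Two outcomes are characteristic and reproduced by the acceptance tests at
the 280-px preset: aggregated over the nine non-piston coefficients, the
validation MSE in raw coefficient units (radians², a scale dominated by
the carrier terms) drops more than 5× from the untrained epoch-0 network,
while the piston's validation error never improves materially on that
baseline — the network cannot learn what the data does not contain, and
per-channel min-max normalization removes every trace of $c_0$ from the
images.

## Aperture synthesis and compensation

For each illumination $i$ the recovered field is (optionally) multiplied
by $e^{-j\phi_i}$ with $\phi_i$ the phase map of the *estimated* orders
3..9 — carriers are kept (they place the tile) and piston is handled
separately — then demodulated by its carrier ramp, Fourier transformed,
restricted to its NA disc, and accumulated. Overlapping tiles are
**averaged** (sum divided by the per-pixel tile count) rather than summed:
plain summation would double-weight overlap regions and ripple the
effective passband, whereas averaging leaves the synthesized transfer
function flat across the union of discs, which is what lets the
compensated MTF track the aberration-free one. Carriers are applied as
exact (sub-pixel) phase ramps; only the disc support is rounded to whole
pixels.

Piston consistency is restored by matching: tiles are processed center-out
(carrier radius ascending, ties by record index), and each new tile's
constant phase is aligned to the already-accumulated spectrum via an
amplitude-weighted mean phase difference over the overlap region, with an
amplitude floor of 1% of the tile's maximum. A single-pixel comparison
would be fragile to ringing; the weighted mean over the overlap preserves
the intent (one consistent piston) while being robust. The reference tile
keeps offset zero, so pistons are only ever determined up to a global
constant — which is all an intensity image needs. A tile whose disc does
not overlap the already-matched region is a topology error, reported with
the tile index. In ground-truth experiments the piston can instead be
removed exactly from the known $c_0$, which is the default for the
reconstruction comparisons.

The illumination sets used for reconstruction place carriers on a
hexagonal lattice with spacing 0.75 mask diameters: close enough that the
disc union has no holes (lattice covering radius $s/\sqrt{3} < $ mask
radius) and that every tile overlaps its inner neighbors for matching,
sparse enough that a full-scale 62.5%-coverage run stays near 44 tiles.

## Resolution accounting

A binary bar target with bands from 21 to 500 lp/mm (500 lp/mm is the
Nyquist frequency of the 1 µm grid) is generated directly on the
reconstruction grid; band modulation is measured on the reconstructed
*intensity* as $(I_{95} - I_{5})/(I_{95} + I_{5})$ per row, averaged over
rows, using 95th/5th percentiles instead of extremes to suppress coherent
ringing spikes. Guard gaps of two periods separate bands. Values are
reported unclipped.

Two numbers anchor the geometry. A synthesis covering 62.5% of the full
band reaches $0.625 \times 500 = 312.5$ lp/mm, so bands beyond it must
collapse — with one raster subtlety: at 1 µm pitch the 400 lp/mm band has
a 2.5-px period, and its floor-discretized bars repeat exactly every 5 px,
an $f/2 = 200$ lp/mm subharmonic that lies *inside* the synthesized
passband and legitimately modulates the reconstruction. Only the
500 lp/mm band (an exact 2-px period, subharmonic-free) is a clean
blocked-band probe; the full-scale run measures it below 0.15. And a band
at 167 lp/mm lies well inside that coverage, where flat averaging
predicts a modulation near
$(a+b)^2 - (a-b)^2$ over $(a+b)^2 + (a-b)^2 \approx 0.97$ for a binary
grating that keeps only DC and its fundamental ($a = 1/2$,
$b = 2/\pi$), slightly reduced by the percentile estimator — the
acceptance run reproduces a value above 0.9, comfortably above the 0.8
the full-scale geometry is designed to hold through 167 lp/mm.

The spoke (Siemens-star) chart complements the bars: its local line-pair
frequency $n_{\mathrm{spokes}}/(2\pi r)$ sweeps resolution continuously
with radius, so the blur radius of a reconstruction reads off directly.

## Numerical choices and degenerate inputs

* Centered FFT convention everywhere; DC at 0-based pixel (N/2, N/2);
  both transform directions scaled $1/N$ (unitary pair).
* Propagation zeroes evanescent components and applies the
  sampled-transfer-function band limit; `propagate(0)` is the identity
  object, and the d-then-minus-d round trip is exact to ~1e-15 for
  band-limited fields.
* Min-max normalization of a constant channel returns all zeros rather
  than dividing by zero.
* The MTF estimator returns 0 where a band's percentile sum underflows
  (all-dark bands) instead of 0/0.
* Hologram recovery validates that the four frames share one grid;
  synthesis errors on an empty record list; a non-overlapping tile under
  piston matching names the offending tile.
* Training determinism: a fixed seed fixes initialization and batch
  order; bit-identical runs additionally require a single-threaded BLAS
  (multi-threaded backends may reorder sums).

## What the simulation does not capture

The generator is noise-free by design: no shot or read noise, no
polarization-camera demosaicing, no condenser field curvature, no
chromatic effects, and the reference beam is perfectly uniform. Passing
tests therefore demonstrate the *method* — recovery exactness,
compensation fidelity, piston matching, resolution bookkeeping — under
ideal photometry, not robustness to experimental noise. Estimator
accuracy measured here is an upper bound for what identical training on
real data could achieve. The spectral tiles are also placed from
ground-truth carriers in the reconstruction experiments (the estimator's
carrier predictions exist but are not used for placement by default), so
estimator error enters reconstruction only through orders 3..9, mirroring
how the method separates "where the tile goes" from "how it is
distorted". Iterative (ptychographic) refinement of the estimates is
deliberately out of scope.

## Problem sizes used by the shipped checks

The test suite and the acceptance script choose sizes as the package's
own defaults for CPU-scale verification: unit tests run at 120-280 px;
the compensation-fidelity check at 560 px with 19 illuminations; the
estimator check at 280 px with 4200 samples and 36 epochs; the
full-geometry resolution check and the acceptance script at the complete
2240-px layout with a 43-tile illumination grid. Full-scale training
(100k samples, 100 epochs, 224-px inputs on the bottleneck network) is
supported by configuration but is a GPU-days undertaking and is not part
of the shipped checks.
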