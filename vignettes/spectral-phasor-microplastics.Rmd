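---
title: "Spectral phasor analysis of dye-stained microplastics: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spectral phasor analysis of dye-stained microplastics: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phasorMP)
```

## The problem and the model

Microplastics (MPs) — synthetic polymer particles from the millimeter scale
down to nanometers — can be stained with a solvatochromic fluorescent dye
whose emission spectrum red-shifts with the polarity of its
microenvironment. Bound to a nonpolar polyolefin (polypropylene or
polyethylene) the dye emits blue-green; bound to a polar polymer such as
polyethylene terephthalate it emits red. A confocal microscope acquiring a
*lambda stack* — an image `I(x, y, lambda)` where every pixel carries a full
emission spectrum — therefore encodes the polymer class of every imaged
fragment in the per-pixel spectral shape.

Spectra of different polymer classes overlap substantially, so instead of
band ratios or unmixing, this package uses the **spectral phasor**: each
pixel's spectrum is condensed to the normalized first Fourier harmonic

$$X = \frac{\sum_\lambda I(\lambda)\cos(2\pi n\lambda/L)}{\sum_\lambda I(\lambda)},
\qquad
Y = \frac{\sum_\lambda I(\lambda)\sin(2\pi n\lambda/L)}{\sum_\lambda I(\lambda)},
\qquad n = 1,$$

with $\lambda$ the channel offset from the first channel and $L$ the
amplitude of the spectral range. $(X, Y)$ always lies in the unit disk; the
polar angle encodes the spectral center of mass (a red shift rotates the
phasor) and the modulus is inversely related to the spectral bandwidth
(wider spectra sit closer to the origin). Because $X$ and $Y$ are ratios of
linear functionals of the spectrum, phasors of spectral mixtures are exactly
the intensity-weighted vector sums of the component phasors
(`combine_phasors()` tests this to machine precision). Pixels with similar
spectra form compact clouds in the phasor plot; circular **cursors** drawn
around the clouds are mapped back to the image as a class segmentation, from
which particles and composition fractions follow.

## Conventions and numerical choices

* **Phase origin.** The transform uses channel *offsets* ($\lambda -
  \lambda_\text{start}$), so the first channel has phase 0 and results are
  independent of the absolute wavelength origin. An $L$ of 320 nm for a
  420–740 nm axis only makes sense for offsets, which fixes the convention.
* **$L$ is data-derived.** $L$ defaults to the axis span
  $(\text{count} - 1)\cdot\text{step}$ and is overridable in
  `compute_phasor()` / `phasor_image()`. Nothing is hard-coded: a 2.5 nm
  axis over 420–740 nm gives $L = 320$ nm, the 3 nm acquisition grid gives
  318 nm. Uniform wavelength grids only; non-uniform axes are rejected
  because the discrete transform above assumes fixed steps.
* **Orientation.** The printed formulas are implemented verbatim, giving
  counterclockwise-increasing angles in standard math axes. The familiar
  "red shift moves clockwise" picture is purely a display convention:
  `plot_phasor()` inverts the rendered Y axis and nothing else.
* **Empty spectra.** A spectrum with zero total intensity has no phasor; the
  transform raises an error rather than emitting NaN. In images such pixels
  are simply masked invalid.
* **Background threshold.** Pixels are phasor-transformed only when their
  total intensity exceeds a background threshold. The default is Otsu's
  method computed on `log1p(total intensity)` and mapped back. Linear-domain
  Otsu is provably wrong for this data class: fluorescence MP fields are a
  tight dark background plus a sparse foreground whose brightness spans an
  order of magnitude, and maximizing between-class variance on the linear
  histogram places the threshold *inside* the foreground mode, silently
  discarding dim particles (measured on the synthetic default scene: linear
  Otsu ~1768 counts vs a dimmest-particle total of ~1450). In the log domain
  the two modes are compact and the threshold falls in the gap.
  `"otsu-linear"` and absolute values remain available.
* **Harmonic.** `n = 1` throughout; higher harmonics are accepted but
  flagged experimental in the documentation and are not used by the
  pipeline.

## Classification rules

Cursors are circles (default radius 0.08 in phasor units — class clouds
separate by several times that, while shot noise at typical photon-counting
intensities scatters a cloud by ~0.02). A pixel inside several cursors goes
to the nearest cursor center; exact ties break by cursor list order. Both
rules matter only for pathological overlaps — reference clouds have no or
minimal overlap — but a deterministic rule is required and tested.

LDPE and HDPE are merged into a single `LDPE/HDPE` cursor by default: both
are polyethylene, their bulk spectra differ only slightly, and at image
noise levels their phasor clouds superimpose and cannot be separated. A
strict mode (`merge_pe = FALSE`) keeps them apart for bulk-spectrum work.

Particles are connected components per class (8-connectivity default, 4
available) of at least `min_particle_size = 4` pixels — smaller islands are
noise speckle, and neither value is dictated by the method so both are
configurable. Composition fractions are reported on both bases: summed
pixel area (default, robust to one physical fragment splitting into several
components) and particle count; the basis is recorded in the output because
the two answer different questions.

## What the synthetic generator emulates — and what it does not

`generate_scene()` stands in for a stained-sample acquisition so the whole
pipeline is testable with no instrument:

* **Geometry.** 256 x 256 pixels, ~5 um/pixel (a 1272 um field of view),
  dispersed non-overlapping elliptical fragments of random size (3–12 px
  equivalent radius), eccentricity and orientation, placed by rejection
  sampling.
* **Spectra.** Per-class sum-of-Gaussians references evaluated on the
  420–740 nm, 3 nm acquisition grid. The *numeric* band parameters (PP
  455/485 nm, LDPE 470/505, HDPE 472/507, PS 545, PET 600 broad) are
  synthetic stand-ins — no published per-polymer emission maxima exist for
  this dye — chosen once to respect the qualitative constraints: polyolefins
  show two bands in 450–520 nm, polar polymers a single maximum above
  520 nm, PET reddest and broadest, phasor angle ordered
  PP < LDPE <= HDPE < PS < PET with the material dielectric constants, and
  LDPE/HDPE within ~2 nm so their image clouds superimpose. They live in
  `inst/extdata/polymer_references_synthetic.yaml`, clearly marked.
* **Intensity and noise.** Photon-counting acquisition: expected peak
  signal 120 counts/channel scaled by a per-particle brightness factor
  (uniform 0.6–1.4, emulating uneven staining and thickness), flat
  background of 1 count/channel, and Poisson noise (variance = mean).
  A pixel then carries roughly 1–5 x 10^3 total counts, scattering its
  phasor by ~0.02 — a realistic, not optimistic, photon budget.
* **Not emulated:** dye photophysics, optical blur (PSF), water-matrix
  autofluorescence, detector afterpulsing, spectral bleed-through, overlap
  of touching fragments. A green end-to-end test therefore establishes that
  the *analysis* recovers what the *stated imaging model* encodes — it does
  not validate the staining chemistry or the optics.

Every draw derives from the scene seed, so identical seeds give
bit-identical stacks, ground-truth label maps and particle tables.

## FTIR identification

Bulk chemical identification is encoded as a reference table of
characteristic absorption peaks (cm^-1) per polymer. `match_peaks()` scores
an observed peak list against each reference by greedy nearest-first
one-to-one matching within a tolerance (default 5 cm^-1: the ATR
acquisition resolution is 2 cm^-1, and 5 absorbs peak-picking jitter);
one-to-one matching prevents a single broad band from satisfying several
reference peaks. The LDPE and HDPE reference rows are identical, so
polyethylene input always produces an exact reported tie — the method
cannot and should not distinguish them. Observed peaks the best class
leaves unexplained are reported (`unmatched_observed`) as a purity hint,
but no purity statistic is defined because none is established.
`detect_peaks()` feeds the matcher from raw absorbance curves using
topographic prominence, so a shoulder on a strong band is not double
counted.

## Design decisions that were genuinely open

* **TIFF I/O.** No TIFF reader exists in the supported R environment, so a
  minimal baseline TIFF 6.0 subset (uncompressed grayscale, 8/16/32-bit
  integer and 32/64-bit float, multi-page, both byte orders) is implemented
  in-package and cross-checked in the test suite against an independent
  writer. Wavelength axes travel in a YAML sidecar.
* **Auto-cursors** use intensity-weighted Lloyd k-means with seeded
  k-means++ initialization, returning cursors ordered by phasor angle
  (blue to red). This automates manual circle placement; it is a
  convenience, and the reference-centered cursor set remains the default.
* **Acceptance tolerances on near-zero coordinates.** "Agreement to 1e-12
  relative" is asserted on the natural O(1) scale of the dimensionless
  coordinates (|delta| <= 1e-12 * max(|reference|, 1)): individual
  coordinates of flat random spectra can be ~1e-6, where double precision
  cannot express 1e-12 agreement relative to the coordinate itself.
  Measured disagreement is ~1e-16.
* **Mosaics** are pooled at the particle-table level (concatenation with
  re-keyed ids and tile provenance), which makes pooled fractions exactly
  the area/count-weighted pooling of tiles and requires consistent pixel
  sizes.

## Worked example

```{r example, eval = FALSE}
set.seed(1)
scene <- generate_scene(scene_spec(seed = 1))      # 256x256, 5 classes
pim <- phasor_image(scene$image)                   # per-pixel transform
cursors <- reference_cursors(axis = scene$image$axis)
lm <- classify_pixels(pim, cursors)                # back-mapping
pt <- extract_particles(lm)
composition_fractions(pt, "pixel_area")
plot_phasor(pim, cursors)                          # clockwise-red rendering
```

## Known limitations

* Classification accuracy degrades gracefully but unavoidably when photon
  budgets drop well below ~10^3 counts/pixel; no phasor-space denoising
  (e.g. median filtering of X/Y maps) is applied, since the reference
  workflow does not state one.
* Cursors are circles; elongated clouds (strong within-class bandwidth
  variation) would be captured better by elliptical or free-form gates,
  which are out of scope.
* The synthetic LDPE/HDPE near-degeneracy is by construction; real samples
  may separate more or less than the stand-in spectra do.
* Unmerged LDPE vs HDPE classification on images is supported but
  meaningless at realistic noise; it exists for bulk spectra.
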