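# phasorMP

Identification and quantification of **microplastics** (MPs) in
hyperspectral fluorescence images of samples stained with a solvatochromic
dye, by **spectral phasor analysis**.

## The problem

Plastic fragments stained with a polarity-sensitive fluorescent dye glow
with an emission spectrum that red-shifts with the polarity of the polymer:
polypropylene (PP) blue, polyethylene (LDPE/HDPE) green, polystyrene (PS)
yellow, polyethylene terephthalate (PET) red. A confocal microscope
acquiring a lambda stack `I(x, y, λ)` records that spectrum at every pixel.
The spectra overlap too much for band ratios, so each pixel's spectrum is
condensed to its **spectral phasor** — the normalized first Fourier
harmonic:

```
X = Σλ I(λ)·cos(2πnλ/L) / Σλ I(λ)      Y = Σλ I(λ)·sin(2πnλ/L) / Σλ I(λ)      n = 1
```

with `λ` the channel offset and `L` the amplitude of the spectral range.
`(X, Y)` lies in the unit disk; the angle tracks the spectral center of
mass (red shift = rotation), the modulus shrinks as the spectrum broadens,
and mixtures combine by exact intensity-weighted vector addition. Pixels of
one polymer class form a compact cloud in the phasor plot; circular
**cursors** around the clouds are mapped back to the image as a
segmentation, from which particle counts, sizes and polymer composition
fractions follow. A companion module identifies bulk polymers from
ATR-FTIR characteristic peak lists, and a fully seeded synthetic scene
generator provides ground truth so every stage is testable without an
instrument.

For whom: anyone quantifying MP number, size and composition from spectral
fluorescence imaging, and anyone needing a self-contained, reproducible
phasor-segmentation pipeline in R.

## Worked example

```r
library(phasorMP)

scene <- generate_scene(scene_spec(seed = 1))   # synthetic 256x256 stained field
scene$image
#> <spectral_image> 256 x 256 pixels, 107 channels on axis(420, 3, 107), 4.96875 um/pixel

pim <- phasor_image(scene$image)                # per-pixel phasor transform
pim
#> <phasor_image> 256 x 256 pixels, 7150 valid (threshold 155), harmonic 1

cursors <- reference_cursors(axis = scene$image$axis)  # LDPE/HDPE merged
lm <- classify_pixels(pim, cursors)             # back-map cursors to the image
lm
#> <label_map> 256 x 256 pixels; PP: 1791, PS: 1768, PET: 1069, LDPE/HDPE: 2512; unclassified 58396

pt <- extract_particles(lm)                     # connected components >= 4 px
nrow(pt)
#> [1] 40

composition_fractions(pt, "pixel_area")
#> LDPE/HDPE       PET        PP        PS
#> 0.3518207 0.1497199 0.2508403 0.2476190

round(scene$class_mix_realized, 4)              # generator ground truth
#>   HDPE   LDPE    PET     PP     PS
#> 0.1695 0.1824 0.1495 0.2512 0.2473
```

The pipeline recovers the ground-truth composition to ~3 decimal places
(merged LDPE/HDPE truth is 0.3519 vs 0.3518 recovered): 40 of 40 particles
found, each assigned its true class. `plot_phasor(pim, cursors)` draws the
phasor plot with the conventional clockwise-red orientation.

FTIR identification from a characteristic peak list:

```r
match_peaks(c(1713, 1241, 1094, 720))
#>   class matched total score rank  tied
#> 1   PET       4     4  1.00    1 FALSE
#> 2  LDPE       1     4  0.25    2  TRUE
#> ...
```

## Command line

```sh
Rscript inst/cli/phasormp simulate --seed 1 --out out/          # synthetic scene
Rscript inst/cli/phasormp quantify --in out/scene.tif --out out/run/
Rscript inst/cli/phasormp ftir-id --peaks peaks.csv
Rscript inst/cli/phasormp benchmark --replicates 5 --out out/bench/
```

`quantify` writes per-tile phasor maps (3-page TIFF), label maps (PNG +
JSON legend), particle tables (CSV), the pooled mosaic table, composition
fractions on both bases (`report.json` / `report.md`) and the resolved
configuration, so every run is reproducible from its output directory.

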