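---
title: "Methods: wavelet-pyramid saliency with CSF-weighted integration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: wavelet-pyramid saliency with CSF-weighted integration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wavsal)
```

## The model in one paragraph

`wavsal` implements a bottom-up saliency model of the center–surround
family: an image is expanded into biologically motivated feature
channels, each channel into a multi-scale pyramid, conspicuity arises
from contrast between a fine ("center") and a coarse ("surround") scale,
scales are fused with weights taken from the human contrast sensitivity
function, and features are fused with weights that reward maps with a
single dominant peak over maps that are uniformly busy. The model is
deterministic end to end; randomness enters only through the evaluation
metrics (negative-set sampling) and the synthetic fixation generator.

## Stage by stage

### Features (Layer I)

Low-level channels are intensity (fixed luma weights
`0.2989/0.5870/0.1140` on RGB in `[0, 1]`), the CIELab `a` and `b` axes
as green–red and blue–yellow opponency (sRGB primaries, D65 white point,
via `grDevices::convertColor`), and eight orientation channels obtained
by convolving intensity with a Gabor bank. Medium-level channels apply
the same bank to the two opponency maps, giving joint color×orientation
selectivity; these 16 channels are what separates model version 2 from
version 1. A conjunction target (for example a red horizontal bar among
red vertical and luminance-matched green horizontal bars) ties with some
distractor group in every single low-level channel but stands out in an
oriented-opponency channel — the behavioural motivation for the
medium-level set, and an explicit test in this package.

The Gabor bank is specified only by wavelength (10 px) and the eight
angles `kπ/8`. The remaining parameters are package choices: cosine
phase, envelope `σ = 0.56 × wavelength` (about one octave of bandwidth),
unit aspect ratio, kernel mean subtracted so the DC response is exactly
zero, and unit L2 norm. Zero DC makes "a constant image produces zero
orientation response" an exact invariant rather than an approximate one.
Orientation channels keep the *signed* convolution output; absolute
values enter only through the center–surround operator, which is the one
place the model takes magnitudes. A quadrature-energy bank (phase
invariant) would be a defensible alternative; cosine phase was chosen as
the minimal reading and gives cleaner linearity properties to test.
Convolutions use reflect padding so image borders do not manufacture
contrast.

### Pyramid (Layer II)

Each channel is decomposed with the Symlet-4 wavelet into eight
approximation levels; detail sub-bands are discarded everywhere. Scale 1
is the *first-level* approximation, not the raw image — the scale
schedule below uses indices 1..8 and treating the input as a scale would
create nine entities. Two conventions had to be fixed because they alter
level sizes and values:

* **Boundary**: half-sample symmetric padding, the standard choice for
  image DWT; level length is `floor((n + 7) / 2)`. A 450×800 channel
  gives 228×403 at scale 1.
* **Normalization**: the orthonormal 2-D analysis step doubles constants,
  so each level is rescaled by 1/2. A constant input is then the same
  constant at every level, which makes cross-scale subtraction meaningful
  on a common intensity scale and makes "constant image → zero contrast"
  exact.

The implementation builds the decimated low-pass convolution as a cached
operator matrix per input length; a frozen reference vector from an
independent DWT implementation pins the convention in the tests.

### Center–surround (Layer III)

For a scale pair `(c, s)` the surround is interpolated bilinearly up to
the center's grid and the element-wise absolute difference taken. The
three schemes are fixed tables:

| scheme | pairs |
|---|---|
| 4  | 1⊖3, 1⊖4, 2⊖4, 2⊖5 |
| 6  | + 3⊖5, 3⊖6 |
| 10 | + 4⊖6, 4⊖7, 5⊖7, 5⊖8 |

so the 4-map scheme contrasts only fine scales, and each larger scheme
adds coarser center scales. With 27 channels this yields 108, 162 or 270
contrast maps. Each map is min–max normalized to `[0, 1]` independently,
because the downstream weighted sum presumes comparably scaled inputs; a
map whose value range is zero — or within ~1e-13 relative of zero, i.e.
floating-point dust from an exactly uniform input — is mapped to zeros
rather than having its noise amplified to full scale.

### Conspicuity (Layer IV)

The contrast sensitivity function
`C(f) = (0.0499 + 0.2964 f)·exp(−(0.114 f)^1.1)` (f in cycles/degree)
weights the scales. Calibration is explicit: `pixels_per_degree`
(default 32) refers to the working-size image, and a map's effective
calibration scales with its resolution — a map at half the base
resolution covers twice the visual angle per pixel and therefore samples
only half the maximum spatial frequency. Under this reading the mean CSF
weight decreases as maps coarsen past the CSF peak (≈7.9 cycles/degree),
so fine scales are weighted up, which is the point of the weighting; with
a fixed calibration every DFT grid would span the same frequency band
and the weights would be nearly constant.

Two variants are combined:

* **Global** (scalar weights): `ω_i = mean(C_i(f))` over the map's DFT
  grid, output `Σ ω_i m_i / Σ ω_i` — a convex combination.
* **Local** (per-pixel): each map's spectrum is multiplied bin-wise by
  its CSF matrix, inverse-transformed, the real part kept and negative
  values clamped to zero, then summed and divided by `Σ mean(C_i(f))`.

The source description of the local variant mentions both a Fourier
transform and a "pixel-wise" product; a spatial-domain product between a
frequency-indexed matrix and a spatial map has no coherent units, so the
package applies the product in the frequency domain (classic CSF
filtering). Both readings fit behind the same interface if needed.
The mean over the full DFT grid (not unique radial frequencies) defines
`ω_i`. Fusion happens at the scale-1 grid — the finest grid the pyramid
produces, so no information is discarded; the combination is
`α·global + β·local` with `α = 0.95`, `β = 0.05` (fixed published
values, exposed in the config but not re-fitted).

### Integration (Layer V)

Methods, selectable via `integration_method` (default 4):

1. **Max**: the 8 orientation maps of each base channel are summed and
   rescaled, then the per-pixel maximum over the grouped maps (I, RG,
   BY, O·I, O·RG, O·BY) is taken. Only this method groups orientations;
   methods 2–4 weight all 27 maps individually, following each method's
   stated index set.
2. **Globally weighted**: each map is rescaled to `[0, 1]`; its weight is
   `|Max − mean(other local maxima)|`. A lone peak gets full weight
   (`mean := 0` when no secondary maxima exist); many equal peaks give
   weight near zero. If all weights vanish the unweighted mean is used,
   with a warning.
3. **Locally weighted**: the weight is a matrix `|Max − LocalMax|`,
   where `LocalMax` assigns to each pixel the value of its *nearest*
   local maximum. The source defines the weight only at maxima
   locations; nearest-maximum assignment is the package's reading (a
   grayscale dilation would be another), implemented as an exact
   Euclidean distance transform with label carry in compiled code.
   Pixels with zero total weight output 0; if no map has maxima at all,
   the method falls back to method 2.
4. **Combined** (default): rescaled sum of methods 2 and 3, joining the
   global and local weighting behaviours.

Local maxima use a 3×3 window, value ≥ all neighbours and strictly above
the matrix minimum; an equal-valued plateau collapses to its first
row-major pixel; a constant matrix has none. These tie-break rules make
the whole pipeline deterministic.

### Versions and evaluation

Version 1 = low-level channels + 6-map scheme; version 2 = full channels
+ 6-map scheme; version 3 = full channels × {4, 6, 10} schemes with the
best scheme chosen per image *at evaluation time* by metric score (ties
to the smallest scheme). Without fixations, version 3 exports the three
maps, and `mean_scheme_map()` offers a rescaled mean as a convenience
aggregate — clearly tagged, and not part of the published procedure.

`auc_borji()` samples, per split, as many negatives as there are
fixations uniformly over the frame (with replacement), sweeps thresholds
over all observed saliency values and averages the trapezoidal ROC area
over 100 splits; ties contribute half, so a constant map scores exactly
0.5. `sauc()` draws negatives from other images' fixations instead
(without replacement when the pool allows), which scores a purely
center-biased map at chance when the negatives share the positives'
central tendency. Both are invariant under strictly increasing
transforms of the map. Images are processed at a working size (default
450×800, plain bilinear resize) and maps are resized back to the input
frame for scoring.

## The synthetic generator

The generator emulates classic visual-search displays: bar elements on a
3×5 grid over mid-gray background, bar length 30 px ≈ three Gabor
wavelengths so orientation channels respond strongly. Kinds: color
pop-out (red among gray), orientation pop-out (horizontal among
vertical), conjunction pop-out (red-horizontal among red-vertical and
green-horizontal, with red and green matched in the intensity channel),
uniform, seeded uniform noise, and two texture fixtures:

* `fine_texture` — a 32 px checkerboard patch of period 8 px among
  large, faint luminance blobs. The period is deliberately *above* the
  scale-1 Nyquist limit of the pyramid: content at period ≤ 4 px is
  annihilated by the first low-pass step and would be invisible to every
  scheme, so "fine" here means fine *relative to the pyramid*, not to
  the pixel grid.
* `large_blob` — a smooth Gaussian blob (σ = 40 px) among small
  high-frequency clutter patches; its bounding box is the ±1σ core.

With target-concentrated fixations (60 on target, 15 background — an
80% concentration typical of strong pop-out displays), the fine-texture
fixture is scored best by the fine (4-map) scheme and the blob fixture
by the coarse (10-map) scheme, demonstrating the content dependence that
motivates version 3. These stimuli are caricatures: they have flat
backgrounds, isolated targets and no photographic statistics (1/f
spectra, occlusion, semantics). Passing them shows the mechanisms work
as designed — pop-outs capture the argmax, conjunctions require
medium-level channels, scheme preference tracks content scale — not that
any particular score would transfer to natural-image benchmarks, which
require external eye-tracking datasets.

## Numerical choices collected

* Degenerate min–max ranges (≤ 500·eps relative) normalize to zero maps.
* Bilinear resizing aligns pixel centers and clamps at borders; the same
  convention is used for the center–surround upsampling and is checked
  against a per-pixel brute-force oracle.
* FFT-based convolution pads by mirror reflection; kernels are odd-sized.
* Negative values after CSF modulation are clamped to zero (filtered
  contrast is non-negative by intent).
* AUC threshold sweep includes both endpoint vertices; tie handling is
  exact, not approximate.
* All fallbacks (zero feature weights, no local maxima) warn and are
  covered by tests.

## Problem sizes

The test-suite and the acceptance script run the full pipeline at a
225×400 working size — half the default linear resolution — which keeps
a complete version-3 run to a few seconds while leaving every scale of
the 10-map scheme well-resolved (scale 8 is still ≈ 6×8). Oracle
comparisons (explicit DFT, pair-counting AUC, per-pixel interpolation)
use ≤ 6×6 matrices where brute force is exact and fast. The metric
checks use 75–80 fixations and 100 negative splits, putting the
standard error of an AUC near chance at a few hundredths.

## Known limitations

* No high-level features (faces, text, horizon): out of scope for this
  model family by design.
* The Eq-ambiguities noted above (local CSF product domain; LocalMax
  construction; quadrature vs cosine Gabor phase) are resolved by
  documented package choices; alternative readings would change maps
  quantitatively but not the architecture.
* `pixels_per_degree` is a free calibration — no viewing geometry is
  specified by the model — so absolute CSF frequencies, including which
  pyramid scale sits at the sensitivity peak, shift with it.
* Version 3's scheme selection needs fixations; it is an oracle-style
  upper bound, not a content-adaptive predictor. An automatic
  content-analysis mechanism (e.g. edge-density based) would be the
  natural extension.
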