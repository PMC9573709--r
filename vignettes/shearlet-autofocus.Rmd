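---
title: "Shearlet-variance sharpness evaluation: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shearlet-variance sharpness evaluation: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shearFocus)
```

## The problem and the measure

Passive microscope autofocus acquires a defocus–focus–defocus stack and
seeks the frame maximising a sharpness evaluation function. For sparse cell
preparations the scene is a handful of compact objects on a near-uniform
background: most of the image's variance lives at very low spatial
frequencies, and a focus measure that sums raw gradients or spectral energy
over the whole frame is easily dominated by background fluctuations and
noise.

The measure implemented here addresses that by (1) decomposing the image
with a shift-invariant multiscale, multidirectional transform, (2) taking
each sub-band's *variance* as its energy, and (3) scoring sharpness as a
weighted ratio of high- to low-frequency energy:

$$E_L = V(\text{low}),\qquad
  SV_k = \sum_l V_{k,l},\qquad
  E^H_k = SV_k / 2^k,$$
$$E^H = s\,E^H_1 + (1-s)\,\frac{\sum_{k\ge 2} E^H_k}{w},\qquad
  h = E^H / E_L,$$

with defaults $s = 0.8$, $w = 3$ and $k = 1$ the finest scale. The variance
(population form, divide by $MN$) squares deviations from the sub-band mean,
amplifying the strong responses that appear when edges and texture are in
focus; the division by $E_L$ normalises out the background's scale so that
the score compares fine-scale structure against the slowly varying content
rather than against absolute intensity.

Two typographically plausible readings exist for how the coarser scales
enter $E^H$: dividing the coarse-scale *sum* by $w$, or weighting individual
scales. The executable (pseudo-code) form — `s*E2 + (1-s)*(E3+E4)/N` with
three scales — is unambiguous, so the sum-then-divide form is implemented
and generalised to any scale count as written above. Likewise, which high
band carries the dominant weight $s$ is a genuine choice; the finest band is
used because it is the band most sensitive to defocus, which is the signal
the measure exists to detect. The `1/2^k` attenuation then assigns
geometrically decreasing influence to coarser scales.

## The transform

The non-subsampled shearlet transform here is an additive frequency-domain
filter bank:

* **Scales.** Radial windows in the max-norm radius
  $\rho = \max(|\xi_x|, |\xi_y|)/\tfrac12 \in [0,1]$ telescope across
  dyadic cutoffs: the low-pass at scale $j$ transitions from 1 to 0 over
  $[2^{-j}, 2^{-j+1}]$, and band $j$ is the difference of consecutive
  low-passes. The transition profile is the maximally flat polynomial
  $\nu(t) = t^4(35 - 84t + 70t^2 - 20t^3)$ (id `"maxflat"`; a raised-cosine
  profile is available as `"cosine"`). Both satisfy
  $\nu(t) + \nu(1-t) = 1$, so all scale windows sum to one exactly.
* **Directions.** Each high band is multiplied in the frequency domain by a
  bank of smooth angular bumps on the orientation circle $[0, \pi)$, one
  wedge per direction (a power of two per scale, default 4), built from the
  same transition profile so they also form an exact partition of unity.
  The windows are symmetrised under frequency negation so real inputs give
  exactly real sub-bands.

Because every window set sums to one pointwise, synthesis is plain
summation: perfect reconstruction, linearity, the per-scale directional
partition identity, and shift equivariance (all filtering is circular) hold
*by construction*, up to FFT round-off (~1e-15 in the tests, against the
1e-6/1e-8 bounds the test suite asserts). `nsstReconstruct()` exists only to
certify this; the scoring pipeline never inverts the transform.

Images below 32×32 pixels (or $2^{N+2}$ per side for $N$ scales) are
rejected: the dilated coarse-scale windows are meaningless below that
support. The configuration records a nominal `shearFilterSize` for
provenance; the frequency-domain bank defines its windows on the full FFT
grid, so this parameter does not alter the filters.

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `nScales` | 3 | — | pyramid depth; low band covers $\rho < 2^{-3}$ |
| `directionsPerScale` | 4,4,4 | — | orientation wedges; the score sums variances over directions, so it is weakly sensitive to this count |
| `s` | 0.8 | — | weight on the finest-scale energy |
| `w` | 3 | — | divisor of the summed coarser-scale energies |
| `epsilon` | 1e-12 | — | guard for $E_L = 0$: a featureless image scores 0, ranking below any structured frame |
| noise `density` | 0.1 (salt-and-pepper), 0.01 (Gaussian variance) | [0,1] scale | corruption level |
| bilateral `spatialSigma`, `rangeSigma` | 3 px, 0.1 | px, intensity | joint-Gaussian window (radius 2·σ, replicate borders) |
| guided `radius`, `regularization` | 4 px, 0.01 | px, — | local linear model window and edge threshold |

## Curve statistics

Raw per-frame scores are min–max normalised; a zero-range curve is flagged
constant and maps to all zeros. The **narrow width** is the ratio of the
normalised curve's level-set widths at 0.8 and 0.4 around the peak; level
crossings are located by linear interpolation between adjacent frames
because stacks are short (≈20 frames) while the statistic is conventionally
reported to four decimals. The orientation width(0.8)/width(0.4) is used
because for any unimodal curve the 0.8-level set nests inside the 0.4-level
set, giving values in (0, 1] that *increase* with steepness. On a curve with
several peaks an explicit `peak` argument restricts the search to that
peak's basin (out to the nearest local minima), with levels taken relative
to the basin's peak height. A level never crossed inside the frame range
clips the width to the observed range, warns and sets a truncation flag.

**Unimodality diagnostics** collapse runs of equal values to the run's
leftmost frame; an interior local maximum must exceed both neighbouring
runs strictly, an endpoint its single neighbour; a constant curve has zero
maxima by convention. Ties for the global maximum make the narrow width
ambiguous and raise an error unless a peak is chosen.

## Noise protocol

Gaussian noise adds zero-mean variance-`density` noise and clips to [0, 1].
Salt-and-pepper corrupts, by default, *exactly* `round(density · MN)`
distinct pixels (a per-pixel Bernoulli mode is available) — the exact-count
convention makes worked examples and tests deterministic in the corrupted
count. Poisson noise draws each pixel from a Poisson law at the sensor's
quantisation (mean `pixel · 255`, rescaled), the standard shot-noise model
with no free parameter. All draws are seeded per specification and restore
the caller's RNG stream. In the robustness experiment frame $i$ uses seed
`seed + i`, so every measure scores identical corrupted frames.

## The synthetic stack generator

`makePhantom()` renders the statistics the measure is designed for: sparse,
bright, quasi-circular cells (low-order harmonic boundary perturbation
≤ 20% of the radius, soft ~1 px rim) with granular interior texture, placed
disjointly by rejection sampling over a near-uniform background with mild
(amplitude 0.02) low-frequency shading. The texture is white noise smoothed
by a 0.5 px Gaussian: granularity at the resolution limit, so the in-focus
frame genuinely carries finest-scale energy — a perfectly flat disk would
starve every high-frequency measure. `makeStack()` convolves the phantom
with a Gaussian (default) or pillbox defocus PSF, blur sigma
`|i − peak| · 0.6` px over 21 frames by default; sigma is exactly zero at
the peak, so the in-focus frame is the phantom itself and every measure's
maximum lands there by construction.

What the generator does **not** emulate: optical aberrations, illumination
fields beyond mild shading, sensor noise in the clean frames, and —
important for interpreting the robustness results below — the *relative
scale* of real sediment cells, which at 40× on 800×600 frames are far
larger in proportion to realistic defocus blur than 6–14 px cells are to a
6 px endpoint blur on a 256×256 phantom.

## Problem sizes

The test suite and the acceptance script run on 64–128 px images for
transform identities (they hold at any size by construction), the default
256×256 / 21-frame stack for curve-level properties, and five seeds for the
noise protocol. These sizes were chosen so the whole suite completes in
about a minute while every property is still exercised at a scale where the
phantom contains a realistic number of cells.

## Known limitations

* **Noise immunity on synthetic stacks.** The acceptance script computes
  peak-retention and unimodality fractions for the noisy protocols; on the
  default synthetic stack the salt-and-pepper (0.1) + bilateral condition
  fails them. The mechanism is instructive. A bilateral filter removes
  little impulse noise (the corrupted centre pixel and its same-polarity
  neighbours dominate the window weights), so the surviving impulses
  contribute a large, frame-constant amount of high-frequency energy that
  dwarfs the phantom's in-focus signal energy; meanwhile the small cells'
  spectral content sits near the low band's transition, where the
  strongest defocus blur attenuates it, so $E_L$ *falls* towards the stack
  ends and the noisy ratio $h \approx \text{const}/E_L$ peaks at the ends
  instead of the focus. The measure's premise — a focus-insensitive low
  band — holds when objects are large relative to both the blur and the low
  band's cutoff, as on real high-magnification microscope frames, but not
  at the phantom's geometry. The failing condition is reported honestly by
  the acceptance outputs rather than adjusted away.
* The Canny and DCT baselines follow standard textbook definitions with
  fixed thresholds; they are internally consistent for ranking experiments
  but not tuned to any particular reference implementation.
* BMP input is not supported (no reader in the dependency set); PNG, TIFF
  (8/16-bit) and JPEG are.
* The transform uses circular boundary handling throughout. This is what
  makes shift equivariance exact, at the cost of wrap-around edge effects;
  for focus scoring, which aggregates variances globally, these are
  negligible.
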