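# shearFocus

Sharpness evaluation (an autofocus criterion) for medical microscope images,
built around the non-subsampled shearlet transform (NSST).

## The problem

Passive autofocus sweeps the stage through the focal plane, scores every
frame with a *sharpness evaluation function*, and drives the motor to the
frame where the score peaks. For sparse scenes such as urinary-sediment
preparations — a few cells scattered over a near-uniform background — most
classical focus measures (gradient sums, Laplacian energy, spectral
fractions) respond as much to background and noise as to the cells, which
flattens the focus curve and creates spurious local peaks.

## The measure

An image is decomposed with a non-subsampled shearlet transform: a k-level
non-subsampled pyramid splits it into one low-frequency sub-band and k
high-frequency bands, and a bank of shear filters splits every high band
into directional sub-bands. Nothing is subsampled, so every sub-band has the
input's size and the decomposition commutes with translation.

Each sub-band's energy is its (population) variance

    V = (1/MN) Σᵢⱼ (g(i,j) − ḡ)²

and the score aggregates them as

    E_L  = V(low band)
    SV_k = Σ_l V(band k, direction l)          k = 1 is the finest scale
    E_kH = SV_k / 2^k
    E_H  = s·E_1H + (1 − s)·(Σ_{k≥2} E_kH)/w   with s = 0.8, w = 3
    h    = E_H / E_L

Dividing by the low-frequency energy suppresses the influence of the
background (which dominates the low band and barely reacts to defocus),
while the variance of the fine directional sub-bands reacts strongly to it.
The package also implements the classical measures used for comparison
(Tenengrad/Sobel, Roberts, Laplacian, energy of gradient, DCT, Canny, plain
variance), focus-curve statistics — min–max normalisation, the narrow width
α/β (ratio of the curve's widths at the 40% and 80% levels; closer to 1 is
steeper), unimodality diagnostics — a noise-immunity protocol (Gaussian /
salt-and-pepper / Poisson corruption with optional bilateral or guided
pre-filtering) and a synthetic focal-stack generator, so everything is
testable without microscope data.

## Worked example

```r
library(shearFocus)

stack <- syntheticStack(phantomSpec(seed = 1), sweepSpec())
stack
#> FocalStack: 21 frames of 256x256 [frame_01 ... frame_21]

curve <- scoreStack(stack, "nsst")
round(normScores(curve), 3)
#>  [1] 0.000 0.000 0.000 0.000 0.000 0.001 0.002 0.009 0.032 0.143 1.000 0.143
#> [13] 0.032 0.009 0.002 0.001 0.000 0.000 0.000 0.000 0.000

diagnoseCurve(curve)
#> CurveDiagnostics: argmax frame 11, 1 local maxima (unimodal), secondary peak 0.000

narrowWidth(curve)
#> NarrowWidth: alpha(0.4) = 1.3998, beta(0.8) = 0.4666, ratio = 0.3333

nsstEnergyBreakdown(frames(stack)[[11]])
#> EnergyBreakdown: EL = 0.006116, EH = 2.604e-05, h = 0.00425728
#>   per-scale SV: 5.141e-05 1.889e-04 2.787e-04
```

The sweep defocuses symmetrically around frame 11, and the score identifies
that frame, with a single local maximum. The normalised curve is extremely
peaked (the narrow width ratio 1/3 is the limiting value for a curve that
spikes over a single frame), reflecting how fast fine-scale variance decays
under Gaussian defocus. The energy breakdown shows where the in-focus score
comes from: the summed directional variances per scale (SV), their weighted
total (EH) and the low-band energy (EL) it is divided by.

A command-line wrapper over the same functions ships in
`inst/scripts/shearfocus.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("scripts/shearfocus.R", package = "shearFocus"))')" \
    synth --out stack_dir --seed 7
Rscript ... curve --source stack_dir --measures nsst,tenengrad --out results/
```

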