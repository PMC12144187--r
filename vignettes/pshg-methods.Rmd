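---
title: "Pixel-based PSHG analysis: model, estimators and phantoms"
author: "PSHGtools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pixel-based PSHG analysis: model, estimators and phantoms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(PSHGtools)
```

## The physical model

Polarization-resolved SHG records one image per incident linear-polarization
angle φ. Under the cylindrical-symmetry approximation for a fibrillar
harmonophore assembly, a pixel's intensity profile is

$$I(\varphi) = C^2 \sin^2 2(\varphi-\alpha)
  + \left[A \sin^2(\varphi-\alpha) + B \cos^2(\varphi-\alpha)\right]^2,$$

with α the in-plane fiber orientation (defined modulo 180°) and
$A = I_0\chi_{31}$, $B = I_0\chi_{33}$, $C = I_0\chi_{15}$. All angles at
the interface are degrees; radians appear only internally. Because the
signal is a polynomial in $\sin^2$ and $\cos^2$ of $(\varphi-\alpha)$, it
is exactly band-limited: writing $S = A+B$, $D = B-A$,

$$I(\varphi) = c_0 + c_2\cos 2(\varphi-\alpha) + c_4\cos 4(\varphi-\alpha),
\qquad
c_0 = \tfrac{C^2}{2} + \tfrac{S^2}{4} + \tfrac{D^2}{8},\;
c_2 = \tfrac{SD}{2},\;
c_4 = \tfrac{D^2}{8} - \tfrac{C^2}{2},$$

which rotates into the lab-frame five-coefficient series
$a_0 + a_2\cos2\varphi + b_2\sin2\varphi + a_4\cos4\varphi +
b_4\sin4\varphi$. `coeffsFromParams()` implements the closed form;
`synthesizeProfile()` reproduces `intensityProfile()` to machine precision
(property-tested over 1000 random parameter draws).

Two derived summaries matter scientifically:

* the susceptibility ratios $\chi_{15}/\chi_{31} = C/A$ and
  $\chi_{33}/\chi_{31} = B/A$, in which the incident-intensity factor
  cancels, and
* the effective α-helix pitch angle
  $\tan^2\theta^p = 2/(\chi_{33}/\chi_{31} - \chi_{15}/\chi_{31} + 1)$,
  defined only for a positive denominator, strictly decreasing in
  $\chi_{33}/\chi_{31} - \chi_{15}/\chi_{31}$, and approaching 90° as the
  denominator vanishes. `pitchAngle()` returns `NaN` (with a warning) where
  the relation is undefined rather than erroring, so it can run over whole
  maps.

Profiles with $\chi_{33}/\chi_{31} = 1$ and $C > 0$ collapse to
$A^2 + C^2\sin^2 2(\varphi-\alpha)$ and show two maxima per 180° period;
`classifyPeaks()` counts strict local maxima of the analytic profile on a
0.1° grid with plateau merging — cheap and unambiguous for a band-limited
signal, and verified against a brute-force count at a different grid step.

## Per-pixel estimation

For $P \ge 5$ equally spaced angles covering the 180° period (the standard
acquisition uses 18, 0°–170° in 10° steps), discrete means are exact
estimators of the five coefficients by orthogonality:
$a_0 = \mathrm{mean}(I)$, $a_n = 2\,\mathrm{mean}(\cos(n\varphi)\,I)$,
$b_n = 2\,\mathrm{mean}(\sin(n\varphi)\,I)$. For irregular grids the
package falls back to linear least squares on the five basis functions;
both paths share the same tests, and on noise-free profiles P = 9 and
P = 18 give identical results to 1e−10 (the signal is band-limited, so
nothing is gained beyond Nyquist for the fourth harmonic).

Inversion is algebraic. With $\hat\alpha = \tfrac12\,\mathrm{atan2}(b_2,
a_2)$, $c_2 = \sqrt{a_2^2+b_2^2}$ and the *signed* projection
$c_4 = a_4\cos4\hat\alpha + b_4\sin4\hat\alpha$:

$$B = \sqrt{a_0 + c_4 + c_2},\quad
A = \sqrt{a_0 + c_4 - c_2},\quad
C = \sqrt{(B-A)^2/4 - 2c_4}.$$

Numerical and statistical choices here:

* **Branch convention.** The orientation from the second harmonic is
  defined modulo 90° jointly with the sign of $c_2$. Taking $c_2 \ge 0$
  adopts the $B \ge A$ ($\chi_{33} \ge \chi_{31}$) representation,
  consistent with all reported collagen values of this ratio (≈ 1.05–1.16).
  This is not a restriction: a profile generated with $B < A$ is returned
  as the *same* profile's $B \ge A$ representation with α shifted by 90°
  (tested explicitly). A retry of the alternate branch cannot rescue a
  pixel whose $A^2 = a_0 + c_4 - c_2$ is negative — on the α + 90° branch
  the projected $c_2$ flips sign, so the failing quantity reappears as
  $B'^2$ — hence such pixels (a shot-noise phenomenon) are flagged invalid
  directly.
* **Signed $c_4$, not $\sqrt{a_4^2+b_4^2}$.** The sign of $c_4$ separates
  the $C^2$ from the $(B-A)^2$ contribution and is required for a correct
  $C$.
* **Negative $C^2$ clamp.** Shot noise commonly drives the $C^2$ estimate
  slightly negative; excursions above $-0.05\,a_0^2$ are clamped to zero,
  larger ones invalidate the pixel.
* **Isotropy.** Pixels whose second and fourth harmonics are below
  $10^{-9} a_0$ have no defined orientation; they are reported with
  α = 0, $A = B = \sqrt{a_0}$, $C = 0$, flagged `isotropic`, and excluded
  from orientation statistics.

`fitStack()` does all of this vectorized: one matrix product gives all
coefficient maps, inversion is element-wise arithmetic, and the residual
map is the RMS misfit of the synthesized series relative to $a_0$.
Optional neighbor averaging mean-filters the *coefficient* maps over a
$(2r+1)^2$ window before inversion (default radius 1 in the pipeline
configuration, off in the bare function). Averaging is applied to the
coefficients because they are linear in the measured data; averaging
derived, wrapped quantities such as α would bias near the 0°/180° seam.
Window edges renormalize by the in-image window area.

## Image-level statistics

* **Segmentation** (`normalizeAndSegment()`): the polarization-mean image
  is normalized by its 99.9th percentile — rather than the maximum, to
  resist hot pixels — clipped to [0, 1] and thresholded at 0.2 (the
  threshold is a configuration knob; 0.2 is an empirical default for this
  kind of data).
* **Mode values** (`modeValue()`): fixed-bin histograms, 0.01 for
  dimensionless ratios and 0.25° for angles, so two-decimal reporting is
  resolvable; ties break toward the lower bin. Bin widths are
  configurable.
* **Orientation distribution width** (`orientationSD()`): orientations are
  histogrammed in 1° bins on the 180°-periodic axis, the histogram is
  rotated so the modal bin sits mid-axis (the peak is never split by the
  wrap), and $y = y_0 + a\,e^{-(x-\mu)^2/(2\sigma^2)}$ is fitted by
  Levenberg–Marquardt least squares. The offset $y_0$ absorbs the
  isotropic floor seen in real orientation histograms. If the fit fails or
  degenerates, the function falls back to the circular standard deviation
  of the axial data (computed on doubled angles) and flags the result.
* **Fiber density** (`fiberDensity()`): fraction of *all* image pixels at
  or above 0.45 × mean intensity. The all-pixels denominator (rather than
  foreground-only) matches the mask-over-section reading of fiber-density
  figures; both the factor and the denominator convention are explicit
  arguments.

All statistics are invariant to rescaling the stack by any positive
constant (normalization and mean-relative thresholds), which is tested as
a property.

## The phantom generator

No public PSHG image data accompany the study system this package targets,
so the generator is a first-class, tested module rather than a fixture. It
emulates:

* **Gel matrices** (`pshgScenario("gel", col1Fraction)`): straight
  line-segment fibrils (1.5 µm thick at 0.5 µm/pixel, within the reported
  1.3–1.8 µm fibril-thickness range) at uniformly random orientations and
  positions, with per-fibril brightness drawn from U(0.6, 1); overlaps
  keep the brighter fibril. Anchors: the true pitch angle interpolates
  linearly from 47.72° at 100% Col I to 48.19° at 60% Col I;
  $\chi_{33}/\chi_{31}$ is pinned at the mid-range 1.13 and
  $\chi_{15}/\chi_{31}$ solved from the pitch target (one equation in two
  ratios — pinning one and solving the other preserves the pitch anchors
  exactly). Fibril length grows from 6 to 16 µm and the intensity scale
  rises linearly with Col I fraction such that the 80%:60% intensity ratio
  is 1.7.
* **Skin sections** (`pshgScenario("skin", condition)`): dense curved
  strokes (random walks in angle, 1° per 5-px step) whose base
  orientations are wrapped-normal with σ = 25° for scar and
  σ = 31° (= 1.24 × 25°) for healthy tissue; both use a pitch angle of
  46.7° with $\chi_{33}/\chi_{31} = 1.1$. Fibers are rendered 1 px wide at
  a 4 µm/pixel fiber-scale sampling so a 192² field carries thousands of
  independently oriented structures — the orientation-histogram width
  estimate is driven by the number of independent fiber orientations, not
  by pixel count, and a field with few thick bundles gives an unusably
  noisy width estimate (single bundles dominate histogram bins).

Rendering evaluates the forward model exactly per pixel; with a
`NoiseModel`, the stack is scaled so its brightest pixel has expectation
`peakCount` (1000 counts as the default operating point), then sampled
Poisson plus optional Gaussian read noise, clipped at zero. Identical
seeds give bit-identical phantoms and stacks.

What the phantoms do *not* emulate: optical point-spread blur,
birefringence and phase retardation in deep tissue, depth-dependent
scattering, detector pixel cross-talk, and the spatial intensity texture
of real collagen. Passing recovery tests therefore demonstrates estimator
correctness and noise robustness under the stated model, not performance
on real microscope data where those effects are present.

## Problem sizes and reproducibility of the checks

The test suite runs the estimator-calibration experiment on a 128×128
homogeneous phantom at 1000 peak counts (mode of the recovered pitch map
within 0.5° of truth, mode of $\chi_{33}/\chi_{31}$ within 0.02) and the
healthy/scar comparison on 192² fields with five healthy and seven scar
samples per run — the same per-condition sample design as the tissue
comparison it emulates; per-sample fitted widths scatter by a few degrees
(the effective sample size is the fiber count), so the conditions are
compared on mean fitted widths, whose ratio recovers the designed 1.24
contrast within 10%. All stochastic tests fix their seeds; the generator's
scientific parameters (dispersions, ratios, anchors) are part of the
scenario definitions above, not tuning knobs of the tests.

## Known limitations

* The 90° branch convention reports $\chi_{33}/\chi_{31} < 1$ structures
  (some muscle regions) in their reflected representation; the ratio maps
  remain correct as magnitudes of the equivalent representation, but α for
  such structures is shifted by 90°.
* The Gaussian width of a broad wrapped distribution (σ ≳ 40°) is poorly
  identified on a 180° axis regardless of estimator; the circular-SD
  fallback is reported flagged rather than silently substituted.
* Maps are written as 32-bit float TIFF scaled into [0, 1] by per-map
  factors recorded in `maps.yml` and the run report (the TIFF writer used
  stores samples in [0, 1]); invalid pixels are 0 in the map files, with
  validity in `valid_mask.tif`.
* Depth-resolved corrections (birefringence, retardation) are out of
  scope; the model is a surface-layer approximation.
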