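# PSHGtools

Pixel-based analysis of polarization-resolved second harmonic generation
(PSHG) microscopy, aimed at quantifying collagen organization — in
self-assembled collagen gel matrices of varying type I/III composition and
in skin tissue sections — without labels. The package takes a polarization
image stack (one frame per incident linear-polarization angle), fits every
pixel, and produces maps of fiber orientation, second-order susceptibility
ratios and the effective α-helix pitch angle, plus the image-level summary
statistics used to compare samples. A phantom generator renders synthetic
stacks with known per-pixel ground truth, so every stage of the pipeline is
testable end to end.

## The model

Under cylindrical symmetry, the SHG intensity of a fibrillar structure as a
function of the incident polarization angle φ is

    I(φ) = C² sin²2(φ−α) + [A sin²(φ−α) + B cos²(φ−α)]²

where α is the in-plane fiber orientation and A = I₀χ₃₁, B = I₀χ₃₃,
C = I₀χ₁₅ combine the incident intensity with the three independent
susceptibility tensor elements. The profile is exactly band-limited,

    I(φ) = a₀ + a₂cos2φ + b₂sin2φ + a₄cos4φ + b₄sin4φ,

so for P ≥ 5 equally spaced angles the five coefficients are plain discrete
means (`estimateCoefficients()`), and (α, A, B, C) follow in closed form
(`invertCoefficients()`) — no iterative curve fitting per pixel. The
susceptibility ratios χ₁₅/χ₃₁ = C/A and χ₃₃/χ₃₁ = B/A are intensity-free,
and the average organization of the peptide-bond harmonophores is
summarized by the effective α-helix pitch angle θᵖ:

    tan²θᵖ = 2 / (χ₃₃/χ₃₁ − χ₁₅/χ₃₁ + 1)

Image-level statistics mirror standard practice for this kind of data:
histogram mode values of the ratio and pitch maps, the standard deviation
of a Gaussian fitted to the fiber-orientation histogram, and a fiber
density from a binary mask at 0.45 times the mean intensity.

## Worked example

Simulate a collagen-gel phantom (80% Col I), render it with shot noise, and
run the full analysis:

```r
library(PSHGtools)

ph <- pshgScenario("gel", col1Fraction = 0.8, size = 192, seed = 42)
st <- renderStack(ph, noise = NoiseModel(peakCount = 1000, seed = 43))
st
#> PolarizationStack: 192 x 192 pixels, 18 polarization angles
#>   angles (deg): 0 10 20 30 40 50 60 70 80 90 100 110 120 130 140 150 160 170

res <- analyzeStack(st, runConfig(smoothRadius = 0, seed = 42))
res$stats[, 1:4]
#>   mode_chi15 mode_chi33 mode_theta orientation_sd
#> 1      0.495      1.125      47.88          34.31

geometry(ph)$thetaTrue
#> [1] 47.955
```

The mode of the recovered pitch-angle map (47.88°) sits within a tenth of a
degree of the phantom's generating value (47.955°), and the recovered
susceptibility-ratio modes (0.495, 1.125) match the generator's tensor
(0.505, 1.13) to within one histogram bin under shot noise at 1000 peak
counts. For a gel phantom the fibril orientations are uniform, so
`orientation_sd` is not informative there; it is the comparison statistic
for the `"skin"` scenario, where healthy-like fields are generated with a
24% wider orientation distribution than scar-like fields.

A single pitch-angle evaluation at reported gel ratios:

```r
pitchAngle(1.11, 0.51)
#> [1] 48.18969
```

The same pipeline is available from a shell via
`inst/scripts/pshg-cli.R` (`simulate`, `fit`, `summarize`, `pipeline`
subcommands).

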