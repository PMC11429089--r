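---
title: "Phantom-based image quality and dose analysis: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phantom-based image quality and dose analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mammoqc)
```

## The problem

Breast implants are radiopaque. When the automatic exposure control (AEC)
sensor of a mammography unit sits — partly or fully — under an implant, the
servo inflates the tube current-time product (mAs) to push the starved
detector signal up to its target, and the patient absorbs substantially more
dose without any clinical gain. A simple quality-control phantom — a PMMA
slab carrying a thick copper square (the implant stand-in) and a thin
aluminium square (a contrast insert) — lets a physicist reproduce the three
acquisition techniques that occur in practice (automatic with the sensor on
tissue, automatic with the sensor on the implant, and manual settings) and
quantify the consequences with task-based metrics.

`mammoqc` implements that entire workflow as code: a deterministic
acquisition simulator stands in for the mammography unit, and the analysis
chain computes the signal-difference-to-noise ratio (SDNR), the presampled
slanted-edge MTF, the normalized noise power spectrum (nNPS), the NPWE
model-observer detectability index for 0.1 mm and 0.25 mm disc tasks, and
the average glandular dose (AGD) per the EUREF formalism, with
Kruskal-Wallis / Dunn statistics for the technique comparisons.

## The acquisition simulator

### Signal model

The expected (noise-free) detector signal is

```
mean(x, y) = dcOffset + gain * mAs * heel(x, y) * blur(T(x, y)),
```

where `T` is Beer-Lambert transmission `exp(-sum_m mu_m t_m(x, y))` through
the PMMA slab and the insert squares, and `blur` is a Gaussian presampling
point-spread function of width `psfSigma` (default 0.035 mm). Because the
transmission of a uniform-thickness insert is linear in its indicator
function, the Gaussian blur of each rotated square is evaluated *in closed
form* as a product of error functions: the mean map is exact, fast, and the
realized edge profile is an analytic erf — which is what makes the Gaussian
MTF of the chain exactly `exp(-2 pi^2 sigma^2 u^2)` and recoverable by the
slanted-edge estimator to high accuracy.

The attenuation coefficients are *effective monoenergetic-equivalent*
values, not narrow-beam physics: every metric in scope depends only on the
realized contrast and noise, not on spectra. Defaults (per mm): PMMA 0.060,
Al 0.68 (giving an Al-square contrast of `1 - exp(-0.68 * 0.2) = 0.127`),
and Cu 0.598 so that a sensor fully under the 1 mm Cu square sees
transmission 0.55 and the servo answers with roughly the +80 % mAs
inflation observed on clinical units. These are configuration constants of
the beam object.

### Noise model

Pixels receive Gaussian quantum noise with variance
`quantumGain * (mean - dcOffset)` (default `quantumGain = 0.17`, chosen so
a flat field at the servo target shows ROI SNR near 50, typical of console
statistics) plus additive electronic noise (`electronicSD = 3` counts),
then are rounded to integer counts and clipped to 16 bits. Noise is applied
*after* the PSF blur of the mean map; the noise is therefore white by
construction and the blur-induced noise correlation of a real detector is
deliberately not modelled. Seeds are explicit arguments, recorded in the
image metadata, and the caller's RNG state is never disturbed.

### Heel field

The heel effect is a multiplicative field in (0, 1]. Along the
chest-wall-to-nipple axis the log-profile has three *plateaus* — an
elevated chest-wall level (1.113), a unit central level, and a reduced
nipple level (0.576) — joined by smoothstep transitions confined to the
row-fraction bands (0.16, 0.25) and (0.64, 0.84); a small linear
cross-tilt (6 % across the width) splits the two corners of each side.

The plateau design is deliberate. ROI statistics (SNR = mean/SD) measure a
*level* only where the field is locally flat; a globally smooth profile
steep enough to depress nipple-corner SNR by ~25 % puts a gradient inside
the corner ROIs, the ROI SD then measures the gradient rather than the
noise, and the observed uniformity pattern becomes an artefact of ROI
size. With plateaus under every standard ROI, five repeated flat fields
show chest-wall corner SNRs a few percent above centre and nipple corners
20-30 % below — the signature of a clinical unit — with repeatability COV
well under 0.02. The transition bands are also kept clear of the
horizontal slanted-edge analysis band, where a background trend along the
edge-spread direction would bias the low-frequency MTF.

### AEC servo

`emulateAEC()` selects kVp from a compressed-thickness lookup (28 kVp up
to 50 mm, stepping up beyond) and returns the mAs that brings the mean
expected signal over the 7 sensor footprints to the target (460 counts
above offset), quantized to 0.5 mAs and capped at 500 mAs (saturation is
an error). The servo is *flat-field calibrated per position*: the
footprint signal is referenced to the local heel level, so on a
homogeneous slab all seven positions select identical mAs — as clinical
units do, since they are calibrated against their own field
non-uniformity — and any mAs inflation purely reflects radiopaque
coverage of the sensor. The target of 460 counts is the calibration that
places the automatic reference exposure (98 mAs) below the reduced manual
exposure (104.4 mAs), reproducing the dose ordering reference < reduced <
recommended of the three techniques.

With the default geometry, sensor positions 1 and 2 are fully under the
copper square, position 3 half under it, and positions 4-7 outside: the
"misused" (1-3) vs "reference" (4-7) grouping of the comparison study.

### Frames and scaling

The default frame is a 512 x 640 px cut-down at the physical 70 um pitch;
the full 24 x 29 cm panel (3428 x 4142 px) is available behind a flag.
Insert and sensor geometry are defined as fractions of the frame, while
analysis ROI sizes are held fixed in *pixels* (64 px squares for SDNR and
nNPS tiles on small frames, the clinical 256 px ROIs on frames of 1024 px
or more), so ROI statistics transfer between frame sizes up to sampling
error. Repeatability runs use 1024 x 1280 px frames with 256 px ROIs —
the per-ROI pixel count of the clinical analysis at a fraction of the
cost.

## The metric chain

**SNR and SDNR.** `roiSNR()` returns `(mean - dcOffset)/sd`: the
offset-subtracted convention makes SNR vanish at zero exposure and is the
default; the raw-mean convention sits behind a flag. `sdnr()` is
`(mean_bg - mean_Al)/sd_bg`, offset-free by construction. Sample (n-1)
standard deviations are used throughout, matching small-replicate
summaries.

**Slanted-edge MTF.** Per scan line, the 50 %-threshold crossing of the
edge is located by linear interpolation around the maximum-gradient
sample and a straight line is fitted; angles outside 1-10 degrees or
steps below five local noise SDs are rejected. Pixels are projected onto
the edge normal, the ESF binned at a quarter pixel, differentiated by
centred differences, Hann-windowed about the LSF peak, and the DFT
magnitude (zero-padded for fine frequency sampling) is normalized to 1 at
zero frequency. Sparse empty bins are interpolated; more than 10 % empty
bins is an error suggesting a coarser bin fraction. On a noiseless
simulated edge with a 0.1 mm Gaussian PSF the estimate matches the
analytic MTF within 2 % up to 0.8x Nyquist.

**Normalized NPS.** From a homogeneous region (128 px on test frames,
512 px on full frames), half-overlapping square ROIs (stride half the ROI
side, nine tiles for a region twice the ROI side) are each detrended with
a fitted second-order 2D polynomial — enough to remove the heel trend
without eating broadband noise — and the scaled periodograms
`pitch^2/N^2 |FFT|^2` are averaged and divided by the squared
offset-subtracted large-area signal. Axial sections average the seven
frequency bins flanking each axis; the radial section averages annuli of
one bin width *excluding* those flank bins wherever the annulus still has
support (the spec sentence supports both the include and exclude
readings; one reading is applied consistently to both roles). Low-order
detrending necessarily removes power from the one or two lowest annuli,
so white-noise flatness is assessed above them; the Parseval identity
(integrated 2D spectrum = detrended pixel variance) anchors the FFT
scaling.

**NPWE detectability.** The disc task transform is
`S(u) = R J1(2 pi u R)/u` with `S(0) = pi R^2`. The eye filter is the
standard band-pass visual transfer function `VTF(f) = f^1.3 exp(-c f^2)`
in angular frequency, normalized to peak 1 with `c` fixed so the peak
sits at 4 cycles/degree, converted from image-plane frequencies through a
display magnification of 1.5 and a 400 mm viewing distance. The
detectability index is

```
d'^2 = [2 pi C I1]^2 / [2 pi I2],
I1 = int S^2 MTF^2 VTF^2 u du,   I2 = int S^2 MTF^2 VTF^4 nNPS u du,
```

with trapezoid integration on the shared frequency grid — the radial-nNPS
grid, onto which the averaged orthogonal MTF is interpolated; for
measured curves the grid ends at the detector Nyquist frequency
(7.14 mm^-1 at 70 um). The white-noise closed form
`d' = C sqrt(pi R^2 / N0)` (MTF = VTF = 1, grid extended far beyond the
task band) is the correctness anchor; an internal-noise term is not part
of this observer and is omitted. Contrast is measured on
offset-subtracted signal, `C = (mean_bg - mean_Al)/(mean_bg - dcOffset)`,
tied to the SNR convention.

**Average glandular dose.** `AGD = K g c s`: incident air kerma from
inverse-square tube output (`tubeOutput` 16.7 uGy/mAs at 1 m, a
calibration constant placing the recommended 120 mAs technique near
1.35 mGy), g and c bilinearly interpolated in (breast thickness, HVL)
from packaged tables, s per target/filter (W/Rh 1.042), and the
PMMA-to-breast equivalence table (45 mm PMMA = 53 mm breast). The factor
tables ship as versioned CSV assets transcribed to match the EUREF
formalism's standard-breast assumptions (age 50-64 glandularity column);
they are data, inspectable and replaceable, and no extrapolation is
performed outside their ranges. AGD is exactly linear in mAs at fixed
beam and geometry, which is why a 13 % mAs cut produces exactly a 13 %
AGD cut.

## The comparison studies

`runAECExperiment()` simulates replicate acquisitions at each sensor
position, computes the full metric set per image (MTF from that image's
own Cu edges, nNPS from its homogeneous region), groups positions 1-3 as
misused and 4-7 as reference, and reports median (IQR) summaries —
mean +/- SD for groups of exactly five — Shapiro-Wilk and Levene screens
(reported, never gating), the tie-corrected Kruskal-Wallis omnibus and
Dunn pairwise z-tests on pooled ranks with Bonferroni correction over all
pairs at alpha = 0.05. Quantiles are type-7 (linear interpolation).
`runManualExperiment()` compares the recommended manual exposure
(120 mAs), the console's first reduction level (a 13 % cut — the
magnitude is a configuration default consistent with dose linearity, not
a manufacturer datum), and the automatic reference arm.

Ten replicates per condition at the default test frame run in well under
a minute; every run is reproducible bit for bit from its seed base.

## What the generator does and does not emulate

The simulator reproduces: linear "for processing" signal, offset and
gain, Poisson-like and electronic noise, Gaussian presampling blur, heel
non-uniformity, servo behaviour with a movable sensor, and the dose
arithmetic. It does **not** model spectra, scatter or grids, detector
glare, noise correlation from blur, real anatomy or implant shapes, or —
importantly — *session-to-session variability* (repositioning, tube
output drift): replicate scatter comes from counting noise alone.
Consequently equivalence-style conclusions are overpowered relative to a
physical study: a ~6 % image-quality drop that a clinical study may not
flag at n = 10 is decisively flagged here. Passing tests therefore
demonstrate the correctness and internal consistency of the metrics and
the direction and scale of the technique effects, not the absolute
metric values or p-values of any particular physical unit.

## Numerical choices and degenerate inputs

Quarter-pixel ESF bins with a Hann window; second-order polynomial
detrend; type-7 quantiles; Bonferroni multiplication capped at 1; mAs
quantized to 0.5; zero-SD ROIs, zero-noise d' denominators, out-of-table
dose lookups, axis-aligned edges and unreachable servo targets are all
*errors with diagnoses*, never silent NaNs or extrapolations. Radial
nNPS annuli whose off-axis exclusion would leave them empty fall back to
all off-DC bins of the annulus, so the detectability integrand is defined
from zero frequency.

## Known limitations

Absolute d' values exceed those of any particular clinical unit (no
detector glare or scatter floor is modelled, and the simulated MTF is
comparatively good); only orderings and scalings are asserted. The heel
field is not resolved in the dose model (AGD uses a single incident air
kerma). The EUREF factor tables are transcription-grade data assets, not
a certified dosimetry service. The AEC does not modulate kVp jointly with
mAs on radiopaque targets — phantom studies observe stable kVp at fixed
thickness, and the thickness lookup reflects that.
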