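---
title: "ribbonq: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ribbonq: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ribbonq)
```

# What the package computes

`ribbonq` re-implements, as a tested and reusable pipeline, the
quantification used in studies of zebrafish lateral-line hair cells:
counting and pairing of presynaptic ribbon (Ribeye) and postsynaptic
density (MAGUK) puncta in 3D immunofluorescence stacks, analysis of
evoked and spontaneous Ca^2+^ indicator traces, and four-parameter
logistic dose--response fitting. Because raw imaging data of this kind
is rarely released, every stage is exercised against a built-in
synthetic phantom generator that returns exact ground truth.

# Morphology pipeline

## Background subtraction

Each z-slice is background-corrected by the rolling-ball estimate:
grayscale opening with a non-flat ball structuring element of radius
`rolling_ball_radius` (default 50 px), subtracted from the slice. For
radii above 10 px the opening is computed on a block-minimum
downsampled grid with a correspondingly shrunk ball and interpolated
back (the standard acceleration for large balls); the background is
finally clipped below the image so the output is non-negative. A
constant slice maps exactly to zero and a planar gradient is removed,
which the tests verify against a naive double-loop opening.

The ball radius is not a sensitive parameter as long as it is large
relative to the puncta (sub-micrometre objects, i.e. < 10 px at the
default pixel size); 50 px is kept configurable.

## Band-pass

The PSD channel is additionally band-passed to suppress structures
outside the 6--20 px band, using a per-slice difference of Gaussians
with `sigma = size / 2.355` (FWHM-matched). The closed-form response of
a DoG to a Gaussian blob of variance $s_b$ is
$s_b/(s_b+s_1) - s_b/(s_b+s_2)$, which the tests use as the oracle: a
single-pixel impulse and a 40 px structure are both attenuated relative
to a 10 px structure. With this kernel dialect the attenuation of a
40 px blob is a factor ~3 relative to 10 px, not total suppression; the
filter is a preference, not a brick wall.

## Segmentation

The (corrected, and for the PSD channel band-passed) stack is min--max
normalized per stack, binarized, and split into puncta:

1. **Threshold** -- Otsu's method on a 256-bin histogram of the
   normalized stack by default; an absolute threshold on the normalized
   scale can be supplied instead (useful when the half-max footprint
   itself is the quantity of interest, since thresholding a noise-free
   blob at 0.5 of its normalized peak reproduces its half-max area).
   Normalization is per stack, not per slice, so axial intensity decay
   is not re-amplified slice by slice.
2. **Seeds** -- local maxima of the smoothed (sigma = 1 px) normalized
   stack, with a minimum Chebyshev separation `maxima_min_distance`
   (default: the expected punctum diameter in pixels, derived from the
   channel's minimum area).
3. **Watershed** -- foreground voxels are visited from brightest to
   dimmest; an unlabeled voxel joins the label of its brightest
   already-labeled 26-neighbor. This grows basins downhill from the
   seeds and splits touching puncta along their intensity saddle;
   components without any seed start a fresh label at their brightest
   voxel, so the flood is a strict superset of connected-component
   labeling and every above-threshold voxel gets exactly one label.

Each label is then measured: intensity-weighted 3D centroid converted
to micrometres with the anisotropic voxel sizes (0-based voxel
coordinates), the area of its max-projection footprint (per-label
projection, so two puncta overlapping only in projection keep separate
footprints and counts), and the integrated intensity of that footprint
on the max projection of the *input* (non-normalized) stack, so
intensities stay in acquisition units. Multiplying a stack by a gain
factor k multiplies integrated intensities by k and changes nothing
else.

The minimum projected-area filter (ribbon 0.08 um^2, PSD 0.04 um^2) is
applied after measurement with an inclusive boundary: a punctum exactly
at the minimum is kept, one at 0.079 um^2 is removed. For
extrasynaptic-aggregate counting the filter is skipped entirely.

## Pairing

A ribbon--PSD pair is a complete synapse when the 3D Euclidean distance
between centroids is at most the radius-sum threshold
$\sqrt{A_r/\pi} + \sqrt{A_p/\pi}$ computed from the two projected 2D
areas (mixed 2D-area / 3D-distance convention, matching the original
workflow). With the two minimum areas this is
$\sqrt{0.08/\pi} + \sqrt{0.04/\pi} \approx 0.2724$ um. Candidates are
matched greedily in ascending distance order, ties broken by
(ribbon id, PSD id), strictly one-to-one; the wording "find *the*
partner punctum" implies a unique partner, and one-to-one matching
makes the pair count well-defined. Pairing is therefore invariant to
input order. Unpaired PSDs are the orphan postsynapses; unpaired
ribbon puncta from an unfiltered segmentation pass give the
extrasynaptic Ribeye count.

`proximity_summary()` reports the percentage of distances strictly
below a cutoff (matching the "< 1 um" convention), rounded to the
nearest integer percent, with the median of the within-cutoff subset.

# Trace analysis

## Evoked responses

`F0` is the mean over the pre-stimulus window, `dF/F0 = (F - F0)/F0`,
and the peak is taken over all frames from stimulus onset to the end of
the record (not the stimulus window alone -- slow indicators peak after
stimulus offset). Activity classification uses a *strict* threshold:
peak > 0.25 for the presynaptic membrane indicator, > 0.05 for the
mitochondrial indicators; a peak exactly at the threshold is inactive.
`dF/F0` is invariant under multiplicative gain by construction.

## Bleach correction

The correction model is mono-exponential plus offset,
$a e^{-t/\tau} + c$, fitted by Levenberg--Marquardt with iterative
masking (up to six rounds) of samples more than 2 robust SD above the
fit, so transient events do not bias the baseline; the trace is divided
by the fitted curve normalized to its value at t = 0, which preserves
dF/F0 ratios. A flat trace passes through essentially unchanged, and a
failed fit falls back to a flagged no-op rather than silently altering
the data.

## Spontaneous statistics

Baseline `F0` is the bottom 15th percentile of the corrected
fluorescence values -- read as the 15th-percentile *value* with linear
interpolation; the alternative reading (mean of the lowest 15% of
samples) is available via `percentile_mode = "mean_below"`. `dF/F0`
samples below the 10% noise threshold are zeroed before anything else,
i.e. the threshold is applied per sample, not only to event peaks. The
per-cell magnitude is the sum of the remaining `dF/F0` divided by the
frame count (generalizing the fixed divisor of 300 frames, which is
exactly a 900 s recording at 0.33 Hz). Events are local maxima of the
thresholded `dF/F0` with a minimum separation of 3 frames and a minimum
prominence equal to the noise threshold -- at the 0.2--0.33 Hz
acquisition rates this counts one peak per transient; frequency is the
event count divided by the recording duration.

## Registration, ROIs, correlation, normalization

Frame-to-frame drift is estimated as an integer-pixel translation by
FFT cross-correlation against the first frame, ties broken toward zero
shift (a constant movie registers at (0,0)). Rotation is not modeled:
the drift in these preparations is translational and the synthetic
fixtures contain no rotation. Circular ROIs include the pixels whose
*centers* fall inside the circle, making ROI pixel counts exactly
reproducible from the diameter and pixel pitch. Two-channel coupling is
summarized as the Pearson correlation of every cell pair, with
zero-variance traces yielding flagged `NA` entries. Baseline
pharmacology experiments are normalized to mock-treated controls
imaged in the same trial: each treated post/pre ratio is divided by the
mean mock post/pre ratio, so the mock set itself averages to 1.

## Dose--response

The 4PL model with variable slope,
$y = b + (t - b) / (1 + (d/\mathrm{IC}_{50})^h)$, is fitted by
Levenberg--Marquardt with starting values from the data extremes and
the dose nearest the midpoint crossing. Dose 0 is handled by the closed
form ($0^h = 0$, so the fitted response at dose 0 is the top
asymptote). A response table carrying no dose information is reported
as a degenerate fit, never as a spurious IC~50~.

# The synthetic phantoms

## Image phantoms

Puncta are rendered as anisotropic 3D Gaussians. The lateral sigma is
set from the sampled true area A via $A = 2\pi \ln 2\, \sigma^2$, so
the *half-max projected footprint* of the blob equals the sampled area
by construction -- the property the segmentation round-trip test
checks. The axial extent defaults to a 0.9 um FWHM, the measured axial
resolution scale of Airyscan systems. Voxel sizes default to 0.3 um
axial and 0.05 um lateral; the acquisition pixel pitch is not published
for these data sets, so the lateral default was chosen once as a
typical Airyscan sampling that makes the 6--20 px band-pass span
0.3--1 um structures, and is configurable.

Ribbon sites are placed uniformly with a minimum mutual separation
(default 1.2 um) so phantom puncta are resolvable; each paired PSD sits
at a |Normal(0.15, 0.03)| um gap in a uniform random 3D direction.
Per-blob peak amplitudes are jittered +/-30% so intensity measurements
have dynamic range; the optional third channel deposits a scaled copy
of each ribbon blob (coefficient x ribbon amplitude), giving an exact
linearity target for ROI intensity measurements. Background is a
constant plus a planar gradient along x; noise is Poisson
(photon gain g: `rpois(F/g) * g`) followed by additive Gaussian read
noise, the standard detector model, in that order. With peak intensity
100 and gain 1 the peak SNR is 10, the stress condition used in the
recovery tests.

The phantoms deliberately contain no PSF convolution, no Airyscan
reconstruction artifacts, no cell-body autofluorescence, and no
clustered/overlapping synapses beyond what the gap distribution
creates. Passing the recovery tests therefore shows the pipeline's
logic is correct on resolvable puncta at realistic noise, not that it
would segment arbitrarily crowded real tissue.

## Trace phantoms

Evoked traces follow
$F(t) = F_0 (1 + r(t))\, e^{-t/\tau_\mathrm{bleach}}$ where the
response r(t) rises as $1 - e^{-t/\tau_r}$ toward the channel plateau
while the stimulus is on and decays as $e^{-t/\tau_d}$ after it ends --
the single-exponential impulse response driven by a boxcar stimulus,
which makes the plateau the exact noise-free peak for stimuli much
longer than the rise constant. Channel defaults mirror the two
compartments studied: a fast cytosolic indicator (rise 0.06 s, decay
constant 3--4 s, i.e. return to baseline within ~12 s) and a slow
mitochondrial one (rise on the second scale, decay constant ~100 s,
i.e. ~5 min return).

Spontaneous events are a Poisson process per cell; when an exact
planted count is requested the times are instead placed one per
stratum of the recording with a guaranteed minimum separation, so a
9-event/900 s phantom yields exactly 0.01 Hz. Each event adds a
difference-of-exponentials transient normalized to unit peak and
scaled by a |Normal| amplitude. A fraction `coupling` of events is
shared between the first two channels at identical times *and
amplitudes* (coupled biological events drive both reporters);
channel-specific events get independent times and amplitudes.
Bleaching multiplies the whole trace by $e^{-t/\tau}$; Gaussian noise
is added last.

# Numerical choices and degenerate inputs

- Problem sizes: the recovery tests use 16 x 400 x 400 voxel phantoms
  (60 ribbons, 50 synapses) for the end-to-end checks and
  12 x 160 x 160 phantoms elsewhere; spontaneous recordings are 900 s
  at 0.2--1 Hz. These sizes give stable statistics while keeping the
  whole suite to a few minutes on one core.
- Empty or all-zero stacks segment to an empty punctum list, not an
  error; empty punctum lists pair to zero pairs with correct orphan
  counts.
- Thresholding uses `>=` on the normalized stack; min-area filtering
  uses `>=` (inclusive); activity classification uses `>` (strict);
  proximity uses `<` (strict). Each convention is pinned by a test.
- All generators consume a single integer seed and are bit-reproducible;
  every written table carries a provenance header (package version,
  seed, config hash).

# Known limitations

- The watershed operates on smoothed intensity, not a distance
  transform; heavily overlapping puncta of very different brightness
  can split asymmetrically.
- Integer-pixel registration cannot correct sub-pixel drift or
  rotation.
- The band-pass only attenuates out-of-band structure (factor ~3 at
  4x the band edge); gross low-frequency background should be removed
  by the rolling ball first.
- The bleach model is mono-exponential; strongly bi-exponential
  bleaching will leave residual drift (the fit diagnostics expose
  this via the returned `tau` and `corrected` flag).
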