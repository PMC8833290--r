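---
title: "Methods: CBCT image-quality and geometric-stability metrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CBCT image-quality and geometric-stability metrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cbctqa)
```

# Scope and model of the data

`cbctqa` quantifies the imaging performance of a cone-beam CT scanner from
axial reconstructions of modular QA phantoms (the CatPhan family is the
archetype) plus two small tables: per-angle geometric corrections from
repeated flexmap calibrations, and pencil-chamber dose-length products
(DLPs) from the standard 32 cm body dosimetry phantom. The package computes

* **imaging fidelity** — rod-centre distances on a four-rod 50 mm square
  versus their physical truth;
* **CT-number accuracy and linearity** — insert ROI means regressed on
  nominal HU;
* **uniformity** — a signed edge-versus-centre statistic on band-averaged
  CT-number profiles;
* **CNR** — insert-versus-adjacent-background contrast over pooled noise;
* **NPS** — the difference-image ROI-ensemble 2D noise power spectrum,
  its radial reduction and integrated noise magnitude σ~NPS~;
* **MTF** — slanted-edge spatial resolution with the limiting frequency
  f~lim~ at the 10% level;
* **CBDI~w~** — the weighted cone-beam dose index from the five DLP
  readings;
* **calibration reproducibility** — offsets, per-angle spreads and
  rotation-direction hysteresis of the nine flexmap corrections.

Everything consumes one spatial convention: voxel arrays indexed
`[row, col, slice]`, mm coordinates with the origin at the centre of the
first voxel, HU stored as floating point. Reconstruction itself, marker
detection on raw projections, and any physical scatter or beam-hardening
modelling are out of scope: the package starts from reconstructed HU
volumes and from the *outputs* of a flexmap calibration.

# The synthetic test bed

Because deposited scanner data do not exist for this class of device, the
generator in `render_phantom()`, `render_edge()`,
`simulate_calibration_runs()` and `simulate_dlp()` is a first-class,
tested module, and every metric is validated by parameter recovery
against its embedded ground truth.

**What it emulates.** A water-equivalent disk in air (20 cm diameter by
default, 0.4 × 0.4 mm² pixels — the output grid of the scanner class this
models), cylindrical inserts and four fidelity rods rendered with
analytic area-fraction anti-aliasing (4 × 4 subsampling at boundaries) so
noiseless centroids are sub-pixel exact; additive white or
low-frequency-weighted noise; Gaussian blur; a radial *parabolic* cupping
field whose edge-minus-centre value is the stated amplitude; a linear
rim-smearing deficit emulating detector-saturation handling; and a ghost
contour just inside the rim emulating the double contours left by
scan-to-scan geometric instability. Degradations apply in a fixed order
(blur, cupping, smear, ghost, noise) and are exactly reproducible from
the seed.

The parabolic cupping field is the simplest smooth radial field
consistent with reporting only an edge-versus-centre number; the ghost
contour is phenomenological (an additive Gaussian ring at a configurable
offset), because no quantitative model links contour displacement to the
underlying geometric fluctuation — the offset is therefore exposed
directly. Colored noise is synthesized by spectral shaping
|f|^(−exponent/2) of white noise and rescaling to the target SD, which
reproduces the qualitative low-frequency weighting of real CBCT noise
without claiming the device's actual spectrum.

**What it does not emulate.** Projection-space physics (scatter, beam
hardening, lag), streaks, aliasing from angular undersampling, or
spatially varying noise. Passing recovery tests therefore demonstrates
the *estimators* are correct and well-calibrated, not that real scanner
artefacts are fully captured.

**Calibration ensembles.** Each of the nine corrections (focal-spot and
detector-midpoint translations in mm, detector rotations in degrees) is
offset + sinusoidal angular modulation ± half the direction hysteresis +
per-angle Gaussian fluctuation. Defaults mirror the magnitudes observed
on a mobile ring-gantry unit: systematic offsets up to 11.5 mm (tCz) and
0.64° (rx), per-angle fluctuation SDs from 0.6 mm (tSy) to 3.0 mm (tSz),
hysteresis up to 4.6 mm (tSz), over the 520° orbit sampled in 10° steps
(53 views). Values without a published counterpart (e.g. the modulation
amplitudes) were fixed once at plausible mid-range magnitudes.

# Statistical and numerical choices

## ROI statistics

Circular-ROI membership is "pixel centre strictly inside the circle";
rectangular ROIs are half-open `[corner, corner + extent)`. The ROI SD is
the population SD. None of these conventions is dictated by the
measurement definitions, so they are fixed here for exact
reproducibility; with the thousands of pixels of a QA ROI the
population/sample distinction is far below any reported precision.

## Calibration reproducibility

The "overall" mean ± SD of each correction pools all (angle, run)
samples within one rotation direction, reading "averaged over the entire
orbit and all calibrations" literally; whether that SD should instead be
taken across per-run orbit means is ambiguous, so the alternative is
available via `pool = "run_means"` without being endorsed. Per-angle SDs
across runs use n − 1. The CW/CCW comparison differences the two
directions per run and angle, averages over runs, and takes the absolute
value *after* averaging. Angle grids must match exactly across runs — the
device samples a fixed schedule, so interpolation would only disguise
acquisition errors.

## Rod detection and fidelity

The detection threshold sits halfway between the slice median (the
background, assuming the phantom fills most of the field of view) and the
0.999 quantile (the rod plateau); components are labelled, the four
largest kept, and centroids are intensity-weighted. Measured pair
distances are matched to nominal by rank order — with only two distinct
nominal lengths (side, diagonal) this is robust without solving a general
assignment problem. Fidelity uses distances only, so it is invariant to
global translation and rotation of the rod set; tests assert this.

## Uniformity

"Profile length" is the masked phantom extent along the profile
direction, not the image width — 5%/95% of the image width could fall in
air and make the statistic meaningless. Edge and centre values are single
linearly-interpolated samples at 5%, 50% and 95% of that extent (no local
averaging; an averaging window would change the statistic and the
definitions give no licence for one). The result keeps the sign of the
larger edge-minus-centre difference. Note one consequence verified by the
closed form: for a parabolic cupping field of amplitude A the statistic
reads A·(0.9)² ≈ 0.81 A, because the 5% sample sits at 0.9 of the disk
radius — recovery tests compare against the parabola evaluated at the
actual sample position, not against A.

## NPS

The estimator is the difference-image ROI-ensemble periodogram: two
slices four slice-thicknesses apart are differenced; >200 overlapping
5 × 5 cm² ROIs are placed on a regular grid (default 6 mm stride) fully
inside the disk; each ROI is offset-corrected by its own mean, DFT'd,
and the squared moduli averaged and scaled by ΔxΔy/(NxNy) with a final
factor 1/2 for the variance doubling of the difference image. No taper or
detrending beyond the mean subtraction is applied — leakage is accepted
and vanishes for white noise, where the estimator is tested. Overlapping
ROIs are deliberately allowed: a 20 cm disk cannot hold >200 disjoint
5 cm ROIs; the induced correlation between periodograms biases nothing,
it only slows the variance decay of the ensemble average.

The radial 1D NPS is an unweighted mean over annuli one frequency sample
wide. Integration to σ~NPS~ weights each annulus by its *exact discrete
area* on the frequency grid (n~k~·Δf², equal to 2πf~k~Δf for annuli fully
inside the grid). The continuum Jacobian 2πfΔf would over-count the
clipped corner annuli of the square frequency support by a factor
approaching 2π/4 in total power, so the discrete-area rule is what makes
the radial route agree with the direct 2D integral (tested to be exact
here, with a 2% tolerance granted for binning in general).

Dose normalization of noise ("noise at 1 mGy") uses the quantum-limited
square-root law σ(ref) = σ(D)·√(D/ref). This is an assumption of the
report layer — the conversion rule is not part of any measurement
definition used here — and is documented as such.

## MTF

The oversampled ESF is built classically: per-row half-maximum crossings,
a line fit for the edge angle (admissible tilt 0.5–15°; at 0° there is no
sub-pixel phase diversity and a warning is raised), and projection of
every pixel onto the signed distance from the fitted edge. The ESF is
characterized by a Fermi (logistic) step
E(x) = B + A/(1 + exp(−(x − x₀)/s)) fitted with deterministic
initialization (plateau medians, half-crossing, IQR/2.2) and perturbed
restarts.

Two MTF routes exist, and the distinction is the package's main design
decision. `mtf_from_lsf()` is the *model-based* route: the LSF is the
analytic logistic density of the fitted width, sampled at one tenth of
the pixel size, with closed-form transform 2π²sf/sinh(2π²sf). It is exact
when the edge truly is Fermi-shaped. But the logistic is not a universal
PSF model: for a Gaussian kernel the best-fitting width is s ≈ 0.588σ and
the model MTF then deviates from the true Gaussian MTF by up to ≈0.05,
placing the model f~lim~ where the true kernel MTF is ≈5%, not 10%. The
end-to-end pipeline `edge_mtf()` therefore computes the reported MTF
*nonparametrically*: the oversampled ESF is bin-averaged and interpolated
onto a regular grid at pixel/10, differentiated centrally, zero-padded
and DFT'd, normalized to MTF(0) = 1, with f~lim~ linearly interpolated at
the 10% level (threshold configurable). For noiseless Gaussian edges of
σ ∈ {0.3, 0.5, 0.8} mm this recovers the analytic Gaussian MTF to better
than 0.02 up to 0.8 × Nyquist, which the test suite asserts. The Fermi
fit is retained in the pipeline for robust edge location and reported
width. Frequencies are reported both in cycles/mm and lp/cm (10 ×).

## CBDI~w~

CBDI~w~ = DLP~central~/(3L) + 2·mean(DLP~peripheral~)/(3L) with L the
chamber length, carried as data (10 cm default) rather than a constant.
The weights sum to 1/L, so equal DLPs D everywhere give exactly D/L;
linearity in every DLP holds to machine precision and is tested.
Replicate tables aggregate with n − 1 SD. `simulate_dlp()` inverts the
formula exactly, so the recovery test is algebraic; with multiplicative
reading noise of CV 5% the estimator is unbiased to <0.5% over seeds.

# Degenerate inputs and error policy

Errors are raised (never silently corrected) for: ROIs crossing the
slice boundary, mismatched calibration angle grids, fewer detected
components than expected rods (with the count in the message), identical
difference-image slices, heterogeneous ROI shapes in an NPS ensemble,
ESFs without two distinct plateaus, non-positive Fermi widths, and DLP
tables without exactly one central and four peripheral rows. Warnings
cover recoverable oddities: a schedule step not dividing the range, slice
pairs not 4 thicknesses apart, and edge angles below the oversampling
threshold.

# Problem sizes in the tests

The suite renders 512² slices at 0.4 mm for the headline recovery checks
(matching the modelled scanner grid) and 256²–280² grids at 0.4–0.8 mm
for replicated Monte-Carlo loops (50-seed rod detection, 20-seed
linearity, 200-ensemble calibration recovery). These sizes were chosen so
each recovery statistic has comfortably more precision than the tolerance
it is tested against; the full suite runs in well under a minute of CPU.

# Interfaces

The package is a library: the exported functions plus
`scripts/acceptance.R` (which regenerates the headline synthetic-phantom
quantities as JSON) are the interface, and tabular inputs travel as plain
CSV (`read_calibration_csv()`, `read_dose_table()`), volumes as NIfTI-1
or a raw-binary + JSON fallback. DICOM series are not read directly;
convert to NIfTI upstream and, if needed, use `apply_rescale()` for
stored-value-to-HU transforms.

# Known limitations

* Degradations are phenomenological; no projection-domain simulation.
* The nonparametric MTF inherits noise from the ESF derivative; for very
  noisy edges the Fermi-model route is more stable but model-limited.
* Rod detection assumes compact, well-separated rods and a phantom
  filling most of the field of view.
* Nominal insert HU values are configuration, not built-ins: vendors
  publish them per phantom, so tests here use synthetic truth only.
* The noise-versus-dose conversion assumes quantum-limited scaling;
  electronic noise floors would break the square-root law at low dose.
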