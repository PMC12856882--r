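---
title: "Discrete-mode nano-DESI imaging: model, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discrete-mode nano-DESI imaging: model, assumptions, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nanodims)
```

## The measurement this package models

Nanospray desorption electrospray ionization (nano-DESI) samples a tissue
surface through a liquid junction: solvent wets a ~100 um spot, dissolves
analytes, and carries them to an electrospray emitter. In the conventional
*continuous* mode the probe rasters linescans at constant speed, so every
tissue location is exposed to solvent only for the junction transit time
(diameter / speed; 20 s for a 100 um junction at 5 um/s). In *discrete*
mode the probe parks on each location for a dwell period (1.5 min per
pixel in the reference imaging protocol) before lifting and repositioning.

The payoff of parking is a time axis. During the dwell, species dissolve
at rates governed by how they are held in the tissue: freely soluble
cytosolic proteins flood out immediately and are depleted within tens of
seconds, lipid-anchored membrane-associated proteins emerge after a delay
and peak later, and integral membrane proteins dissolve so slowly that
their signal is still accumulating when the dwell ends. Each pixel of a
discrete-mode image therefore carries an ordered series of native mass
spectra, and each species a chromatography-like *elution profile* whose
shape reports its solubility class. The package's four-dimensional image
store — (x, y, elution time, m/z) — makes that axis a first-class
coordinate: ion images can be restricted to elution-time windows,
segmentation can use the full time-summed spectrum, and chimeric MS2
spectra can be disentangled by when their product ions appear.

## The scan-time convention

Scan indices are 0-based and elution-time windows half-open: scans
`a`..`b` at scan period `dt` span `[a*dt, (b+1)*dt)`. This is the only
convention that reproduces both printed reference mappings at `dt = 2.6` s
(scans 2–4 spanning 5.2–13.0 s, and scans 19–21 spanning 49.4–57.2 s), so
it is adopted package-wide; the scan period is always a schedule field,
never a constant. Half-open windows make adjacent windows tile the time
axis exactly, which the ion-image additivity tests exploit. Raw-stream
scan times are relative to acquisition start; `detect_contact()` locates
the total-ion-current jump when the probe touches tissue, and times are
then re-zeroed so that pre-contact scans carry negative times and are
excluded downstream rather than silently dropped.

## The synthetic-data generator

No instrument data ship with the package; a forward simulator defines the
study conditions and gives every downstream stage a ground truth to be
tested against.

**Dissolution kinetics.** The empirical profile shapes are emulated with
three parametric forms, each normalized to unit peak:

* soluble: `exp(-t / tau_fast)`, default `tau_fast = 10` s — intense on
  contact, ~5% left after 30 s;
* membrane-associated: `(t / tau_rise) * exp(1 - t / tau_rise)`, default
  `tau_rise = 30` s (25 s for the second default species, so the two are
  distinguishable) — delayed onset, peak at `tau_rise`;
* transmembrane: `(1 - exp(-t / tau_rise)) * exp(-t / tau_slow)` scaled to
  unit maximum, defaults `tau_rise = 30` s with `tau_slow = 120` s
  (VDAC-like) or 900 s (myelin-protein-like, near-flat over a 90 s dwell).

The functional forms and time constants are this package's own choices:
the reference measurements publish only empirical profiles, qualitatively
characterized (soluble signal gone by ~30 s, membrane proteins peaking
later, the myelin protein near-flat). Defaults were chosen once to match
those qualitative descriptions and are not tuned thereafter.

**Spectra.** Each species is a charge-state series at
`(M + z * m_p) / z` (proton mass 1.00728 Da) with Gaussian peaks whose
width follows an Orbitrap-like resolving-power law, `R_eff =
R_ref * sqrt(200 / mz)` with `R_ref = 7500` at m/z 200 — at this
resolution a 30 kDa native protein shows no isotopic fine structure, so a
single average-mass peak per charge state is the honest model. Average
(not monoisotopic) masses are used for intact species; monoisotopic
arithmetic appears only in the PTM mass-shift catalog. The default m/z
axis spans the native SIM window 2400–4000 Th at 0.25 Th spacing — fine
enough that any extraction window at the reference tolerances (±0.15 m/z,
or 60 ppm ≈ ±0.18 Th at m/z 3000) always contains grid points, and ~6x
coarser than the peak FWHM (~1.5 Th at m/z 3000), keeping a full 420-pixel
run within desktop memory.

**Noise.** Additive Gaussian baseline noise, clamped at zero (detector
intensities are non-negative). `snr = 10` sets the noise sd to one tenth
of the tallest noiseless peak in the run — a deliberately harsh global
definition, since most species peaks sit well below the tallest one.
Identical seeds give bit-identical streams; the seed is consumed once,
after all noiseless amplitudes are computed.

**What the simulator does not emulate.** Electrospray physics, ion
suppression, detergent-cluster chemical background (its periodic peaks
fall below the 2400–4000 Th SIM window and would never enter an
extraction window), spatial abundance gradients within a region, and
profile-shape variation between pixels of one region. Passing
tests therefore show that the *processing* is correct and robust to
additive noise — not that real tissue obeys the kinetics model.

## Profile extraction and classification

Per-pixel XICs sum all intensity within the tolerance window of every
charge state of a target. With noise present, raw window sums accumulate
the non-negative noise floor into a positive offset that inflates the
apparent late-time signal, so profile averaging defaults to per-scan
noise suppression (`background = "floor"`): the scan's baseline and noise
spread are estimated robustly from the spectrum's quantiles (a
substantial mass of exact zeros marks zero-clamped noise, handled as a
half-normal), and only window points above baseline + 3 sigma are summed.
This mirrors the intensity thresholding that Orbitrap acquisition itself
applies, and it is exactly a no-op on noiseless data, so all exactness
invariants are unaffected.

Averaged profiles normalize each pixel's trace to unit maximum before
taking the per-slot mean and standard deviation. The reference
description ("summed and intensity normalized") does not fix the order;
per-pixel-first makes the ±1 SD band scale-free, so pixels with different
absolute abundance contribute shape rather than magnitude. Both modes are
available (`normalize = FALSE` averages raw traces).

Classification uses a three-rule cascade on profile features:

1. `frac_first_30s >= 0.8` → soluble;
2. else `flatness >= 0.5` → transmembrane;
3. else membrane-associated.

`flatness` is the min/max ratio of the 3-slot moving mean *taken from its
peak slot onward*. Restricting to the decay segment is a deliberate
choice: every delayed-onset profile starts near zero at the first scan
(~1.3 s into the dwell), so a whole-profile min/max ratio is ~0 for both
membrane classes and cannot separate them; the decay segment is flat for
a species depleting much slower than the dwell and clearly falling for a
gamma-like membrane-associated profile. The thresholds (0.8, 0.5) are
package defaults exposed to the caller, not published values.
Classification reflects elution behavior, not annotation — a soluble
protein trapped in myelin-rich tissue elutes, and is classified, like a
membrane protein, which is exactly the behavior reported for the short
SIRT2 isoform.

## Segmentation

The multivariate recipe follows the reference workflow: 2 Th binning over
m/z 2400–4000 (800 bins), per-pixel TIC normalization, column
mean-centering, PCA to 5 components, k-means with k = 2. "Normalization"
is not further specified in the reference; per-pixel TIC scaling is the
standard MSI choice and makes pixels comparable regardless of absolute
signal. k-means is seeded with at least 10 restarts and labels are
canonicalized so class 0 is always the larger class; on noiseless
synthetic data the feature matrix has rank 1 (two distinct normalized
row patterns) and the PCA dimension is reduced with a warning rather
than failing. When an elution-time window and binning are both requested,
time filtering is applied before binning.

## MS2 chimera simplification

Co-isolated precursors (the simulator's default: a soluble crystallin-like
tetramer and a transmembrane aquaporin-like tetramer inside one m/z
6281 ± 15 isolation window) produce chimeric product-ion spectra. Two
operations separate them: `window_mean_spectrum()` reproduces the manual
approach — average the scans of a late elution window, where fast-eluting
products have vanished — and `group_by_profile()` automates it by
single-linkage grouping of product-ion elution profiles at a Pearson
correlation threshold (default r = 0.8). The correlation grouping is an
explicit extension of the manual workflow and is flagged as such in its
documentation; precursor isolation is recorded as a (center, half-width)
window, never physically simulated. The MS2 dwell is always user-supplied
(the reference MS2 residence, ~1.3 min, differs from the 1.5 min imaging
dwell, so no default is inherited).

## The 4D imzML dialect

Standard imzML has (x, y, z) pixel positions; this package stores the
elution-time slot index (1-based) in the z slot and writes a JSON sidecar
carrying the slot → seconds mapping, the acquisition schedule, and
per-spectrum scan metadata. Processed mode (per-spectrum m/z arrays) is
used because scans are never resampled onto a common grid. The dialect is
identified by a `nanodims-4d/elution-time-in-z/v1` tag in the sidecar and
refused on read if absent, so foreign imzML is never silently
misinterpreted. Binary arrays are little-endian float64 with a shared
UUID in XML and ibd; round trips are bit-exact for intensities and m/z.
A dependency-free JSON scan-dump dialect with the same contract backs the
raw-stream reader, alongside mzML via mzR.

## Numerical choices and degenerate inputs

* Scans are assigned to pixels by scan start time (discrete) or stage
  position at the scan midpoint (continuous); an epsilon in the pixel
  index guards against dwell-boundary times landing one ULP low.
* Pre-contact and overhead scans are flagged and counted, never silently
  dropped; the pixelation audit reconciles every input scan.
* An all-zero profile is an error for feature extraction (undefined
  features), while an XIC target outside the scanned m/z range yields
  zeros with a warning flag — the first is a logic error, the second a
  legitimate empty measurement.
* Zero-variance product-ion profiles cannot be correlated and become
  singleton groups with a warning; group output order is deterministic
  (lexicographic smallest member).
* The planner treats per-pixel overhead as 12.9 s by default, the value
  implied by dividing the reference dead time (~1.4 h per image) by its
  390 pixels.

## Problem sizes used in the test suite

The shipped tests run the full reference-scale conditions where the
checks demand them — a 30 x 14 phantom (420 pixels, classes of 369 and
51) at the full 90 s dwell for segmentation, 100 pixels for noiseless
profile recovery, 20 seeds at SNR 10 for classification and MS2 grouping
— and smaller grids (e.g. 3 x 2 pixels) where only correctness of the
arithmetic is at stake. The 420-pixel phantom deserves a note: the
reference class sizes (369 + 51) sum to 420, not to the 390 pixels of the
profile-averaging image, which came from a different tissue extent; the
default segmentation phantom follows the class sizes.

## Known limitations

* Kinetics parameters are calibrated only to qualitative profile shapes;
  absolute dissolution rates for real proteins under a given solvent
  system are unknown and solvent-dependent.
* Continuous-mode simulation evaluates kinetics pointwise at the transit
  time rather than integrating over the junction's passage; the two
  differ by a factor that is constant per species and so does not affect
  any normalized comparison.
* No proteoform identification, isotopic-envelope deconvolution, or
  fragment annotation — targets are defined by the caller.
* The imzML dialect is self-describing but package-specific; standard
  3D imzML readers will see elution-time slots as z planes.
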