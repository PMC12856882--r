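# nanodims

Processing toolkit for **discrete-mode nano-DESI mass spectrometry imaging**
of intact proteins and protein complexes.

Nano-DESI samples a tissue surface through a ~100 µm liquid junction. In
the usual continuous mode the probe rasters linescans, exposing each
location to solvent for only the junction transit time (20 s at 5 µm/s).
In discrete mode the probe *parks* on each location for a dwell period
(1.5 min per pixel), and species dissolve at rates set by how they are
held in the tissue: soluble proteins flood out within seconds, lipid-
anchored proteins emerge after a delay, and integral membrane proteins
dissolve slowly throughout the dwell. Each pixel then carries a
time-resolved series of native mass spectra, and each species a
chromatography-like **elution profile** whose shape reports its
solubility class. This enables co-imaging of soluble and membrane
proteins in one experiment, elution-time-filtered ion images with better
specificity, and simplification of chimeric MS² spectra.

For a species of neutral mass *M* observed at charge *z*, peaks appear at
*m/z* = (*M* + *z·m*<sub>p</sub>)/*z* with *m*<sub>p</sub> = 1.00728 Da;
extracted ion chromatograms sum intensity within a tolerance window
(±0.15 *m/z*, or ppm-scaled) over all charge states of a target. Elution
windows use 0-based, half-open scan indexing: scans *a*..*b* at scan
period Δ*t* span [*a*Δ*t*, (*b*+1)Δ*t*) — e.g. scans 2–4 at Δ*t* = 2.6 s
span 5.2–13.0 s.

The package provides, with a forward simulator standing in for
instrument data:

- **synthetic data** — discrete- and continuous-mode scan streams from a
  two-region tissue phantom with per-class dissolution kinetics, plus a
  chimeric MS² simulator; every run comes with a ground-truth table;
- **I/O** — mzML (via mzR) and a JSON scan-dump dialect; a lossless 4D
  (x, y, elution time, m/z) imzML store with the elution-time index in
  the z slot and a JSON sidecar;
- **pixelation** — tissue-contact detection, discrete-mode spot sampling,
  continuous-mode time binning, acquisition planning;
- **elution profiles** — multi-charge-state XICs with noise-floor
  suppression, averaged profiles with ±1 SD bands, profile features and
  solubility classification, neutral-mass estimation from charge series,
  and lipid-PTM mass-shift matching;
- **imaging & segmentation** — elution-time-filtered ion images, 2 Th
  spectral binning, TIC normalization + PCA + seeded k-means;
- **MS² chimera tools** — elution-window mean spectra and product-ion
  profile grouping by correlation.

## Worked example

```r
library(nanodims)
phantom  <- two_region_phantom(8, 5, 12)   # 40 pixels, two tissue classes
species  <- default_species()
schedule <- acquisition_schedule()         # discrete: 90 s dwell, dt 2.6 s

run   <- simulate_discrete_run(phantom, species, schedule, seed = 1, snr = 10)
image <- spot_sample(run$scans, schedule, run$pixel_order)
image
#> <Image4D> 8 x 5 pixels, 34 elution-time slots, dt = 2.6 s

targets <- species_targets(species)
profile <- average_profiles(image, targets$VDAC1_like)
feats   <- profile_features(profile)
round(unlist(feats), 3)
#>       t_peak_s frac_first_30s       flatness       t_half_s
#>         59.800          0.191          0.748         52.000
classify_solubility(feats)
#> [1] "transmembrane"
```

The VDAC-like channel protein peaks a minute into the dwell, holds only
19% of its signal in the first 30 s, and its decay segment stays within
75% of its peak — a slow-dissolving transmembrane profile.

```r
seg <- segment(bin_spectra(image), n_components = 5, k = 2, seed = 7)
seg
#> <SegmentationResult> k = 2 on 5 PCs; class sizes: 28, 12
```

PCA + k-means on the binned, TIC-normalized spectra recovers the
phantom's 28/12 pixel split exactly (at simulated SNR 10).

```r
neutral_mass_from_series(cbind(c(2788.9, 3067.9, 3408.5, 3834.6),
                               c(11, 10, 9, 8)))
#> M = 30668.0 Da (SD 1.0)

match_mass_shift(286, tol_da = 1)[, c("combo", "shift_da", "error_da")]
#>                                     combo shift_da error_da
#> 1 1x geranylgeranylation + 1x methylation 286.2661   0.2661
```

A four-point charge series inverts to a consistent ~30.7 kDa neutral
mass, and a 286 Da mass difference between observed and sequence mass is
explained by S-geranylgeranylation plus C-terminal methylation — the
signature of a prenylated CaaX-motif protein.

A thin command-line front end wrapping the same functions is installed at
`inst/cli/nanodims` (`simulate`, `assemble`, `xic`, `image`, `segment`).

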