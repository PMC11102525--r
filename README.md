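# patternrecon

Reconstruction and analysis tools for rotating translational-scan
photoacoustic tomography with photobleaching-based temporal unmixing.

## What problem this solves

A translational photoacoustic scan resolves well in plane but is
band-limited along its elevational axis: in k-space it samples only a
thin slab of half-width *We* through the origin. Rotating the scan
direction over a cycle of 32 angles and fusing the slabs with a
density-normalising filter,

&nbsp;&nbsp;&nbsp;&nbsp;H(θ) = S(θ) / Σ<sub>θ′</sub> S(θ′),&nbsp;&nbsp;
S(θ) = **1**{|k<sub>x</sub>cos θ − k<sub>y</sub>sin θ| ≤ W<sub>e</sub>},

restores near-isotropic resolution. Genetically encoded chromophores
photobleach under repeated excitation while intrinsic tissue absorbers do
not, so across an 8-cycle acquisition every voxel's amplitude follows

&nbsp;&nbsp;&nbsp;&nbsp;A(t) = a·exp(−b·t) + c,

with bleachable tag amplitude *a*, bleaching rate *b* (per translational
scan, searched over 0–0.09) and unbleachable background *c*. Fusing
every window of 32 adjacent tomograms gives a 225-volume time series;
fitting the decay voxel by voxel (exhaustive rate search with Pearson
correlation confidence, then linear unmixing) separates tag signal from
tissue background. Detection then only needs to clear the tag map's
noise floor (3× its noise SD) instead of the maximum of the background
("background roof"), which is where the sensitivity gain comes from.

The package provides, for synthetic digital phantoms:

- **scan planning** — bit-reversal ("jumping") and sequential rotation
  orders, translation stepping, acquisition schedules (`scan_plan()`,
  `jump_sequence()`);
- **forward simulation** — photobleaching physics, phantoms, noise,
  depth-dependent fluence (`phys_params()`, `make_phantom()`,
  `simulate_acquisition()`);
- **k-space fusion** — slab filters, density normalisation, sliding
  windows (`slab_indicator()`, `fuse()`, `sliding_fuse()`);
- **temporal unmixing** — per-voxel decay fits and maps (`fit_bleach()`,
  `unmix_volume()`, `noise_floor_mask()`);
- **quantification** — intensity-nonlinearity calibration and
  equivalent concentration (`calibrate_beta()`,
  `equivalent_concentration()`);
- **metrics & ordering study** — BNR, SNR, ROC/AUC, cosine similarity,
  jumping-vs-sequential simulations (`bnr()`, `roc_auc()`,
  `compare_orders()`);
- **I/O and pipeline** — NIfTI/TIFF volumes, YAML configs, a one-call
  pipeline (`run_pipeline()`) and a `patternrecon` CLI script under
  `inst/scripts/`.

## Worked example

Simulate a bleachable tube (a = 1, b = 0.05/scan) on unbleachable
background (c = 0.3) with the standard plan, fuse, and unmix:

```r
library(patternrecon)

plan <- scan_plan(32, 8)               # jumping order, +/-9.6 mm @ 0.6 mm
plan
#> Scan plan: 32 angles x 8 cycles ( jumping order )
#>   translation: +/- 9.6 mm in 0.6 mm steps
#>   steps: 32 per tomogram, 1024 per cycle
#>   tomograms: 256 | fused volumes: 225
#>   first angles (deg): 0, 90, 45, -45, 22.5, -67.5, 67.5, -22.5 ...

ph <- make_phantom("tube", c(64, 64),
                   params = list(a = 1, b = 0.05, c = 0.3, radius_px = 6))
stream <- simulate_acquisition(ph, plan, noise_sigma = 0.01, seed = 7)
fused  <- sliding_fuse(stream, plan)
fused
#> Fused volume series: 225 volumes of 64 x 64 | We = 0.055 cycles/voxel

um <- unmix_volume(fused, grid = rate_grid(c(1e-4, seq(0.01, 0.09, 0.01))))
um$b[33, 33]                           # recovered rate at the tube centre
#> [1] 0.05

fit <- fit_bleach(as_series_array(fused)[33, 33, ], fused$timestamps,
                  rate_grid(c(1e-4, seq(0.01, 0.09, 0.01))))
fit
#> Photobleaching decay fit: A(t) = a*exp(-b*t) + c
#>      a      b      c
#> 0.4944 0.0500 0.3017
#> confidence |r| = 0.9961
```

The fitted amplitude (0.494, not 1) reflects the within-cycle
integration of the decay — each fused window averages one cycle of
bleaching — and the band-limiting of the fusion; the rate and background
are recovered exactly. Comparing detection thresholds:

```r
roi <- matrix(FALSE, 64, 64); roi[1:12, 53:64] <- TRUE  # signal-free
nf <- noise_floor_mask(um$a, roi)      # 3 sigma of the tag map: 0.0194
max(um$c)                              # background roof: 0.315
sensitivity_gain(max(um$c), nf$threshold)
#> [1] 16.2
```

i.e. on this phantom the unmixed tag map detects signal ~16× dimmer than
background thresholding would allow. `plot(fit)` and `plot(um, "a")`
display the decay fit and the tag map; `run_pipeline()` executes the
whole chain from a YAML config and writes NIfTI maps plus a manifest.

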