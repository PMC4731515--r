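# endodance

Quantitative analysis of early and late endosome dynamics in growing
root hairs, with a ground-truthed synthetic-movie generator so that
every stage of the analysis is testable without microscope data.

Root hairs are tip-growing tubular outgrowths of root epidermal cells.
Endosomes labelled with fluorescent markers (early/TGN: GFP-RabA1d,
YFP-VTI12; late/MVB: YFP-RabF2a, YFP-RabF2b, GFP-2xFYVE) move through
them at several micrometres per second, and late endosomes engage in
two kinds of pairwise interaction: *dancing* — transient synchronized
movement at close range (< 1 µm at closest approach, lasting tens of
seconds) that does not end in fusion — and *clustering/fusion* — a
track merge accompanied by a sustained (> 20 s) increase of the summed
fluorescence intensity. This package implements the full measurement
chain used to quantify those behaviours, for researchers doing
single-particle tracking on plant (or any tip-growing) cell time-lapse
data:

- **Spot detection**: Difference-of-Gaussians (DoG) blob detection with
  sub-pixel localization (quadratic fit on the 3×3 response
  neighbourhood), watershed-based diameter measurement, and thresholded
  area fractions per zone.
- **Tracking**: frame-to-frame optimal bipartite assignment
  (Jonker–Volgenant) minimizing total squared displacement under a
  gating radius, gap closing, and the standard 5 µm minimum-trajectory
  filter; speed profiles and stop/go phase segmentation.
- **Kymographs**: intensity sampled along a polyline vs. time; maximum
  speed from the steepest piecewise-linear ridge slope; movement
  classification (continuous = any straight ridge run ≥ 15 µm,
  residual < 1 px RMS).
- **Interactions**: dancing detection (proximity ≤ 2 µm + displacement
  synchrony ≥ 0.5 + duration ≥ 5 s, with closest approach < 1 µm) and
  clustering/fusion detection (track-merge topology + summed intensity
  conserved within 30 % and sustained ≥ 20 s); population composition
  and per-zone event rates (apical = first 10 µm below the tip).
- **SIM sizing**: apparent diameters from the FWHM of normalized
  intensity profiles (first/last half-maximum crossing, so ring-like
  late endosomes yield their outer extent).
- **Synthetic data**: a root-hair-shaped domain with continuous,
  stop-and-go, dancing-pair (Ornstein–Uhlenbeck tethering around a
  0.8 µm equilibrium separation) and cluster-fusion kinetics; rendering
  with a pixel-integrated Gaussian PSF, Poisson shot noise and Gaussian
  read noise at spinning-disc calibration (0.26 µm/px, 0.1 s/frame), or
  as SIM-like frames (~100 nm resolution) where late endosomes are
  two-peaked rings.

All tabular results are tibbles; results chain with the pipe and have
`tidy()`/`glance()`/`autoplot()` methods.

## Worked example

Simulate a growing root hair with late endosomes including two dancing
pairs, render it, and run the full analysis:

```r
library(endodance)

report <- run_pipeline(pipeline_config(
  preset = "FYVE", stage = "growing",
  n_particles = 12, duration = 30, seed = 42))
report
#> <endodance_report> preset: FYVE  seed: 42
#> # A tibble: 1 x 8
#>   n_tracks mean_max_speed mean_speed continuous_fraction kymo_max_speed
#>      <int>          <dbl>      <dbl>               <dbl>          <dbl>
#> 1       37           5.84       4.58               0.536           7.47
#> # i 3 more variables: n_dancing <int>, n_fusion <int>,
#> #   population_size <int>
```

`mean_max_speed` is the mean over tracks of the steepest-slope maximum
speed (µm/s; GFP-2xFYVE-like late endosomes move at ~5.5 µm/s in their
go phases), `continuous_fraction` the share of classifiable tracks with
a straight ≥ 15 µm run (~0.4 for late endosomes), and `n_dancing` /
`n_fusion` the detected interaction events. The report also carries the
spot, track and event tables and per-zone event rates
(`report$event_rates`).

The parameter-recovery experiments reproduce the package's headline
validation numbers directly:

```r
speed_recovery("RabA1d", seed = 1)
#> # A tibble: 1 x 4
#>   preset v_true mean_max_speed n_tracks
#>   <chr>   <dbl>          <dbl>    <int>
#> 1 RabA1d    8.7           8.70       37

size_recovery("FYVE", n = 62, seed = 1)
#> # A tibble: 1 x 5
#>   preset generator_mean_nm drawn_mean_nm measured_mean_nm     n
#>   <chr>              <dbl>         <dbl>            <dbl> <dbl>
#> 1 FYVE                336.          346.             347.    62
```

A thin command-line wrapper ships in `inst/scripts/endodance.R`
(`simulate`, `run`, `recover` subcommands).

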