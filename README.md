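# tirfkin

Simulation and analysis of single-molecule TIRF motility assays for
processive kinesin motors.

In a reconstituted motility assay, fluorescently tagged motor proteins land
on immobilized microtubules and are imaged by total internal reflection
fluorescence (TIRF) microscopy; kymographs of each microtubule turn every
binding event into a measurable line. The standard summary statistics of
such an assay are:

* **velocity** — Gaussian (or two-component Gaussian) fit to the histogram
  of per-event speeds, where each event's speed is net displacement over
  total attached time, pauses included;
* **run length / residency time** — the decay constant τ of
  `A·exp(−x/τ)` fitted to the survival curve (1 − ecdf) of net
  displacements / attachment times, with percentile-bootstrap CI95;
* **landing rate** — events per µm of microtubule per minute, per
  microtubule, compared between constructs with Welch's *t*-test;
* **motile fraction** — share of binding events that move processively,
  with a Wilson 95% interval;
* **photobleaching steps** — number of discrete downward intensity
  transitions of a surface-adsorbed spot, which reports the fluorophore
  (hence subunit) count.

`tirfkin` implements this entire pipeline *plus* a generative simulator of
the assay (Poisson landings, Gaussian-mixture velocities, exponential
detachment and photobleaching, two-state pausing, Gaussian-PSF rendering
with shot and read noise), so every estimator is validated by parameter
recovery on synthetic data with known ground truth. Five calibrated
construct configurations ship with the package (a kinesin-7 truncation
series and a kinesin-1 control); `vignettes/tirfkin-methods.Rmd` documents
the model and every default.

## Worked example

Simulate 289 processive runs of the stalk-stabilised dimer construct
(run-length scale 703.3 nm, velocity 180 ± 40.8 nm/s), measure them with
the kymograph definitions, and run the full analysis:

```r
library(tirfkin)

cfg <- construct_config("cenpe754")
ev  <- sample_run_events(cfg$motor, 289, cfg$optics, seed = 1)
analyze_events(ev, construct = "CENP-E_754-2mNeon", seed = 1)
#> <analysis_report> CENP-E_754-2mNeon: 283 events (258 pass filter, 182 motile)
#>   <motile_fraction> 70.5% (Wilson CI95 [64.7, 75.8]%), 182 / 258 events
#>   <gaussian_fit> 1 component(s), n = 182, r^2 = 0.935
#>   mean 177.7 +/- 3.1 nm/s (s.d. 40.0)
#>   <survival_fit> decay constant 728.20 (CI95 [606.36, 854.43], bootstrap), n = 182, r^2 = 0.997
#>   <survival_fit> decay constant 4.45 (CI95 [3.78, 5.22], bootstrap), n = 182, r^2 = 0.997
```

Reading the output: 6 of the 289 simulated motors never reached a frame and
25 more spanned fewer than 5 frames (removed by the minimum-event filter);
of the 258 analysable events, 182 moved at least 320 nm and count as motile
(short exponential runs fall below the processivity threshold, which is why
the motile fraction exceeds the generative processive probability — see the
vignette). The velocity fit recovers the generative 180 nm/s within its
standard error, and the run-length survival fit recovers the generative
703.3 nm scale within its bootstrap CI (this fixture uses per-distance
detachment, so run lengths are exactly exponential; residency recovery uses
per-time fixtures instead).

Movies and photobleaching work the same way end-to-end:

```r
sim   <- simulate_experiment(cfg, seed = 42)          # field, landings, truth
movie <- render_movie(sim$field, sim$trajectories, sim$optics, seed = 7)
ky    <- build_kymograph(movie, sim$field, mt_id = 1)
ev2   <- extract_events(ky)                           # automated tracking
tr    <- sample_bleach_trace(cfg$motor, 200, 30, 400, seed = 3)
count_steps(tr)                                       # change-point steps
```

A thin command-line front-end over the same functions lives at
`inst/cli/motility.R` (`simulate`, `analyze`, `bleach` subcommands).

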