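# curtainr

Simulation and quantification of single-molecule ssDNA-curtain experiments
in R.

In a DNA-curtain assay, single-stranded DNA molecules are tethered at one
end and imaged in parallel by TIRF microscopy while a fluorescently
labelled motor protein (a RecQ-family helicase) binds and translocates
along them. Each molecule is reduced to a kymograph — position along the
molecule versus time — and the biology is read out as a handful of
statistics. curtainr implements that full analysis chain, together with a
ground-truth simulator of the assay, so the chain can be validated end to
end:

* **simulate** — binding events on RPA-coated ssDNA or recombinase
  filaments, with Gaussian-distributed velocities (truncated at the 5 nt/s
  detection floor), exponentially distributed run lengths parameterised by
  half-life, RPA-cluster landscapes, and ATP-hydrolysis time courses;
* **render** — two-colour kymographs (motor channel + RPA channel with
  coat, cluster, or wake-tract appearance) and image stacks, with Gaussian
  PSF, Poisson photon statistics and read noise; TIFF + JSON-sidecar I/O;
* **track** — per-frame spot detection with sub-pixel centroids, greedy
  nearest-neighbour linking with gap bridging, and trajectory measurement
  (run length in nt via the 1000 nt/pixel conversion, velocity in nt/s as
  distance over time);
* **quantify** — Gaussian fits to 10 nt/s-binned velocity histograms
  (mean ± fitted sd), single-exponential survival-curve half-lives
  (processivity, in knt), percentile-bootstrap confidence intervals,
  two-colour colocalization fractions, binding-position distributions,
  events per molecule, Welch/Student comparisons, and ATPase
  k<sub>cat</sub> estimation with rate ratios.

The headline estimators, in the field's notation: velocities are binned
and fitted to A·exp(−(x−μ)²/2σ²) (reported as μ ± σ); run-length survival
curves S(d) = P(run ≥ d) are fitted to S(d) = exp(−d·ln2/L½) with the
processivity reported as the half-life L½. The pipeline additionally
corrects two detection-selection effects that matter at realistic sample
sizes (a velocity-dependent run-length floor, removed by the memoryless
excess-run construction, and an exp(−λv) sampling tilt on velocities,
removed analytically); the methods vignette derives both.

Everything is tibble-in/tibble-out and pipe-friendly; fitted objects have
`broom::tidy()`/`glance()` methods and `ggplot2::autoplot()` figures.

## Worked example

Simulate a full experiment on Rad51-filament ssDNA at the study scale
(125 binding events, one molecule each), render noisy two-colour
kymographs, track, and quantify:

```r
library(curtainr)

report <- experiment_config("rad51", n_events = 125, seed = 5) |>
  run_pipeline()

report$velocity
#> # A tibble: 1 x 6
#>   mean_nt_s sd_nt_s amplitude bin_width_nt_s     n method
#>       <dbl>   <dbl>     <dbl>          <dbl> <int> <chr>
#> 1      25.7    45.2      196.             10   109 histogram

report$processivity
#> # A tibble: 1 x 5
#>   halflife_knt decay_rate_per_knt ci_low ci_high     n
#>          <dbl>              <dbl>  <dbl>   <dbl> <int>
#> 1         4.27              0.162   3.50    5.18   100

report$colocalization
#> # A tibble: 1 x 6
#>   n_coloc n_total fraction percent ci_low ci_high
#>     <int>   <int>    <dbl>   <dbl>  <dbl>   <dbl>
#> 1      95     110    0.864      86  0.791   0.918
```

Here the generating condition was 29 ± 29 nt/s with a 4.1 knt half-life
and binding at RPA clusters with probability 0.79: the fitted velocity
mean (25.7 nt/s) and half-life (4.27 knt, bootstrap CI [3.5, 5.2])
recover the inputs within their sampling uncertainty at ~109 tracked
trajectories, and the colocalized fraction (86 %) sits at the generating
0.79 plus the expected ~7 % chance overlap of uniform events with
clusters at this landscape density. `autoplot()` on the fit objects
draws the histogram-plus-Gaussian and survival-curve figures.

The ATPase worked example, at the published turnover numbers for this
helicase (256 s⁻¹) versus the recombinase (0.012 s⁻¹):

```r
tc <- simulate_atpase(kcat_s = 256, enzyme_conc = 1e-9, atp_conc = 2e-3,
                      times_s = seq(10, 2000, by = 10))
fit_initial_rate(tc)$kcat_s
#> [1] 256
rate_ratio(256, 0.012)$label
#> [1] "2 x 10^4"
```

## Package layout

| file | contents |
| --- | --- |
| `R/params.R` | acquisition parameters, motor presets |
| `R/simulate.R` | clusters, trajectories, curtains, ATPase time courses |
| `R/render.R` | kymograph/stack rendering |
| `R/imgio.R` | TIFF + sidecar and CSV table I/O, kymograph extraction |
| `R/tracking.R` | spot detection, linking, measurement, event classification |
| `R/quantify.R` | velocity/survival/bootstrap/colocalization/ATPase statistics |
| `R/pipeline.R` | configs, end-to-end runs, reports |
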