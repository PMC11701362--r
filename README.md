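# wellkinetics

Camera-based kinetics for multi-well colour reactions: extract per-well
colour traces from a fixed-camera video of a plate, detect reaction end
points and induction times from the colour-contrast profile, grade slow
processes by area under the curve, diagnose specular glare, and rank
colour channels by mutual information against off-line reference
measurements.

## The problem

A single camera watching a plate records every well at once: twelve
reactions followed serially at ~3,500 s each would occupy an instrument
for 42,000 s, while one parallel recording takes 3,500 s — a 92% saving.
At 25 fps the camera also samples every 0.04 s, far denser than manual
sampling. The price is that the raw signal is colour, not concentration,
so the analysis has to be principled about colour spaces, noise and
quantisation.

## Core model

Each frame is an H × W × 3 sRGB array. For every well, pixels inside a
circular region of interest are averaged and converted to CIE-L\*a\*b\*
(IEC 61966-2-1 decoding, sRGB/D65 primaries, D65 2° white). The contrast
trace is the CIE76 colour difference against the well's first frame:

ΔE(t) = ‖Lab(t) − Lab(t₀)‖₂

The reaction **end point** is found from the smoothed dΔE/dt: after the
rate has once exceeded 0.05 ΔE·s⁻¹, the end point is the earliest time
it falls below that threshold and stays below for ≥ 10 s. A trace that
never activates, or never persists below threshold, reports `NA` — "no
plateau observed", never a fabricated time. **Induction time** is the
maximum-rate point, **AUC** the trapezoidal area under ΔE(t), and
channel relevance against external data (e.g. chromatography) is scored
by equal-frequency-binned mutual information.

A deterministic synthetic plate generator (closed-form well kinetics +
Gaussian noise + optional glare, seeded per frame) provides ground truth
for every one of those definitions via `analytic_summary()`.

## Worked example

Simulate a 6-well plate where each well bleaches by first-order kinetics
at a different rate, then recover the kinetics from the rendered video:

```r
library(wellkinetics)

grid  <- grid_spec(2, 3, origin = c(10, 10), pitch = 20, diameter = 14)
wells <- setNames(lapply(1:6, function(i)
  well_kinetic_spec("exponential_decay", c(90, 30, 140), c(235, 235, 235),
                    rate = 0.01 * i)), grid_labels(grid))
spec   <- plate_video_spec(grid, wells, 60, 80, fps = 5, duration = 240,
                           noise_sd = 2, seed = 42)
traces <- extract_traces(plate_frame_source(spec), spec$masks)
print(traces, n = 3)
#> # A tibble: 7,206 × 12
#>   label time_s     R     G     B     L     a     b     H     S     V deltaE
#>   <chr>  <dbl> <dbl> <dbl> <dbl> <dbl> <dbl> <dbl> <dbl> <dbl> <dbl>  <dbl>
#> 1 A1       0    90.1  30.0  140.  26.7  47.2 -49.2  273. 0.786 0.549  0
#> 2 A1       0.2  90.1  30.2  140.  26.8  47.1 -49.2  273. 0.784 0.549  0.104
#> 3 A1       0.4  90.7  30.9  140.  27.0  47.0 -49.0  273. 0.780 0.550  0.343
#> # ℹ 7,203 more rows

summarise_kinetics(traces, endpoint_config(smoothing_window = 51))
#> # A tibble: 6 × 6
#>   label endpoint_s induction_s max_rate    auc complete
#> * <chr>      <dbl>       <dbl>    <dbl>  <dbl> <lgl>
#> 1 A1          NA          13      0.854 14322. FALSE
#> 2 A2         202.          6.2    1.66  18212. TRUE
#> 3 A3         148           5.6    2.41  19729. TRUE
#> 4 B1         117           5.2    3.13  20537. TRUE
#> 5 B2         102.          5.2    3.76  20984. TRUE
#> 6 B3          85.2         5.2    4.32  21265. TRUE
```

Faster programmed kinetics finish earlier, and the slowest well has not
plateaued within the 240 s recording, so its end point is honestly `NA`.

To analyse real footage, extract numbered frames first (e.g.
`ffmpeg -i run.mp4 frames/frame_%05d.png`), then:

```r
fs     <- read_frames("frames/", fps = 25)
masks  <- build_masks(grid, fs$height, fs$width)
traces <- extract_traces(fs, masks)
```

The same pipeline is scriptable end to end through `cmd_simulate()`,
`cmd_analyze()`, `cmd_rank()` and `cmd_glare()`, driven by YAML configs;
re-running `cmd_analyze()` on the same input reproduces its CSV outputs
byte for byte.

See the methods vignette (`vignettes/colour-kinetics-methods.Rmd`) for
the end-point rule in full, the quantisation-vs-noise analysis, and the
mutual-information estimator's properties.

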