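# dropfreq

Monitoring of dynamic droplet-generation processes in microfluidic devices
from high-speed microscopy video, in R.

## The problem

Droplet microfluidic generators emit monodisperse emulsion droplets at tens
of hertz to several kilohertz. Product uniformity (microgels, digital-assay
partitions, microcapsules) depends on the generation process staying stable,
so the generation **frequency** and its dispersion need continuous
monitoring — ideally from the high-speed camera already on the rig, without
segmenting droplets in every frame.

## The method

A stable generation process is nearly periodic: each time the droplet train
advances by one spacing, the field of view repeats. `dropfreq` exploits this
with three steps:

1. **Similarity vector.** Every frame is flattened to a grayscale pixel
   vector **h**(i) and compared against a fixed reference frame (frame 1 by
   default) with cosine similarity
   S(**a**, **b**) = **a**ᵀ**b** / (‖**a**‖‖**b**‖) ∈ [−1, 1].
   The resulting time series s₁, …, s_N oscillates at the droplet
   generation frequency.
2. **Cyclic auto-spectrum.** The one-sided FFT periodogram of the
   mean-subtracted similarity vector, on a grid of resolution
   Δf = frame rate / N.
3. **Peak → (f̄, CV_f).** The fundamental is the lowest-frequency prominent
   spectral peak; over its half-maximum band (refined on a 32× zoomed local
   DFT grid) the power-weighted centroid gives the mean frequency f̄ and the
   power-weighted width over the centroid gives the frequency CV in percent.

Because several parallel channels contribute separate oscillations to one
similarity vector, a single spectrum of a multi-channel clip shows one
fundamental per channel; harmonics are grouped onto their fundamentals
automatically. A FIFO ring-buffer mode updates the similarity vector with
one dot product per incoming frame (constant per-frame cost), enabling
real-time streaming estimation; batch and streaming paths share one
compiled kernel and agree bit for bit.

## Worked example

Simulate a 5,000-frame, 512 × 62 px clip at 1,200 Hz captured at 10,000
fps, and estimate its generation frequency:

```r
library(dropfreq)

cfg <- synthetic_video_config(1200, frame_rate = 10000, n_frames = 5000,
                              seed = 2001)
vid <- generate_video(cfg)
droplet_frequency(vid$stack)
#> <frequency_estimate> mean 1200.0000 Hz, CV 0.0395%, peak bin 1200.0000 Hz,
#>   delta_f 2 Hz (5000 frames @ 10000 fps)
```

The fundamental lands in the 1,200 Hz bin of the 2 Hz grid; the refined
centroid reproduces the generating rate to sub-millihertz, and the CV is
small because a noiseless-schedule clip is almost perfectly periodic (the
residual width is finite-window leakage).

Monitoring a process whose rate ramps from 1,200 to 1,320 Hz mid-clip, in
0.1 s windows:

```r
sch <- data.frame(start = c(0, 0.25), end = c(0.25, 0.5), freq = c(1200, 1320))
cfg <- synthetic_video_config(sch, frame_rate = 10000, n_frames = 5000,
                              transition_s = 0.1, seed = 2002)
vid <- generate_video(cfg)
monitor_process(vid$stack, window_frames = 1000)
#> <monitor_report> 5 windows, interval 0.1 s
#>  window_start_s window_end_s mean_freq_hz cv_percent peak_power n_frames
#>             0.0          0.1     1200.001  0.1977229  0.3639440     1000
#>             0.1          0.2     1200.001  0.1977263  0.3635962     1000
#>             0.2          0.3     1202.579  0.2668804  0.1417930     1000
#>             0.3          0.4     1317.228  0.2493982  0.1338128     1000
#>             0.4          0.5     1320.001  0.1797491  0.3631702     1000
```

Window means track the schedule without delay; windows overlapping the ramp
show elevated CV and reduced peak power. See the vignette
(`vignettes/droplet-frequency-monitoring.Rmd`) for the model, estimator
details, the synthetic generator, and known limitations.

A command-line interface wraps the same pipeline
(`inst/cli/dropfreq <estimate|monitor|stream|simulate|compose>`), reading
PNG/TIFF frame directories or uncompressed AVI clips and writing CSV/JSON
reports.

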