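---
title: "Monitoring droplet generation frequency by frame cosine similarity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Monitoring droplet generation frequency by frame cosine similarity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Droplet microfluidic devices emit monodisperse emulsion droplets at rates
from tens of hertz to several kilohertz. The uniformity of everything made
from those droplets — microgels, digital-assay partitions, microcapsules —
depends on the generation process staying stable, so one wants to monitor
the generation *frequency* and its dispersion continuously, from the
high-speed camera that is already part of a typical rig, without segmenting
droplets in every frame.

`dropfreq` implements a similarity-spectrum approach. A stable generation
process is very nearly periodic: whenever the droplet train advances by one
inter-droplet spacing, the field of view repeats. Comparing every frame
against a fixed reference frame therefore produces a *periodic* scalar
signal whose oscillation rate is the droplet generation frequency.

## The model

Each grayscale frame ($m \times n$ pixels) is flattened into a vector
$\mathbf h(i)$ by listing pixels column by column. Two frames are compared
by cosine similarity,

$$S(\mathbf a, \mathbf b) = \frac{\mathbf a^{\mathsf T}\mathbf b}
  {\lVert\mathbf a\rVert\,\lVert\mathbf b\rVert} \in [-1, 1],$$

which is symmetric and invariant to positive rescaling of either argument —
bit depth, exposure and normalization constants drop out (the package
asserts this as a property test). With non-negative intensities all values
lie in $[0, 1]$, and the reference frame scores exactly 1 against itself.

With reference frame $r$ (frame 1 by default), the **similarity vector**
$s_i = S(\mathbf h(i), \mathbf h(r))$, $i = 1, \dots, N$, oscillates at the
generation frequency $f$: it returns towards 1 each time the droplet
pattern realigns with the reference. Its **cyclic auto-spectrum** is the
one-sided periodogram of the mean-subtracted similarity vector, computed by
FFT. Subtracting the mean first matters: the similarities hover just below
1 (0.92–1.00 on typical clips), and without detrending the DC term dwarfs
the oscillation. Power is scaled as $|X_k|^2/N$ with interior bins doubled,
so the one-sided total equals $N$ times the population variance of the
signal (Parseval, also a test). The grid spacing — the spectral resolution
— is $\Delta f = \mathrm{frame\ rate}/N$; clip length directly buys
frequency accuracy, and truncating a 5,000-frame clip to 1,000 frames
coarsens $\Delta f$ exactly five-fold.

### From peak to mean and CV

The **fundamental** is taken as the lowest-frequency prominent local
maximum rather than the global one, because the sharp similarity dips of
droplet passage generate harmonics that can rival the fundamental, and the
generation rate is always the lowest line of that family. A peak qualifies
when its power reaches `prominence_frac` (default 0.5) of the global
maximum **and** exceeds `min_snr` (default 50) times the median spectral
power; the second gate makes a flat noise spectrum report "no peak" instead
of electing the tallest noise excursion. Ties between equal adjacent bins
resolve to the lower frequency.

Around the fundamental, the band is the contiguous run of bins with at
least half the peak power (FWHM), at least one bin, and at most $\pm 5\%$
of the peak frequency so high noise floors cannot drag the band open. The
reported quantities are the power-weighted moments over that band:

$$\bar f = \frac{\sum_k f_k P_k}{\sum_k P_k}, \qquad
  \sigma_f = \sqrt{\frac{\sum_k P_k (f_k - \bar f)^2}{\sum_k P_k}}, \qquad
  CV_f = 100\,\frac{\sigma_f}{\bar f}.$$

A pure tone concentrated in one bin gives $CV_f = 0$; a drifting or
disturbed process spreads power across the band and inflates $CV_f$. Note
that $\sigma_f$ also contains the spectral-leakage width of the finite
observation window ($\approx 0.4\,\Delta f$ for a stable clip), so the CV
of a perfectly regular process is small but not zero, shrinking with clip
length. CV values are therefore most meaningful *comparatively* — stable
versus disturbed windows of the same length — which is how the monitoring
workflow uses them.

### Sub-bin refinement

A centroid restricted to the natural grid inherits a worst-case
quantization error of a large fraction of one bin (an off-bin tone can put
its entire FWHM in a single bin). Since the spectrum object carries its
source signal, `estimate_frequency()` re-evaluates the periodogram on a
local grid of spacing $\Delta f/32$ spanning the band (a direct zoomed DFT,
at most ~1,500 points) and takes the FWHM centroid there. The refined main
lobe is symmetric about the true frequency, which reduces the recovery
error on stable synthetic clips from a fraction of a bin to the
$10^{-3}$–$10^{-2}$ bin range. The natural grid, `delta_f`, and the
peak-bin frequency `peak_freq` are reported unchanged; hand-constructed
spectra (no signal attached) are estimated on the natural grid.

### Multiple channels

Parallel channels with non-overlapping rates contribute additively enough
to the similarity oscillation that one spectrum shows one fundamental per
channel. `detect_fundamentals()` collects all prominent local maxima in
ascending frequency and drops any peak lying within `harmonic_tol`
(default 2%, relative) of an integer multiple (2×–6×) of an already
accepted fundamental. Grouping is applied regardless of the peaks'
relative power so that reported fundamentals are never near-multiples of
one another; two genuine channels tuned to an exact harmonic ratio are
thus deliberately outside the method's scope. Each surviving fundamental
gets its own band, truncated halfway to its neighbours so bands stay
disjoint. For composites whose channels differ strongly in apparent area
(and hence spectral power), `prominence_frac` should be lowered; the
package's own multi-channel analyses use 0.2.

## Streaming and monitoring

`init_stream()`/`push_frame()` maintain two index-aligned FIFO ring buffers
(default capacity 5,000) of recent frames and of their similarities against
a reference fixed at init. Admitting a frame costs one multiply-add pass
over its pixels — the reference norm is cached — so the per-update cost is
independent of buffer length; the buffer phase switches from build-up to
real-time exactly when the buffer first fills, and estimates during
build-up are flagged provisional because their $\Delta f$ is coarser. The
spectrum is recomputed by full FFT of the buffer on demand: at a capacity
of 5,000 the FFT is negligible next to the similarity update, so an
incremental DFT would add complexity without measurable benefit. Batch and
streaming paths share one compiled similarity kernel, and the package
asserts their results agree bit for bit. `reref_stream()` can re-designate
the reference (one pass over the buffer) after a regime change so large
that the original reference pattern no longer recurs.

`monitor_process()` covers the windowed-online workflow: consecutive
windows of `window_frames` frames (non-overlapping by default), each
analysed against its own first frame. Window means track rate changes at
the window cadence, and the window CV flags disturbed periods.

## The synthetic-data generator

`generate_video()` renders the study conditions under which the package is
validated: a bright channel bore (background 0.9, walls at 80% of it)
crossed by dark anti-aliased circular droplets (contrast 0.6, diameter 24
px, spacing 64 px in the canonical 62 × 512 px geometry), born at the
nozzle at the scheduled instantaneous rate and advected at spacing × rate
pixels per second, plus seeded Gaussian pixel noise (σ = 0.02, clipped at
0). Anti-aliased edges matter: hard-edged disks make the similarity signal
piecewise constant in time and alias the spectrum. For a constant schedule
the construction is *exactly* periodic with period $1/f$, so the true
fundamental is known to machine precision; droplet birth times and the
scheduled instantaneous frequency are returned as ground truth, and
`truth_statistics()` converts them to interval-based mean/CV references.

Rate changes are piecewise-constant schedules with an optional linear ramp
(`transition_s`) at each boundary, emulating pump-driven flow toggles that
sweep the rate continuously rather than stepping it; the hard step
(`transition_s = 0`) is the default. Disturbance tests place a ramp across
a full monitoring window, the regime in which a disturbed process shows its
several-fold CV elevation.

What the generator does **not** emulate: droplet break-up physics
(squeezing/dripping/jetting dynamics, flow-rate-to-frequency mapping),
illumination drift, focus changes, camera shot-noise statistics, or
compression artifacts. Passing the validation suite therefore demonstrates
correct recovery of periodic image recurrence under pixel noise and
geometric reconstruction — not robustness to every optical nuisance of a
real rig.

Multi-channel clips are emulated by `compose_multichannel()`: a vertical
stack of equal-width clips, or zoomed/rotated (bilinear, zero-filled)
copies centre-cropped into horizontal bands of a larger canvas — the
video-editor style reconstruction used to build multi-channel fields of
view from single-channel footage. Composite validation generates the channel
clips directly at one shared frame rate rather than resampling rendered
frames, which would only add interpolation artifacts on top of the same
ground truth.

## Numerical choices and degenerate inputs

* All-zero frames abort with the offending index rather than being skipped;
  a black frame means acquisition failure, and silent skipping would
  corrupt the time base.
* A constant similarity vector (no oscillation) flags the spectrum
  degenerate; band finding then raises a no-peak error.
* A fundamental above 0.4× the frame rate raises an aliasing warning — the
  acquisition rule is a frame rate above 5× the generation frequency.
* Windowing is rectangular; on strong narrow peaks the refined centroid
  does not need a taper, and the FWHM band bounds leakage influence.
* Frame rates are always caller-supplied, never read from container
  metadata, because high-speed clips are routinely re-wrapped at playback
  rates.
* Videos are stored losslessly (8-bit PNG frame directories or
  uncompressed grayscale AVI); stacks quantized to 8 bits round-trip
  bit-exactly, which the suite asserts end to end through the similarity
  vector.

## Validation scale

The bundled validation runs at the canonical acquisition scale: 512 × 62 px
clips of 5,000 frames for single-channel recovery (frequencies 67.3 Hz to
4,707.9 Hz at frame rates 5–8× the frequency), 1,000-frame clips for the
multi-channel composites (two-channel 124 × 512 stack, three-channel
512 × 512 canvas at zooms 110/200/150% and rotations −13°/3°/147°), and
small 24 × 96 px clips for property tests. These sizes keep the full suite
in the minutes range on one CPU while exercising the exact geometry of the
validated conditions.

## Limitations

* The spectral CV is a band-width-over-centroid surrogate; it contains the
  finite-window leakage width and is capped by the ±5% band extent, so very
  large disturbances saturate it. Interval-level CV (from segmentation or
  the generator's ground truth) is the reference when absolute dispersion
  matters.
* Channels in exact harmonic ratio cannot be separated.
* Frequencies changing faster than one window (or buffer) length are
  averaged, not resolved; the method has no time-frequency resolution
  within a window.
* Compressed AVI input is not decoded; use frame directories or
  uncompressed AVI.
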