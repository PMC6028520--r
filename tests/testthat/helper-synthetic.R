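# Small synthetic clips shared across tests: 24 x 96 px keeps generation in
# the tens of milliseconds while preserving the generative model (moving
# anti-aliased droplets in a bright channel).

small_cfg <- function(freq = 100, frame_rate = 2000, n_frames = 600,
                      seed = 42, noise_sigma = 0.01, jitter = 0, ...) {
  synthetic_video_config(freq, frame_rate = frame_rate, n_frames = n_frames,
                         resolution = c(24, 96), channel_width = 16,
                         droplet_diameter = 10, spacing_px = 24,
                         noise_sigma = noise_sigma, jitter = jitter,
                         seed = seed, ...)
}

small_clip <- function(...) generate_video(small_cfg(...))

# independent elementwise-loop cosine implementation (oracle)
cosine_loop <- function(a, b) {
  sab <- 0; sa <- 0; sb <- 0
  for (i in seq_along(a)) {
    sab <- sab + a[i] * b[i]
    sa <- sa + a[i]^2
    sb <- sb + b[i]^2
  }
  sab / (sqrt(sa) * sqrt(sb))
}
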