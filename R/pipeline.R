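#' One-shot droplet generation frequency estimation
#'
#' Runs the full pipeline on a clip: build the similarity vector against the
#' reference frame, compute the cyclic auto-spectrum, and estimate either a
#' single fundamental or (for `max_channels > 1`) one fundamental per
#' channel.
#'
#' @param stack A [frame_stack()].
#' @param reference_index Reference frame index (default 1, the first frame).
#' @param max_channels Number of channels to look for (default 1).
#' @param prominence_frac Peak prominence threshold relative to the global
#'   maximum, see [find_fundamental_band()].
#' @param harmonic_tol Harmonic grouping tolerance for multi-channel
#'   detection, see [detect_fundamentals()].
#' @param roi Optional `c(row1, row2, col1, col2)` crop applied to all frames.
#' @param refine Sub-bin centroid refinement (default `TRUE`).
#' @return A `frequency_estimate`, or a `multichannel_estimate` when
#'   `max_channels > 1`.
#' @examples
#' cfg <- synthetic_video_config(100, frame_rate = 2000, n_frames = 400,
#'                               resolution = c(24, 96), channel_width = 16,
#'                               droplet_diameter = 10, spacing_px = 24,
#'                               noise_sigma = 0, seed = 7)
#' vid <- generate_video(cfg)
#' droplet_frequency(vid$stack)
#' @export
droplet_frequency <- function(stack, reference_index = 1L, max_channels = 1L,
                              prominence_frac = 0.5, harmonic_tol = 0.02,
                              roi = NULL, refine = TRUE) {
  sv <- build_similarity_vector(stack, reference_index, roi = roi)
  spec <- compute_auto_spectrum(sv)
  if (max_channels > 1L) {
    detect_fundamentals(spec, max_channels = max_channels,
                        prominence_frac = prominence_frac,
                        harmonic_tol = harmonic_tol, refine = refine)
  } else {
    estimate_frequency(spec, refine = refine,
                       prominence_frac = prominence_frac)
  }
}

#' Export a spectrum as a frequency/power table
#'
#' @param spectrum An `auto_spectrum`.
#' @param path Optional CSV output path (columns `freq_hz`, `power`).
#' @return The data frame, invisibly if written to `path`.
#' @export
spectrum_table <- function(spectrum, path = NULL) {
  df <- data.frame(freq_hz = spectrum$freqs, power = spectrum$power)
  if (!is.null(path)) {
    utils::write.csv(df, path, row.names = FALSE)
    return(invisible(df))
  }
  df
}
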