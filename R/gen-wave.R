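#' Synthetic planar-wave fluorescence frame stack
#'
#' Emits a voltage-dye-like frame stack in which a wave of activation
#' spreads from `origin` at constant `velocity`: each pixel's fluorescence
#' drops (dye polarity; see [activation_map()]'s `invert`) through a
#' half-cosine upstroke of width `upstroke_ms` centred at
#' `distance(origin) / velocity`. Per-pixel gain and offset vary to emulate
#' heterogeneous staining. The analytic activation-time truth (ms) is
#' attached in `$events`.
#'
#' @param nrow,ncol grid size in pixels.
#' @param pitch_um pixel pitch, micrometres.
#' @param origin `c(row, col)` of the wave origin (1-based, inside grid).
#' @param velocity_um_ms conduction velocity, micrometres per ms (> 0).
#' @param frame_rate_hz frame rate, Hz.
#' @param upstroke_ms upstroke width, ms.
#' @param pad_ms quiescent baseline before the origin activates and tail
#'   after the last pixel, ms.
#' @param noise_sd additive noise SD, arbitrary units (signal amplitude 1).
#' @param seed integer seed.
#' @return A [frame_stack()] with `$events$activation_ms` truth matrix.
#' @export
gen_wave_stack <- function(nrow = 16, ncol = 16, pitch_um = 100,
                           origin = c(1, 1), velocity_um_ms = 100,
                           frame_rate_hz = 1000, upstroke_ms = 5,
                           pad_ms = 10, noise_sd = 0, seed = 1) {
  if (velocity_um_ms <= 0) stop("'velocity_um_ms' must be > 0")
  if (origin[1] < 1 || origin[1] > nrow || origin[2] < 1 ||
      origin[2] > ncol) {
    stop("'origin' lies outside the pixel grid")
  }
  rows <- matrix(seq_len(nrow), nrow, ncol)
  cols <- matrix(seq_len(ncol), nrow, ncol, byrow = TRUE)
  dist_um <- sqrt((rows - origin[1])^2 + (cols - origin[2])^2) * pitch_um
  act_ms <- dist_um / velocity_um_ms

  total_ms <- max(act_ms) + 2 * pad_ms + upstroke_ms
  nframes <- ceiling(total_ms / 1000 * frame_rate_hz) + 1L
  t_ms <- (seq_len(nframes) - 1L) / frame_rate_hz * 1000

  withr_seed(seed)
  gain <- matrix(stats::runif(nrow * ncol, 0.8, 1.2), nrow, ncol)
  offs <- matrix(stats::runif(nrow * ncol, 0, 0.5), nrow, ncol)

  frames <- array(0, dim = c(nrow, ncol, nframes))
  for (k in seq_len(nframes)) {
    # phase of the half-cosine upstroke, centred at the activation time
    u <- (t_ms[k] - (act_ms + pad_ms)) / upstroke_ms + 0.5
    u <- pmin(pmax(u, 0), 1)
    sig <- (1 - cos(pi * u)) / 2          # 0 -> 1 through the upstroke
    frames[, , k] <- offs + gain * (1 - sig)  # fluorescence decreases
  }
  if (noise_sd > 0) {
    frames <- frames + array(stats::rnorm(length(frames), 0, noise_sd),
                             dim = dim(frames))
  }
  out <- frame_stack(frames, pitch_um = pitch_um,
                     frame_rate_hz = frame_rate_hz)
  out$events <- list(activation_ms = act_ms + pad_ms, origin = origin,
                     velocity_um_ms = velocity_um_ms)
  out
}
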