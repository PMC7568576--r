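#' Zero-phase band-pass filter for cardio-mechanical signals
#'
#' Butterworth IIR band-pass (default 0.8-25 Hz, the informative band of
#' seismo-/gyro-cardiography) applied forward-backward
#' ([signal::filtfilt()]) so the waveform morphology is preserved with
#' zero phase distortion.
#'
#' @param samples numeric vector.
#' @param fs_hz sampling rate; must exceed twice the upper edge.
#' @param low_hz,high_hz pass-band edges in Hz.
#' @param order Butterworth design order (4 poles per edge by default).
#' @return filtered vector of the same length.
#' @examples
#' x <- sin(2 * pi * 5 * seq(0, 2, by = 1 / 256))
#' y <- bandpass(x, 256)
#' @export
bandpass <- function(samples, fs_hz, low_hz = 0.8, high_hz = 25, order = 4) {
  if (fs_hz <= 2 * high_hz) {
    abort(sprintf("fs_hz = %g puts the %g Hz band edge at/above Nyquist",
                  fs_hz, high_hz),
          class = "cardiowave_nyquist_violation")
  }
  if (!length(samples)) {
    abort("empty input", class = "cardiowave_invalid_argument")
  }
  bf <- signal::butter(order, c(low_hz, high_hz) / (fs_hz / 2), type = "pass")
  as.numeric(signal::filtfilt(bf, samples))
}

#' Non-overlapping RMS envelope
#'
#' Root-mean-square of consecutive non-overlapping windows (window =
#' step, default 0.5 s); the trailing partial window is dropped. This is
#' the noise envelope the segmentation threshold is applied to.
#'
#' @param samples numeric vector.
#' @param fs_hz sampling rate.
#' @param step_s window/step size in seconds.
#' @return tibble with `t_start_s` (window start) and `rms`.
#' @export
rms_envelope <- function(samples, fs_hz, step_s = 0.5) {
  if (!length(samples)) {
    abort("empty input", class = "cardiowave_invalid_argument")
  }
  stopifnot(step_s > 0)
  w <- round(step_s * fs_hz)
  k <- floor(length(samples) / w)
  if (k < 1) {
    abort("input shorter than one RMS window",
          class = "cardiowave_invalid_argument")
  }
  m <- matrix(samples[seq_len(k * w)], nrow = w)
  tibble(
    t_start_s = (seq_len(k) - 1) * step_s,
    rms = sqrt(colMeans(m^2))
  )
}

#' Segment a recording into low-noise fixed-length windows
#'
#' Band-pass filters one channel, computes its non-overlapping RMS
#' envelope, and tiles the recording into consecutive `segment_s`-second
#' candidate windows starting at t = 0. A candidate is accepted iff the
#' maximum envelope value inside it does not exceed
#' `threshold` x median(envelope over the whole recording) - a single
#' motion-artifact burst therefore disqualifies its window.
#'
#' @param session a `recording_session`.
#' @param channel channel label (`"SCG_Z"` etc.).
#' @param segment_s segment length in seconds (default 10).
#' @param threshold envelope-median multiplier (default 1.5).
#' @param step_s RMS window/step (default 0.5 s).
#' @param filter apply [bandpass()] first (default TRUE).
#' @return tibble with one row per accepted segment: `subject_id`,
#'   `channel`, `start_s`, `fs_hz`, `class_label` and a list-column
#'   `samples` holding the filtered samples (length exactly
#'   `round(segment_s * fs_hz)`). Zero rows if the recording is shorter
#'   than one segment or no window passes.
#' @export
segment_recording <- function(session, channel, segment_s = 10,
                              threshold = 1.5, step_s = 0.5, filter = TRUE) {
  stopifnot(inherits(session, "recording_session"))
  x <- get_channel(session, channel)  # validates channel
  fs <- session$fs_hz
  seg_n <- round(segment_s * fs)
  if (length(x) < seg_n) {
    return(empty_segments())
  }
  if (filter) x <- bandpass(x, fs)
  env <- rms_envelope(x, fs, step_s)
  cutoff <- threshold * median(env$rms)
  per_seg <- round(segment_s / step_s)
  n_cand <- floor(length(x) / seg_n)
  rows <- list()
  for (k in seq_len(n_cand)) {
    idx_env <- ((k - 1) * per_seg + 1):(k * per_seg)
    idx_env <- idx_env[idx_env <= nrow(env)]
    if (max(env$rms[idx_env]) <= cutoff) {
      s0 <- (k - 1) * seg_n
      rows[[length(rows) + 1]] <- tibble(
        subject_id = session$subject_id,
        channel = channel,
        start_s = s0 / fs,
        fs_hz = fs,
        class_label = session$class_label,
        samples = list(x[(s0 + 1):(s0 + seg_n)])
      )
    }
  }
  if (!length(rows)) return(empty_segments())
  bind_rows(rows)
}

empty_segments <- function() {
  tibble(
    subject_id = character(0), channel = character(0),
    start_s = numeric(0), fs_hz = numeric(0),
    class_label = character(0), samples = list()
  )
}

#' Segment every session of a cohort
#'
#' @param cohort a `cw_cohort`.
#' @param channels channel labels to segment (default all six).
#' @inheritParams segment_recording
#' @return tibble of accepted segments across sessions and channels (see
#'   [segment_recording()]).
#' @export
segment_cohort <- function(cohort, channels = CHANNELS, segment_s = 10,
                           threshold = 1.5, step_s = 0.5) {
  out <- lapply(cohort, function(s) {
    bind_rows(lapply(channels, function(ch) {
      segment_recording(s, ch, segment_s, threshold, step_s)
    }))
  })
  bind_rows(out)
}
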