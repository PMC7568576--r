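#' Simulate a subject profile
#'
#' Draws the latent, subject-level parameters that shape one subject's
#' six-axis seismocardiogram (SCG) / gyrocardiogram (GCG) recording:
#' resting heart rate, per-channel beat amplitudes, the oscillation
#' frequencies of the systolic beat complex, the disease-effect band and
#' gain, the broadband sensor-noise level, and the motion-artifact rate.
#' All cardio-mechanical content lives below 25 Hz; the aortic-stenosis
#' (AS) effect band lies below 10 Hz, where the discriminative energy of
#' real AS recordings concentrates.
#'
#' Class labels are `"NON_AS"` (no disease effect, gain 0), `"AS"` (pure
#' aortic stenosis), and the co-occurrence classes `"AS_MI"`, `"AS_MS"`,
#' `"AS_TR"` which share the AS primary band but add a distinct secondary
#' band each, so that 4-class separation is learnable.
#'
#' @param class_label one of `"AS"`, `"NON_AS"`, `"AS_MI"`, `"AS_MS"`,
#'   `"AS_TR"`.
#' @param seed non-negative integer; fixes the subject's entire
#'   realization (profile draws and, later, the signal realization).
#' @return an object of class `subject_profile`: a list with fields
#'   `subject_id`, `class_label`, `heart_rate_bpm`, `beat_amplitude`
#'   (named 6-vector), `base_freqs_hz`, `beat_sigma_s`,
#'   `class_effect_band_hz`, `class_effect_freq_hz`, `class_effect_gain`,
#'   `secondary_band_hz`, `secondary_freq_hz`, `secondary_gain`,
#'   `noise_sd`, `artifact_rate_per_min`, `seed`.
#' @examples
#' p <- generate_subject("AS", seed = 7)
#' p$class_effect_gain > 0
#' @export
generate_subject <- function(class_label, seed) {
  if (!is.character(class_label) || length(class_label) != 1 ||
      !class_label %in% CLASS_LEVELS) {
    abort(paste0("unknown class label: ", paste(class_label, collapse = ",")),
          class = "cardiowave_invalid_label")
  }
  stopifnot(is.numeric(seed), length(seed) == 1, seed >= 0)
  seed <- as.integer(seed)
  # offset the profile stream per class so e.g. AS/seed 7 and NON_AS/seed 7
  # are distinct subjects
  profile_seed <- as.integer(
    (as.numeric(seed) * 5 + match(class_label, CLASS_LEVELS)) %%
      .Machine$integer.max)

  bands <- list(
    AS    = c(4.5, 8.5),
    NON_AS = c(4.5, 8.5),   # carried for symmetry; gain is 0
    AS_MI = c(4.5, 8.5),
    AS_MS = c(4.5, 8.5),
    AS_TR = c(4.5, 8.5)
  )
  secondary <- list(
    AS_MI = c(1.2, 2.8),
    AS_MS = c(10.5, 13.5),
    AS_TR = c(15, 19)
  )

  with_seed(profile_seed, {
    channel_base <- c(SCG_X = 0.8, SCG_Y = 0.9, SCG_Z = 1.2,
                      GCG_X = 1.0, GCG_Y = 1.2, GCG_Z = 0.8)
    amp <- channel_base * runif(6, 0.9, 1.1)
    band <- bands[[class_label]]
    gain <- if (class_label == "NON_AS") 0 else runif(1, 1.3, 1.7)
    sec_band <- secondary[[class_label]]
    sec_gain <- if (is.null(sec_band)) 0 else runif(1, 0.8, 1.1)
    prof <- structure(list(
      subject_id = sprintf("%s_seed%d", class_label, seed),
      class_label = class_label,
      heart_rate_bpm = runif(1, 55, 95),
      beat_amplitude = amp,
      base_freqs_hz = c(runif(1, 9, 14), runif(1, 18, 23)),
      beat_sigma_s = 0.08,
      class_effect_band_hz = band,
      class_effect_freq_hz = runif(1, band[1], band[2]),
      class_effect_gain = gain,
      secondary_band_hz = sec_band,
      secondary_freq_hz = if (is.null(sec_band)) NULL else
        runif(1, sec_band[1], sec_band[2]),
      secondary_gain = sec_gain,
      noise_sd = runif(1, 0.8, 1.2),
      baseline_gain = 1.2,
      artifact_rate_per_min = 2,
      seed = seed
    ), class = "subject_profile")
    prof
  })
}

#' Simulate one six-axis inertial recording
#'
#' Synthesizes the recording implied by a [generate_subject()] profile: a
#' beat train of Gaussian-windowed sinusoids repeated at the heart-rate
#' interval, plus (for AS-family subjects) Gaussian-windowed disease-band
#' tone bursts shortly after each beat, plus white sensor noise, plus
#' Poisson-placed high-amplitude motion-artifact bursts (tone bursts of
#' 0.5-2 s at >= 10x the channel beat amplitude) that downstream
#' RMS-median segmentation must reject. Per-channel gains come from
#' `profile$beat_amplitude`. The realization is fully determined by
#' `profile$seed`.
#'
#' @param profile a `subject_profile`.
#' @param duration_s recording length in seconds (default 300, i.e. the
#'   5-minute seated rest protocol the pipeline assumes).
#' @param fs_hz sampling rate in Hz (default 256).
#' @return an object of class `recording_session`: list with
#'   `subject_id`, `class_label`, `fs_hz`, `duration_s`, `channels`
#'   (canonical order `SCG_X ... GCG_Z`), `data` (tibble with `time_s`
#'   and one lower-case column per channel), and `artifacts` (tibble
#'   `onset_s`, `duration_s` of injected bursts).
#' @examples
#' p <- generate_subject("NON_AS", seed = 1)
#' s <- generate_recording(p, duration_s = 30, fs_hz = 128)
#' dim(s$data)
#' @export
generate_recording <- function(profile, duration_s = 300, fs_hz = 256) {
  stopifnot(inherits(profile, "subject_profile"))
  if (!is.numeric(duration_s) || duration_s <= 0 ||
      !is.numeric(fs_hz) || fs_hz <= 0) {
    abort("duration_s and fs_hz must be positive",
          class = "cardiowave_invalid_argument")
  }
  n <- round(fs_hz * duration_s)
  t <- (seq_len(n) - 1) / fs_hz

  with_seed(profile$seed, {
    period <- 60 / profile$heart_rate_bpm
    beat_centers <- seq(period / 2, duration_s, by = period)

    env_train <- function(centers, sigma) {
      env <- numeric(n)
      half <- ceiling(4 * sigma * fs_hz)
      for (tc in centers) {
        ic <- round(tc * fs_hz) + 1
        if (ic - half > n || ic + half < 1) next
        idx <- max(1, ic - half):min(n, ic + half)
        env[idx] <- env[idx] + exp(-((t[idx] - tc)^2) / (2 * sigma^2))
      }
      env
    }

    # S1-like burst at the beat center plus a weaker S2-like burst 350 ms
    # later, so the RMS envelope stays close to unimodal
    env_beat <- env_train(beat_centers, profile$beat_sigma_s) +
      0.7 * env_train(beat_centers + 0.35, profile$beat_sigma_s)
    phases <- runif(length(profile$base_freqs_hz), 0, 2 * pi)
    weights <- c(1, 0.6)[seq_along(profile$base_freqs_hz)]
    s0 <- numeric(n)
    for (j in seq_along(profile$base_freqs_hz)) {
      s0 <- s0 + weights[j] * env_beat *
        cos(2 * pi * profile$base_freqs_hz[j] * t + phases[j])
    }

    # continuous multi-tone in-band baseline (respiratory/vascular
    # micro-vibration floor); near-constant window RMS, which keeps the
    # envelope median stable against noise fluctuations
    bg <- profile$baseline_gain %||% 0
    if (bg > 0) {
      base_tones <- c(1.3, 2.7, 5.3, 7.9, 11.7, 14.3, 17.9, 21.3)
      ph <- runif(length(base_tones), 0, 2 * pi)
      for (j in seq_along(base_tones)) {
        s0 <- s0 + bg / sqrt(length(base_tones)) *
          cos(2 * pi * base_tones[j] * t + ph[j])
      }
    }

    # disease-effect component: murmur-like burst ~150 ms after each beat
    if (profile$class_effect_gain > 0) {
      env_cls <- env_train(beat_centers + 0.15, 0.1)
      s0 <- s0 + profile$class_effect_gain * env_cls *
        cos(2 * pi * profile$class_effect_freq_hz * t + runif(1, 0, 2 * pi))
    }
    if (!is.null(profile$secondary_band_hz) && profile$secondary_gain > 0) {
      env_sec <- env_train(beat_centers + 0.25, 0.1)
      s0 <- s0 + profile$secondary_gain * env_sec *
        cos(2 * pi * profile$secondary_freq_hz * t + runif(1, 0, 2 * pi))
    }

    # Poisson-placed motion artifacts, shared timing across channels
    rate <- profile$artifact_rate_per_min
    n_art <- if (rate > 0) rpois(1, rate * duration_s / 60) else 0L
    artifacts <- tibble(onset_s = numeric(0), duration_s = numeric(0))
    art_sig <- numeric(n)
    if (n_art > 0) {
      # onsets and durations on the 0.5-s RMS lattice, so every envelope
      # window a burst overlaps is fully inside the burst and rejection
      # by the 1.5x-median rule is deterministic
      durs <- 0.5 * sample(1:4, n_art, replace = TRUE)
      onsets <- 0.5 * vapply(durs, function(d)
        sample.int(max(1, 2 * (duration_s - d)), 1) - 1, numeric(1))
      freqs <- runif(n_art, 3, 20)
      for (k in seq_len(n_art)) {
        idx <- which(t >= onsets[k] & t < onsets[k] + durs[k])
        if (!length(idx)) next
        win <- sin(pi * (t[idx] - onsets[k]) / durs[k])  # half-sine window
        art_sig[idx] <- art_sig[idx] +
          12 * win * cos(2 * pi * freqs[k] * t[idx] + runif(1, 0, 2 * pi))
      }
      artifacts <- tibble(onset_s = onsets, duration_s = durs)
    }

    cols <- lapply(seq_along(CHANNELS), function(ch) {
      profile$beat_amplitude[ch] * (s0 + art_sig) +
        rnorm(n, sd = profile$noise_sd)
    })
    names(cols) <- tolower(CHANNELS)
    data <- as_tibble(c(list(time_s = t), cols))

    structure(list(
      subject_id = profile$subject_id,
      class_label = profile$class_label,
      fs_hz = fs_hz,
      duration_s = duration_s,
      channels = CHANNELS,
      data = data,
      artifacts = artifacts
    ), class = "recording_session")
  })
}

#' Simulate a labeled cohort of recordings
#'
#' Generates one recording per requested subject, with subject-level
#' random effects (heart rate, channel gains, effect frequencies) drawn
#' independently per subject, so that leave-one-subject-out validation is
#' strictly harder than segment-level hold-out. The default cohort sizes
#' mirror a clinical AS study arm of 21 AS patients and 13 non-AS
#' controls.
#'
#' @param n_per_class named integer vector of subjects per class, e.g.
#'   `c(AS = 21, NON_AS = 13)`.
#' @param duration_s,fs_hz passed to [generate_recording()].
#' @param seed integer master seed; the whole cohort is deterministic in
#'   it.
#' @return a list of `recording_session` objects (class `cw_cohort`) with
#'   a `metadata` attribute: tibble `subject_id`, `class_label`, `fs_hz`.
#' @examples
#' coh <- generate_cohort(c(AS = 2, NON_AS = 1), duration_s = 30,
#'                        fs_hz = 128, seed = 1)
#' length(coh)
#' @export
generate_cohort <- function(n_per_class, duration_s = 300, fs_hz = 256,
                            seed = 1) {
  if (length(n_per_class) == 0) {
    abort("empty cohort request", class = "cardiowave_invalid_argument")
  }
  if (is.null(names(n_per_class)) || any(!names(n_per_class) %in% CLASS_LEVELS)) {
    abort("n_per_class must be named with valid class labels",
          class = "cardiowave_invalid_label")
  }
  stopifnot(all(n_per_class >= 0))
  labels <- rep(names(n_per_class), times = n_per_class)
  n_total <- length(labels)
  if (n_total == 0) {
    abort("cohort request has zero subjects",
          class = "cardiowave_invalid_argument")
  }
  subject_seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1, n_total))
  sessions <- vector("list", n_total)
  counters <- setNames(integer(length(n_per_class)), names(n_per_class))
  for (i in seq_len(n_total)) {
    lab <- labels[i]
    counters[lab] <- counters[lab] + 1L
    prof <- generate_subject(lab, subject_seeds[i])
    prof$subject_id <- sprintf("%s_%02d", lab, counters[lab])
    sessions[[i]] <- generate_recording(prof, duration_s, fs_hz)
  }
  meta <- tibble(
    subject_id = vapply(sessions, function(s) s$subject_id, character(1)),
    class_label = vapply(sessions, function(s) s$class_label, character(1)),
    fs_hz = fs_hz
  )
  structure(sessions, class = "cw_cohort", metadata = meta)
}

#' Cohort metadata table
#'
#' @param cohort a `cw_cohort` from [generate_cohort()] or
#'   [read_cohort_csv()].
#' @return tibble with `subject_id`, `class_label`, `fs_hz`.
#' @export
cohort_metadata <- function(cohort) {
  attr(cohort, "metadata")
}

#' Extract one channel of a recording as a numeric vector
#'
#' @param session a `recording_session`.
#' @param channel one of `SCG_X`, `SCG_Y`, `SCG_Z`, `GCG_X`, `GCG_Y`,
#'   `GCG_Z`.
#' @return numeric vector of samples.
#' @export
get_channel <- function(session, channel) {
  stopifnot(inherits(session, "recording_session"))
  if (!channel %in% CHANNELS) {
    abort(paste0("unknown channel: ", channel),
          class = "cardiowave_invalid_channel")
  }
  session$data[[tolower(channel)]]
}

#' Write / read a cohort as plain CSV files
#'
#' One `<subject_id>.csv` per session with columns
#' `time_s,scg_x,scg_y,scg_z,gcg_x,gcg_y,gcg_z`, plus `metadata.csv`
#' (`subject_id,class_label,fs_hz`).
#'
#' @param cohort a `cw_cohort`.
#' @param dir output directory (created if missing).
#' @return `write_cohort_csv()` returns `dir` invisibly;
#'   `read_cohort_csv()` returns a `cw_cohort` (without artifact
#'   annotations, which are not part of the on-disk format).
#' @export
write_cohort_csv <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- cohort_metadata(cohort)
  readr::write_csv(meta, file.path(dir, "metadata.csv"))
  for (s in cohort) {
    readr::write_csv(s$data, file.path(dir, paste0(s$subject_id, ".csv")))
  }
  invisible(dir)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(dir) {
  meta <- readr::read_csv(file.path(dir, "metadata.csv"),
                          show_col_types = FALSE)
  sessions <- lapply(seq_len(nrow(meta)), function(i) {
    d <- readr::read_csv(file.path(dir, paste0(meta$subject_id[i], ".csv")),
                         show_col_types = FALSE)
    structure(list(
      subject_id = meta$subject_id[i],
      class_label = meta$class_label[i],
      fs_hz = meta$fs_hz[i],
      duration_s = nrow(d) / meta$fs_hz[i],
      channels = CHANNELS,
      data = d,
      artifacts = tibble(onset_s = numeric(0), duration_s = numeric(0))
    ), class = "recording_session")
  })
  structure(sessions, class = "cw_cohort", metadata = as_tibble(meta))
}

#' Simulate labeled band-structured scalogram-like images
#'
#' Direct generator of two-class single-channel images that mimic
#' scalograms whose classes differ by which frequency rows carry energy:
#' class 0 concentrates energy in one row band, class 1 in a disjoint
#' band, each blurred in time and embedded in positive noise. Used to
#' exercise and test the 2-D CNN without running the full signal
#' pipeline.
#'
#' @param n_per_class images per class.
#' @param height,width image size in pixels.
#' @param noise_sd standard deviation of the background noise.
#' @param seed integer seed.
#' @return list with `images` (array `height x width x n`) and `labels`
#'   (integer vector of 0/1).
#' @export
simulate_band_images <- function(n_per_class, height = 60, width = 80,
                                 noise_sd = 0.3, seed = 1) {
  stopifnot(n_per_class >= 1, height >= 10, width >= 10)
  n <- 2L * n_per_class
  with_seed(seed, {
    imgs <- array(abs(rnorm(height * width * n, sd = noise_sd)),
                  dim = c(height, width, n))
    labels <- rep(c(0L, 1L), each = n_per_class)
    band0 <- round(height * c(0.15, 0.35))
    band1 <- round(height * c(0.60, 0.80))
    for (i in seq_len(n)) {
      band <- if (labels[i] == 0L) band0 else band1
      rows <- band[1]:band[2]
      # a few time-localized blobs within the class band
      for (b in seq_len(3)) {
        ct <- sample.int(width, 1)
        tt <- pmax(1, ct - 6):pmin(width, ct + 6)
        blob <- outer(exp(-((rows - mean(rows))^2) / (2 * (length(rows) / 3)^2)),
                      exp(-((tt - ct)^2) / 18))
        imgs[rows, tt, i] <- imgs[rows, tt, i] + blob
      }
    }
    list(images = imgs, labels = labels)
  })
}
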