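#' Build the CWT frequency grid
#'
#' Log2-spaced analysis frequencies with `voices_per_octave` points per
#' octave, spanning 0.79-25.39 Hz (the band the statistical features are
#' drawn from), returned in descending order. The grid carries the
#' generalized Morse wavelet parameters gamma and beta
#' (time-bandwidth product gamma*beta, default 60).
#'
#' @param fs_hz sampling rate the grid will be used at; `f_max_hz` must
#'   lie below Nyquist.
#' @param voices_per_octave grid density (default 16).
#' @param f_min_hz,f_max_hz frequency range in Hz.
#' @param gamma,beta Morse wavelet shape parameters.
#' @return object of class `cwt_grid`: list with `frequencies_hz`
#'   (descending), `voices_per_octave`, `f_min_hz`, `f_max_hz`, `gamma`,
#'   `beta`, `fs_hz`.
#' @examples
#' g <- build_cwt_grid(256)
#' length(g$frequencies_hz)  # 81
#' @export
build_cwt_grid <- function(fs_hz, voices_per_octave = 16,
                           f_min_hz = 0.79, f_max_hz = 25.39,
                           gamma = 3, beta = 20) {
  stopifnot(f_min_hz > 0, f_min_hz < f_max_hz, voices_per_octave >= 1)
  if (f_max_hz >= fs_hz / 2) {
    abort(sprintf("f_max_hz = %g >= Nyquist (%g)", f_max_hz, fs_hz / 2),
          class = "cardiowave_nyquist_violation")
  }
  n_f <- floor(voices_per_octave * log2(f_max_hz / f_min_hz)) + 1
  freqs <- f_max_hz * 2^(-(seq_len(n_f) - 1) / voices_per_octave)
  freqs <- pmin(pmax(freqs, f_min_hz), f_max_hz)
  structure(list(
    frequencies_hz = freqs,
    voices_per_octave = voices_per_octave,
    f_min_hz = f_min_hz, f_max_hz = f_max_hz,
    gamma = gamma, beta = beta, fs_hz = fs_hz
  ), class = "cwt_grid")
}

#' Continuous wavelet transform with a generalized Morse wavelet
#'
#' FFT-based CWT using the analytic generalized Morse wavelet
#' \deqn{\Psi(\omega) = 2 (e\gamma/\beta)^{\beta/\gamma} \omega^\beta
#' e^{-\omega^\gamma}, \quad \omega > 0,} peak-normalized so a unit
#' sinusoid at a grid frequency produces ridge magnitude ~ 1 (L1-type
#' normalization). The signal is zero-padded to the next power of two at
#' least twice its length (zero-padding boundary handling; no
#' cone-of-influence masking).
#'
#' @param samples numeric vector, or one row of a segment tibble via
#'   `samples[[i]]`.
#' @param fs_hz sampling rate.
#' @param grid a `cwt_grid`; its `fs_hz` must match.
#' @param subject_id,channel optional provenance carried on the result.
#' @return object of class `scalogram`: list with `magnitude` (F x T
#'   matrix of |CWT|), `frequencies_hz`, `times_s`, `grid`, `subject_id`,
#'   `channel`.
#' @examples
#' fs <- 128
#' x <- sin(2 * pi * 5 * seq(0, 10, by = 1 / fs))
#' g <- build_cwt_grid(fs)
#' sc <- cwt_morse(x, fs, g)
#' @export
cwt_morse <- function(samples, fs_hz, grid = build_cwt_grid(fs_hz),
                      subject_id = NA_character_, channel = NA_character_) {
  stopifnot(inherits(grid, "cwt_grid"))
  if (!isTRUE(all.equal(grid$fs_hz, fs_hz))) {
    abort("grid was built for a different sampling rate",
          class = "cardiowave_invalid_argument")
  }
  if (!length(samples)) {
    abort("empty input", class = "cardiowave_invalid_argument")
  }
  n <- length(samples)
  m <- 2^ceiling(log2(2 * n))
  xf <- fft(c(samples, numeric(m - n)))
  gamma <- grid$gamma
  beta <- grid$beta
  peak_omega <- (beta / gamma)^(1 / gamma)
  lognorm <- log(2) + (beta / gamma) * (1 + log(gamma) - log(beta))

  omega <- 2 * pi * (0:(m - 1)) / m          # rad/sample over the DFT bins
  pos <- which(omega > 0 & omega <= pi)      # analytic: positive freqs only
  scales <- peak_omega * fs_hz / (2 * pi * grid$frequencies_hz)
  so <- omega[pos] %o% scales                # |pos| x F
  psi <- matrix(0, m, length(scales))
  psi[pos, ] <- exp(lognorm + beta * log(so) - so^gamma)
  w <- stats::mvfft(psi * xf, inverse = TRUE) / m
  mag <- t(Mod(w[seq_len(n), , drop = FALSE]))
  structure(list(
    magnitude = mag,
    frequencies_hz = grid$frequencies_hz,
    times_s = (seq_len(n) - 1) / fs_hz,
    grid = grid,
    subject_id = subject_id,
    channel = channel
  ), class = "scalogram")
}

#' Per-frequency statistical features of a scalogram
#'
#' For every frequency row of the magnitude matrix, computes five
#' statistics over the time axis: MEAN (arithmetic), MED (type-7 median),
#' MAX, STD (population standard deviation, divisor N) and IQR
#' (type-7 Q3 - Q1). Output is ordered by (statistic, descending
#' frequency) and named `<CHANNEL>_<STAT>_<freq>` with the frequency
#' printed to two decimals, so each feature's provenance can be parsed
#' back out for distribution summaries.
#'
#' @param scalogram a `scalogram`; must carry a channel label (or pass
#'   `channel`).
#' @param channel optional channel override used in feature names.
#' @return tibble with `feature` and `value`, `5 * F` rows.
#' @export
extract_features <- function(scalogram, channel = NULL) {
  stopifnot(inherits(scalogram, "scalogram"))
  m <- scalogram$magnitude
  if (!length(m)) {
    abort("empty scalogram", class = "cardiowave_invalid_argument")
  }
  ch <- channel %||% scalogram$channel
  if (is.na(ch)) ch <- "NA"
  f <- scalogram$frequencies_hz
  # type-7 quantiles from one sort per row (hot path)
  nt <- ncol(m)
  h <- (nt - 1) * c(0.25, 0.5, 0.75) + 1
  lo <- floor(h); fr <- h - lo
  q <- t(apply(m, 1, function(row) {
    sr <- sort.int(row, method = "quick")
    c(sr[lo] + fr * (sr[pmin(lo + 1, nt)] - sr[lo]), sr[nt])
  }))
  mu <- rowMeans(m)
  stats_list <- list(
    MEAN = mu,
    MED = q[, 2],
    MAX = q[, 4],
    STD = sqrt(pmax(rowMeans(m^2) - mu^2, 0)),
    IQR = q[, 3] - q[, 1]
  )
  tibble(
    feature = unlist(lapply(STATS, function(s)
      sprintf("%s_%s_%.2f", ch, s, f))),
    value = unlist(stats_list[STATS], use.names = FALSE)
  )
}

#' Parse feature names back into (channel, statistic, frequency)
#'
#' Inverse of the naming scheme used by [extract_features()].
#'
#' @param names character vector like `"SCG_Z_MAX_5.00"`.
#' @return tibble with `feature`, `channel`, `statistic`, `freq_hz`.
#' @export
parse_feature_names <- function(names) {
  pat <- sprintf("^((?:SCG|GCG)_[XYZ])_(%s)_([0-9]+\\.[0-9]{2})$",
                 paste(STATS, collapse = "|"))
  ok <- grepl(pat, names)
  if (any(!ok)) {
    abort(paste0("malformed feature name(s): ",
                 paste(head(names[!ok], 3), collapse = ", ")),
          class = "cardiowave_malformed_feature_name")
  }
  tibble(
    feature = names,
    channel = sub(pat, "\\1", names),
    statistic = sub(pat, "\\2", names),
    freq_hz = as.numeric(sub(pat, "\\3", names))
  )
}

#' Build a segments-by-features table for a cohort
#'
#' Runs the Morse CWT and [extract_features()] on every segment and
#' joins channels on the (subject, window start) key, keeping only
#' windows accepted on every requested channel, so each row is one time
#' window with the concatenated per-channel features.
#'
#' @param segments segment tibble from [segment_cohort()].
#' @param grid a `cwt_grid` matching the segments' sampling rate.
#' @param channels channels to include (default: all present).
#' @return tibble with `subject_id`, `class_label`, `start_s` and one
#'   numeric column per feature.
#' @export
build_feature_table <- function(segments, grid,
                                channels = unique(segments$channel)) {
  stopifnot(nrow(segments) > 0)
  segs <- filter(segments, .data$channel %in% channels)
  per_channel <- lapply(channels, function(ch) {
    sub <- filter(segs, .data$channel == ch)
    if (!nrow(sub)) return(NULL)
    feats <- lapply(seq_len(nrow(sub)), function(i) {
      sc <- cwt_morse(sub$samples[[i]], sub$fs_hz[i], grid,
                      subject_id = sub$subject_id[i], channel = ch)
      fv <- extract_features(sc)
      stats::setNames(fv$value, fv$feature)
    })
    wide <- as_tibble(do.call(rbind, feats))
    bind_cols(
      tibble(subject_id = sub$subject_id, class_label = sub$class_label,
             start_s = sub$start_s),
      wide
    )
  })
  per_channel <- per_channel[!vapply(per_channel, is.null, logical(1))]
  out <- purrr::reduce(per_channel, function(a, b)
    inner_join(a, b, by = c("subject_id", "class_label", "start_s")))
  out
}

#' Select the feature columns of a feature table by channel
#'
#' @param table feature table from [build_feature_table()].
#' @param channels channels to keep.
#' @return feature table restricted to metadata columns plus the
#'   requested channels' features.
#' @export
filter_channels <- function(table, channels) {
  feats <- feature_columns(table)
  keep <- feats[parse_feature_names(feats)$channel %in% channels]
  select(table, all_of(c(meta_columns(table), keep)))
}

meta_columns <- function(table) {
  intersect(c("subject_id", "class_label", "start_s"), names(table))
}

feature_columns <- function(table) {
  setdiff(names(table), c("subject_id", "class_label", "start_s"))
}
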