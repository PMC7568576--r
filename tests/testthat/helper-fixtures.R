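# shared fixture builders; everything is generated in code at test time

quiet_profile <- function(class_label = "NON_AS", seed = 1) {
  p <- generate_subject(class_label, seed)
  p$artifact_rate_per_min <- 0
  p
}

# feature table with k planted discriminative columns (mean shift d for
# class AS) among p standard-normal columns; ground truth in attr
make_planted_table <- function(n = 200, p = 250, k = 10, d = 2, seed = 42,
                               subjects = 20) {
  withr::with_seed(seed, {
    labels <- rep(c("AS", "NON_AS"), length.out = n)
    x <- matrix(rnorm(n * p), n, p)
    stats <- rep(c("MEAN", "MED", "MAX", "STD", "IQR"), length.out = p)
    chans <- rep(c("SCG_X", "SCG_Y", "SCG_Z", "GCG_X", "GCG_Y", "GCG_Z"),
                 length.out = p)
    freqs <- round(seq(1, 25, length.out = p), 2)
    names <- sprintf("%s_%s_%.2f", chans, stats, freqs)
    planted <- sample(p, k)
    x[labels == "AS", planted] <- x[labels == "AS", planted] + d
    colnames(x) <- names
    tb <- dplyr::bind_cols(
      tibble::tibble(
        subject_id = sprintf("S%02d", rep_len(seq_len(subjects), n)),
        class_label = labels),
      tibble::as_tibble(x))
    attr(tb, "planted") <- names[planted]
    tb
  })
}

# small well-separated 2-class table for classifier sanity checks
make_separable_table <- function(n = 60, p = 20, d = 3, seed = 7) {
  make_planted_table(n = n, p = p, k = 5, d = d, seed = seed, subjects = 6)
}

# session object with a burst injected into one channel at a known time
inject_burst <- function(session, channel, t0, dur, amplitude) {
  col <- tolower(channel)
  t <- session$data$time_s
  idx <- which(t >= t0 & t < t0 + dur)
  session$data[[col]][idx] <- session$data[[col]][idx] +
    amplitude * sin(2 * pi * 10 * t[idx])
  session
}
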