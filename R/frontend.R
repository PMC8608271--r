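# Acoustic and neural frontends: cochlear-model auditory spectrogram and
# high-gamma envelope extraction.

#' Cochlear-model auditory spectrogram
#'
#' Transforms mono audio into a 16-band auditory spectrogram using a bank of
#' 128 asymmetric filters equally spaced on a logarithmic frequency axis,
#' followed by nonlinear (cube-root) compression, a first-order derivative
#' along the spectral axis with half-wave rectification (a lateral-inhibition
#' stage), envelope estimation, and resampling of the 128 channels into 16
#' contiguous log-spaced bands.
#'
#' The filters have a shallow low-frequency skirt and a sharp high-frequency
#' skirt, mimicking cochlear tuning asymmetry. The frequency span is
#' 180 Hz to 5.5 kHz; audio sampled at 11.025 kHz therefore covers the full
#' span (its Nyquist limit caps the top analysis frequency at ~5.5 kHz).
#'
#' @param audio numeric vector of audio samples
#' @param sr sampling rate in Hz (>= 8000)
#' @param frame_rate output frame rate in Hz (default 100, i.e. 10 ms frames)
#' @param n_channels number of cochlear filters (default 128)
#' @param n_bands number of output bands (default 16)
#' @param fmin,fmax frequency span of the filterbank in Hz
#' @param compression exponent of the power-law compression (default 1/3)
#' @return a [spectrogram] (time x `n_bands`)
#' @export
auditory_spectrogram <- function(audio, sr, frame_rate = 100,
                                 n_channels = 128, n_bands = 16,
                                 fmin = 180, fmax = 5500,
                                 compression = 1 / 3) {
  if (any(!is.finite(audio))) stop("audio contains non-finite samples")
  if (sr < 8000) stop("sampling rate must be at least 8000 Hz")
  if (sr / 2 < fmax)
    stop(sprintf(paste0("sampling rate %g Hz cannot represent the top filter; ",
                        "maximum representable frequency is %g Hz"), sr, sr / 2))
  hop <- round(sr / frame_rate)
  win <- 2 * hop
  n_frames <- max(0, floor((length(audio) - win) / hop) + 1)
  if (n_frames < 1) stop("audio shorter than one analysis frame")
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(win) / (win + 1))  # Hann
  fc <- geom_seq(fmin, fmax, n_channels)
  freqs <- (0:(win %/% 2)) * sr / win
  # asymmetric filter magnitudes on the FFT bins (channels x bins)
  # shallow low-frequency skirt, very sharp high-frequency cutoff; the
  # sharp side is set so the post-inhibition (spectral-derivative) peak
  # stays in the driving tone's band after cube-root compression
  sig_lo <- 0.35; sig_hi <- 0.03
  H <- matrix(0, n_channels, length(freqs))
  for (c in seq_len(n_channels)) {
    d <- log2(pmax(freqs, 1) / fc[c])
    H[c, ] <- ifelse(d <= 0, exp(-d^2 / (2 * sig_lo^2)),
                             exp(-d^2 / (2 * sig_hi^2)))
    H[c, freqs < 1] <- 0
  }
  E <- matrix(0, n_frames, n_channels)
  for (t in seq_len(n_frames)) {
    seg <- audio[((t - 1) * hop + 1):((t - 1) * hop + win)] * w
    P <- Mod(stats::fft(seg)[seq_along(freqs)])^2
    E[t, ] <- sqrt(H %*% P)
  }
  E <- E^(2 * compression)            # power -> compressed amplitude
  # lateral inhibition: spectral first difference, half-wave rectified
  D <- cbind(E[, 1, drop = FALSE], E[, -1, drop = FALSE] - E[, -n_channels, drop = FALSE])
  D[D < 0] <- 0
  # envelope estimation: short leaky integration along time
  if (n_frames > 1) {
    a <- 0.4
    for (t in 2:n_frames) D[t, ] <- (1 - a) * D[t, ] + a * D[t - 1, ]
  }
  # resample 128 channels -> n_bands contiguous log-spaced groups
  grp <- rep(seq_len(n_bands), each = n_channels %/% n_bands)
  V <- sapply(seq_len(n_bands), function(b) rowMeans(D[, grp == b, drop = FALSE]))
  V <- matrix(V, nrow = n_frames)
  centers <- sapply(seq_len(n_bands), function(b) exp(mean(log(fc[grp == b]))))
  spectrogram(V, frame_rate, centers)
}

#' Preprocess raw intracranial recordings
#'
#' Resamples to 500 Hz, removes DC drift with a 1st-order Butterworth
#' high-pass at 1 Hz, and removes line noise at 60 Hz and its harmonics up
#' to 240 Hz with 2nd-order IIR notch filters of 1 Hz bandwidth. All
#' filters are applied forward-backward (zero phase) so later latency
#' estimates are not biased by group delay.
#'
#' @param raw numeric matrix, electrodes x samples (a vector is treated as
#'   one electrode)
#' @param sr sampling rate of `raw` in Hz (>= 500)
#' @param line_freq line-noise fundamental in Hz (default 60)
#' @return list with `values` (electrodes x samples at 500 Hz) and `sr` (500)
#' @export
preprocess_raw <- function(raw, sr, line_freq = 60) {
  if (is.null(dim(raw))) raw <- matrix(raw, nrow = 1)
  if (sr < 500) stop("sampling rate must be at least 500 Hz")
  fs <- 500
  if (sr != fs) {
    g <- as.integer(gcd_int(fs, round(sr)))
    raw <- t(apply(raw, 1, function(x)
      signal::resample(x, fs %/% g, round(sr) %/% g)))
  }
  hp <- signal::butter(1, 1 / (fs / 2), type = "high")
  raw <- t(apply(raw, 1, function(x) signal::filtfilt(hp, x)))
  for (f0 in seq(line_freq, 4 * line_freq, by = line_freq)) {
    bs <- signal::butter(1, c(f0 - 0.5, f0 + 0.5) / (fs / 2), type = "stop")
    raw <- t(apply(raw, 1, function(x) signal::filtfilt(bs, x)))
  }
  list(values = raw, sr = fs)
}

#' Extract z-scored high-gamma envelopes
#'
#' Applies [preprocess_raw], splits the 70-150 Hz high-gamma range into 8
#' equal 10 Hz sub-bands, takes the magnitude of the analytic signal in
#' each sub-band, averages the 8 envelopes, downsamples the envelope to
#' `out_rate`, and z-scores each electrode by the mean and standard
#' deviation of the prestimulus baseline window.
#'
#' @param raw numeric matrix, electrodes x samples
#' @param sr sampling rate in Hz (>= 500)
#' @param baseline_window numeric length-2, start and end of the baseline
#'   (prestimulus silence) in seconds
#' @param out_rate output envelope frame rate in Hz (default 100)
#' @param preprocessed set TRUE if `raw` is already at 500 Hz and filtered
#' @return an [hg_response]
#' @export
extract_high_gamma <- function(raw, sr, baseline_window, out_rate = 100,
                               preprocessed = FALSE) {
  if (is.null(dim(raw))) raw <- matrix(raw, nrow = 1)
  flat <- apply(raw, 1, stats::sd) == 0
  if (any(flat))
    stop(sprintf("constant raw signal on electrode(s) %s: channel flagged",
                 paste(which(flat), collapse = ",")))
  if (!preprocessed) {
    pp <- preprocess_raw(raw, sr)
    raw <- pp$values; fs <- pp$sr
  } else fs <- sr
  n_el <- nrow(raw)
  edges <- seq(70, 150, by = 10)
  env <- matrix(0, n_el, ncol(raw))
  for (b in seq_len(8)) {
    bp <- signal::butter(4, c(edges[b], edges[b + 1]) / (fs / 2), type = "pass")
    for (e in seq_len(n_el)) {
      env[e, ] <- env[e, ] + analytic_envelope(signal::filtfilt(bp, raw[e, ]))
    }
  }
  env <- env / 8
  # downsample by block averaging to the spectrogram frame rate
  dec <- fs / out_rate
  if (abs(dec - round(dec)) > 1e-9)
    stop("out_rate must divide 500 Hz")
  dec <- as.integer(round(dec))
  if (dec > 1) {
    n_out <- ncol(env) %/% dec
    env <- sapply(seq_len(n_out), function(i)
      rowMeans(env[, ((i - 1) * dec + 1):(i * dec), drop = FALSE]))
    env <- matrix(env, nrow = n_el)
  }
  i0 <- floor(baseline_window[1] * out_rate) + 1
  i1 <- floor(baseline_window[2] * out_rate)
  if (i0 < 1 || i1 > ncol(env) || i1 <= i0)
    stop("baseline_window outside recording")
  bm <- rowMeans(env[, i0:i1, drop = FALSE])
  bs <- apply(env[, i0:i1, drop = FALSE], 1, stats::sd)
  if (any(bs <= 0))
    stop(sprintf("constant baseline on electrode(s) %s: channel flagged",
                 paste(which(bs <= 0), collapse = ",")))
  z <- (env - bm) / bs
  hg_response(z, out_rate, bm, bs)
}

gcd_int <- function(a, b) if (b == 0) a else gcd_int(b, a %% b)
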