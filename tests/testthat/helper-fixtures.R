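# Shared fixtures, built once per session and cached. All synthetic, all
# seeded, nothing on disk.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, force(build), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# small gradient cohort with matched responses at a given SNR
fix_cohort <- function() fixture("cohort", synth_cohort(
  n_sites = 12, duration_s = 45, seed = 101))

fix_responses_clean <- function() fixture("resp_clean",
  generate_responses(fix_cohort(), snr_db = Inf))

fix_responses_0db <- function() fixture("resp_0db",
  generate_responses(fix_cohort(), snr_db = 0))

fix_fits_clean <- function() fixture("fits_clean",
  fit_strf(fix_cohort()$stimulus, fix_responses_clean()))

# direct convolution oracle, independent of lag_matrix
conv_oracle <- function(S, W) {
  n_t <- nrow(S); n_l <- nrow(W)
  out <- numeric(n_t)
  for (t in seq_len(n_t)) {
    lmax <- min(n_l, t)
    for (l in seq_len(lmax)) out[t] <- out[t] + sum(W[l, ] * S[t - l + 1, ])
  }
  out
}

# Gaussian excitatory blob STRF on the default 16-band axis
blob_strf <- function(lag_idx = 9, band_idx = 8, n_lags = 31, n_bands = 16,
                      sd_lag = 1.5, sd_band = 1.2) {
  outer(exp(-((seq_len(n_lags) - lag_idx)^2) / (2 * sd_lag^2)),
        exp(-((seq_len(n_bands) - band_idx)^2) / (2 * sd_band^2)))
}

# windowed temporal grating STRF with Gaussian spectral profile
grating_strf <- function(rate, n_lags = 64, frame_rate = 100,
                         band_centers = NULL, f0 = 1000) {
  if (is.null(band_centers)) band_centers <- fix_cohort()$stimulus$band_centers
  lag <- (seq_len(n_lags) - 1) * 1000 / frame_rate
  env <- 0.5 - 0.5 * cos(2 * pi * seq(0.5, n_lags - 0.5) / n_lags)
  outer(env * cos(2 * pi * rate * lag / 1000),
        exp(-(log2(band_centers / f0))^2 / (2 * 0.6^2)))
}
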