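# Synthetic cohort generator: speech-like stimuli, ground-truth STRF sites
# with planted tuning gradients, phoneme-evoked codes, and the
# speech/nonspeech trial set. Everything is seeded and bit-reproducible.

speaker_pitches <- c(92, 104, 174, 191, 120, 150, 210, 240)

#' Generate a speech-like stimulus spectrogram and phoneme alignment table
#'
#' Synthesizes a multi-speaker "story" directly in the auditory-spectrogram
#' domain: a sequence of phones with log-normal durations, each rendered as
#' a phoneme-specific spectral prototype (formant-like for vowels, frication
#' shelves, bursts, murmurs) warped per speaker, plus a harmonic stack at the
#' speaker's nominal pitch for voiced phones, under raised-cosine temporal
#' envelopes. The slow phone-rate envelopes give the stimulus a speech-like
#' low-pass modulation spectrum (energy concentrated below ~8 Hz).
#'
#' Speaker pitches default to 92, 104, 174 and 191 Hz (two male and two
#' female voices).
#'
#' @param duration_s stimulus duration in seconds (> 0)
#' @param n_speakers number of speakers, 1..8
#' @param seed integer seed; same seed reproduces the stimulus bit-exactly
#' @param frame_rate spectrogram frame rate in Hz
#' @param n_bands number of spectrogram bands
#' @param mean_phone_s median phone duration in seconds (log-normal)
#' @param sdlog_phone log-sd of phone durations
#' @return list with `stimulus` (a [spectrogram]), `phoneme_table`
#'   (data.frame: phoneme, onset_s, offset_s, speaker, manner, place,
#'   voicing, height, backness), and `speakers` (data.frame: speaker, pitch_hz)
#' @export
#' @examples
#' st <- generate_stimulus(10, n_speakers = 2, seed = 1)
#' nrow(st$phoneme_table)
generate_stimulus <- function(duration_s, n_speakers = 4, seed = 1,
                              frame_rate = 100, n_bands = 16,
                              mean_phone_s = 0.09, sdlog_phone = 0.35) {
  if (!is.numeric(duration_s) || duration_s <= 0)
    stop("duration_s must be positive")
  if (n_speakers < 1 || n_speakers > 8)
    stop("n_speakers must be between 1 and 8")
  inv <- phoneme_inventory()
  centers <- default_band_centers(n_bands)
  speakers <- data.frame(speaker = paste0("spk", seq_len(n_speakers)),
                         pitch_hz = speaker_pitches[seq_len(n_speakers)])
  n_frames <- round(duration_s * frame_rate)
  with_seed(seed, {
    S <- matrix(0, n_frames, n_bands)
    # phoneme sampling weights: vowels twice as frequent as consonants
    wts <- ifelse(inv$manner == "vowel", 2, 1)
    rows <- list(); t_cur <- 0.05; spk_i <- 0
    # speaker-warped prototypes cached per (speaker, phoneme)
    protos <- lapply(seq_len(n_speakers), function(s) {
      warp <- (speakers$pitch_hz[s] / 130)^0.25
      lapply(seq_len(nrow(inv)), function(i)
        phoneme_prototype(inv[i, ], centers / warp))
    })
    harmonics <- lapply(seq_len(n_speakers), function(s) {
      f0 <- speakers$pitch_hz[s]
      h <- rep(0, n_bands)
      for (k in 1:12) {
        f <- k * f0
        if (f < min(centers) / 1.3 || f > max(centers) * 1.3) next
        h <- h + exp(-(log2(centers / f))^2 / (2 * 0.08^2)) / k
      }
      h / max(max(h), 1e-9)
    })
    while (t_cur < duration_s - 0.3) {
      spk_i <- spk_i %% n_speakers + 1
      sent_end <- min(t_cur + stats::runif(1, 1.5, 2.5), duration_s - 0.05)
      while (t_cur < sent_end) {
        pi_ <- sample(nrow(inv), 1, prob = wts)
        dur <- min(max(stats::rlnorm(1, log(mean_phone_s), sdlog_phone), 0.03), 0.25)
        if (t_cur + dur > sent_end) dur <- sent_end - t_cur
        if (dur < 0.02) break
        f0i <- floor(t_cur * frame_rate) + 1
        f1i <- floor((t_cur + dur) * frame_rate)
        if (f1i >= f0i && f1i <= n_frames) {
          nf <- f1i - f0i + 1
          env <- 0.5 - 0.5 * cos(2 * pi * seq(0.5, nf - 0.5) / nf)  # raised cosine
          env <- pmin(env * 2.2, 1)
          voiced <- inv$voicing[pi_] == "voiced"
          prof <- protos[[spk_i]][[pi_]] +
            (if (voiced) 0.5 else 0.08) * harmonics[[spk_i]]
          amp <- exp(stats::rnorm(1, 0, 0.2))
          S[f0i:f1i, ] <- S[f0i:f1i, ] + amp * outer(env, prof)
          rows[[length(rows) + 1]] <- data.frame(
            phoneme = inv$phoneme[pi_], onset_s = t_cur,
            offset_s = t_cur + dur, speaker = speakers$speaker[spk_i],
            manner = inv$manner[pi_], place = inv$place[pi_],
            voicing = inv$voicing[pi_], height = inv$height[pi_],
            backness = inv$backness[pi_])
        }
        t_cur <- t_cur + dur
      }
      t_cur <- t_cur + stats::runif(1, 0.12, 0.28)   # inter-sentence pause
    }
    tab <- do.call(rbind, rows)
    rownames(tab) <- NULL
    list(stimulus = spectrogram(S, frame_rate, centers),
         phoneme_table = tab, speakers = speakers)
  })
}

# Gabor-type ground-truth STRF: temporal Gabor at the planted rate times a
# spectral Gaussian at the planted best frequency; peak value 1 at
# (latency, band nearest bf).
make_gabor_strf <- function(bf, latency_ms, btm, band_centers,
                            n_lags = 31, frame_rate = 100,
                            sigma_oct = 0.4, sigma_t_ms = NULL) {
  lag_ms <- (seq_len(n_lags) - 1) * 1000 / frame_rate
  if (is.null(sigma_t_ms))
    sigma_t_ms <- min(max(1000 / (2.5 * btm), 20), 60)
  tm <- exp(-(lag_ms - latency_ms)^2 / (2 * sigma_t_ms^2)) *
    cos(2 * pi * btm * (lag_ms - latency_ms) / 1000)
  fm <- exp(-(log2(band_centers / bf))^2 / (2 * sigma_oct^2))
  W <- outer(tm, fm)
  W / max(W)
}

#' Generate a synthetic electrode cohort with planted tuning gradients
#'
#' Builds a full study-in-a-box: a multi-speaker stimulus, a set of neural
#' sites with ground-truth STRFs laid out along a simulated Heschl's-gyrus
#' axis, and planted gradients of the five tuning attributes along that
#' axis: best frequency and best temporal modulation decreasing
#' posteromedial to anterolateral, and response latency, speaker invariance
#' and speech gain increasing.
#'
#' @param n_sites number of electrodes
#' @param duration_s stimulus duration in seconds
#' @param n_speakers number of speakers
#' @param seed integer seed
#' @param axis_deg orientation of the simulated gyrus axis in the (ML, PA)
#'   plane, degrees
#' @param axis_len_mm extent of the electrode array along the axis (mm)
#' @param layout `"line"`: electrodes strung along the gyrus axis with
#'   ~1 mm scatter (a thin gyrus); `"patch"`: electrodes uniform over a
#'   2-D patch, with the tuning gradients keyed to the projection onto the
#'   axis (needed when the gradient *direction* is itself under study)
#' @param gradients if TRUE plant along-axis gradients; if FALSE draw each
#'   attribute independently (no spatial organization)
#' @param invariance `"gradient"` (alpha increases along the axis), a single
#'   numeric alpha in \[0, 1\] for all sites, `"speaker_invariant"`
#'   (alpha = 1) or `"speaker_dependent"` (alpha = 0)
#' @param speech_gain_range range of the post-linear speech response gain
#'   along the axis; `c(1, 1)` means no speech preference anywhere
#' @param bf_range,latency_range_ms,btm_range spans of the planted gradients
#' @param n_lags STRF lag count at `frame_rate` (31 lags at 100 Hz = 0-300 ms)
#' @param frame_rate spectrogram frame rate (Hz)
#' @return object of class `"hg_cohort"`: `sites` (data.frame of ground
#'   truth and geometry), `strfs` (list of lag x band matrices), `stimulus`,
#'   `phoneme_table`, `speakers`, `seed`
#' @export
synth_cohort <- function(n_sites = 50, duration_s = 60, n_speakers = 4,
                         seed = 1, axis_deg = 40, axis_len_mm = 20,
                         layout = c("line", "patch"),
                         gradients = TRUE, invariance = "gradient",
                         speech_gain_range = c(1, 1),
                         bf_range = c(300, 4000),
                         latency_range_ms = c(40, 190),
                         btm_range = c(2, 16),
                         n_lags = 31, frame_rate = 100) {
  stim <- generate_stimulus(duration_s, n_speakers, seed,
                            frame_rate = frame_rate)
  centers <- stim$stimulus$band_centers
  layout <- match.arg(layout)
  sites <- with_seed(seed + 1000L, {
    a <- axis_deg * pi / 180
    if (layout == "line") {
      t_pos <- sort(stats::runif(n_sites, 0, axis_len_mm))
      ml <- t_pos * cos(a) + stats::rnorm(n_sites, 0, 1)
      pa <- t_pos * sin(a) + stats::rnorm(n_sites, 0, 1)
    } else {
      ml <- stats::runif(n_sites, 0, axis_len_mm)
      pa <- stats::runif(n_sites, 0, axis_len_mm)
      t_pos <- ml * cos(a) + pa * sin(a)
    }
    u <- (t_pos - min(t_pos)) / diff(range(t_pos))
    ml <- ml - min(ml)
    if (gradients) {
      bf <- 2^(log2(bf_range[2]) - u * diff(log2(bf_range)) +
                 stats::rnorm(n_sites, 0, 0.25))
      lat <- latency_range_ms[1] + u * diff(latency_range_ms) +
        stats::rnorm(n_sites, 0, 8)
      btm <- 2^(log2(btm_range[2]) - u * diff(log2(btm_range)) +
                  stats::rnorm(n_sites, 0, 0.2))
      alpha_g <- pmin(1, pmax(0, u + stats::rnorm(n_sites, 0, 0.05)))
      gain <- speech_gain_range[1] + u * diff(speech_gain_range) +
        stats::rnorm(n_sites, 0, 0.02 * diff(speech_gain_range))
    } else {
      bf <- 2^stats::runif(n_sites, log2(bf_range[1]), log2(bf_range[2]))
      lat <- stats::runif(n_sites, latency_range_ms[1], latency_range_ms[2])
      btm <- 2^stats::runif(n_sites, log2(btm_range[1]), log2(btm_range[2]))
      alpha_g <- stats::runif(n_sites)
      gain <- stats::runif(n_sites, speech_gain_range[1], speech_gain_range[2])
    }
    alpha <- if (identical(invariance, "gradient")) alpha_g
      else if (identical(invariance, "speaker_invariant")) rep(1, n_sites)
      else if (identical(invariance, "speaker_dependent")) rep(0, n_sites)
      else if (is.numeric(invariance)) rep(invariance, n_sites)
      else stop("unknown invariance mode")
    bf <- pmin(pmax(bf, 200), 5200)
    lat <- pmin(pmax(lat, 25), (n_lags - 2) * 1000 / frame_rate)
    btm <- pmin(pmax(btm, 1.2), 28)
    gain <- pmax(gain, 0)
    data.frame(site_id = sprintf("site%03d", seq_len(n_sites)),
               hemisphere = rep(c("L", "R"), length.out = n_sites),
               ml_mm = ml, pa_mm = pa, axis_pos_mm = t_pos,
               true_bf = bf, true_latency = lat, true_btm = btm,
               alpha = alpha, speech_gain = pmax(gain, 0))
  })
  strfs <- lapply(seq_len(n_sites), function(i)
    make_gabor_strf(sites$true_bf[i], sites$true_latency[i],
                    sites$true_btm[i], centers, n_lags, frame_rate))
  structure(list(sites = sites, strfs = strfs, stimulus = stim$stimulus,
                 phoneme_table = stim$phoneme_table, speakers = stim$speakers,
                 n_lags = n_lags, frame_rate = frame_rate, seed = seed),
            class = "hg_cohort")
}

#' @export
print.hg_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d sites, %.0f s stimulus, %d speakers, seed %d\n",
              nrow(x$sites), nrow(x$stimulus$values) / x$frame_rate,
              nrow(x$speakers), x$seed))
  invisible(x)
}

# lagged design matrix: X[t, (l-1)*nb + b] = S[t-l+1, b]
lag_matrix <- function(S, n_lags) {
  n_t <- nrow(S); nb <- ncol(S)
  X <- matrix(0, n_t, n_lags * nb)
  for (l in seq_len(n_lags))
    X[l:n_t, ((l - 1) * nb + 1):(l * nb)] <- S[1:(n_t - l + 1), , drop = FALSE]
  X
}

strf_weight_vec <- function(W) as.vector(t(W))

apply_nonlinearity <- function(x, nonlinearity) {
  switch(nonlinearity,
         none = x,
         rectify = pmax(x, 0),
         saturating = {
           s <- 2 * stats::sd(x)
           if (s == 0) x else s * tanh(x / s)
         },
         stop("nonlinearity must be one of none, rectify, saturating"))
}

phone_active_mask <- function(table, n_frames, frame_rate) {
  m <- logical(n_frames)
  f0 <- pmax(floor(table$onset_s * frame_rate) + 1, 1)
  f1 <- pmin(floor(table$offset_s * frame_rate), n_frames)
  for (i in seq_along(f0)) if (f1[i] >= f0[i]) m[f0[i]:f1[i]] <- TRUE
  m
}

#' Simulate cohort responses to the story stimulus
#'
#' Each site's response is the convolution of the stimulus spectrogram with
#' its ground-truth STRF, passed through an optional static nonlinearity,
#' scaled by the site's speech gain on phone-active frames, plus a
#' phoneme-locked evoked code whose speaker dependence follows the site's
#' invariance mixing weight alpha (alpha = 1: purely phonetic, speaker
#' invariant; alpha = 0: purely speaker identity), plus white Gaussian
#' noise at the requested SNR.
#'
#' @param cohort an [synth_cohort] object
#' @param snr_db signal-to-noise ratio in dB; `Inf` for noiseless
#' @param nonlinearity `"none"`, `"rectify"` or `"saturating"`
#' @param evoked_scale amplitude of the phoneme-locked code relative to the
#'   per-site STRF-driven response SD; 0 (default) disables it so the
#'   response is a pure (possibly nonlinear) STRF world
#' @param seed seed for the noise and evoked weights; defaults to
#'   `cohort$seed + 1`
#' @return an [hg_response] (sites x frames)
#' @export
generate_responses <- function(cohort, snr_db = Inf, nonlinearity = "none",
                               evoked_scale = 0, seed = cohort$seed + 1L) {
  S <- cohort$stimulus$values
  fr <- cohort$frame_rate
  n_t <- nrow(S); n_sites <- nrow(cohort$sites)
  X <- lag_matrix(S, cohort$n_lags)
  Wmat <- vapply(cohort$strfs, strf_weight_vec, numeric(ncol(X)))
  clean <- X %*% Wmat                       # T x sites
  with_seed(seed, {
    resp <- apply(clean, 2, apply_nonlinearity, nonlinearity = nonlinearity)
    resp <- matrix(resp, nrow = n_t)
    mask <- phone_active_mask(cohort$phoneme_table, n_t, fr)
    for (i in seq_len(n_sites))
      resp[mask, i] <- resp[mask, i] * cohort$sites$speech_gain[i]
    if (evoked_scale > 0) {
      tab <- cohort$phoneme_table
      spks <- cohort$speakers$speaker
      attrs <- c("manner", "place", "voicing", "height", "backness")
      bump_len <- round(0.10 * fr)
      bump <- 0.5 - 0.5 * cos(2 * pi * seq(0.5, bump_len - 0.5) / bump_len)
      # invariant code: a random onset-locked temporal profile per
      # (site, attribute level), shared by all speakers; speaker-dependent
      # code: a different attribute-level-to-profile mapping per speaker
      # (decodable within a speaker, does not transfer across), plus a
      # speaker-identity offset
      w_inv <- lapply(attrs, function(a) {
        lv <- sort(unique(tab[[a]]))
        array(stats::rnorm(n_sites * length(lv) * bump_len),
              c(n_sites, length(lv), bump_len), dimnames = list(NULL, lv, NULL))
      })
      w_dep <- lapply(attrs, function(a) {
        lv <- sort(unique(tab[[a]]))
        array(stats::rnorm(n_sites * length(lv) * bump_len * length(spks)),
              c(n_sites, length(lv), bump_len, length(spks)),
              dimnames = list(NULL, lv, NULL, spks))
      })
      w_sp <- matrix(stats::rnorm(n_sites * length(spks)), n_sites,
                     dimnames = list(NULL, spks))
      sds <- apply(resp, 2, stats::sd)
      f_on <- floor(tab$onset_s * fr) + 1 + round(0.05 * fr)
      al <- cohort$sites$alpha
      for (j in seq_len(nrow(tab))) {
        idx <- f_on[j]:(f_on[j] + bump_len - 1)
        keep <- idx >= 1 & idx <= n_t
        if (!any(keep)) next
        code_inv <- 0; code_dep <- 0        # sites x bump frames
        for (ai in seq_along(attrs)) {
          lev <- tab[[attrs[ai]]][j]
          code_inv <- code_inv + w_inv[[ai]][, lev, ]
          code_dep <- code_dep + w_dep[[ai]][, lev, , tab$speaker[j]]
        }
        C <- al * code_inv / sqrt(5) +
          (1 - al) * (code_dep / sqrt(5) + w_sp[, tab$speaker[j]]) / sqrt(2)
        C <- C * rep(bump, each = n_sites) * (evoked_scale * sds)
        resp[idx[keep], ] <- resp[idx[keep], ] + t(C[, keep, drop = FALSE])
      }
    }
    if (is.finite(snr_db)) {
      pw <- colMeans(resp^2)
      if (any(pw == 0))
        stop("zero-power signal: SNR undefined")
      nsd <- sqrt(pw) * 10^(-snr_db / 20)
      resp <- resp + matrix(stats::rnorm(n_t * n_sites), n_t) %*% diag(nsd, n_sites)
    }
    hg_response(t(resp), fr)
  })
}

#' Generate the speech/nonspeech trial sound set
#'
#' Builds the labelled trial set used for the speech-sensitivity analysis:
#' 16 speech and 53 nonspeech trials (tones, noise bursts, amplitude-
#' modulated noise, spectral sweeps, click trains), assembled with 1 s
#' inter-trial silences, plus a long silence segment used for response
#' normalization. Trials average `trial_s` seconds; the field recording
#' this emulates used 13.5 s trials and a 2 minute silence.
#'
#' @param seed integer seed
#' @param n_speech,n_nonspeech trial counts (defaults 16 and 53)
#' @param trial_s mean trial duration in seconds (default 13.5)
#' @param gap_s inter-trial silence in seconds (default 1)
#' @param silence_s duration of the normalization silence segment (default 120)
#' @param frame_rate,n_bands spectrogram geometry
#' @return list: `trials` (list of [spectrogram]s), `labels`
#'   (`"speech"`/`"nonspeech"`), `manifest` (trial_id, label, start_s,
#'   end_s), `silence_s`, `frame_rate`, `band_centers`
#' @export
generate_sound_set <- function(seed = 1, n_speech = 16, n_nonspeech = 53,
                               trial_s = 13.5, gap_s = 1, silence_s = 120,
                               frame_rate = 100, n_bands = 16) {
  centers <- default_band_centers(n_bands)
  nf <- round(trial_s * frame_rate)
  with_seed(seed, {
    trials <- list(); labels <- character(0)
    for (i in seq_len(n_speech)) {
      st <- generate_stimulus(trial_s, n_speakers = sample(4, 1),
                              seed = sample.int(1e6, 1), frame_rate = frame_rate,
                              n_bands = n_bands)
      trials[[length(trials) + 1]] <- st$stimulus
      labels <- c(labels, "speech")
    }
    kinds <- rep(c("tone", "noise", "am_noise", "sweep", "clicks"),
                 length.out = n_nonspeech)
    tgrid <- seq(0.5, nf - 0.5) / frame_rate
    for (k in kinds) {
      V <- matrix(0, nf, n_bands)
      V <- switch(k,
        tone = {
          b <- sample(n_bands, 1)
          V[, b] <- 1; V
        },
        noise = matrix(stats::runif(nf * n_bands, 0.3, 0.7), nf),
        am_noise = {
          rate <- sample(c(1, 2, 4, 8, 16), 1)
          env <- 0.5 + 0.5 * sin(2 * pi * rate * tgrid)
          outer(env, stats::runif(n_bands, 0.4, 0.8))
        },
        sweep = {
          b <- 1 + (n_bands - 1) * (tgrid %% 2) / 2
          for (t in seq_len(nf))
            V[t, ] <- exp(-(seq_len(n_bands) - b[t])^2 / 2)
          V
        },
        clicks = {
          on <- which((seq_len(nf) %% round(frame_rate / 2)) < 3)
          V[on, ] <- 1; V
        })
      # roughly match speech loudness
      V <- V * 0.6 / max(mean(V), 1e-9)
      trials[[length(trials) + 1]] <- spectrogram(V, frame_rate, centers)
      labels <- c(labels, "nonspeech")
    }
    ord <- sample(length(trials))
    trials <- trials[ord]; labels <- labels[ord]
    durs <- vapply(trials, function(s) nrow(s$values) / frame_rate, 0)
    starts <- cumsum(c(0, head(durs + gap_s, -1)))
    manifest <- data.frame(trial_id = sprintf("trial%02d", seq_along(trials)),
                           label = labels, start_s = starts,
                           end_s = starts + durs)
    list(trials = trials, labels = labels, manifest = manifest,
         silence_s = silence_s, frame_rate = frame_rate,
         band_centers = centers)
  })
}

#' Simulate cohort responses to the speech/nonspeech trial set
#'
#' Each trial response is the STRF prediction of that trial's spectrogram,
#' passed through the nonlinearity, with the site's speech gain applied
#' (post-linear) on speech trials only, plus Gaussian noise at `snr_db`.
#' A noise-only response to the silence segment is returned for
#' silence-based normalization.
#'
#' @param cohort an [synth_cohort]
#' @param sound_set output of [generate_sound_set]
#' @param snr_db signal-to-noise ratio in dB
#' @param nonlinearity static nonlinearity before the speech gain
#' @param seed noise seed; defaults to `cohort$seed + 2`
#' @return list: `trial_responses` (list of sites x frames matrices),
#'   `labels`, `silence_response` (sites x frames)
#' @export
generate_trial_responses <- function(cohort, sound_set, snr_db = 10,
                                     nonlinearity = "none",
                                     seed = cohort$seed + 2L) {
  n_sites <- nrow(cohort$sites)
  Wmat <- vapply(cohort$strfs, strf_weight_vec,
                 numeric(cohort$n_lags * length(cohort$stimulus$band_centers)))
  clean <- lapply(sound_set$trials, function(tr) {
    X <- lag_matrix(tr$values, cohort$n_lags)
    P <- X %*% Wmat
    P <- apply(P, 2, apply_nonlinearity, nonlinearity = nonlinearity)
    matrix(P, nrow = nrow(X))
  })
  gains <- cohort$sites$speech_gain
  for (i in seq_along(clean))
    if (sound_set$labels[i] == "speech")
      clean[[i]] <- clean[[i]] %*% diag(gains, n_sites)
  rms <- sqrt(colMeans(do.call(rbind, clean)^2))
  nsd <- if (is.finite(snr_db)) rms * 10^(-snr_db / 20) else rep(0, n_sites)
  nsd <- pmax(nsd, 1e-8)          # silence normalization needs nonzero sd
  with_seed(seed, {
    resp <- lapply(clean, function(P)
      t(P + matrix(stats::rnorm(length(P)), nrow(P)) %*% diag(nsd, n_sites)))
    sil_nf <- round(sound_set$silence_s * sound_set$frame_rate)
    sil <- t(matrix(stats::rnorm(sil_nf * n_sites), sil_nf) %*% diag(nsd, n_sites))
    list(trial_responses = resp, labels = sound_set$labels,
         silence_response = sil)
  })
}
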