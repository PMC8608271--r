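# STRF estimation: recovery against generator ground truth, the inclusion
# gate, excitatory-region tuning extraction, and modulation decomposition.

test_that("noiseless responses recover the planted filters", {
  co <- fix_cohort()
  fits <- fix_fits_clean()
  wc <- mapply(function(f, W) cor(as.vector(f$weights), as.vector(W)),
               fits, co$strfs)
  expect_gte(median(wc), 0.95)
  expect_gte(median(vapply(fits, `[[`, 0, "prediction_r")), 0.99)
})

test_that("time-shuffled responses predict at chance", {
  co <- fix_cohort()
  set.seed(8)
  shuf <- fix_responses_clean()$values[1:3, ]
  shuf <- shuf[, sample(ncol(shuf))]
  fits <- fit_strf(co$stimulus, hg_response(shuf, co$frame_rate))
  expect_true(all(abs(vapply(fits, `[[`, 0, "prediction_r")) < 0.1))
})

test_that("fit_strf validates its inputs", {
  co <- fix_cohort()
  short <- hg_response(fix_responses_clean()$values[, 1:100], co$frame_rate)
  expect_error(fit_strf(co$stimulus, short), "length")
  const <- hg_response(matrix(1, 1, nrow(co$stimulus$values)), co$frame_rate)
  expect_error(fit_strf(co$stimulus, const), "constant")
})

test_that("strf methods expose coefficients, predictions and residuals", {
  co <- fix_cohort()
  f <- fix_fits_clean()[[1]]
  expect_identical(coef(f), f$weights)
  expect_length(f$fold_rs, 20)
  pred <- predict(f, co$stimulus)
  resp <- fix_responses_clean()$values[1, ]
  expect_gt(cor(pred, resp), 0.999)
  expect_equal(predict(f) + residuals(f), f$response, tolerance = 1e-9)
  expect_output(print(f), "STRF")
  expect_output(print(summary(f)), "Best frequency")
})

test_that("prediction accuracy is non-decreasing in stimulus duration", {
  rs <- vapply(c(30, 60, 120), function(dur) {
    co <- synth_cohort(n_sites = 3, duration_s = dur, seed = 13)
    fits <- fit_strf(co$stimulus, generate_responses(co, snr_db = Inf))
    mean(vapply(fits, `[[`, 0, "prediction_r"))
  }, 0)
  expect_true(all(diff(rs) >= -1e-6))
})

test_that("STRFs fit on disjoint halves agree at 0 dB (test-retest)", {
  co <- fix_cohort()
  r <- fix_responses_0db()
  n_t <- nrow(co$stimulus$values)
  h1 <- seq_len(n_t %/% 2); h2 <- (n_t %/% 2 + 1):n_t
  f1 <- fit_strf(spectrogram(co$stimulus$values[h1, ], 100,
                             co$stimulus$band_centers),
                 hg_response(r$values[, h1], 100))
  f2 <- fit_strf(spectrogram(co$stimulus$values[h2, ], 100,
                             co$stimulus$band_centers),
                 hg_response(r$values[, h2], 100))
  rr <- mapply(function(a, b) cor(as.vector(a$weights), as.vector(b$weights)),
               f1, f2)
  expect_gt(median(rr), 0.8)
})

test_that("inclusion gate requires 20 folds and flags obvious cases", {
  good <- structure(list(list(fold_rs = rep(0.9, 20), prediction_r = 0.9),
                         list(fold_rs = rnorm(20, 0, 0.01),
                              prediction_r = 0)), class = "strf_list")
  tab <- include_electrodes(good)
  expect_true(tab$included[1])
  expect_false(tab$included[2])
  bad <- list(list(fold_rs = 0.5, prediction_r = 0.5))
  expect_error(include_electrodes(bad), "folds")
})

test_that("excitatory-region centroid recovers a planted blob", {
  co <- fix_cohort()
  bc <- co$stimulus$band_centers
  W <- blob_strf(lag_idx = 9, band_idx = 8)    # 80 ms, ~band 8
  bl <- extract_bf_latency(W, band_centers = bc)
  expect_lt(abs(log2(bl$bf / bc[8])), mean(diff(log2(bc))) / 2)
  expect_lt(abs(bl$latency - 80), 5)
  # delayed inhibitory sideband must not move the excitatory centroid
  W2 <- W - 0.7 * blob_strf(lag_idx = 16, band_idx = 8)
  bl2 <- extract_bf_latency(W2, band_centers = bc)
  expect_equal(bl2$bf, bl$bf, tolerance = 1e-3)
  expect_equal(bl2$latency, bl$latency, tolerance = 1e-3)
  # robust to the region-growing threshold over 30-70%
  for (thr in c(0.3, 0.5, 0.7)) {
    blt <- extract_bf_latency(W2, band_centers = bc, threshold = thr)
    expect_lt(abs(blt$latency - 80), 5)
    expect_lt(abs(log2(blt$bf / bc[8])), mean(diff(log2(bc))))
  }
  expect_error(extract_bf_latency(-W, band_centers = bc), "positive")
})

test_that("recovered latencies span the planted 30-200 ms range", {
  co <- synth_cohort(n_sites = 16, duration_s = 45, seed = 17,
                     latency_range_ms = c(30, 200))
  fits <- fit_strf(co$stimulus, generate_responses(co, snr_db = Inf))
  lats <- vapply(fits, function(f) extract_bf_latency(f)$latency, 0)
  expect_lt(min(lats), 60)
  expect_gt(max(lats), 160)
})

test_that("modulation filterbank localizes planted gratings (Fourier oracle)", {
  bc <- fix_cohort()$stimulus$band_centers
  for (r in c(2, 4, 8, 16)) {
    W <- grating_strf(r, band_centers = bc)
    d <- modulation_decompose(W, band_centers = bc)
    m <- rate_marginal(d)
    # Fourier oracle: peak of the temporal power spectrum
    P <- rowMeans(Mod(stats::mvfft(rbind(W, matrix(0, 192, 16))))^2)
    fr_ax <- (seq_len(256) - 1) / 256 * 100
    expect_lt(abs(fr_ax[which.max(P[2:128]) + 1] - r) / r, 0.3)
    expect_equal(d$rates[which.max(m)], r)
  }
  z <- modulation_decompose(matrix(0, 31, 16),
                            band_centers = bc)
  expect_true(all(z$power == 0))
})

test_that("equal-amplitude gratings share the rate marginal within 10%", {
  bc <- fix_cohort()$stimulus$band_centers
  W <- grating_strf(2, n_lags = 512, band_centers = bc) +
    grating_strf(8, n_lags = 512, band_centers = bc)
  m <- rate_marginal(modulation_decompose(W, band_centers = bc))
  expect_lt(abs(m[2] / m[4] - 1), 0.1)
})

test_that("rate centroid arithmetic and symmetry hold", {
  d <- structure(list(power = array(0, c(1, 6, 1, 1)),
                      rates = c(1, 2, 4, 8, 16, 32), scales = 1),
                 class = "mod_decomp")
  d$power[1, 3, 1, 1] <- 5
  expect_equal(compute_btm(d), 4)
  d$power[1, , 1, 1] <- c(0, 1, 0, 1, 0, 0)
  expect_equal(compute_btm(d), 5)
  d$power[1, , 1, 1] <- 0
  expect_error(compute_btm(d), "zero")
  bc <- fix_cohort()$stimulus$band_centers
  W <- grating_strf(4, band_centers = bc)
  b1 <- compute_btm(modulation_decompose(W, band_centers = bc))
  b2 <- compute_btm(modulation_decompose(W[nrow(W):1, ], band_centers = bc))
  expect_equal(b1, b2, tolerance = 1e-9)
  expect_lt(abs(b1 - 4) / 4, 0.25)
})
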