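# Spectrotemporal receptive field estimation by regularized (normalized)
# reverse correlation, with cross-validated hyperparameters, an
# FDR-corrected inclusion gate, and tuning extraction (best frequency,
# latency, temporal modulation).

#' Fit spectrotemporal receptive fields by regularized reverse correlation
#'
#' Estimates, for each electrode, the linear filter over stimulus
#' spectrogram lags and frequency bands that best predicts the high-gamma
#' response. The estimator is ridge regression on the lagged stimulus
#' (mathematically the normalized reverse correlation: the ridge solution
#' divides the stimulus-response cross-correlation by the regularized
#' stimulus autocorrelation). An optional sparseness stage shrinks filter
#' entries below a fraction of the peak magnitude to zero. Both the ridge
#' parameter and the sparseness threshold are chosen by contiguous-block
#' cross-validation; the per-fold held-out Pearson correlations are kept on
#' the fitted object for the downstream inclusion test.
#'
#' @param stimulus a [spectrogram]
#' @param response an [hg_response] with the same frame rate and length, or
#'   a numeric vector/matrix (electrodes x time)
#' @param n_lags number of stimulus lags (default 31: 0-300 ms at 100 Hz)
#' @param folds number of contiguous cross-validation blocks (default 20)
#' @param lambdas ridge grid; default log-spaced over six decades scaled to
#'   the stimulus autocorrelation
#' @param sparseness grid of shrinkage thresholds as fractions of the peak
#'   absolute weight (default 0 and 0.1)
#' @return a single object of class `"strf"` when one electrode is given,
#'   otherwise a list of them (class `"strf_list"`). Each `"strf"` carries
#'   `weights` (lag x band), `lag_ms`, `band_centers`, `ridge_param`,
#'   `sparseness_param`, `prediction_r` (mean held-out r), `fold_rs`.
#' @seealso [include_electrodes()], [extract_bf_latency()],
#'   [modulation_decompose()]
#' @export
fit_strf <- function(stimulus, response, n_lags = 31, folds = 20,
                     lambdas = NULL, sparseness = c(0, 0.1)) {
  S <- stimulus$values
  fr <- stimulus$frame_rate
  if (inherits(response, "hg_response")) {
    if (abs(response$frame_rate - fr) > 1e-9)
      stop("stimulus and response frame rates differ")
    Y <- t(response$values)
  } else if (is.matrix(response)) Y <- t(response)
  else Y <- matrix(response, ncol = 1)
  if (nrow(Y) != nrow(S))
    stop("stimulus and response lengths differ")
  if (any(apply(Y, 2, stats::sd) == 0))
    stop("constant response: STRF undefined")
  n_t <- nrow(S); ns <- ncol(Y); p <- n_lags * ncol(S)
  X <- lag_matrix(S, n_lags)
  xm <- colMeans(X); ym <- colMeans(Y)
  X <- sweep(X, 2, xm); Y <- sweep(Y, 2, ym)
  # grid centered on the mean eigenvalue of X'X (= trace/p), spanning six
  # decades, so cross-validation can reach both the near-unregularized and
  # the heavily smoothed regimes
  if (is.null(lambdas))
    lambdas <- 10^seq(-3, 3, length.out = 7) * mean(colSums(X^2))
  fold_id <- contiguous_folds(n_t, folds)
  XtX <- crossprod(X); XtY <- crossprod(X, Y)
  nl <- length(lambdas); nsp <- length(sparseness)
  r_cv <- array(NA_real_, c(folds, nl, nsp, ns))
  for (f in seq_len(folds)) {
    idx <- which(fold_id == f)
    Xf <- X[idx, , drop = FALSE]; Yf <- Y[idx, , drop = FALSE]
    eg <- eigen(XtX - crossprod(Xf), symmetric = TRUE)
    Z <- crossprod(eg$vectors, XtY - crossprod(Xf, Yf))
    for (li in seq_len(nl)) {
      W <- eg$vectors %*% (Z / (pmax(eg$values, 0) + lambdas[li]))
      for (si in seq_len(nsp)) {
        Ws <- W
        if (sparseness[si] > 0) {
          thr <- sparseness[si] * apply(abs(W), 2, max)
          Ws[abs(W) < rep(thr, each = p)] <- 0
        }
        P <- Xf %*% Ws
        r_cv[f, li, si, ] <- suppressWarnings(
          sapply(seq_len(ns), function(s) stats::cor(P[, s], Yf[, s])))
      }
    }
  }
  r_cv[is.na(r_cv)] <- 0
  mean_r <- apply(r_cv, c(2, 3, 4), mean)
  eg_all <- eigen(XtX, symmetric = TRUE)
  Z_all <- crossprod(eg_all$vectors, XtY)
  models <- vector("list", ns)
  lag_ms <- (seq_len(n_lags) - 1) * 1000 / fr
  for (s in seq_len(ns)) {
    best <- which(mean_r[, , s] == max(mean_r[, , s]), arr.ind = TRUE)[1, ]
    li <- best[1]; si <- best[2]
    w <- eg_all$vectors %*% (Z_all[, s] / (pmax(eg_all$values, 0) + lambdas[li]))
    if (sparseness[si] > 0)
      w[abs(w) < sparseness[si] * max(abs(w))] <- 0
    W <- matrix(w, n_lags, ncol(S), byrow = TRUE)
    fitted <- as.vector(X %*% w) + ym[s]
    models[[s]] <- structure(list(
      weights = W, lag_ms = lag_ms, band_centers = stimulus$band_centers,
      frame_rate = fr, ridge_param = lambdas[li],
      sparseness_param = sparseness[si],
      prediction_r = mean(r_cv[, li, si, s]), fold_rs = r_cv[, li, si, s],
      included = NA, x_mean = xm, y_mean = ym[s],
      fitted = fitted, response = Y[, s] + ym[s],
      call = match.call()), class = "strf")
  }
  if (ns == 1) models[[1]] else structure(models, class = "strf_list")
}

#' @export
print.strf <- function(x, ...) {
  cat(sprintf("STRF: %d lags (0-%.0f ms) x %d bands, held-out r = %.3f\n",
              length(x$lag_ms), max(x$lag_ms), length(x$band_centers),
              x$prediction_r))
  cat(sprintf("  ridge = %.3g, sparseness = %.2g, included = %s\n",
              x$ridge_param, x$sparseness_param, x$included))
  invisible(x)
}

#' @export
print.strf_list <- function(x, ...) {
  cat(sprintf("%d fitted STRFs; held-out r: median %.3f, range %.3f-%.3f\n",
              length(x), stats::median(sapply(x, `[[`, "prediction_r")),
              min(sapply(x, `[[`, "prediction_r")),
              max(sapply(x, `[[`, "prediction_r"))))
  invisible(x)
}

#' @export
summary.strf <- function(object, ...) {
  tune <- tryCatch(extract_bf_latency(object), error = function(e) NULL)
  out <- list(prediction_r = object$prediction_r,
              fold_rs = object$fold_rs,
              ridge_param = object$ridge_param,
              sparseness_param = object$sparseness_param,
              bf = if (is.null(tune)) NA else tune$bf,
              latency = if (is.null(tune)) NA else tune$latency)
  class(out) <- "summary.strf"
  out
}

#' @export
print.summary.strf <- function(x, ...) {
  cat(sprintf("Held-out prediction r: %.3f (%d folds, sd %.3f)\n",
              x$prediction_r, length(x$fold_rs), stats::sd(x$fold_rs)))
  cat(sprintf("Best frequency: %.0f Hz   latency: %.0f ms\n", x$bf, x$latency))
  cat(sprintf("ridge = %.3g, sparseness = %.2g\n",
              x$ridge_param, x$sparseness_param))
  invisible(x)
}

#' @export
coef.strf <- function(object, ...) object$weights

#' Predict a response from a fitted STRF
#' @param object a `"strf"`
#' @param newdata a [spectrogram]; if omitted, fitted values are returned
#' @param ... unused
#' @return numeric vector of predicted response
#' @export
predict.strf <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted)
  X <- lag_matrix(newdata$values, length(object$lag_ms))
  as.vector(sweep(X, 2, object$x_mean) %*% strf_weight_vec(object$weights)) +
    object$y_mean
}

#' @export
residuals.strf <- function(object, ...) object$response - object$fitted

#' @export
plot.strf <- function(x, ...) {
  cols <- grDevices::hcl.colors(64, "RdBu", rev = TRUE)
  m <- max(abs(x$weights))
  graphics::image(x$lag_ms, seq_along(x$band_centers), x$weights,
                  zlim = c(-m, m), col = cols, xlab = "lag (ms)",
                  ylab = "frequency band", yaxt = "n", ...)
  at <- pretty(seq_along(x$band_centers))
  at <- at[at >= 1 & at <= length(x$band_centers)]
  graphics::axis(2, at = at, labels = sprintf("%.0f", x$band_centers[at]))
  invisible(x)
}

#' Gate electrodes by STRF prediction significance
#'
#' For each electrode, tests whether its per-fold held-out prediction
#' correlations exceed zero (one-sample t-test against 0), then corrects
#' across electrodes with the Benjamini-Hochberg false discovery rate at
#' `alpha` (default 0.01, with the 20 cross-validation folds as samples).
#'
#' @param models a `"strf_list"` (or list of `"strf"` objects)
#' @param alpha FDR level (default 0.01)
#' @return data.frame with `prediction_r`, `p`, `q`, `included` per electrode
#' @export
include_electrodes <- function(models, alpha = 0.01) {
  if (inherits(models, "strf")) models <- list(models)
  ps <- vapply(models, function(m) {
    if (length(m$fold_rs) < 2) stop("need at least 2 folds for inclusion test")
    if (stats::sd(m$fold_rs) == 0)            # degenerate: all folds equal
      return(if (m$fold_rs[1] > 0) 0 else 1)
    stats::t.test(m$fold_rs, mu = 0, alternative = "greater")$p.value
  }, 0)
  q <- stats::p.adjust(ps, method = "BH")
  data.frame(prediction_r = vapply(models, `[[`, 0, "prediction_r"),
             p = ps, q = q, included = q < alpha)
}

#' Best frequency and response latency from an STRF
#'
#' Locates the maximal positive weight, grows the contiguous positive
#' region around it above a threshold fraction of that maximum (default
#' 50%), and returns the power-weighted centroid of the region: along the
#' log-frequency axis (best frequency, Hz) and along the lag axis
#' (response latency, ms). This is the center of the excitatory region of
#' the receptive field; inhibitory sidebands are ignored by construction.
#'
#' @param model a `"strf"` or a lag x band weight matrix
#' @param band_centers,frame_rate needed only when `model` is a bare matrix
#' @param threshold region-growing threshold as a fraction of the peak
#'   positive weight (default 0.5)
#' @return list with `bf` (Hz) and `latency` (ms)
#' @export
extract_bf_latency <- function(model, band_centers = NULL, frame_rate = 100,
                               threshold = 0.5) {
  if (inherits(model, "strf")) {
    W <- model$weights; band_centers <- model$band_centers
    lag_ms <- model$lag_ms
  } else {
    W <- model
    if (is.null(band_centers)) stop("band_centers required for a bare matrix")
    lag_ms <- (seq_len(nrow(W)) - 1) * 1000 / frame_rate
  }
  if (max(W) <= 0) stop("no positive weights: tuning undefined")
  pk <- which(W == max(W), arr.ind = TRUE)[1, ]
  thr <- threshold * max(W)
  # grow 4-connected region of weights >= thr around the peak
  inreg <- matrix(FALSE, nrow(W), ncol(W))
  stack <- list(pk)
  while (length(stack)) {
    c0 <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
    i <- c0[1]; j <- c0[2]
    if (i < 1 || j < 1 || i > nrow(W) || j > ncol(W)) next
    if (inreg[i, j] || W[i, j] < thr) next
    inreg[i, j] <- TRUE
    stack <- c(stack, list(c(i - 1, j), c(i + 1, j), c(i, j - 1), c(i, j + 1)))
  }
  w <- W[inreg]
  idx <- which(inreg, arr.ind = TRUE)
  bf <- 2^(sum(w * log2(band_centers[idx[, 2]])) / sum(w))
  lat <- sum(w * lag_ms[idx[, 1]]) / sum(w)
  list(bf = bf, latency = lat)
}

#' Rate-scale modulation decomposition of an STRF
#'
#' Filters the STRF with a bank of directional complex modulation filters
#' over time x log-frequency. Each filter is a Gaussian (in log magnitude)
#' around a temporal modulation rate (Hz) and a spectral modulation scale
#' (cycles/octave), with upward and downward sweep quadrants collapsed by
#' magnitude. The result is the four-dimensional modulation power
#' (scale x rate x time x band).
#'
#' @param model a `"strf"` or a lag x band matrix
#' @param rates temporal modulation grid in Hz
#' @param scales spectral modulation grid in cycles/octave
#' @param frame_rate,band_centers needed only for a bare matrix
#' @param sigma_oct filter bandwidth in octaves of the log-modulation axis
#' @return list of class `"mod_decomp"`: `power` (scale x rate x lag x band
#'   array), `rates`, `scales`
#' @export
modulation_decompose <- function(model, rates = c(1, 2, 4, 8, 16, 32),
                                 scales = c(0.25, 0.5, 1, 2, 4, 8),
                                 frame_rate = 100, band_centers = NULL,
                                 sigma_oct = 0.5) {
  if (length(rates) < 1 || length(scales) < 1 || any(rates <= 0) ||
      any(scales <= 0))
    stop("rates and scales must be non-empty and positive")
  if (inherits(model, "strf")) {
    W <- model$weights; band_centers <- model$band_centers
    frame_rate <- model$frame_rate
  } else {
    W <- model
    if (is.null(band_centers)) band_centers <- default_band_centers(ncol(W))
  }
  if (all(W == 0)) {
    nt <- nrow(W); nb <- ncol(W)
    return(structure(list(power = array(0, c(length(scales), length(rates),
                                             nt, nb)),
                          rates = rates, scales = scales),
                     class = "mod_decomp"))
  }
  nt <- nrow(W); nb <- ncol(W)
  oct_per_band <- mean(diff(log2(band_centers)))
  ntp <- 2^ceiling(log2(max(4 * nt, 128)))
  nbp <- 2^ceiling(log2(max(4 * nb, 32)))
  Wp <- matrix(0, ntp, nbp); Wp[1:nt, 1:nb] <- W
  Fw <- stats::fft(Wp)
  ft <- (0:(ntp - 1)) / ntp * frame_rate
  ft[ft > frame_rate / 2] <- ft[ft > frame_rate / 2] - frame_rate
  fs_ax <- (0:(nbp - 1)) / nbp / oct_per_band
  fs_ax[fs_ax > 1 / (2 * oct_per_band)] <-
    fs_ax[fs_ax > 1 / (2 * oct_per_band)] - 1 / oct_per_band
  gband <- function(f, f0) ifelse(f == 0, 0,
    exp(-(log2(abs(f) / f0))^2 / (2 * sigma_oct^2)))
  power <- array(0, c(length(scales), length(rates), nt, nb))
  for (si in seq_along(scales)) for (ri in seq_along(rates)) {
    Ht <- gband(ft, rates[ri]); Hs <- gband(fs_ax, scales[si])
    H2 <- outer(Ht, Hs)
    qt <- outer(ft > 0, fs_ax > 0) | outer(ft < 0, fs_ax < 0)   # "up"
    qd <- outer(ft > 0, fs_ax < 0) | outer(ft < 0, fs_ax > 0)   # "down"
    up <- stats::fft(Fw * H2 * qt, inverse = TRUE) / (ntp * nbp)
    dn <- stats::fft(Fw * H2 * qd, inverse = TRUE) / (ntp * nbp)
    power[si, ri, , ] <- (Mod(up)^2 + Mod(dn)^2)[1:nt, 1:nb]
  }
  structure(list(power = power, rates = rates, scales = scales),
            class = "mod_decomp")
}

#' Best temporal modulation from a modulation decomposition
#'
#' Averages the four-dimensional modulation power over scale, time and
#' frequency to obtain the rate vector, then returns its power-weighted
#' centroid: `btm = sum(rate * p(rate)) / sum(p(rate))`.
#'
#' @param decomp output of [modulation_decompose]
#' @return best temporal modulation in Hz
#' @export
compute_btm <- function(decomp) {
  p <- rate_marginal(decomp)
  if (sum(p) <= 0) stop("zero total modulation power")
  sum(decomp$rates * p) / sum(p)
}

#' Rate marginal of a modulation decomposition
#' @param decomp output of [modulation_decompose]
#' @return numeric vector of mean power per rate
#' @export
rate_marginal <- function(decomp) apply(decomp$power, 2, mean)

#' Five-attribute tuning profile of a fitted site
#'
#' Convenience wrapper combining [extract_bf_latency] and [compute_btm];
#' speaker invariance and speech sensitivity are supplied by their own
#' analyses and can be attached by the caller.
#'
#' @param model a `"strf"`
#' @param si,ss optional speaker-invariance and speech-sensitivity values
#' @param ... passed to [extract_bf_latency]
#' @return data.frame with columns bf, latency, btm, si, ss
#' @export
tuning_profile <- function(model, si = NA_real_, ss = NA_real_, ...) {
  bl <- extract_bf_latency(model, ...)
  btm <- compute_btm(modulation_decompose(model))
  data.frame(bf = bl$bf, latency = bl$latency, btm = btm, si = si, ss = ss)
}
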