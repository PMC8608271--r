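#' Auditory spectrogram container
#'
#' Time-by-band non-negative matrix with its frame rate and band center
#' frequencies. All downstream STRF and decoding code consumes this class.
#'
#' @param values numeric matrix, time frames x frequency bands, non-negative
#' @param frame_rate frames per second (Hz)
#' @param band_centers strictly increasing band center frequencies (Hz)
#' @return object of class `"spectrogram"`
#' @export
spectrogram <- function(values, frame_rate, band_centers) {
  values <- as.matrix(values)
  if (any(!is.finite(values))) stop("spectrogram values must be finite")
  if (any(values < -1e-12)) stop("spectrogram values must be non-negative")
  values[values < 0] <- 0
  if (ncol(values) != length(band_centers))
    stop("ncol(values) must equal length(band_centers)")
  if (any(diff(band_centers) <= 0))
    stop("band_centers must be strictly increasing")
  structure(list(values = values, frame_rate = frame_rate,
                 band_centers = as.numeric(band_centers)),
            class = "spectrogram")
}

#' @export
print.spectrogram <- function(x, ...) {
  cat(sprintf("Auditory spectrogram: %d frames x %d bands @ %g Hz\n",
              nrow(x$values), ncol(x$values), x$frame_rate))
  cat(sprintf("  band centers: %.0f - %.0f Hz (log-spaced)\n",
              min(x$band_centers), max(x$band_centers)))
  invisible(x)
}

#' @export
dim.spectrogram <- function(x) dim(x$values)

#' High-gamma response container
#'
#' Electrodes-by-time matrix of z-scored high-gamma envelopes, with the
#' per-electrode baseline statistics the z-scoring used.
#'
#' @param values numeric matrix, electrodes x time frames (z-units)
#' @param frame_rate frames per second (Hz)
#' @param baseline_mean,baseline_sd per-electrode baseline statistics
#' @return object of class `"hg_response"`
#' @export
hg_response <- function(values, frame_rate,
                        baseline_mean = rep(0, nrow(values)),
                        baseline_sd = rep(1, nrow(values))) {
  values <- as.matrix(values)
  if (any(baseline_sd <= 0)) stop("baseline_sd must be positive")
  structure(list(values = values, frame_rate = frame_rate,
                 baseline_mean = baseline_mean, baseline_sd = baseline_sd),
            class = "hg_response")
}

#' @export
print.hg_response <- function(x, ...) {
  cat(sprintf("High-gamma response: %d electrodes x %d frames @ %g Hz\n",
              nrow(x$values), ncol(x$values), x$frame_rate))
  invisible(x)
}

#' @export
dim.hg_response <- function(x) dim(x$values)

# default 16-band log axis spanning 180 Hz - 5.5 kHz
default_band_centers <- function(n_bands = 16, fmin = 180, fmax = 5500) {
  edges <- geom_seq(fmin, fmax, n_bands + 1)
  sqrt(edges[-1] * edges[-(n_bands + 1)])
}
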