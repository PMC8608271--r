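# End-to-end orchestration: from stimulus + responses to the five
# per-site tuning attributes, and from feature maps to gradient statistics.

#' Characterize every site's tuning from stimulus and responses
#'
#' Runs the full single-site pipeline: STRF fitting with cross-validated
#' regularization, the FDR inclusion gate, best frequency and latency from
#' the excitatory region, best temporal modulation from the rate-scale
#' decomposition, the per-site speaker invariance index from
#' phoneme-aligned windows, and (when trial data are given) the
#' speech-sensitivity t value with its STRF-predicted counterpart.
#'
#' @param stimulus a [spectrogram]
#' @param responses an [hg_response] (sites x time)
#' @param phoneme_table phoneme event table for the invariance index
#'   (NULL to skip)
#' @param phoneme_responses responses used for the phoneme-aligned
#'   invariance analysis; defaults to `responses`
#' @param trial_responses,trial_labels,silence speech/nonspeech task data
#'   for the sensitivity statistic (NULL to skip)
#' @param sound_set the trial spectrograms, needed for predicted sensitivity
#' @param n_lags,folds passed to [fit_strf]
#' @param si_window ms window for the invariance classifiers
#' @return list: `features` (data.frame per site: prediction_r, included,
#'   bf, latency, btm, si, ss, predicted_ss), `models` (the fitted
#'   `"strf_list"`), `inclusion` (the gate table)
#' @export
characterize_sites <- function(stimulus, responses, phoneme_table = NULL,
                               phoneme_responses = responses,
                               trial_responses = NULL, trial_labels = NULL,
                               silence = NULL, sound_set = NULL,
                               n_lags = 31, folds = 20,
                               si_window = c(70, 180)) {
  models <- fit_strf(stimulus, responses, n_lags = n_lags, folds = folds)
  if (inherits(models, "strf")) models <- structure(list(models),
                                                    class = "strf_list")
  inc <- include_electrodes(models)
  n <- length(models)
  bf <- lat <- btm <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    tune <- tryCatch(extract_bf_latency(models[[i]]), error = function(e) NULL)
    if (!is.null(tune)) { bf[i] <- tune$bf; lat[i] <- tune$latency }
    btm[i] <- tryCatch(compute_btm(modulation_decompose(models[[i]])),
                       error = function(e) NA_real_)
  }
  si <- rep(NA_real_, n)
  if (!is.null(phoneme_table)) {
    si_tab <- speaker_invariance_index(phoneme_responses, phoneme_table,
                                       window = si_window)
    si[si_tab$site] <- si_tab$si
  }
  ss <- pss <- rep(NA_real_, n)
  if (!is.null(trial_responses)) {
    sens <- speech_sensitivity(trial_responses, trial_labels, silence)
    ss <- sens$t
    if (!is.null(sound_set)) pss <- predicted_sensitivity(models, sound_set)$t
  }
  feats <- data.frame(prediction_r = inc$prediction_r, included = inc$included,
                      bf = bf, latency = lat, btm = btm, si = si, ss = ss,
                      predicted_ss = pss)
  list(features = feats, models = models, inclusion = inc)
}

#' Gradient statistics of the five tuning maps
#'
#' Computes the along-axis distance from electrode coordinates, the
#' Pearson correlation of each tuning attribute with it (best frequency on
#' a log2 axis), optional hemisphere comparisons, the joint standardized
#' PCA of the five maps, and the CCA best direction of the first
#' principal-component projection.
#'
#' @param features data.frame with columns `bf`, `latency`, `btm`, `si`,
#'   `ss` (as from [characterize_sites])
#' @param coords n x 2 (ML, PA) electrode positions in mm
#' @param hemisphere optional `"L"`/`"R"` labels for rank-sum comparisons
#' @return list: `along_hg`, `correlations` (data.frame feature/r/p),
#'   `pca` (from [joint_pca]), `cca` (from [cca_best_direction]),
#'   `hemisphere` (data.frame of rank-sum results, or NULL)
#' @export
tuning_gradients <- function(features, coords, hemisphere = NULL) {
  fm <- c("bf", "latency", "btm", "si", "ss")
  keep <- stats::complete.cases(features[, fm])
  X <- as.matrix(features[keep, fm])
  coords <- as.matrix(coords)[keep, , drop = FALSE]
  along <- along_hg_distance(coords)
  cors <- do.call(rbind, lapply(fm, function(f) {
    ct <- feature_axis_correlation(X[, f], along, log_transform = (f == "bf"))
    data.frame(feature = f, r = ct$r, p = ct$p, n = ct$n)
  }))
  Xp <- X
  Xp[, "bf"] <- log2(Xp[, "bf"])
  pca <- joint_pca(Xp, feature_names = fm)
  cca <- cca_best_direction(pca$projections[, 1], coords)
  hemi <- NULL
  if (!is.null(hemisphere)) {
    h <- hemisphere[keep]
    hemi <- do.call(rbind, lapply(fm, function(f) {
      ct <- compare_hemispheres(X[, f], h)
      data.frame(feature = f, W = ct$W, p = ct$p,
                 n_left = ct$n_left, n_right = ct$n_right)
    }))
  }
  list(along_hg = along, correlations = cors, pca = pca, cca = cca,
       hemisphere = hemi)
}
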