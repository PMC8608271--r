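# Speech sensitivity: silence-normalized trial averages, the unpaired
# t statistic contrasting speech and nonspeech trials, and its comparison
# against the STRF-predicted statistic.

# trial_responses: list of sites x frames matrices; returns sites x trials
trial_means_normalized <- function(trial_responses, sil_mean, sil_sd) {
  sapply(trial_responses, function(M)
    rowMeans((M - sil_mean) / sil_sd))
}

#' Speech sensitivity of each site
#'
#' Normalizes every trial response by the mean and standard deviation of
#' the site's silent-interval activity, averages each normalized trial
#' over time, and computes the unpaired two-sample t statistic (speech
#' minus nonspeech) per site. Sites are flagged significantly
#' speech-responsive by a one-sided test with Benjamini-Hochberg FDR
#' across sites at `q`.
#'
#' @param trial_responses list of sites x frames response matrices, one
#'   per trial
#' @param labels `"speech"`/`"nonspeech"` per trial
#' @param silence sites x frames matrix of silent-interval responses, or a
#'   list with `mean` and `sd` vectors per site
#' @param q FDR level for the speech-responsive flag (default 0.01)
#' @param var_equal use the equal-variance (Student) t (default TRUE);
#'   FALSE gives Welch
#' @return data.frame per site: `t`, `df`, `p` (one-sided), `q`,
#'   `significant`, plus attributes `n_speech`, `n_nonspeech`
#' @export
speech_sensitivity <- function(trial_responses, labels, silence, q = 0.01,
                               var_equal = TRUE) {
  if (is.null(silence)) stop("missing silence segment")
  lab <- labels == "speech"
  if (sum(lab) < 2 || sum(!lab) < 2)
    stop("need at least 2 trials per label")
  if (is.list(silence) && !is.matrix(silence)) {
    sm <- silence$mean; ss <- silence$sd
  } else {
    sm <- rowMeans(silence); ss <- apply(silence, 1, stats::sd)
  }
  if (any(ss <= 0)) stop("silence has zero variance on some site")
  TM <- trial_means_normalized(trial_responses, sm, ss)   # sites x trials
  TM <- matrix(TM, ncol = length(trial_responses))
  res <- t(apply(TM, 1, function(v) {
    tt <- stats::t.test(v[lab], v[!lab], var.equal = var_equal,
                        alternative = "two.sided")
    c(t = unname(tt$statistic), df = unname(tt$parameter))
  }))
  p_one <- stats::pt(res[, "t"], res[, "df"], lower.tail = FALSE)
  qv <- stats::p.adjust(p_one, method = "BH")
  out <- data.frame(t = res[, "t"], df = res[, "df"], p = p_one, q = qv,
                    significant = qv < q)
  attr(out, "n_speech") <- sum(lab)
  attr(out, "n_nonspeech") <- sum(!lab)
  out
}

#' STRF-predicted speech sensitivity
#'
#' Simulates each trial's response as the STRF prediction of the trial
#' spectrogram and runs the identical speech-sensitivity statistic on the
#' predictions. The predicted silent-interval output of a linear filter is
#' constant, so when its variance is zero the normalization falls back to
#' the prediction's overall SD; the t statistic is invariant to this
#' common affine rescaling. Returned for paired comparison with the actual
#' sensitivity: an excess of actual over predicted t indicates speech
#' preference beyond linear spectrotemporal tuning.
#'
#' @param models a `"strf_list"` (or list of `"strf"`), one per site
#' @param sound_set output of [generate_sound_set] (or any list with
#'   `trials`, `labels`, `silence_s`, `frame_rate`)
#' @param q FDR level passed through
#' @return data.frame as in [speech_sensitivity] with column `t` being
#'   the predicted statistic; all-zero STRFs yield `NA` with a flag column
#' @export
predicted_sensitivity <- function(models, sound_set, q = 0.01) {
  if (inherits(models, "strf")) models <- list(models)
  zero <- vapply(models, function(m) all(m$weights == 0), TRUE)
  pred_trials <- lapply(sound_set$trials, function(tr)
    t(sapply(models, function(m) predict(m, tr))))
  n_sites <- length(models)
  sil_mean <- vapply(models, `[[`, 0, "y_mean")
  sil_sd <- apply(do.call(cbind, pred_trials), 1, stats::sd)
  sil_sd[sil_sd <= 0] <- 1
  out <- speech_sensitivity(pred_trials, sound_set$labels,
                            list(mean = sil_mean, sd = sil_sd), q = q)
  out$t[zero] <- NA_real_
  out$flag_zero_strf <- zero
  out
}
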