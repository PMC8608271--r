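# Phoneme-aligned analyses: evoked-response segmentation, window selection
# by F-statistic, regularized least-squares classification, the speaker
# invariance index, F-ratio discriminability and MDS embedding.

#' Segment responses into phoneme-aligned evoked windows
#'
#' Cuts one row per phoneme instance out of the response matrix, using a
#' half-open window \[start, end) in ms relative to phoneme onset. With
#' frame rate `fr`, the selected 0-based frame indices are
#' `floor(onset*fr) + floor(start*fr/1000) ... floor(onset*fr) +
#' floor(end*fr/1000) - 1`. Features are the concatenation over sites of
#' each site's windowed samples. Instances whose window falls outside the
#' recording are dropped and counted.
#'
#' @param responses an [hg_response] (sites x time) or plain matrix
#' @param table phoneme event table (columns phoneme, onset_s, offset_s,
#'   speaker and the five phonetic attributes)
#' @param window numeric length 2: window start and end in ms after onset
#' @param frame_rate needed when `responses` is a bare matrix
#' @return list of class `"evoked"`: `features` (instances x (frames*sites)),
#'   `labels` (the retained table rows), `window`, `n_dropped`,
#'   `n_frames_per_site`, `n_sites`
#' @export
segment_evoked <- function(responses, table, window = c(90, 150),
                           frame_rate = NULL) {
  if (inherits(responses, "hg_response")) {
    R <- responses$values; fr <- responses$frame_rate
  } else {
    R <- as.matrix(responses)
    fr <- if (is.null(frame_rate)) stop("frame_rate required") else frame_rate
  }
  if (is.null(table) || nrow(table) == 0) stop("empty phoneme table")
  if (window[1] >= window[2]) stop("window start must precede end")
  lo <- floor(window[1] * fr / 1000)
  hi <- floor(window[2] * fr / 1000) - 1
  nw <- hi - lo + 1
  if (nw < 1) stop("window shorter than one frame")
  on_f <- floor(table$onset_s * fr + 1e-9)
  first <- on_f + lo; last <- on_f + hi          # 0-based
  ok <- first >= 0 & last < ncol(R)
  n_drop <- sum(!ok)
  tab <- table[ok, , drop = FALSE]
  ns <- nrow(R)
  feats <- matrix(NA_real_, nrow(tab), nw * ns)
  for (j in seq_len(nrow(tab))) {
    idx <- (first[ok][j]:last[ok][j]) + 1        # to 1-based
    feats[j, ] <- as.vector(t(R[, idx, drop = FALSE]))  # site-major blocks
  }
  structure(list(features = feats, labels = tab, window = window,
                 n_dropped = n_drop, n_frames_per_site = nw, n_sites = ns),
            class = "evoked")
}

# pooled-over-features one-way F statistic machinery
fstat_per_feature <- function(X, y) {
  y <- as.factor(droplevels(factor(y)))
  k <- nlevels(y); n <- nrow(X)
  if (k < 2) stop("need at least 2 classes")
  gm <- colMeans(X)
  ssb <- rep(0, ncol(X)); ssw <- rep(0, ncol(X))
  for (lev in levels(y)) {
    idx <- y == lev
    m <- colMeans(X[idx, , drop = FALSE])
    ssb <- ssb + sum(idx) * (m - gm)^2
    ssw <- ssw + colSums(sweep(X[idx, , drop = FALSE], 2, m)^2)
  }
  list(ssb = ssb, ssw = ssw, k = k, n = n)
}

#' Select an analysis window by the F-statistic of class separation
#'
#' Evaluates each candidate window by segmenting the responses, computing
#' the per-feature one-way F-statistic between the classes, and averaging
#' across features; the window with the maximal mean F is returned, ties
#' broken toward the earlier window. When the best window's mean F is close
#' to 1 (no separation beyond sampling noise) the result is flagged
#' non-informative.
#'
#' @param responses an [hg_response] or matrix
#' @param table phoneme event table
#' @param windows list of candidate `c(start, end)` windows in ms
#' @param label_col column of `table` holding the class labels
#' @param frame_rate for bare matrices
#' @return list: `window` (the selected one), `mean_f` per candidate,
#'   `informative` flag
#' @export
select_window_by_fstat <- function(responses, table, windows,
                                   label_col = "phoneme", frame_rate = NULL) {
  mf <- vapply(windows, function(w) {
    ev <- segment_evoked(responses, table, w, frame_rate)
    st <- fstat_per_feature(ev$features, ev$labels[[label_col]])
    mean((st$ssb / (st$k - 1)) / pmax(st$ssw / (st$n - st$k), 1e-12))
  }, 0)
  best <- which(mf == max(mf))[1]        # earliest on ties
  list(window = windows[[best]], mean_f = mf,
       informative = mf[best] > 1.5)
}

#' Pooled F-ratio discriminability of labelled evoked responses
#'
#' Ratio of between-class to within-class variance pooled over all
#' features: `F = (sum SSB / (k-1)) / (sum SSW / (n-k))`. Used to compare,
#' e.g., speaker discriminability against manner-of-articulation
#' discriminability in the same response space. Zero pooled within-class
#' variance returns `Inf` with attribute `flag = "zero-within"`.
#'
#' @param evoked an `"evoked"` object or a plain feature matrix
#' @param labels class labels (defaults to the evoked table's `phoneme`)
#' @return the pooled F ratio (numeric scalar)
#' @export
f_ratio <- function(evoked, labels = NULL) {
  X <- if (inherits(evoked, "evoked")) evoked$features else as.matrix(evoked)
  if (is.null(labels)) labels <- evoked$labels$phoneme
  y <- factor(labels)
  if (min(table(y)) < 2) stop("each class needs at least 2 instances")
  st <- fstat_per_feature(X, y)
  ssw <- sum(st$ssw); ssb <- sum(st$ssb)
  if (ssw <= 0)
    return(structure(Inf, flag = "zero-within"))
  (ssb / (st$k - 1)) / (ssw / (st$n - st$k))
}

#' Permutation test for the pooled F-ratio
#' @param evoked `"evoked"` object or feature matrix
#' @param labels class labels
#' @param n_perm number of label permutations
#' @param seed RNG seed
#' @return list with `f`, `p` (permutation p-value), `null` (null draws)
#' @export
f_ratio_perm <- function(evoked, labels = NULL, n_perm = 200, seed = 1) {
  X <- if (inherits(evoked, "evoked")) evoked$features else as.matrix(evoked)
  if (is.null(labels)) labels <- evoked$labels$phoneme
  f0 <- f_ratio(X, labels)
  null <- with_seed(seed, replicate(n_perm, f_ratio(X, sample(labels))))
  list(f = f0, p = (1 + sum(null >= f0)) / (1 + n_perm), null = null)
}

# stratified fold ids: round-robin within class for balanced folds
stratified_folds <- function(y, k) {
  id <- integer(length(y))
  for (lev in unique(y)) {
    idx <- which(y == lev)
    id[idx] <- rep(seq_len(k), length.out = length(idx))
  }
  id
}

#' Regularized least-squares (RLS) classification
#'
#' One-vs-rest ridge regression on +/-1 indicator targets with an
#' intercept, decision by argmax of the class scores. The ridge parameter
#' is selected on a stratified 10% validation split of the training data.
#'
#' @param train_x,train_y training features (n x d) and labels
#' @param test_x,test_y test features and (optional) labels
#' @param lambdas candidate ridge parameters
#' @param val_frac validation fraction for ridge selection (default 0.1)
#' @param seed seed for the validation split
#' @return list: `predicted`, `accuracy` (NA if `test_y` missing),
#'   `confusion` (rows = true class), `lambda`, `per_class_recall`
#' @export
rls_classify <- function(train_x, train_y, test_x, test_y = NULL,
                         lambdas = 10^seq(-2, 4, by = 1), val_frac = 0.1,
                         seed = 1) {
  train_x <- as.matrix(train_x); test_x <- as.matrix(test_x)
  if (ncol(train_x) != ncol(test_x)) stop("feature dimensions differ")
  y <- factor(train_y)
  lv <- levels(y)
  if (!is.null(test_y) && !all(test_y %in% lv))
    stop("class absent from training data")
  fit_w <- function(X, Yp, lambda) {
    xm <- colMeans(X); Xc <- sweep(X, 2, xm)
    n <- nrow(Xc); d <- ncol(Xc)
    if (d <= n) {
      W <- solve(crossprod(Xc) + diag(lambda, d), crossprod(Xc, Yp))
    } else {
      A <- solve(tcrossprod(Xc) + diag(lambda, n), Yp)
      W <- crossprod(Xc, A)
    }
    list(W = W, xm = xm, ym = colMeans(Yp))
  }
  score <- function(fit, X)
    sweep(sweep(X, 2, fit$xm) %*% fit$W, 2, -fit$ym)
  Y <- sapply(lv, function(l) ifelse(y == l, 1, -1))
  Y <- matrix(Y, ncol = length(lv))
  lambda <- lambdas[1]
  if (length(lambdas) > 1) {
    vid <- with_seed(seed, {
      f <- stratified_folds(y, max(2L, round(1 / val_frac)))
      f == 1
    })
    if (sum(vid) >= length(lv) && length(unique(y[!vid])) == length(lv)) {
      accs <- vapply(lambdas, function(l) {
        fit <- fit_w(train_x[!vid, , drop = FALSE],
                     Y[!vid, , drop = FALSE], l)
        pred <- lv[max.col(score(fit, train_x[vid, , drop = FALSE]))]
        mean(pred == y[vid])
      }, 0)
      lambda <- lambdas[which.max(accs)]
    }
  }
  fit <- fit_w(train_x, Y, lambda)
  pred <- lv[max.col(score(fit, test_x))]
  out <- list(predicted = pred, lambda = lambda, accuracy = NA_real_,
              confusion = NULL, per_class_recall = NULL)
  if (!is.null(test_y)) {
    tt <- factor(test_y, levels = lv)
    out$accuracy <- mean(pred == as.character(tt))
    out$confusion <- table(true = tt, predicted = factor(pred, levels = lv))
    out$per_class_recall <- diag(prop.table(out$confusion + 0, 1))
  }
  out
}

# k-fold CV accuracy of the RLS classifier (stratified folds)
rls_cv_accuracy <- function(X, y, k = 10, seed = 1, lambdas = 10^seq(-2, 4, 1)) {
  y <- factor(droplevels(factor(y)))
  fid <- with_seed(seed, {
    ord <- sample(length(y))      # shuffle before round-robin
    id <- integer(length(y))
    id[ord] <- stratified_folds(y[ord], k)
    id
  })
  accs <- c()
  for (f in unique(fid)) {
    tr <- fid != f
    if (length(unique(y[tr])) < nlevels(y)) next
    r <- rls_classify(X[tr, , drop = FALSE], y[tr],
                      X[!tr, , drop = FALSE], y[!tr],
                      lambdas = lambdas, seed = seed)
    accs <- c(accs, r$accuracy)
  }
  mean(accs)
}

#' Speaker invariance index
#'
#' Quantifies how speaker-normalized the phonetic code of a site (or a
#' population) is. For each of the five phonetic attributes, an RLS
#' classifier trained on all-but-one speakers is tested on the held-out
#' speaker (leave-one-speaker-out, "cross" accuracy) and compared with the
#' 10-fold within-speaker cross-validated accuracy ("within"). The index
#' is `si = cross_acc / within_acc`, averaged over held-out speakers and
#' attributes: a site whose phonetic code carries over to an unheard
#' speaker scores near 1; a speaker-specific code scores much lower.
#' Vowel-only attributes (height, backness) are evaluated on vowel
#' instances.
#'
#' @param responses an [hg_response] or matrix (sites x time)
#' @param table phoneme event table
#' @param window ms window after onset (default 70-180)
#' @param attributes phonetic attribute columns to aggregate over
#' @param sites optional site indices; default all, one result per site
#' @param population if TRUE, use the whole population's concatenated
#'   features as a single classifier input
#' @param frame_rate for bare matrices
#' @param seed RNG seed for CV splits
#' @return for `population = TRUE`, a list with `si`, `cross_acc`,
#'   `within_acc`, `per_attribute` and `unreliable`; otherwise a data.frame
#'   with one row per site
#' @export
speaker_invariance_index <- function(responses, table, window = c(70, 180),
                                     attributes = c("manner", "place",
                                                    "voicing", "height",
                                                    "backness"),
                                     sites = NULL, population = FALSE,
                                     frame_rate = NULL, seed = 1) {
  ev <- segment_evoked(responses, table, window, frame_rate)
  spk <- ev$labels$speaker
  if (length(unique(spk)) < 2) stop("need at least 2 speakers")
  nw <- ev$n_frames_per_site
  si_core <- function(feat) {
    per_attr <- sapply(attributes, function(at) {
      lab <- ev$labels[[at]]
      keep <- lab != "none"
      if (!any(keep)) return(c(NA, NA))
      X <- feat[keep, , drop = FALSE]; y <- factor(lab[keep])
      sp <- spk[keep]
      usp <- unique(sp)
      cross <- c(); within <- c()
      for (s in usp) {
        tr <- sp != s
        if (length(unique(y[tr])) < nlevels(droplevels(y)) ||
            length(unique(y[!tr])) < 2) next
        r <- rls_classify(X[tr, , drop = FALSE], droplevels(y[tr]),
                          X[!tr, , drop = FALSE], as.character(y[!tr]),
                          seed = seed)
        cross <- c(cross, r$accuracy)
        within <- c(within, rls_cv_accuracy(X[!tr, , drop = FALSE],
                                            y[!tr], seed = seed))
      }
      c(mean(cross), mean(within))
    })
    cross <- mean(per_attr[1, ], na.rm = TRUE)
    within <- mean(per_attr[2, ], na.rm = TRUE)
    list(si = cross / within, cross_acc = cross, within_acc = within,
         per_attribute = per_attr[1, ] / per_attr[2, ],
         unreliable = within <= 1 / 2.5)   # near-chance baseline flag
  }
  if (population) return(si_core(ev$features))
  if (is.null(sites)) sites <- seq_len(ev$n_sites)
  out <- lapply(sites, function(s) {
    cols <- ((s - 1) * nw + 1):(s * nw)
    r <- si_core(ev$features[, cols, drop = FALSE])
    data.frame(site = s, si = r$si, cross_acc = r$cross_acc,
               within_acc = r$within_acc, unreliable = r$unreliable)
  })
  do.call(rbind, out)
}

#' Two-dimensional MDS embedding minimizing Kruskal stress
#'
#' Embeds a symmetric dissimilarity matrix in `dims` dimensions by
#' non-metric multidimensional scaling with Kruskal's normalized stress-1
#' criterion (classical scaling as the starting configuration).
#'
#' @param d symmetric non-negative dissimilarity matrix with zero diagonal
#' @param dims embedding dimension (default 2)
#' @return list: `points` (n x dims), `stress` (Kruskal stress-1, 0-1 scale)
#' @export
mds_embed <- function(d, dims = 2) {
  d <- as.matrix(d)
  if (!isSymmetric(unname(d), tol = 1e-8)) stop("dissimilarity matrix must be symmetric")
  if (any(diag(d) != 0)) stop("diagonal must be zero")
  if (any(d < 0)) stop("dissimilarities must be non-negative")
  eps <- max(d) * 1e-8
  dd <- d; dd[dd == 0] <- eps; diag(dd) <- 0
  init <- stats::cmdscale(dd, k = dims)
  if (ncol(init) < dims)
    init <- cbind(init, matrix(1e-6, nrow(dd), dims - ncol(init)))
  fit <- MASS::isoMDS(stats::as.dist(dd), y = init, k = dims, trace = FALSE)
  list(points = fit$points, stress = fit$stress / 100)
}
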