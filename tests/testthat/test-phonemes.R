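# Phoneme-aligned decoding: window arithmetic, F statistics, the RLS
# classifier, speaker invariance, and MDS embedding.

test_that("evoked windows follow the half-open frame convention", {
  R <- matrix(seq_len(2 * 300), nrow = 2, byrow = TRUE)   # 2 sites, 3 s
  tab <- data.frame(phoneme = "AA", onset_s = 1.0, offset_s = 1.1,
                    speaker = "spk1")
  ev <- segment_evoked(R, tab, c(90, 150), frame_rate = 100)
  # onset frame 100, window frames 109..114 (0-based), six per site
  expect_equal(ev$n_frames_per_site, 6)
  expect_equal(ev$features[1, 1:6], 110:115)               # site 1, 1-based
  expect_equal(dim(ev$features), c(1, 12))
})

test_that("instances at the recording edge are dropped and counted", {
  R <- matrix(rnorm(100), nrow = 1)
  tab <- data.frame(phoneme = c("AA", "IY"), onset_s = c(0.2, 0.98),
                    offset_s = c(0.3, 1.0), speaker = "spk1")
  ev <- segment_evoked(R, tab, c(90, 150), frame_rate = 100)
  expect_equal(nrow(ev$features), 1)
  expect_equal(ev$n_dropped, 1)
  expect_error(segment_evoked(R, tab[0, ], c(90, 150), frame_rate = 100),
               "empty")
})

test_that("window selection maximizes the class F-statistic", {
  set.seed(5)
  n <- 120
  R <- matrix(rnorm(1 * 8000, sd = 0.5), nrow = 1)
  onsets <- seq(0.5, 70, length.out = n)
  cls <- rep(c("a", "b"), n / 2)
  # separability planted only at 90-150 ms after onset
  for (i in seq_len(n)) {
    idx <- floor(onsets[i] * 100) + (9:14) + 1
    R[1, idx] <- R[1, idx] + ifelse(cls[i] == "a", 2, -2)
  }
  tab <- data.frame(phoneme = cls, onset_s = onsets, offset_s = onsets + 0.1,
                    speaker = "spk1")
  wins <- list(c(10, 70), c(90, 150), c(200, 260))
  sel <- select_window_by_fstat(R, tab, wins, frame_rate = 100)
  expect_equal(sel$window, c(90, 150))
  expect_true(sel$informative)
  # identical class distributions: flagged non-informative, earliest window
  R0 <- matrix(rnorm(8000, sd = 0.5), nrow = 1)
  sel0 <- select_window_by_fstat(R0, tab, wins, frame_rate = 100)
  expect_false(sel0$informative)
  # ties break toward the earlier window
  mf <- c(2, 2, 1)
  expect_equal(which(mf == max(mf))[1], 1)
})

test_that("RLS separates a wide-margin code and is at chance when shuffled", {
  set.seed(6)
  n <- 200; d <- 8
  y <- sample(c("p", "q"), n, replace = TRUE)
  X <- matrix(rnorm(n * d, sd = 0.1), n) + outer(ifelse(y == "p", 3, -3),
                                                 rep(1, d))
  tr <- seq_len(150)
  r <- rls_classify(X[tr, ], y[tr], X[-tr, ], y[-tr])
  expect_gte(r$accuracy, 0.99)
  expect_equal(dim(r$confusion), c(2, 2))
  # permuted labels: accuracy within 3 binomial sd of chance
  yp <- sample(y)
  rp <- rls_classify(X[tr, ], yp[tr], X[-tr, ], yp[-tr])
  expect_lt(abs(rp$accuracy - 0.5), 3 * sqrt(0.25 / 50))
  expect_error(rls_classify(X[tr, ], y[tr], X[-tr, 1:3], y[-tr]), "dimensions")
  expect_error(rls_classify(X[y == "p", ], y[y == "p"], X, y), "absent")
})

test_that("pooled F-ratio matches its construction and degenerate cases", {
  set.seed(7)
  n <- 120
  y <- rep(c("a", "b"), each = n / 2)
  X <- matrix(rnorm(n * 4), n)
  X[y == "b", ] <- X[y == "b", ] + 10      # 10 within-sd separation
  expect_gt(f_ratio(X, y), 50)
  # identical class means: F fluctuates around 1 under the null
  nulls <- replicate(50, f_ratio(matrix(rnorm(40 * 3), 40),
                                 rep(c("a", "b"), 20)))
  expect_lt(abs(mean(nulls) - 1), 0.35)
  expect_error(f_ratio(X[c(1, n), ], y[c(1, n)]), "at least 2 instances")
  Xz <- matrix(rep(c(0, 1), each = 8), 16, 2)
  fz <- f_ratio(Xz, rep(c("a", "b"), each = 8))
  expect_true(is.infinite(fz))
  expect_equal(attr(fz, "flag"), "zero-within")
})

test_that("permutation p-value is small for planted effects", {
  set.seed(8)
  y <- rep(c("a", "b"), 30)
  X <- matrix(rnorm(60 * 3), 60) + outer(ifelse(y == "a", 1, -1), rep(1, 3))
  pr <- f_ratio_perm(X, y, n_perm = 199, seed = 3)
  expect_lt(pr$p, 0.01)
})

test_that("speaker invariance index separates planted coding regimes", {
  run <- function(mode) {
    co <- synth_cohort(n_sites = 4, duration_s = 40, seed = 23,
                       invariance = mode)
    r <- generate_responses(co, snr_db = 5, evoked_scale = 4)
    speaker_invariance_index(r, co$phoneme_table)
  }
  inv <- run("speaker_invariant")
  dep <- run("speaker_dependent")
  expect_gte(mean(inv$si), 0.9)
  expect_lt(mean(dep$si), mean(inv$si))
  # generalization cannot beat the training domain except by noise
  n_inst <- 300   # instance count scale for the binomial guard
  expect_lte(mean(inv$cross_acc),
             mean(inv$within_acc) + 3 * sqrt(0.25 / n_inst) + 0.05)
  # affine rescaling of a site's response leaves the index unchanged
  co <- synth_cohort(n_sites = 2, duration_s = 40, seed = 24,
                     invariance = 0.5)
  r <- generate_responses(co, snr_db = 5, evoked_scale = 4)
  s1 <- speaker_invariance_index(r, co$phoneme_table, sites = 1)
  r2 <- r; r2$values[1, ] <- 3 * r2$values[1, ] + 7
  s2 <- speaker_invariance_index(r2, co$phoneme_table, sites = 1)
  expect_equal(s1$si, s2$si, tolerance = 0.05)
})

test_that("population decoding of all five attributes beats chance", {
  co <- synth_cohort(n_sites = 6, duration_s = 40, seed = 29,
                     invariance = 0.5)
  r <- generate_responses(co, snr_db = 5, evoked_scale = 4)
  ev <- segment_evoked(r, co$phoneme_table, c(70, 180))
  for (at in c("manner", "place", "voicing", "height", "backness")) {
    lab <- ev$labels[[at]]
    keep <- lab != "none"
    X <- ev$features[keep, ]; y <- factor(lab[keep])
    acc <- rls_cv_accuracy(X, y, k = 5, seed = 1)
    chance <- max(table(y)) / length(y)
    expect_gt(acc, chance + 3 * sqrt(chance * (1 - chance) / length(y)))
  }
})

test_that("MDS embeds exact configurations with near-zero stress", {
  pts <- cbind(c(0, 1, 2, 3.5), 0)
  D <- as.matrix(dist(pts))
  em <- mds_embed(D)
  expect_lte(em$stress, 1e-3)
  Dhat <- as.matrix(dist(em$points))
  expect_lt(max(abs(Dhat - D) / max(D)), 0.01)
  # all-equal distances among 3 points: equilateral triangle
  D3 <- matrix(1, 3, 3) - diag(3)
  em3 <- mds_embed(D3)
  d3 <- as.matrix(dist(em3$points))[upper.tri(diag(3))]
  expect_lt(diff(range(d3)) / mean(d3), 0.01)
  bad <- D; bad[1, 2] <- 5
  expect_error(mds_embed(bad), "symmetric")
})

test_that("MDS separates speakers in dependent mode, phonemes in invariant", {
  layout_for <- function(mode, seed) {
    co <- synth_cohort(n_sites = 6, duration_s = 40, seed = seed,
                       invariance = mode)
    r <- generate_responses(co, snr_db = 5, evoked_scale = 4)
    ev <- segment_evoked(r, co$phoneme_table, c(90, 150))
    keep <- ev$labels$phoneme %in% c("UW", "L", "AO", "OW")
    g <- interaction(ev$labels$phoneme[keep], ev$labels$speaker[keep])
    M <- apply(ev$features[keep, ], 2, function(col) tapply(col, g, mean))
    M <- M[table(g)[rownames(M)] > 0, ]
    em <- mds_embed(as.matrix(dist(M)))
    sil <- function(lab) {
      D <- as.matrix(dist(em$points))
      mean(vapply(seq_along(lab), function(i) {
        a <- mean(D[i, lab == lab[i]][-which(which(lab == lab[i]) == i)])
        b <- min(tapply(D[i, lab != lab[i]], lab[lab != lab[i]], mean))
        (b - a) / max(a, b)
      }, 0))
    }
    ph <- sub("\\..*", "", rownames(M)); sp <- sub(".*\\.", "", rownames(M))
    c(phon = sil(ph), spk = sil(sp))
  }
  dep <- layout_for("speaker_dependent", 37)
  inv <- layout_for("speaker_invariant", 37)
  expect_gt(dep["spk"], dep["phon"])
  expect_gt(inv["phon"], inv["spk"])
})
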