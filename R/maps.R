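# Spatial analysis of electrode tuning maps: the along-gyrus axis, map
# smoothing / interpolation / imputation, feature-versus-distance
# correlations, hemisphere comparisons, and the joint PCA + CCA gradient
# analysis.

#' Medial-lateral distance from midsagittal x coordinates
#'
#' Absolute distance to the midsagittal plane with the cohort minimum
#' subtracted, so the most medial electrode sits at 0 mm.
#' @param x_mm signed x coordinates in mm (midsagittal plane at 0)
#' @return non-negative ML distances in mm
#' @export
ml_distance <- function(x_mm) {
  d <- abs(x_mm)
  d - min(d)
}

#' Distance along the electrode array's principal axis
#'
#' Projects electrode (ML, PA) positions onto their first principal
#' component -- the long axis of the array -- with the origin at the most
#' medial site and the sign chosen so distance increases medially to
#' laterally. A warning is emitted when the electrode cloud is nearly
#' isotropic (eigenvalue ratio below `min_ratio`), in which case the axis
#' direction is unstable.
#'
#' @param coords n x 2 matrix of (ML, PA) positions in mm
#' @param min_ratio eigenvalue ratio below which a warning is raised
#' @return numeric vector of along-axis distances (mm), with attributes
#'   `axis` (unit 2-vector) and `eigen_ratio`
#' @export
along_hg_distance <- function(coords, min_ratio = 1.2) {
  coords <- as.matrix(coords)
  if (nrow(coords) < 3) stop("need at least 3 sites")
  pc <- stats::prcomp(coords, center = TRUE, scale. = FALSE)
  ratio <- pc$sdev[1]^2 / max(pc$sdev[2]^2, 1e-12)
  if (ratio < min_ratio)
    warning(sprintf("electrode cloud nearly isotropic (eigenvalue ratio %.2f): axis unstable",
                    ratio))
  axis <- pc$rotation[, 1]
  proj <- as.vector(coords %*% axis)
  if (stats::cor(proj, coords[, 1]) < 0) { axis <- -axis; proj <- -proj }
  most_medial <- which.min(coords[, 1])
  out <- proj - proj[most_medial]
  attr(out, "axis") <- axis
  attr(out, "eigen_ratio") <- ratio
  out
}

#' K-nearest-neighbor smoothing of a feature map
#'
#' Replaces each site's displayed value with the mean of its `k` nearest
#' neighboring electrodes (Euclidean distance, self excluded). Smoothing
#' is for display; statistics should use the raw values. Distance ties and
#' duplicate coordinates are broken deterministically by site order.
#'
#' @param values numeric vector per site
#' @param coords n x 2 positions
#' @param k number of neighbors (default 4)
#' @return smoothed values
#' @export
knn_smooth <- function(values, coords, k = 4) {
  coords <- as.matrix(coords)
  n <- length(values)
  if (n <= k) stop("need more sites than neighbors")
  D <- as.matrix(stats::dist(coords))
  vapply(seq_len(n), function(i) {
    ord <- order(D[i, -i], seq_len(n - 1))    # deterministic tie-break
    nb <- setdiff(seq_len(n), i)[ord][seq_len(k)]
    mean(values[nb])
  }, 0)
}

#' Piecewise-linear interpolation surface over electrode positions
#'
#' Fits a barycentric (piecewise linear) interpolant on the Delaunay
#' triangulation of the sites and evaluates it on a rectangular grid.
#' Grid points outside the convex hull are `NA` (masked).
#'
#' @param values numeric vector per site
#' @param coords n x 2 positions
#' @param grid_x,grid_y grid coordinates
#' @return matrix of length(grid_x) x length(grid_y) interpolated values
#' @export
interpolate_surface <- function(values, coords, grid_x, grid_y) {
  coords <- as.matrix(coords)
  if (nrow(coords) < 3) stop("need at least 3 sites")
  x <- coords[, 1]; y <- coords[, 2]
  if (abs(stats::cor(x, y)) > 1 - 1e-9 || stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("sites are collinear: no interpolation surface")
  tris <- delaunay_triangulate(x, y)
  out <- matrix(NA_real_, length(grid_x), length(grid_y))
  for (i in seq_along(grid_x)) for (j in seq_along(grid_y)) {
    for (t in seq_len(nrow(tris))) {
      l <- barycentric_coords(grid_x[i], grid_y[j], x, y, tris[t, ])
      if (!anyNA(l) && all(l >= -1e-9)) {
        out[i, j] <- sum(l * values[tris[t, ]])
        break
      }
    }
  }
  out
}

#' Nearest-neighbor imputation of missing map values
#'
#' Fills `NA` entries with the value of the nearest site that has one
#' (KNN imputation with k = 1). Display-only; statistics should use the
#' observed values.
#'
#' @param values numeric vector with `NA`s to fill
#' @param coords n x 2 positions
#' @return filled vector
#' @export
impute_missing <- function(values, coords) {
  coords <- as.matrix(coords)
  obs <- which(!is.na(values))
  if (!length(obs)) stop("all values missing: nothing to impute from")
  miss <- which(is.na(values))
  if (!length(miss)) return(values)
  D <- as.matrix(stats::dist(coords))
  for (i in miss) {
    j <- obs[order(D[i, obs], obs)][1]
    values[i] <- values[j]
  }
  values
}

#' Correlation of a tuning feature with along-axis distance
#'
#' Pearson correlation of the raw (unsmoothed) per-site values against the
#' along-gyrus distance, with the two-sided t-test p-value. Best frequency
#' should be passed with `log_transform = TRUE` (tonotopic gradients are
#' log-linear).
#'
#' @param values raw per-site feature values
#' @param along_hg along-axis distances
#' @param log_transform log2-transform the values first
#' @return list with `r`, `p`, `n`
#' @export
feature_axis_correlation <- function(values, along_hg, log_transform = FALSE) {
  keep <- is.finite(values) & is.finite(along_hg)
  v <- values[keep]; d <- along_hg[keep]
  if (log_transform) v <- log2(v)
  if (stats::sd(v) == 0 || stats::sd(d) == 0)
    stop("zero variance: correlation undefined")
  ct <- stats::cor.test(v, d, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(v))
}

#' Compare a tuning feature between hemispheres
#'
#' Two-sided Wilcoxon rank-sum test on the raw values of left versus right
#' hemisphere sites.
#'
#' @param values per-site feature values
#' @param hemisphere `"L"`/`"R"` labels
#' @return list with `W`, `p`, `n_left`, `n_right`
#' @export
compare_hemispheres <- function(values, hemisphere) {
  l <- values[hemisphere == "L"]; r <- values[hemisphere == "R"]
  if (!length(l) || !length(r)) stop("both hemispheres must be represented")
  exact <- FALSE
  if (min(length(l), length(r)) < 3) {
    warning("a hemisphere has fewer than 3 sites: exact test used")
    exact <- TRUE
  }
  wt <- suppressWarnings(stats::wilcox.test(l, r, exact = exact))
  list(W = unname(wt$statistic), p = wt$p.value,
       n_left = length(l), n_right = length(r))
}

#' Joint PCA of the five tuning feature maps
#'
#' Standardizes each feature column (z-score) and computes principal
#' components across sites. The sign of each component is fixed so that
#' its largest-magnitude feature weight is positive. Best frequency should
#' enter as log2(Hz).
#'
#' @param X N sites x M features matrix (M >= 2)
#' @param feature_names optional column names
#' @return list: `weights` (M x M, columns = PCs), `var_frac` explained
#'   variance fractions, `projections` (N x M per-site scores)
#' @export
joint_pca <- function(X, feature_names = colnames(X)) {
  X <- as.matrix(X)
  if (ncol(X) < 2 || nrow(X) <= ncol(X))
    stop("need at least 2 features and more sites than features")
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0))
    stop(sprintf("constant feature column: %s",
                 paste(feature_names[sds == 0], collapse = ", ")))
  pc <- stats::prcomp(X, center = TRUE, scale. = TRUE)
  W <- pc$rotation; P <- pc$x
  for (j in seq_len(ncol(W))) {
    if (W[which.max(abs(W[, j])), j] < 0) {
      W[, j] <- -W[, j]; P[, j] <- -P[, j]
    }
  }
  rownames(W) <- feature_names
  list(weights = W, var_frac = pc$sdev^2 / sum(pc$sdev^2), projections = P)
}

#' Best anatomical direction of a tuning projection by CCA
#'
#' Finds the unit vector over (ML, PA) whose linear combination of
#' coordinates maximally correlates with the projected tuning value
#' (canonical correlation analysis with a one-column Y). With random Y the
#' returned directions are uniform over angle; with a planted gradient the
#' direction recovers the gradient axis.
#'
#' @param projection per-site tuning projection (e.g. a PC score)
#' @param coords n x 2 (ML, PA) positions
#' @return list: `a` (unit 2-vector), `r` (canonical correlation),
#'   `angle_deg` (direction in degrees from the ML axis)
#' @export
cca_best_direction <- function(projection, coords) {
  coords <- as.matrix(coords)
  if (nrow(coords) <= 3) stop("need more than 3 sites")
  if (any(apply(coords, 2, stats::sd) == 0)) stop("degenerate coordinates")
  cc <- stats::cancor(coords, matrix(projection, ncol = 1))
  a <- cc$xcoef[, 1]
  a <- a / sqrt(sum(a^2))
  if (stats::cor(as.vector(coords %*% a), projection) < 0) a <- -a
  list(a = a, r = cc$cor[1],
       angle_deg = atan2(a[2], a[1]) * 180 / pi)
}

#' Rayleigh test for circular uniformity of directions
#'
#' Used as the control for [cca_best_direction]: angles from random
#' projections should be uniform on the circle. Axial data (directions
#' defined up to sign) are doubled before testing.
#'
#' @param angles_deg directions in degrees
#' @param axial treat angles as axial (mod 180) and double them
#' @return list with `R_bar` (mean resultant length) and `p`
#' @export
rayleigh_test <- function(angles_deg, axial = TRUE) {
  th <- angles_deg * pi / 180
  if (axial) th <- 2 * th
  n <- length(th)
  rb <- sqrt(mean(cos(th))^2 + mean(sin(th))^2)
  z <- n * rb^2
  p <- exp(-z) * (1 + (2 * z - z^2) / (4 * n))
  list(R_bar = rb, p = max(min(p, 1), 0))
}
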