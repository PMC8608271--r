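# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards so generators are
#' reproducible without clobbering the global stream.
#' @param seed integer seed
#' @param code expression to evaluate
#' @return value of `code`
#' @keywords internal
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("seed must be a single finite number")
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv()),
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  force(code)
}

# Analytic-signal magnitude via FFT (Marple construction); x real vector.
analytic_envelope <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  Mod(stats::fft(X * h, inverse = TRUE) / n)
}

# Geometric sequence of n points from a to b.
geom_seq <- function(a, b, n) exp(seq(log(a), log(b), length.out = n))

# Contiguous fold assignment: n samples into k blocks, sizes differing by <= 1.
contiguous_folds <- function(n, k) {
  rep(seq_len(k), times = diff(floor(seq(0, n, length.out = k + 1))))
}

# ---------------------------------------------------------------------------
# Delaunay triangulation (Bowyer-Watson) and barycentric interpolation.
# Small-N tool for electrode maps; numerical tolerance suits mm-scale coords.

delaunay_triangulate <- function(x, y) {
  n <- length(x)
  stopifnot(length(y) == n, n >= 3)
  # super-triangle enclosing all points
  cx <- mean(range(x)); cy <- mean(range(y))
  d <- max(diff(range(x)), diff(range(y)), 1e-9) * 20
  px <- c(x, cx - 2 * d, cx + 2 * d, cx)
  py <- c(y, cy - d, cy - d, cy + 2 * d)
  tris <- matrix(c(n + 1L, n + 2L, n + 3L), nrow = 1)
  circum <- function(tri) {
    ax <- px[tri[1]]; ay <- py[tri[1]]
    bx <- px[tri[2]]; by <- py[tri[2]]
    cxx <- px[tri[3]]; cyy <- py[tri[3]]
    dd <- 2 * (ax * (by - cyy) + bx * (cyy - ay) + cxx * (ay - by))
    if (abs(dd) < 1e-12) return(c(Inf, Inf, Inf))
    ux <- ((ax^2 + ay^2) * (by - cyy) + (bx^2 + by^2) * (cyy - ay) +
           (cxx^2 + cyy^2) * (ay - by)) / dd
    uy <- ((ax^2 + ay^2) * (cxx - bx) + (bx^2 + by^2) * (ax - cxx) +
           (cxx^2 + cyy^2) * (bx - ax)) / dd
    c(ux, uy, (ux - ax)^2 + (uy - ay)^2)
  }
  cc <- matrix(circum(tris[1, ]), nrow = 1)
  for (ip in seq_len(n)) {
    bad <- which((px[ip] - cc[, 1])^2 + (py[ip] - cc[, 2])^2 <= cc[, 3] * (1 + 1e-9))
    if (length(bad) == 0) next
    # boundary polygon = edges of bad triangles not shared by two bad triangles
    edges <- NULL
    for (t in bad) {
      tr <- tris[t, ]
      edges <- rbind(edges, tr[c(1, 2)], tr[c(2, 3)], tr[c(3, 1)])
    }
    key <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
    keep <- !(key %in% key[duplicated(key)])
    edges <- edges[keep, , drop = FALSE]
    tris <- tris[-bad, , drop = FALSE]
    cc <- cc[-bad, , drop = FALSE]
    for (e in seq_len(nrow(edges))) {
      tri <- c(edges[e, 1], edges[e, 2], ip)
      tris <- rbind(tris, tri)
      cc <- rbind(cc, circum(tri))
    }
  }
  keep <- apply(tris, 1, function(tr) all(tr <= n))
  tris <- tris[keep, , drop = FALSE]
  rownames(tris) <- NULL
  tris
}

# Barycentric coordinates of point (qx,qy) in triangle rows of (x,y)[tri,].
barycentric_coords <- function(qx, qy, x, y, tri) {
  x1 <- x[tri[1]]; y1 <- y[tri[1]]
  x2 <- x[tri[2]]; y2 <- y[tri[2]]
  x3 <- x[tri[3]]; y3 <- y[tri[3]]
  det <- (y2 - y3) * (x1 - x3) + (x3 - x2) * (y1 - y3)
  if (abs(det) < 1e-12) return(c(NA, NA, NA))
  l1 <- ((y2 - y3) * (qx - x3) + (x3 - x2) * (qy - y3)) / det
  l2 <- ((y3 - y1) * (qx - x3) + (x1 - x3) * (qy - y3)) / det
  c(l1, l2, 1 - l1 - l2)
}
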