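# Internal 3-D vector / polyline helpers. Points are n x 3 numeric matrices in
# world millimetre coordinates throughout the package.

.vnorm <- function(v) sqrt(sum(v * v))

.unit <- function(v) {
  n <- .vnorm(v)
  if (!is.finite(n) || n < 1e-12) stop("degenerate zero-length direction")
  v / n
}

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Rodrigues rotation of v about axis k by theta radians
.rotate3 <- function(v, k, theta) {
  k <- .unit(k)
  v * cos(theta) + .cross3(k, v) * sin(theta) + k * sum(k * v) * (1 - cos(theta))
}

# unit vector perpendicular to d at azimuth phi (radians) in the plane normal to d
.perp_at <- function(d, phi) {
  d <- .unit(d)
  ref <- if (abs(d[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- .unit(.cross3(d, ref))
  e2 <- .cross3(d, e1)
  .unit(cos(phi) * e1 + sin(phi) * e2)
}

.as_points <- function(pts) {
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 3, byrow = TRUE)
  storage.mode(pts) <- "double"
  pts
}

.seg_lengths <- function(pts) {
  if (nrow(pts) < 2) return(numeric(0))
  d <- pts[-1, , drop = FALSE] - pts[-nrow(pts), , drop = FALSE]
  sqrt(rowSums(d * d))
}

.cum_arc <- function(pts) c(0, cumsum(.seg_lengths(pts)))

.poly_length <- function(pts) sum(.seg_lengths(pts))

# interpolated point at arc length s, clamped to [0, L]
.point_at_arc <- function(pts, s) {
  if (nrow(pts) == 1) return(pts[1, ])
  cum <- .cum_arc(pts)
  L <- cum[length(cum)]
  s <- min(max(s, 0), L)
  i <- findInterval(s, cum, rightmost.closed = TRUE)
  i <- min(max(i, 1), nrow(pts) - 1)
  seg <- cum[i + 1] - cum[i]
  t <- if (seg < 1e-12) 0 else (s - cum[i]) / seg
  pts[i, ] + t * (pts[i + 1, ] - pts[i, ])
}

# resample a polyline at approximately `step` mm arc spacing, keeping both ends
.resample_polyline <- function(pts, step) {
  pts <- .as_points(pts)
  L <- .poly_length(pts)
  if (nrow(pts) < 2 || L < step / 2) return(pts)
  s <- seq(0, L, by = step)
  if (L - s[length(s)] > 1e-9) s <- c(s, L)
  t(vapply(s, function(si) .point_at_arc(pts, si), numeric(3)))
}

# discrete Menger curvature (1/R of the circumcircle) at interior vertices of an
# approximately evenly sampled polyline; returns one value per interior vertex
.menger_curvature <- function(pts) {
  n <- nrow(pts)
  if (n < 3) return(numeric(0))
  vapply(seq_len(n - 2), function(i) {
    a <- pts[i, ]; b <- pts[i + 1, ]; c3 <- pts[i + 2, ]
    ab <- b - a; bc <- c3 - b; ac <- c3 - a
    lab <- .vnorm(ab); lbc <- .vnorm(bc); lac <- .vnorm(ac)
    if (lab < 1e-9 || lbc < 1e-9 || lac < 1e-9) return(0)
    2 * .vnorm(.cross3(ab, bc)) / (lab * lbc * lac)
  }, numeric(1))
}

# endpoint-preserving kernel smoothing (0.25, 0.5, 0.25), several passes;
# counteracts the staircase of voxel-centre paths
.smooth_path <- function(pts, passes = 3) {
  pts <- .as_points(pts)
  n <- nrow(pts)
  if (n < 3) return(pts)
  for (p in seq_len(passes)) {
    inner <- 0.25 * pts[1:(n - 2), , drop = FALSE] +
             0.50 * pts[2:(n - 1), , drop = FALSE] +
             0.25 * pts[3:n, , drop = FALSE]
    pts <- rbind(pts[1, ], inner, pts[n, ])
  }
  pts
}

# for each row of A, minimum Euclidean distance to any row of B
.min_dist_to_set <- function(A, B) {
  A <- .as_points(A); B <- .as_points(B)
  if (nrow(B) == 0) return(rep(Inf, nrow(A)))
  out <- numeric(nrow(A))
  chunk <- max(1L, floor(2e6 / nrow(B)))
  i <- 1L
  while (i <= nrow(A)) {
    j <- min(i + chunk - 1L, nrow(A))
    a <- A[i:j, , drop = FALSE]
    d2 <- outer(rowSums(a * a), rowSums(B * B), "+") - 2 * tcrossprod(a, B)
    out[i:j] <- sqrt(pmax(0, apply(d2, 1, min)))
    i <- j + 1L
  }
  out
}

# symmetric Hausdorff distance between two point sets
.hausdorff_sets <- function(A, B) {
  max(max(.min_dist_to_set(A, B)), max(.min_dist_to_set(B, A)))
}
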