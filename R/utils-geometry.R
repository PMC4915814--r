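# Planar polygon helpers shared across modules. Polygons are CCW matrices
# with columns x, y; angles are degrees anticlockwise from East (posterior).

.poly_signed_area <- function(x, y) {
  n <- length(x)
  j <- c(2:n, 1L)
  sum(x * y[j] - x[j] * y) / 2
}

.poly_centroid <- function(x, y) {
  n <- length(x)
  j <- c(2:n, 1L)
  cr <- x * y[j] - x[j] * y
  a <- sum(cr) / 2
  if (abs(a) < .Machine$double.eps) return(c(mean(x), mean(y)))
  c(sum((x + x[j]) * cr), sum((y + y[j]) * cr)) / (6 * a)
}

.poly_perimeter <- function(x, y) {
  n <- length(x)
  j <- c(2:n, 1L)
  sum(sqrt((x[j] - x)^2 + (y[j] - y)^2))
}

# second central moment (covariance) matrix of the uniform lamina
.poly_moments <- function(x, y) {
  n <- length(x)
  j <- c(2:n, 1L)
  cr <- x * y[j] - x[j] * y
  a <- sum(cr) / 2
  cx <- sum((x + x[j]) * cr) / (6 * a)
  cy <- sum((y + y[j]) * cr) / (6 * a)
  ixx <- sum((x^2 + x * x[j] + x[j]^2) * cr) / 12
  iyy <- sum((y^2 + y * y[j] + y[j]^2) * cr) / 12
  ixy <- sum((x * y[j] + 2 * x * y + 2 * x[j] * y[j] + x[j] * y) * cr) / 24
  m <- matrix(c(ixx / a - cx^2, ixy / a - cx * cy,
                ixy / a - cx * cy, iyy / a - cy^2), 2, 2)
  m
}

# TRUE if the closed polygon has no self-intersections (adjacent edges and
# shared endpoints allowed)
.poly_is_simple <- function(x, y) {
  n <- length(x)
  if (n < 3L) return(FALSE)
  j <- c(2:n, 1L)
  segs <- cbind(x, y, x[j], y[j])
  for (p in seq_len(n - 1L)) {
    for (q in (p + 1L):n) {
      if (q == p || q == (p %% n) + 1L || p == (q %% n) + 1L) next
      if (.segments_cross(segs[p, ], segs[q, ])) return(FALSE)
    }
  }
  TRUE
}

.segments_cross <- function(s1, s2) {
  d1 <- .orient(s2[1:2], s2[3:4], s1[1:2])
  d2 <- .orient(s2[1:2], s2[3:4], s1[3:4])
  d3 <- .orient(s1[1:2], s1[3:4], s2[1:2])
  d4 <- .orient(s1[1:2], s1[3:4], s2[3:4])
  (d1 * d2 < 0) && (d3 * d4 < 0)
}

.orient <- function(a, b, c) {
  (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
}

# angle in degrees anticlockwise from East, in [0, 360)
.angle_deg <- function(dx, dy) {
  a <- atan2(dy, dx) * 180 / pi
  a %% 360
}

# principal matrix square root / log of a 2x2 SPD matrix
.sqrtm2 <- function(m) {
  e <- eigen(m, symmetric = TRUE)
  v <- pmax(e$values, 0)
  e$vectors %*% diag(sqrt(v), 2) %*% t(e$vectors)
}

.logm2_spd <- function(m) {
  e <- eigen(m, symmetric = TRUE)
  if (any(e$values <= 0)) stop("matrix not positive definite", call. = FALSE)
  e$vectors %*% diag(log(e$values), 2) %*% t(e$vectors)
}

# real matrix log of a general (near-identity) 2x2 matrix via pracma
.logm2 <- function(m) {
  out <- tryCatch(pracma::logm(m), error = function(e) NULL)
  if (is.null(out) || any(!is.finite(out))) {
    stop("matrix logarithm failed (singular deformation fit)", call. = FALSE)
  }
  Re(out)
}

# clip a convex polygon (matrix, CCW) to the half-plane {p : n . p <= d}
.clip_halfplane <- function(poly, nrm, d, label, labels) {
  n <- nrow(poly)
  if (n == 0L) return(list(poly = poly, labels = labels))
  val <- poly %*% nrm - d
  keep_any <- any(val <= 1e-12)
  if (!keep_any) {
    return(list(poly = poly[0, , drop = FALSE], labels = integer(0)))
  }
  out <- matrix(0, 0, 2)
  lab <- integer(0)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    vi <- val[i]; vj <- val[j]
    if (vi <= 1e-12) {
      out <- rbind(out, poly[i, ])
      lab <- c(lab, labels[i])
    }
    if ((vi < -1e-12 && vj > 1e-12) || (vi > 1e-12 && vj < -1e-12)) {
      t <- vi / (vi - vj)
      out <- rbind(out, poly[i, ] + t * (poly[j, ] - poly[i, ]))
      # the edge leaving the intersection point lies on the clip line when we
      # are exiting the half-plane, otherwise it keeps the old edge label
      lab <- c(lab, if (vi < 0) label else labels[i])
    }
  }
  list(poly = out, labels = lab)
}
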