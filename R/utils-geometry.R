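# Internal geometry helpers. Convention used throughout the package:
# points are (row, col), 1-based, origin top-left; angles are in degrees with
# 0 = +col direction and counter-clockwise positive as the image is displayed
# (i.e. towards -row). Unit vector for angle a: (-sin a, cos a).

deg2vec <- function(deg) {
  a <- deg * pi / 180
  c(-sin(a), cos(a))
}

vec2deg <- function(v) {
  (atan2(-v[1], v[2]) * 180 / pi) %% 360
}

# Rotate a (row, col) vector counter-clockwise (display sense) by `deg`.
rot2 <- function(v, deg) {
  a <- deg * pi / 180
  c(v[1] * cos(a) - v[2] * sin(a), v[2] * cos(a) + v[1] * sin(a))
}

# z-component of the cross product h x w in display coordinates.
# Positive means w points to the left side of heading h (fly's left).
cross2 <- function(h, w) h[1] * w[2] - h[2] * w[1]

# Unsigned angle in [0, 180] between two (row, col) vectors.
angle_between <- function(u, v) {
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) return(NA_real_)
  acos(pmin(1, pmax(-1, sum(u * v) / (nu * nv)))) * 180 / pi
}

dist2 <- function(p, q) sqrt(sum((p - q)^2))

# --- rasterization on an nr x nc logical grid, pixel centers at integers ---

blank_mask <- function(nr, nc) matrix(FALSE, nr, nc)

# Filled rotated ellipse; `center` (row, col), semi-axes a (along dir) and b.
fill_ellipse <- function(nr, nc, center, a, b, dir_deg) {
  u <- deg2vec(dir_deg)
  nvec <- c(u[2], -u[1])
  r0 <- max(1L, floor(center[1] - a - b)); r1 <- min(nr, ceiling(center[1] + a + b))
  c0 <- max(1L, floor(center[2] - a - b)); c1 <- min(nc, ceiling(center[2] + a + b))
  m <- blank_mask(nr, nc)
  if (r0 > r1 || c0 > c1) return(m)
  rr <- r0:r1; cc <- c0:c1
  dr <- outer(rr - center[1], rep(1, length(cc)))
  dc <- outer(rep(1, length(rr)), cc - center[2])
  pu <- dr * u[1] + dc * u[2]
  pv <- dr * nvec[1] + dc * nvec[2]
  m[rr, cc] <- (pu / a)^2 + (pv / b)^2 <= 1
  m
}

# Filled triangle via barycentric sign tests; vertices are (row, col) pairs.
fill_triangle <- function(nr, nc, v1, v2, v3) {
  r0 <- max(1L, floor(min(v1[1], v2[1], v3[1]))); r1 <- min(nr, ceiling(max(v1[1], v2[1], v3[1])))
  c0 <- max(1L, floor(min(v1[2], v2[2], v3[2]))); c1 <- min(nc, ceiling(max(v1[2], v2[2], v3[2])))
  m <- blank_mask(nr, nc)
  if (r0 > r1 || c0 > c1) return(m)
  rr <- r0:r1; cc <- c0:c1
  pr <- outer(rr, rep(1, length(cc)))
  pc <- outer(rep(1, length(rr)), cc)
  edge <- function(a, b) (pr - a[1]) * (b[2] - a[2]) - (pc - a[2]) * (b[1] - a[1])
  e1 <- edge(v1, v2); e2 <- edge(v2, v3); e3 <- edge(v3, v1)
  eps <- 1e-9
  inside <- (e1 >= -eps & e2 >= -eps & e3 >= -eps) | (e1 <= eps & e2 <= eps & e3 <= eps)
  m[rr, cc] <- inside
  m
}

# 1-px-wide segment from p to q (rounded dense sampling).
draw_segment <- function(nr, nc, p, q) {
  m <- blank_mask(nr, nc)
  n <- max(2L, 2L * ceiling(dist2(p, q)))
  t <- seq(0, 1, length.out = n)
  r <- round(p[1] + t * (q[1] - p[1]))
  c <- round(p[2] + t * (q[2] - p[2]))
  keep <- r >= 1 & r <= nr & c >= 1 & c <= nc
  m[cbind(r[keep], c[keep])] <- TRUE
  m
}

fill_disc <- function(nr, nc, center, radius) {
  fill_ellipse(nr, nc, center, radius, radius, 0)
}

# Mask centroid as (row, col); NULL for an empty mask.
mask_centroid <- function(m) {
  idx <- which(m, arr.ind = TRUE)
  if (nrow(idx) == 0) return(NULL)
  c(mean(idx[, 1]), mean(idx[, 2]))
}
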