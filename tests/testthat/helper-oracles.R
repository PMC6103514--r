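# Independent brute-force oracles used to validate the package's
# implementations. These deliberately use the slowest, most literal
# formulation of each computation.

# Otsu: exhaustive scan over all 256 candidate thresholds, recomputing the
# between-class variance from the raw class memberships each time.
oracle_otsu <- function(values) {
  v <- as.vector(values)
  best_t <- NA_integer_; best_sb <- -Inf
  for (t in 0:254) {
    lo <- v[v <= t]; hi <- v[v > t]
    if (length(lo) == 0L || length(hi) == 0L) next
    w0 <- length(lo) / length(v); w1 <- 1 - w0
    sb <- w0 * w1 * (mean(lo) - mean(hi))^2
    if (sb > best_sb + 1e-12) { best_sb <- sb; best_t <- t }
  }
  best_t
}

# Minimum enclosing circle: exhaustive search over all circles defined by
# point pairs (diameters) and triples (circumcircles), keeping the
# smallest that covers every point.
oracle_mec <- function(pts) {
  n <- nrow(pts)
  tol <- 1e-9
  covers <- function(cx, cy, r) {
    all(sqrt((pts[, 1] - cx)^2 + (pts[, 2] - cy)^2) <= r + tol)
  }
  best <- list(radius = Inf)
  if (n == 1L) return(list(center = pts[1, ], radius = 0))
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    cx <- (pts[i, 1] + pts[j, 1]) / 2; cy <- (pts[i, 2] + pts[j, 2]) / 2
    r <- sqrt((pts[i, 1] - pts[j, 1])^2 + (pts[i, 2] - pts[j, 2])^2) / 2
    if (r < best$radius && covers(cx, cy, r)) best <- list(center = c(cx, cy), radius = r)
  }
  if (n >= 3L) for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
    p <- pts[i, ]; q <- pts[j, ]; s <- pts[k, ]
    d <- 2 * (p[1] * (q[2] - s[2]) + q[1] * (s[2] - p[2]) + s[1] * (p[2] - q[2]))
    if (abs(d) < 1e-12) next
    p2 <- sum(p^2); q2 <- sum(q^2); s2 <- sum(s^2)
    cx <- (p2 * (q[2] - s[2]) + q2 * (s[2] - p[2]) + s2 * (p[2] - q[2])) / d
    cy <- (p2 * (s[1] - q[1]) + q2 * (p[1] - s[1]) + s2 * (q[1] - p[1])) / d
    r <- sqrt((p[1] - cx)^2 + (p[2] - cy)^2)
    if (r < best$radius && covers(cx, cy, r)) best <- list(center = c(cx, cy), radius = r)
  }
  best
}

# Minimum-area enclosing rectangle: rotate the full point set by every
# hull-edge angle with an explicit rotation matrix and take the smallest
# axis-aligned bounding box over those orientations.
oracle_mer_area <- function(pts) {
  hp <- if (nrow(pts) > 2) pts[grDevices::chull(pts), , drop = FALSE] else pts
  nh <- nrow(hp)
  if (nh <= 2) {
    d <- if (nh == 2) sqrt(sum((hp[1, ] - hp[2, ])^2)) else 0
    return(0)
  }
  best <- Inf
  for (i in seq_len(nh)) {
    e <- hp[i %% nh + 1, ] - hp[i, ]
    th <- atan2(e[2], e[1])
    Rm <- matrix(c(cos(-th), sin(-th), -sin(-th), cos(-th)), 2, 2)
    rot <- pts %*% t(Rm)
    area <- diff(range(rot[, 1])) * diff(range(rot[, 2]))
    best <- min(best, area)
  }
  best
}

# Majority filter: literal per-pixel neighbourhood count with edge
# replication.
oracle_median_filter <- function(mask, size) {
  k <- (size - 1) %/% 2
  n <- nrow(mask); m <- ncol(mask)
  out <- mask
  for (i in 1:n) for (j in 1:m) {
    ri <- pmin(pmax((i - k):(i + k), 1), n)
    ci <- pmin(pmax((j - k):(j + k), 1), m)
    out[i, j] <- as.integer(2 * sum(mask[ri, ci]) > size * size)
  }
  out
}

# Set-based Minkowski morphology on explicit pixel sets.
oracle_disk <- function(radius) {
  g <- expand.grid(dy = -radius:radius, dx = -radius:radius)
  g[g$dx^2 + g$dy^2 <= radius^2, ]
}

oracle_erode <- function(mask, radius) {
  offs <- oracle_disk(radius)
  n <- nrow(mask); m <- ncol(mask)
  out <- matrix(0L, n, m)
  for (i in 1:n) for (j in 1:m) {
    ok <- TRUE
    for (t in seq_len(nrow(offs))) {
      ii <- i + offs$dy[t]; jj <- j + offs$dx[t]
      if (ii < 1 || ii > n || jj < 1 || jj > m || mask[ii, jj] == 0L) { ok <- FALSE; break }
    }
    out[i, j] <- as.integer(ok)
  }
  out
}

oracle_dilate <- function(mask, radius) {
  offs <- oracle_disk(radius)
  n <- nrow(mask); m <- ncol(mask)
  out <- matrix(0L, n, m)
  for (i in 1:n) for (j in 1:m) {
    hit <- FALSE
    for (t in seq_len(nrow(offs))) {
      ii <- i + offs$dy[t]; jj <- j + offs$dx[t]
      if (ii >= 1 && ii <= n && jj >= 1 && jj <= m && mask[ii, jj] == 1L) { hit <- TRUE; break }
    }
    out[i, j] <- as.integer(hit)
  }
  out
}

# Closed-form Deming regression slope (error-variance ratio lambda).
oracle_deming_slope <- function(x, y, lambda = 1) {
  sxx <- sum((x - mean(x))^2); syy <- sum((y - mean(y))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  (syy - lambda * sxx + sqrt((syy - lambda * sxx)^2 + 4 * lambda * sxy^2)) /
    (2 * sxy)
}

# Scene used throughout the segmentation tests: compact frame, the default
# plant/soil/distractor palette.
test_scene <- function(seed, ...) {
  render_scene(scene_spec(width = 160, height = 120, plant_radius = 35,
                          seed = seed, ...))
}

# Random small mask with n foreground pixels in a frame.
random_mask <- function(n, h = 40, w = 40) {
  m <- matrix(0L, h, w)
  m[sample(h * w, n)] <- 1L
  m
}

# Ground-truth models used by the fitting tests: plausible coefficient
# magnitudes per family (the exponential one carries the published optimal
# Lab coefficients).
truth_for <- function(fam, gs_variant = "MCC") {
  canopy_model(
    model_spec(fam, "Lab", gs_variant),
    a = switch(fam,
      linear = c(-0.05, -0.4, 0.3),
      reciprocal = c(2.7, -22.4, -4.8),
      power = c(-1.6, 0.65, -0.4),
      logarithmic = c(0.8, 1.6, -1.3),
      exponential = c(-4.471, -11.927, -2.782)),
    b0 = if (fam == "exponential") -4.274 else -4,
    a0 = switch(fam, exponential = 237.374, power = , logarithmic = 50),
    b1 = if (gs_variant != "none") { if (fam == "exponential") 26.248 else 26 },
    normalizers = if (fam == "exponential") c(100, 200, 40))
}
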