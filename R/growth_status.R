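#' Growth-status indicators
#'
#' Nitrogen supply affects aboveground biomass as well as leaf colour, so
#' canopy *shape* carries signal beyond colour means. The growth-status
#' indicators quantify how densely the segmented plant fills its enclosing
#' shape: `GS_MER = S_p / MER_p` and `GS_MCC = S_p / MCC_p`, where `S_p` is
#' the plant pixel count and `MER_p` / `MCC_p` are the pixel counts of the
#' minimum enclosing rectangle and the minimum circumscribed circle of the
#' plant pixels. Both ratios are dimensionless and scale-free.
#'
#' Geometry is computed on pixel centres in a 0-based frame (x = column,
#' y = row). Enclosing-shape pixel counts are rasterized counts of integer
#' pixel centres inside (or on) the shape; an enclosing shape may overhang
#' the frame, in which case its full lattice count is used, keeping the
#' ratios geometry-true for plants near the image border.
#'
#' @name growth_status_indicators
NULL

mask_points <- function(mask) {
  idx <- which(mask != 0, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("mask has no foreground pixels", call. = FALSE)
  cbind(x = idx[, 2] - 1, y = idx[, 1] - 1)
}

circle_from2 <- function(p, q) {
  c0 <- (p + q) / 2
  list(center = c0, radius = sqrt(sum((p - q)^2)) / 2)
}

circle_from3 <- function(p, q, r) {
  # circumcircle; returns NULL when the points are (near-)collinear
  d <- 2 * (p[1] * (q[2] - r[2]) + q[1] * (r[2] - p[2]) + r[1] * (p[2] - q[2]))
  if (abs(d) < 1e-12) return(NULL)
  p2 <- sum(p^2); q2 <- sum(q^2); r2 <- sum(r^2)
  ux <- (p2 * (q[2] - r[2]) + q2 * (r[2] - p[2]) + r2 * (p[2] - q[2])) / d
  uy <- (p2 * (r[1] - q[1]) + q2 * (p[1] - r[1]) + r2 * (q[1] - p[1])) / d
  ctr <- c(ux, uy)
  list(center = ctr, radius = sqrt(sum((p - ctr)^2)))
}

in_circle <- function(pt, circ, tol) {
  sqrt(sum((pt - circ$center)^2)) <= circ$radius + tol
}

welzl_mec <- function(pts) {
  # Move-to-front Welzl on a fixed point order; exact for any order, with
  # expected-linear behaviour on shuffled input. Callers pass convex-hull
  # vertices, so n is small and the order is immaterial for speed.
  tol <- 1e-10
  n <- nrow(pts)
  circ <- list(center = pts[1, ], radius = 0)
  if (n == 1L) return(circ)
  for (i in 2:n) {
    if (in_circle(pts[i, ], circ, tol * (1 + circ$radius))) next
    circ <- list(center = pts[i, ], radius = 0)
    if (i >= 2) for (j in 1:(i - 1)) {
      if (in_circle(pts[j, ], circ, tol * (1 + circ$radius))) next
      circ <- circle_from2(pts[i, ], pts[j, ])
      if (j >= 2) for (k in 1:(j - 1)) {
        if (in_circle(pts[k, ], circ, tol * (1 + circ$radius))) next
        c3 <- circle_from3(pts[i, ], pts[j, ], pts[k, ])
        if (is.null(c3)) {
          # collinear triple: smallest circle is the diameter of the two
          # farthest of the three points
          trio <- rbind(pts[i, ], pts[j, ], pts[k, ])
          dd <- as.matrix(stats::dist(trio))
          w <- which(dd == max(dd), arr.ind = TRUE)[1, ]
          c3 <- circle_from2(trio[w[1], ], trio[w[2], ])
        }
        circ <- c3
      }
    }
  }
  circ
}

hull_points <- function(pts) {
  if (nrow(pts) <= 2L) return(pts)
  h <- grDevices::chull(pts[, 1], pts[, 2])
  pts[h, , drop = FALSE]
}

count_in_circle <- function(circ, tol = 1e-7) {
  r <- circ$radius + tol
  xs <- ceiling(circ$center[1] - r):floor(circ$center[1] + r)
  ys <- ceiling(circ$center[2] - r):floor(circ$center[2] + r)
  if (length(xs) == 0L || length(ys) == 0L) return(0L)
  dx2 <- (xs - circ$center[1])^2
  dy2 <- (ys - circ$center[2])^2
  sum(outer(dy2, dx2, `+`) <= r^2)
}

#' Minimum circumscribed circle of a mask's foreground
#'
#' Smallest circle containing all foreground pixel centres, computed by
#' Welzl's algorithm on the convex hull. The rasterized pixel count
#' `mcc_p` is the number of integer pixel centres within the radius.
#'
#' @param mask 0/1 matrix with at least one foreground pixel.
#' @return list with `center` (x, y), `radius`, `mcc_p` and the continuous
#'   `area`.
#' @export
min_enclosing_circle <- function(mask) {
  pts <- mask_points(mask)
  circ <- welzl_mec(hull_points(pts))
  cnt <- count_in_circle(circ)
  list(center = unname(circ$center), radius = unname(circ$radius),
       mcc_p = max(cnt, nrow(pts)), area = pi * circ$radius^2)
}

rect_at_angle <- function(pts, theta) {
  u <- c(cos(theta), sin(theta)); v <- c(-u[2], u[1])
  a <- pts %*% u; b <- pts %*% v
  list(theta = theta, u = u, v = v,
       a1 = min(a), a2 = max(a), b1 = min(b), b2 = max(b),
       area = (max(a) - min(a)) * (max(b) - min(b)))
}

#' Minimum-area enclosing rectangle of a mask's foreground
#'
#' Minimum-area arbitrarily-oriented rectangle over foreground pixel
#' centres (rotating-calipers over convex-hull edge orientations: the
#' optimal rectangle has a side collinear with a hull edge). With
#' `rotated = FALSE` the axis-aligned bounding box is returned instead.
#' `mer_p` is the rasterized count of integer pixel centres inside or on
#' the rectangle.
#'
#' @param mask 0/1 matrix with at least one foreground pixel.
#' @param rotated use the rotated (minimum-area) rectangle (default) or the
#'   axis-aligned box.
#' @return list with `corners` (4 x 2 matrix), continuous `area` and
#'   `mer_p`.
#' @export
min_enclosing_rectangle <- function(mask, rotated = TRUE) {
  pts <- mask_points(mask)
  hp <- hull_points(pts)
  if (!rotated || nrow(hp) == 1L) {
    best <- rect_at_angle(hp, 0)
  } else if (nrow(hp) == 2L) {
    e <- hp[2, ] - hp[1, ]               # collinear set: align with it
    best <- rect_at_angle(hp, atan2(e[2], e[1]))
  } else {
    nh <- nrow(hp)
    edges <- rbind(hp[c(2:nh, 1), ] - hp)
    thetas <- atan2(edges[, 2], edges[, 1])
    best <- NULL
    for (th in thetas) {
      r <- rect_at_angle(hp, th)
      if (is.null(best) || r$area < best$area - 1e-15) best <- r
    }
  }
  corners <- rbind(
    best$a1 * best$u + best$b1 * best$v,
    best$a2 * best$u + best$b1 * best$v,
    best$a2 * best$u + best$b2 * best$v,
    best$a1 * best$u + best$b2 * best$v
  )
  colnames(corners) <- c("x", "y")
  cnt <- count_in_rect(best)
  list(corners = corners, area = best$area,
       mer_p = max(cnt, nrow(pts)))
}

count_in_rect <- function(rect, tol = 1e-7) {
  corn <- rbind(rect$a1 * rect$u + rect$b1 * rect$v,
                rect$a2 * rect$u + rect$b1 * rect$v,
                rect$a2 * rect$u + rect$b2 * rect$v,
                rect$a1 * rect$u + rect$b2 * rect$v)
  xr <- range(corn[, 1]); yr <- range(corn[, 2])
  xs <- ceiling(xr[1] - tol):floor(xr[2] + tol)
  ys <- ceiling(yr[1] - tol):floor(yr[2] + tol)
  if (length(xs) == 0L || length(ys) == 0L) return(0L)
  g <- cbind(rep(xs, times = length(ys)), rep(ys, each = length(xs)))
  a <- g %*% rect$u; b <- g %*% rect$v
  sum(a >= rect$a1 - tol & a <= rect$a2 + tol &
      b >= rect$b1 - tol & b <= rect$b2 + tol)
}

#' Growth status of a segmented plant
#'
#' @param mask final segmentation mask (0/1 matrix, nonempty).
#' @param rotated_rect use the rotated minimum-area rectangle (default) or
#'   the axis-aligned bounding box for `GS_MER`.
#' @param clamp clamp the ratios to `(0, 1]` (default); rasterization at
#'   the boundary can otherwise push a ratio marginally above 1.
#' @return a one-row tibble with `s_p`, `mer_p`, `mcc_p`, `gs_mer`,
#'   `gs_mcc`, plus the circle (`mcc_cx`, `mcc_cy`, `mcc_r`).
#' @examples
#' m <- matrix(0L, 50, 50); m[11:40, 11:40] <- 1L
#' growth_status(m)  # solid square: gs_mer = 1
#' @export
growth_status <- function(mask, rotated_rect = TRUE, clamp = TRUE) {
  s_p <- sum(mask != 0)
  if (s_p == 0L) stop("mask has no foreground pixels", call. = FALSE)
  circ <- min_enclosing_circle(mask)
  rect <- min_enclosing_rectangle(mask, rotated = rotated_rect)
  gs_mer <- s_p / rect$mer_p
  gs_mcc <- s_p / circ$mcc_p
  if (clamp) {
    gs_mer <- min(gs_mer, 1)
    gs_mcc <- min(gs_mcc, 1)
  }
  tibble::tibble(
    s_p = s_p, mer_p = rect$mer_p, mcc_p = circ$mcc_p,
    gs_mer = gs_mer, gs_mcc = gs_mcc,
    mcc_cx = circ$center[1], mcc_cy = circ$center[2], mcc_r = circ$radius
  )
}
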