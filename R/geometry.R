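# Low-level polyline geometry shared by the synthetic generator and the
# flat-map module. All coordinates are continuous pixel coordinates:
# 0-based, origin at the top-left pixel center, x rightward, y downward.

cumulative_arc <- function(v) {
  d <- sqrt(diff(v[, 1])^2 + diff(v[, 2])^2)
  c(0, cumsum(d))
}

# Linear interpolation of an ordered polyline to (approximately) uniform
# arc-length spacing. Returns a matrix of vertices including both endpoints.
resample_polyline <- function(v, spacing = 1) {
  stopifnot(is.matrix(v), ncol(v) == 2, nrow(v) >= 2, spacing > 0)
  s <- cumulative_arc(v)
  total <- s[length(s)]
  if (total <= 0) stop_cf("polyline has zero total length")
  n_out <- max(2L, as.integer(round(total / spacing)) + 1L)
  t_out <- seq(0, total, length.out = n_out)
  cbind(
    stats::approx(s, v[, 1], xout = t_out, ties = "ordered")$y,
    stats::approx(s, v[, 2], xout = t_out, ties = "ordered")$y
  )
}

# Natural-spline curve through ordered control points, returned as a dense
# polyline resampled to `spacing` px. Parameterised by chord length.
spline_through <- function(control, spacing = 1) {
  stopifnot(is.matrix(control), ncol(control) == 2, nrow(control) >= 2)
  if (nrow(control) == 2) return(resample_polyline(control, spacing))
  s <- cumulative_arc(control)
  t_dense <- seq(0, s[length(s)], by = spacing / 2)
  x <- stats::spline(s, control[, 1], xout = t_dense)$y
  y <- stats::spline(s, control[, 2], xout = t_dense)$y
  resample_polyline(cbind(x, y), spacing)
}

# Point on a dense polyline at arc length `a` (clamped), plus unit tangent
# and leftward normal there. Vectorised over `a`.
polyline_point_at <- function(v, a) {
  s <- cumulative_arc(v)
  total <- s[length(s)]
  a <- pmin(pmax(a, 0), total)
  seg <- pmin(findInterval(a, s, rightmost.closed = TRUE), nrow(v) - 1L)
  frac <- (a - s[seg]) / pmax(s[seg + 1L] - s[seg], .Machine$double.eps)
  px <- v[seg, 1] + frac * (v[seg + 1L, 1] - v[seg, 1])
  py <- v[seg, 2] + frac * (v[seg + 1L, 2] - v[seg, 2])
  tx <- v[seg + 1L, 1] - v[seg, 1]
  ty <- v[seg + 1L, 2] - v[seg, 2]
  len <- sqrt(tx^2 + ty^2)
  tx <- tx / len; ty <- ty / len
  # leftward normal relative to travel direction (y axis points down)
  list(point = cbind(px, py), tangent = cbind(tx, ty),
       normal = cbind(ty, -tx))
}

# Nearest-point projection of points onto a polyline: for every point the
# arc length (px, from the first vertex) of the closest point on any
# segment (orthogonal projection clamped to segment ends) and the Euclidean
# distance. Ties broken toward the smaller arc position.
project_onto_polyline <- function(points, v) {
  stopifnot(is.matrix(points), ncol(points) == 2)
  s <- cumulative_arc(v)
  nseg <- nrow(v) - 1L
  if (nseg < 1L) stop_cf("degenerate polyline: need at least 2 vertices")
  px <- points[, 1]; py <- points[, 2]
  best_d2 <- rep(Inf, nrow(points))
  best_arc <- rep(NA_real_, nrow(points))
  eps <- 1e-9
  for (i in seq_len(nseg)) {
    ax <- v[i, 1]; ay <- v[i, 2]
    bx <- v[i + 1L, 1]; by <- v[i + 1L, 2]
    dx <- bx - ax; dy <- by - ay
    L2 <- dx * dx + dy * dy
    if (L2 <= 0) next
    t <- pmin(pmax(((px - ax) * dx + (py - ay) * dy) / L2, 0), 1)
    qx <- ax + t * dx; qy <- ay + t * dy
    d2 <- (px - qx)^2 + (py - qy)^2
    arc <- s[i] + t * sqrt(L2)
    upd <- d2 < best_d2 - eps |
      (abs(d2 - best_d2) <= eps & arc < best_arc)
    if (any(upd)) {
      best_d2[upd] <- d2[upd]
      best_arc[upd] <- arc[upd]
    }
  }
  list(arc = best_arc, distance = sqrt(best_d2))
}

# Even-odd (crossing-number) point-in-polygon with boundary points counted
# as inside. Vectorised over points; `poly` is an open ring (first vertex
# not repeated).
points_in_polygon <- function(points, poly, eps = 1e-9) {
  px <- points[, 1]; py <- points[, 2]
  n <- nrow(poly)
  inside <- rep(FALSE, length(px))
  on_edge <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    # boundary test: point within eps of segment i-j
    dx <- xj - xi; dy <- yj - yi
    L2 <- dx * dx + dy * dy
    if (L2 > 0) {
      t <- pmin(pmax(((px - xi) * dx + (py - yi) * dy) / L2, 0), 1)
      d2 <- (px - (xi + t * dx))^2 + (py - (yi + t * dy))^2
      on_edge <- on_edge | d2 <= eps^2
    } else {
      on_edge <- on_edge | ((px - xi)^2 + (py - yi)^2 <= eps^2)
    }
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside | on_edge
}

# TRUE if the closed polygon (open ring) is simple, i.e. no two
# non-adjacent edges intersect.
polygon_is_simple <- function(poly) {
  n <- nrow(poly)
  if (n < 3) return(FALSE)
  seg <- function(i) {
    j <- if (i == n) 1L else i + 1L
    rbind(poly[i, ], poly[j, ])
  }
  segs_intersect <- function(p1, p2, p3, p4) {
    d <- function(a, b, c) {
      (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
    }
    d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
    d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
    if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
        ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) return(TRUE)
    on_seg <- function(a, b, c) {
      min(a[1], b[1]) - 1e-12 <= c[1] && c[1] <= max(a[1], b[1]) + 1e-12 &&
        min(a[2], b[2]) - 1e-12 <= c[2] && c[2] <= max(a[2], b[2]) + 1e-12
    }
    (d1 == 0 && on_seg(p3, p4, p1)) || (d2 == 0 && on_seg(p3, p4, p2)) ||
      (d3 == 0 && on_seg(p1, p2, p3)) || (d4 == 0 && on_seg(p1, p2, p4))
  }
  for (i in seq_len(n - 2L)) {
    a <- seg(i)
    jmax <- if (i == 1L) n - 1L else n
    if (i + 2L > jmax) next
    for (j in (i + 2L):jmax) {
      b <- seg(j)
      if (segs_intersect(a[1, ], a[2, ], b[1, ], b[2, ])) return(FALSE)
    }
  }
  TRUE
}
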