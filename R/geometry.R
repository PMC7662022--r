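# Planar geometry primitives.
#
# All coordinates are metres in a single projected CRS. Polygons are two-column
# (x, y) matrices of distinct vertices, ring not closed (first vertex is not
# repeated); counter-clockwise orientation is canonical.

#' Signed polygon area (shoelace formula)
#'
#' Positive for counter-clockwise rings.
#'
#' @param poly two-column matrix of vertices (ring not closed).
#' @return signed area in square metres.
#' @keywords internal
#' @noRd
signed_area <- function(poly) {
  n <- nrow(poly)
  if (is.null(n) || n < 3) return(0)
  x <- poly[, 1]; y <- poly[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

poly_area <- function(poly) abs(signed_area(poly))

#' Force counter-clockwise orientation
#' @noRd
ccw <- function(poly) {
  if (signed_area(poly) < 0) poly[rev(seq_len(nrow(poly))), , drop = FALSE] else poly
}

#' Drop repeated and collinear vertices; close-ring duplicates removed.
#' @noRd
clean_ring <- function(poly, eps = 1e-9) {
  n <- nrow(poly)
  if (n >= 2 && all(abs(poly[1, ] - poly[n, ]) <= eps)) poly <- poly[-n, , drop = FALSE]
  n <- nrow(poly)
  if (n < 3) return(poly)
  keep <- rep(TRUE, n)
  for (i in seq_len(n)) {
    p <- poly[if (i == 1) n else i - 1, ]
    q <- poly[i, ]
    r <- poly[if (i == n) 1 else i + 1, ]
    if (sqrt(sum((q - p)^2)) <= eps) { keep[i] <- FALSE; next }
    cr <- (q[1] - p[1]) * (r[2] - p[2]) - (q[2] - p[2]) * (r[1] - p[1])
    len <- sqrt(sum((r - p)^2))
    if (len > 0 && abs(cr) / len <= eps) keep[i] <- FALSE
  }
  poly[keep, , drop = FALSE]
}

#' Does a simple polygon self-intersect?
#'
#' O(n^2) check over non-adjacent edge pairs; fine at fixture scale.
#' @noRd
ring_self_intersects <- function(poly, eps = 1e-12) {
  n <- nrow(poly)
  if (n < 4) return(FALSE)
  seg <- function(i) rbind(poly[i, ], poly[if (i == n) 1 else i + 1, ])
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      # skip adjacent edges (shared vertex)
      if (j == i + 1 || (i == 1 && j == n)) next
      if (segments_cross(seg(i), seg(j), eps)) return(TRUE)
    }
  }
  FALSE
}

# proper or improper crossing of two segments (each a 2x2 matrix)
segments_cross <- function(s1, s2, eps = 1e-12) {
  !is.null(segment_intersection(s1[1, ], s1[2, ], s2[1, ], s2[2, ], eps))
}

#' Intersection point of segments p1-p2 and p3-p4, or NULL
#'
#' Collinear overlaps return NULL (callers treat those as shared edges,
#' not crossings).
#' @noRd
segment_intersection <- function(p1, p2, p3, p4, eps = 1e-12) {
  d1 <- p2 - p1; d2 <- p4 - p3
  denom <- d1[1] * d2[2] - d1[2] * d2[1]
  if (abs(denom) < eps) return(NULL)
  t <- ((p3[1] - p1[1]) * d2[2] - (p3[2] - p1[2]) * d2[1]) / denom
  u <- ((p3[1] - p1[1]) * d1[2] - (p3[2] - p1[2]) * d1[1]) / denom
  tol <- 1e-9
  if (t < -tol || t > 1 + tol || u < -tol || u > 1 + tol) return(NULL)
  p1 + t * d1
}

#' Points in polygon, boundary inclusive (closed polygon convention)
#'
#' Ray-casting with an explicit on-edge test; vectorised over points.
#'
#' @param px,py point coordinates (equal-length numeric vectors).
#' @param poly polygon vertex matrix.
#' @param eps boundary snap distance in metres.
#' @return logical vector.
#' @keywords internal
#' @noRd
points_in_polygon <- function(px, py, poly, eps = 1e-9) {
  n <- nrow(poly)
  m <- length(px)
  inside <- rep(FALSE, m)
  on_edge <- rep(FALSE, m)
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    dx <- xj - xi; dy <- yj - yi
    len2 <- dx * dx + dy * dy
    if (len2 > 0) {
      tproj <- ((px - xi) * dx + (py - yi) * dy) / len2
      tproj <- pmin(pmax(tproj, 0), 1)
      ddx <- px - (xi + tproj * dx); ddy <- py - (yi + tproj * dy)
      on_edge <- on_edge | (ddx * ddx + ddy * ddy <= eps * eps)
    }
    crosses <- ((yi > py) != (yj > py))
    if (any(crosses)) {
      xint <- xi + (py - yi) * (xj - xi) / (yj - yi)
      inside <- xor(inside, crosses & (px < xint))
    }
    j <- i
  }
  inside | on_edge
}

#' Clip a polygon to a convex polygon (Sutherland-Hodgman)
#'
#' Subject may be any simple polygon; clip must be convex. Exact for the
#' zone shapes the package constructs (buffers, admin tiles).
#'
#' @return clipped vertex matrix, or NULL when the intersection is empty.
#' @keywords internal
#' @noRd
clip_polygon_convex <- function(subject, clip, eps = 1e-9) {
  clip <- ccw(clip)
  out <- ccw(subject)
  nc <- nrow(clip)
  a <- clip[nc, ]
  for (i in seq_len(nc)) {
    b <- clip[i, ]
    inp <- out
    if (is.null(inp) || nrow(inp) < 3) return(NULL)
    ex <- b[1] - a[1]; ey <- b[2] - a[2]
    m <- nrow(inp)
    side <- ex * (inp[, 2] - a[2]) - ey * (inp[, 1] - a[1])  # >=0 is inside
    res <- vector("list", 2L * m)
    k <- 0L
    prev <- m
    for (v in seq_len(m)) {
      P <- inp[prev, ]; Q <- inp[v, ]
      Pin <- side[prev] >= -eps; Qin <- side[v] >= -eps
      if (Qin) {
        if (!Pin) {
          ip <- line_edge_intersection(P, Q, a, b)
          if (!is.null(ip)) { k <- k + 1L; res[[k]] <- ip }
        }
        k <- k + 1L; res[[k]] <- Q
      } else if (Pin) {
        ip <- line_edge_intersection(P, Q, a, b)
        if (!is.null(ip)) { k <- k + 1L; res[[k]] <- ip }
      }
      prev <- v
    }
    if (k < 3L) return(NULL)
    out <- clean_ring(do.call(rbind, res[seq_len(k)]))
    a <- b
  }
  if (is.null(out) || nrow(out) < 3 || poly_area(out) <= eps) NULL else out
}

# intersection of segment P-Q with the infinite line through a-b
line_edge_intersection <- function(P, Q, a, b) {
  d <- Q - P; e <- b - a
  denom <- d[1] * e[2] - d[2] * e[1]
  if (abs(denom) < 1e-300) return(NULL)
  t <- ((a[1] - P[1]) * e[2] - (a[2] - P[2]) * e[1]) / denom
  P + t * d
}

#' Is a polygon convex?
#' @noRd
is_convex <- function(poly, eps = 1e-9) {
  poly <- clean_ring(poly)
  n <- nrow(poly)
  if (n < 3) return(FALSE)
  sgn <- 0
  for (i in seq_len(n)) {
    p <- poly[i, ]
    q <- poly[if (i == n) 1 else i + 1, ]
    r <- poly[if (i >= n - 1) i + 2 - n else i + 2, ]
    cr <- (q[1] - p[1]) * (r[2] - q[2]) - (q[2] - p[2]) * (r[1] - q[1])
    if (abs(cr) > eps) {
      if (sgn == 0) sgn <- sign(cr)
      else if (sign(cr) != sgn) return(FALSE)
    }
  }
  TRUE
}

#' Regular-polygon approximation of a circle
#'
#' Vertices lie on the true circle; with the default 128 segments the area
#' deficit relative to pi r^2 is 0.04%.
#' @noRd
circle_polygon <- function(cx, cy, radius, segments = 128L) {
  theta <- seq(0, 2 * pi, length.out = segments + 1L)[-(segments + 1L)]
  cbind(cx + radius * cos(theta), cy + radius * sin(theta))
}

#' Axis-aligned rectangle polygon from corner coordinates
#' @noRd
rect_polygon <- function(xmin, ymin, xmax, ymax) {
  cbind(c(xmin, xmax, xmax, xmin), c(ymin, ymin, ymax, ymax))
}

#' Length of segment p-q inside a convex polygon (Cyrus-Beck clipping)
#' @noRd
segment_length_in_convex <- function(p, q, poly) {
  poly <- ccw(poly)
  n <- nrow(poly)
  t0 <- 0; t1 <- 1
  d <- q - p
  j <- n
  for (i in seq_len(n)) {
    a <- poly[j, ]; b <- poly[i, ]; j <- i
    # inward normal of edge a->b for a CCW polygon
    nx <- -(b[2] - a[2]); ny <- b[1] - a[1]
    denom <- nx * d[1] + ny * d[2]
    num <- nx * (a[1] - p[1]) + ny * (a[2] - p[2])
    if (abs(denom) < 1e-300) {
      if (num > 0) return(0)  # parallel and outside
    } else {
      t <- num / denom
      if (denom > 0) t0 <- max(t0, t) else t1 <- min(t1, t)
      if (t0 > t1) return(0)
    }
  }
  (t1 - t0) * sqrt(sum(d^2))
}

#' Total network length inside a convex polygon
#' @noRd
network_length_in_convex <- function(network, poly) {
  total <- 0
  for (pl in network$segments) {
    for (i in seq_len(nrow(pl) - 1))
      total <- total + segment_length_in_convex(pl[i, ], pl[i + 1, ], poly)
  }
  total
}

#' Bounding box of a polygon: c(xmin, ymin, xmax, ymax)
#' @noRd
poly_bbox <- function(poly) {
  c(min(poly[, 1]), min(poly[, 2]), max(poly[, 1]), max(poly[, 2]))
}

bboxes_overlap <- function(b1, b2) {
  !(b1[3] < b2[1] || b2[3] < b1[1] || b1[4] < b2[2] || b2[4] < b1[2])
}
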