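# Minimal planar polygon-rectangle intersection used for range-vs-cell
# overlap. Closed-set convention throughout: touching at an edge or corner
# counts as intersecting. Rings are n x 2 matrices (lon, lat), implicitly
# closed; polygons with holes are not supported (species ranges are unions
# of simple rings).

# Is point p on segment (a, b)? Collinear within tolerance and inside the
# bounding box of the segment.
point_on_segment <- function(p, a, b, eps = 1e-12) {
  cross <- (b[1] - a[1]) * (p[2] - a[2]) - (b[2] - a[2]) * (p[1] - a[1])
  if (abs(cross) > eps * max(1, abs(b[1] - a[1]), abs(b[2] - a[2]))) {
    return(FALSE)
  }
  p[1] >= min(a[1], b[1]) - eps && p[1] <= max(a[1], b[1]) + eps &&
    p[2] >= min(a[2], b[2]) - eps && p[2] <= max(a[2], b[2]) + eps
}

# Even-odd point-in-polygon; boundary points count as inside.
point_in_ring <- function(p, ring) {
  n <- nrow(ring)
  j <- n
  inside <- FALSE
  for (i in seq_len(n)) {
    a <- ring[i, ]; b <- ring[j, ]
    if (point_on_segment(p, a, b)) return(TRUE)
    if ((a[2] > p[2]) != (b[2] > p[2])) {
      xint <- a[1] + (p[2] - a[2]) / (b[2] - a[2]) * (b[1] - a[1])
      if (p[1] < xint) inside <- !inside
    }
    j <- i
  }
  inside
}

# Do closed segments (p1, p2) and (q1, q2) intersect (touching included)?
segments_intersect <- function(p1, p2, q1, q2, eps = 1e-12) {
  orient <- function(a, b, c) {
    v <- (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
    if (abs(v) <= eps) 0 else sign(v)
  }
  o1 <- orient(p1, p2, q1); o2 <- orient(p1, p2, q2)
  o3 <- orient(q1, q2, p1); o4 <- orient(q1, q2, p2)
  if (o1 != o2 && o3 != o4) return(TRUE)
  (o1 == 0 && point_on_segment(q1, p1, p2)) ||
    (o2 == 0 && point_on_segment(q2, p1, p2)) ||
    (o3 == 0 && point_on_segment(p1, q1, q2)) ||
    (o4 == 0 && point_on_segment(p2, q1, q2))
}

# Does ring intersect the axis-aligned rectangle c(xmin, ymin, xmax, ymax)?
ring_intersects_rect <- function(ring, rect) {
  # quick reject on bounding boxes
  if (max(ring[, 1]) < rect[1] || min(ring[, 1]) > rect[3] ||
      max(ring[, 2]) < rect[2] || min(ring[, 2]) > rect[4]) {
    return(FALSE)
  }
  # any ring vertex inside (or on) the rectangle
  inside <- ring[, 1] >= rect[1] & ring[, 1] <= rect[3] &
    ring[, 2] >= rect[2] & ring[, 2] <= rect[4]
  if (any(inside)) return(TRUE)
  corners <- rbind(c(rect[1], rect[2]), c(rect[3], rect[2]),
                   c(rect[3], rect[4]), c(rect[1], rect[4]))
  # any rectangle corner inside the ring (covers rect fully inside polygon)
  for (i in 1:4) {
    if (point_in_ring(corners[i, ], ring)) return(TRUE)
  }
  # any edge crossing
  n <- nrow(ring)
  j <- n
  for (i in seq_len(n)) {
    for (k in 1:4) {
      k2 <- if (k == 4) 1L else k + 1L
      if (segments_intersect(ring[i, ], ring[j, ],
                             corners[k, ], corners[k2, ])) {
        return(TRUE)
      }
    }
    j <- i
  }
  FALSE
}

# Does a species range (list of rings) intersect the rectangle?
range_intersects_rect <- function(rings, rect) {
  for (ring in rings) {
    if (ring_intersects_rect(as.matrix(ring), rect)) return(TRUE)
  }
  FALSE
}
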