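# Planar geometry primitives used by the availability null and the landscape
# annotator. All coordinates are metres in the local planar projection.

#' Signed polygon area (shoelace formula)
#'
#' @param xy two-column matrix of vertices (open ring; the closing edge is
#'   implied). Positive for counter-clockwise rings.
#' @return signed area in squared coordinate units.
#' @keywords internal
polygon_signed_area <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  xs <- c(x[-1], x[1]); ys <- c(y[-1], y[1])
  sum(x * ys - xs * y) / 2
}

polygon_perimeter <- function(xy) {
  xs <- c(xy[-1, 1], xy[1, 1]); ys <- c(xy[-1, 2], xy[1, 2])
  sum(sqrt((xs - xy[, 1])^2 + (ys - xy[, 2])^2))
}

#' Even-odd point-in-polygon test (ray casting)
#'
#' Boundary points count as inside. Works for arbitrary simple polygons;
#' vectorised over query points.
#'
#' @param px,py query coordinates.
#' @param xy polygon ring (open).
#' @return logical vector.
#' @keywords internal
point_in_polygon <- function(px, py, xy) {
  n <- nrow(xy)
  x1 <- xy[, 1]; y1 <- xy[, 2]
  x2 <- c(x1[-1], x1[1]); y2 <- c(y1[-1], y1[1])
  inside <- logical(length(px))
  on_edge <- logical(length(px))
  for (e in seq_len(n)) {
    # on-segment check
    dx <- x2[e] - x1[e]; dy <- y2[e] - y1[e]
    cross <- (px - x1[e]) * dy - (py - y1[e]) * dx
    dot <- (px - x1[e]) * dx + (py - y1[e]) * dy
    len2 <- dx * dx + dy * dy
    on_edge <- on_edge | (abs(cross) < 1e-9 * max(1, sqrt(len2)) &
                            dot >= -1e-9 & dot <= len2 + 1e-9)
    # ray crossing (half-open rule avoids double counting at vertices)
    crosses <- ((y1[e] > py) != (y2[e] > py))
    xint <- x1[e] + (py - y1[e]) / (y2[e] - y1[e]) * dx
    inside <- xor(inside, crosses & !is.na(xint) & px < xint)
  }
  inside | on_edge
}

#' Distance from points to a polyline
#'
#' Minimum Euclidean distance from each query point to any segment of the
#' polyline `xy` (consecutive rows are segment endpoints).
#'
#' @keywords internal
dist_to_polyline <- function(px, py, xy) {
  if (nrow(xy) < 2) return(sqrt((px - xy[1, 1])^2 + (py - xy[1, 2])^2))
  best <- rep(Inf, length(px))
  for (e in seq_len(nrow(xy) - 1)) {
    ax <- xy[e, 1]; ay <- xy[e, 2]
    bx <- xy[e + 1, 1]; by <- xy[e + 1, 2]
    dx <- bx - ax; dy <- by - ay
    len2 <- dx * dx + dy * dy
    t <- if (len2 == 0) rep(0, length(px)) else
      pmin(1, pmax(0, ((px - ax) * dx + (py - ay) * dy) / len2))
    d <- sqrt((px - (ax + t * dx))^2 + (py - (ay + t * dy))^2)
    best <- pmin(best, d)
  }
  best
}

#' Distance from points to the boundary and interior test for a convex ring
#'
#' @return numeric vector: 0 for points inside or on the hull, otherwise the
#'   Euclidean distance to the hull boundary.
#' @keywords internal
dist_to_convex <- function(px, py, xy) {
  inside <- point_in_convex(px, py, xy)
  d <- rep(0, length(px))
  if (any(!inside)) {
    ring <- rbind(xy, xy[1, , drop = FALSE])
    d[!inside] <- dist_to_polyline(px[!inside], py[!inside], ring)
  }
  d
}

#' Point-in-convex-polygon via cross-product signs
#'
#' Ring must be counter-clockwise; boundary counts as inside.
#' @keywords internal
point_in_convex <- function(px, py, xy) {
  n <- nrow(xy)
  x2 <- c(xy[-1, 1], xy[1, 1]); y2 <- c(xy[-1, 2], xy[1, 2])
  ok <- rep(TRUE, length(px))
  for (e in seq_len(n)) {
    cr <- (x2[e] - xy[e, 1]) * (py - xy[e, 2]) -
          (y2[e] - xy[e, 2]) * (px - xy[e, 1])
    ok <- ok & (cr >= -1e-9)
  }
  ok
}
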