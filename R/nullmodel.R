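# Availability null model: per-trip minimum convex polygon, buffered by half
# the square root of its area, and five roost-anchored correlated random
# walks per trip resampled from the trip's own step lengths and turning
# angles.

#' Minimum convex polygon of a point set
#'
#' The convex hull of a trip's relocations — the classic home-range /
#' availability boundary.
#'
#' @param points two-column matrix of planar coordinates.
#' @return object of class `convex_region`: `vertices` (counter-clockwise,
#'   open ring), `area` (m^2, shoelace formula), `perimeter` (m).
#' @export
minimum_convex_polygon <- function(points) {
  if (is.data.frame(points)) points <- cbind(points$x, points$y)
  points <- unique(points[stats::complete.cases(points), , drop = FALSE])
  if (nrow(points) < 3) stop("degenerate geometry: need >= 3 distinct points")
  idx <- grDevices::chull(points)
  v <- points[idx, , drop = FALSE]
  a <- polygon_signed_area(v)
  if (abs(a) < 1e-9) stop("degenerate geometry: points are collinear")
  if (a < 0) v <- v[nrow(v):1, , drop = FALSE]  # enforce counter-clockwise
  structure(list(vertices = v, area = abs(a), perimeter = polygon_perimeter(v)),
            class = "convex_region")
}

#' @export
print.convex_region <- function(x, ...) {
  cat(sprintf("<convex_region: %d vertices, area %.3f km^2>\n",
              nrow(x$vertices), x$area / 1e6))
  invisible(x)
}

#' Buffer a convex region by half the square root of its area
#'
#' Minkowski dilation of the minimum convex polygon by
#' `d = 0.5 * sqrt(area)`, the availability zone within which random walks
#' are confined. For a convex polygon the dilated area has the closed form
#' `A + P*d + pi*d^2`.
#'
#' @param region a `convex_region`.
#' @param width buffer radius in metres; default `0.5 * sqrt(region$area)`.
#' @return object of class `buffered_region`: the source `region`,
#'   `buffer_width`, exact `area`, and a discretised `boundary` ring
#'   (vertex arcs sampled every ~6 degrees) for plotting/export.
#' @export
buffer_region <- function(region, width = 0.5 * sqrt(region$area)) {
  stopifnot(inherits(region, "convex_region"), width >= 0)
  structure(list(region = region, buffer_width = width,
                 area = region$area + region$perimeter * width + pi * width^2,
                 boundary = buffer_boundary(region$vertices, width)),
            class = "buffered_region")
}

# discretised boundary of the dilation: offset edges joined by vertex arcs
buffer_boundary <- function(v, d) {
  n <- nrow(v)
  nxt <- c(2:n, 1)
  out <- NULL
  for (i in seq_len(n)) {
    e_in <- v[i, ] - v[if (i == 1) n else i - 1, ]
    e_out <- v[nxt[i], ] - v[i, ]
    # outward normals (ring is CCW, outward normal is (dy, -dx) normalised)
    n_in <- c(e_in[2], -e_in[1]) / sqrt(sum(e_in^2))
    n_out <- c(e_out[2], -e_out[1]) / sqrt(sum(e_out^2))
    a0 <- atan2(n_in[2], n_in[1]); a1 <- atan2(n_out[2], n_out[1])
    if (a1 < a0) a1 <- a1 + 2 * pi  # normals rotate CCW around a CCW ring
    arc <- seq(a0, a1, length.out = max(2, ceiling(abs(a1 - a0) / 0.1) + 1))
    out <- rbind(out, cbind(v[i, 1] + d * cos(arc), v[i, 2] + d * sin(arc)))
  }
  out
}

#' @export
print.buffered_region <- function(x, ...) {
  cat(sprintf("<buffered_region: width %.1f m, area %.3f km^2>\n",
              x$buffer_width, x$area / 1e6))
  invisible(x)
}

#' Does a buffered region contain the points?
#'
#' A point is inside iff its distance to the source hull is at most the
#' buffer width. `region = NULL` means unconstrained (always TRUE).
#'
#' @param region a `buffered_region` or `NULL`.
#' @param points two-column matrix.
#' @return logical vector.
#' @export
region_contains <- function(region, points) {
  if (is.null(region)) return(rep(TRUE, nrow(points)))
  stopifnot(inherits(region, "buffered_region"))
  dist_to_convex(points[, 1], points[, 2], region$region$vertices) <=
    region$buffer_width + 1e-9
}

#' Empirical step-length and turning-angle pools of a trip
#'
#' Step length is the planar displacement between consecutive fixes; the
#' turning angle is the signed heading change between consecutive steps,
#' wrapped to (-pi, pi]. Junctions involving a zero-length step have no
#' defined heading change; they are excluded from the angle pool and counted
#' in the `"n_undefined_angles"` attribute.
#'
#' @param trip a `bat_trip`, or a two-column coordinate matrix.
#' @return list: `step_lengths` (n-1 values, m), `turning_angles` (up to
#'   n-2 values, radians), `headings` (per step), `start` (first point).
#' @export
empirical_steps <- function(trip) {
  xy <- if (inherits(trip, "bat_trip")) cbind(trip$fixes$x, trip$fixes$y) else trip
  if (nrow(xy) < 3) stop("need at least 3 fixes to define turning angles")
  dx <- diff(xy[, 1]); dy <- diff(xy[, 2])
  len <- sqrt(dx^2 + dy^2)
  head <- atan2(dy, dx)
  turn <- wrap_angle(diff(head))
  undef <- len[-length(len)] == 0 | len[-1] == 0
  list(step_lengths = len, turning_angles = turn[!undef], headings = head,
       start = xy[1, ],
       n_undefined_angles = sum(undef))
}

# wrap radians to (-pi, pi]
wrap_angle <- function(a) {
  w <- a %% (2 * pi)
  w[w > pi] <- w[w > pi] - 2 * pi
  w
}

# dead-reckon a path from a start point, initial heading, step lengths and
# turning angles (length(angles) == length(steps) - 1)
recompose_path <- function(start, heading0, steps, angles) {
  h <- cumsum(c(heading0, angles))
  cbind(start[1] + cumsum(c(0, steps * cos(h))),
        start[2] + cumsum(c(0, steps * sin(h))))
}

#' Constrained correlated random walks for one trip
#'
#' Builds `n_replicates` pseudo-trips with the same number of relocations as
#' the source trip: each walk starts at the roost with a uniform initial
#' heading and iteratively draws a step length and a turning angle,
#' independently and with replacement, from the trip's own empirical pools.
#' Walks are confined to the buffered minimum convex polygon: under
#' `mode = "reject"` a completed walk with any vertex outside is discarded
#' and regenerated (after `max_attempts` rejections the offending steps are
#' resampled individually as a fallback); `mode = "stepwise"` constrains
#' each step as it is drawn.
#'
#' @param trip a `bat_trip` (or coordinate matrix) supplying the pools and
#'   the relocation count.
#' @param region `buffered_region` from [buffer_region()], or `NULL` for an
#'   unconstrained walk.
#' @param roost planar `c(x, y)` start point; must lie inside `region`.
#' @param n_replicates number of walks (default 5).
#' @param seed integer; replicate `r` uses seed `seed + r`, so a (trip,
#'   seed) pair is fully reproducible.
#' @param mode `"reject"` (whole-walk rejection, the default null) or
#'   `"stepwise"`.
#' @param max_attempts whole-walk rejections tolerated before the per-step
#'   fallback (default 10000).
#' @param step_retries per-step resampling cap (default 1000); exhausting it
#'   raises an infeasible-region error.
#' @return list of class `pseudo_trips`; each element has `source_trip_id`,
#'   `replicate`, `seed`, `fixes` (matrix), `mode_used`.
#' @export
generate_crw <- function(trip, region, roost, n_replicates = 5, seed,
                         mode = c("reject", "stepwise"),
                         max_attempts = 10000, step_retries = 1000) {
  mode <- match.arg(mode)
  pools <- empirical_steps(trip)
  if (!length(pools$step_lengths) || !length(pools$turning_angles))
    stop("empty step or turning-angle pool")
  n_pts <- length(pools$step_lengths) + 1
  if (!all(region_contains(region, matrix(roost, ncol = 2))))
    stop("roost lies outside the buffered region")
  trip_id <- if (inherits(trip, "bat_trip")) trip$trip_id else "trip"
  reps <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    set.seed(seed + r)
    walk <- NULL
    mode_used <- mode
    if (mode == "reject") {
      for (att in seq_len(max_attempts)) {
        cand <- recompose_path(roost, stats::runif(1, -pi, pi),
                               sample(pools$step_lengths, n_pts - 1, replace = TRUE),
                               sample(pools$turning_angles, n_pts - 2, replace = TRUE))
        if (all(region_contains(region, cand))) { walk <- cand; break }
      }
      if (is.null(walk)) mode_used <- "reject+stepwise_fallback"
    }
    if (is.null(walk)) {
      walk <- crw_stepwise(pools, region, roost, n_pts, step_retries)
      if (mode == "stepwise") mode_used <- "stepwise"
    }
    reps[[r]] <- structure(list(source_trip_id = trip_id, replicate = r,
                                seed = seed + r, fixes = walk,
                                mode_used = mode_used),
                           class = "pseudo_trip")
  }
  structure(reps, class = "pseudo_trips")
}

crw_stepwise <- function(pools, region, roost, n_pts, step_retries,
                         walk_retries = 200) {
  for (w in seq_len(walk_retries)) {
    xy <- matrix(NA_real_, n_pts, 2)
    xy[1, ] <- roost
    h <- stats::runif(1, -pi, pi)
    stuck <- FALSE
    for (k in 2:n_pts) {
      ok <- FALSE
      for (try in seq_len(step_retries)) {
        hh <- if (k == 2) h else h + sample(pools$turning_angles, 1)
        L <- sample(pools$step_lengths, 1)
        cand <- xy[k - 1, ] + L * c(cos(hh), sin(hh))
        if (all(region_contains(region, matrix(cand, ncol = 2)))) {
          xy[k, ] <- cand; h <- hh; ok <- TRUE; break
        }
      }
      if (!ok) { stuck <- TRUE; break }  # cornered: restart the whole walk
    }
    if (!stuck) return(xy)
  }
  stop("infeasible region: no walk of ", n_pts, " relocations stayed inside ",
       "after ", walk_retries, " restarts")
}

#' @export
print.pseudo_trips <- function(x, ...) {
  cat(sprintf("<pseudo_trips: %d replicate(s) of %s, %d relocations each>\n",
              length(x), x[[1]]$source_trip_id, nrow(x[[1]]$fixes)))
  invisible(x)
}

#' Pseudo-trips as a fix-table data.frame
#'
#' @param pseudo a `pseudo_trips` list.
#' @return data.frame with `source_trip_id`, `replicate`, `x`, `y`.
#' @export
pseudo_trips_table <- function(pseudo) {
  do.call(rbind, lapply(pseudo, function(p)
    data.frame(source_trip_id = p$source_trip_id, replicate = p$replicate,
               x = p$fixes[, 1], y = p$fixes[, 2])))
}
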