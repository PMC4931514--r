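# Independent oracles and fixture builders. Everything here is deliberately
# written along a different route than the package code it checks.

# ---- solar: PSA solar-position algorithm (Blanco-Muriel et al. 2001) -------

psa_elevation <- function(time_utc, lon, lat) {
  jd <- as.numeric(time_utc) / 86400 + 2440587.5
  n <- jd - 2451545.0
  hour_utc <- (as.numeric(time_utc) %% 86400) / 3600
  omega <- 2.1429 - 0.0010394594 * n
  meanlong <- 4.8950630 + 0.017202791698 * n
  meananom <- 6.2400600 + 0.0172019699 * n
  ecl_long <- meanlong + 0.03341607 * sin(meananom) +
    0.00034894 * sin(2 * meananom) - 0.0001134 - 0.0000203 * sin(omega)
  ecl_obl <- 0.4090928 - 6.2140e-9 * n + 0.0000396 * cos(omega)
  ra <- atan2(cos(ecl_obl) * sin(ecl_long), cos(ecl_long)) %% (2 * pi)
  dec <- asin(sin(ecl_obl) * sin(ecl_long))
  gmst <- 6.6974243242 + 0.0657098283 * n + hour_utc
  lmst <- (gmst * 15 + lon) * pi / 180
  ha <- lmst - ra
  latr <- lat * pi / 180
  zen <- acos(cos(latr) * cos(ha) * cos(dec) + sin(dec) * sin(latr))
  zen <- zen + 6371.01 / 149597890 * sin(zen)  # parallax
  90 - zen * 180 / pi
}

psa_event <- function(date, lon, lat, rising) {
  d0 <- as.POSIXct(as.Date(date), tz = "UTC")
  f <- function(mins) psa_elevation(d0 + mins * 60, lon, lat) + 0.833
  noon_utc <- 720 - 4 * lon
  iv <- if (rising) c(noon_utc - 720, noon_utc) else c(noon_utc, noon_utc + 720)
  d0 + stats::uniroot(f, iv, tol = 0.5)$root * 60
}

# ---- geometry: gift-wrapping convex hull (independent of grDevices::chull) --

jarvis_hull <- function(pts) {
  pts <- unique(pts)
  n <- nrow(pts)
  start <- which.min(pts[, 1] + 1e-9 * pts[, 2])
  hull <- integer(0)
  cur <- start
  repeat {
    hull <- c(hull, cur)
    cand <- if (length(hull) == 1) setdiff(seq_len(n), cur) else seq_len(n)[-cur]
    nxt <- cand[1]
    for (j in cand[-1]) {
      cr <- (pts[nxt, 1] - pts[cur, 1]) * (pts[j, 2] - pts[cur, 2]) -
        (pts[nxt, 2] - pts[cur, 2]) * (pts[j, 1] - pts[cur, 1])
      d_nxt <- sum((pts[nxt, ] - pts[cur, ])^2)
      d_j <- sum((pts[j, ] - pts[cur, ])^2)
      if (cr > 1e-12 || (abs(cr) <= 1e-12 && d_j > d_nxt)) nxt <- j
    }
    if (nxt == start) break
    cur <- nxt
  }
  pts[hull, , drop = FALSE]
}

# ---- exact tests: brute-force enumeration ----------------------------------

enum_mw_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  splits <- utils::combn(n1 + n2, n1)
  us <- apply(splits, 2, function(ix) sum(r[ix])) - n1 * (n1 + 1) / 2
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  lo <- mean(us <= u_obs + 1e-9); hi <- mean(us >= u_obs - 1e-9)
  min(1, 2 * min(lo, hi))
}

enum_wsr_p <- function(before, after) {
  d <- before - after
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  ws <- signs %*% r
  lo <- mean(ws <= w_obs + 1e-9); hi <- mean(ws >= w_obs - 1e-9)
  min(1, 2 * min(lo, hi))
}

# ---- two-sample KS distance (ties allowed) ---------------------------------

ks_distance <- function(a, b) {
  v <- sort(unique(c(a, b)))
  max(abs(stats::ecdf(a)(v) - stats::ecdf(b)(v)))
}

# ---- fixture builders ------------------------------------------------------

# grid landscape with i.i.d. cell classes: any sampling scheme sees the
# global class proportions
iid_landscape <- function(props, half = 5000, cellsize = 50,
                          turbines = NULL, linear = list(), seed = 1) {
  set.seed(seed)
  n <- as.integer(2 * half / cellsize)
  classes <- matrix(sample(names(props), n * n, replace = TRUE, prob = props),
                    nrow = n)
  if (is.null(turbines))
    turbines <- data.frame(x = 2000, y = 1500, hub_height = 100,
                           rotor_radius = 33)
  landscape(list(x0 = -half, y0 = -half, cellsize = cellsize,
                 classes = classes),
            turbines, linear, roost = c(0, 0))
}

# wrap planar coordinates (+ optional heights) into a bat_trip
make_trip <- function(xy, t0 = as.POSIXct("2014-06-05 20:00:00", tz = "UTC"),
                      id = "B1", sex = "M", type = "evening",
                      heights = NULL, interval = 30) {
  n <- nrow(xy)
  structure(list(
    trip_id = paste0(id, "_trip"), individual_id = id, sex = sex,
    season = "early_summer", trip_type = type,
    night = as.Date(t0), sunset = t0 - 20 * 60, sunrise = t0 + 8 * 3600,
    fixes = data.frame(individual_id = id,
                       timestamp = t0 + (seq_len(n) - 1) * interval,
                       lon = NA_real_, lat = NA_real_,
                       x = xy[, 1], y = xy[, 2],
                       height_agl = if (is.null(heights)) NA_real_ else heights)),
    class = "bat_trip")
}

# random-walk coordinates for synthetic trips
rw_xy <- function(n, step_mean = 150, seed = 1, start = c(0, 0)) {
  set.seed(seed)
  h <- cumsum(c(runif(1, -pi, pi), rnorm(n - 2, 0, 0.5)))
  L <- rgamma(n - 1, shape = 4, scale = step_mean / 4)
  cbind(start[1] + cumsum(c(0, L * cos(h))),
        start[2] + cumsum(c(0, L * sin(h))))
}
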