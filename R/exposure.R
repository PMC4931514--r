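# Overlap between flight heights over open habitat and the rotor-swept
# heights of the turbine fleet. The rotor-swept zone of a turbine is the
# interval [hub_height - rotor_radius, hub_height + rotor_radius].

#' Rotor-swept height density of a turbine fleet
#'
#' For every 1-m height above ground, the count and fraction of turbines
#' whose rotor-swept interval covers that height (closed at both ends).
#'
#' @param turbines data.frame with `hub_height` and `rotor_radius` (metres),
#'   e.g. the `turbines` layer of a [landscape].
#' @param step height grid step in metres (default 1).
#' @return data.frame of class `blade_profile`: `height`, `count`,
#'   `fraction`; attribute `n_turbines`. Empty fleet gives an empty profile
#'   with a warning.
#' @export
blade_density <- function(turbines, step = 1) {
  tb <- as.data.frame(turbines)
  if ("hub_height_m" %in% names(tb) && !"hub_height" %in% names(tb)) {
    tb$hub_height <- tb$hub_height_m; tb$rotor_radius <- tb$rotor_radius_m
  }
  if (!nrow(tb)) {
    warning("empty turbine fleet: blade profile is empty")
    return(structure(data.frame(height = numeric(), count = integer(),
                                fraction = numeric()),
                     class = c("blade_profile", "data.frame"), n_turbines = 0L))
  }
  lo <- tb$hub_height - tb$rotor_radius
  hi <- tb$hub_height + tb$rotor_radius
  z <- seq(floor(min(lo)) - step, ceiling(max(hi)) + step, by = step)
  cnt <- vapply(z, function(h) sum(lo <= h & h <= hi), 0L)
  structure(data.frame(height = z, count = cnt, fraction = cnt / nrow(tb)),
            class = c("blade_profile", "data.frame"), n_turbines = nrow(tb))
}

#' Peak rotor-density height band
#'
#' The maximal contiguous run of grid heights at the fleet's peak rotor
#' density — the band "most intensively used for wind power production".
#'
#' @param profile a `blade_profile` from [blade_density()].
#' @return list: `band` `c(lo, hi)` (m), `fraction` of turbines whose rotors
#'   sweep the whole band.
#' @export
peak_blade_band <- function(profile) {
  stopifnot(nrow(profile) > 0)
  peak <- max(profile$count)
  at_peak <- profile$count == peak
  runs <- rle(at_peak)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  best <- which(runs$values)[which.max(runs$lengths[runs$values])]
  list(band = c(profile$height[starts[best]], profile$height[ends[best]]),
       fraction = peak / attr(profile, "n_turbines"))
}

#' Occupancy of a height band over open habitat
#'
#' Count and percentage of open-habitat fixes whose height lies within a
#' closed band `[lo, hi]`, e.g. the fleet's rotor-swept zone. The percentage
#' of record is unrounded; `label` renders it to the nearest integer as
#' printed in field reports.
#'
#' @param heights numeric heights above ground (m) of open-habitat fixes;
#'   NAs excluded (their count is reported).
#' @param band `c(lo, hi)` with `lo < hi` (infinite bounds allowed).
#' @return list of class `exposure_band`: `n_in`, `n_total`, `percent`
#'   (unrounded), `label` ("`n_in`/`n_total` = X%", nearest integer),
#'   `band`. All-missing heights give a result flagged `absent`.
#' @export
band_occupancy <- function(heights, band) {
  stopifnot(length(band) == 2, band[1] < band[2])
  h <- as.numeric(heights)
  n_na <- sum(is.na(h))
  h <- h[!is.na(h)]
  if (!length(h)) {
    return(structure(list(n_in = NA_integer_, n_total = 0L, percent = NA_real_,
                          label = "no heights available", band = band,
                          absent = TRUE, n_missing = n_na),
                     class = "exposure_band"))
  }
  n_in <- sum(h >= band[1] & h <= band[2])
  pct <- 100 * n_in / length(h)
  structure(list(n_in = n_in, n_total = length(h), percent = pct,
                 label = sprintf("%d%% (n = %d/%d)", round_half_up(pct),
                                 n_in, length(h)),
                 band = band, absent = FALSE, n_missing = n_na),
            class = "exposure_band")
}

# nearest-integer with halves away from zero (not banker's rounding)
round_half_up <- function(x) floor(x + 0.5)

#' @export
print.exposure_band <- function(x, ...) {
  cat(sprintf("heights in [%s, %s] m: %s\n", format(x$band[1]),
              format(x$band[2]), x$label))
  invisible(x)
}

#' Central height interval at a given coverage
#'
#' The central `coverage` interval of the flight heights,
#' `[q((1-c)/2), q(1-(1-c)/2)]` with linearly interpolated quantiles; the
#' lower bound is clamped at 0 when all heights are non-negative (heights
#' above ground cannot be negative, so the interval is reported as starting
#' at 0 rather than below it).
#'
#' @param heights numeric heights (m), at least `min_n` non-missing.
#' @param coverage central coverage, default 0.95.
#' @param min_n minimum sample size (default 20).
#' @return numeric `c(lower, upper)` in metres.
#' @export
height_interval <- function(heights, coverage = 0.95, min_n = 20) {
  h <- as.numeric(heights); h <- h[!is.na(h)]
  if (length(h) < min_n) stop("insufficient data: need at least ", min_n, " heights")
  stopifnot(coverage > 0, coverage < 1)
  a <- (1 - coverage) / 2
  q <- unname(stats::quantile(h, c(a, 1 - a)))
  if (min(h) >= 0) q[1] <- max(0, q[1])
  q
}

#' Per-stratum exposure report
#'
#' The flight-height exposure summary for one sex stratum: sample size over
#' open habitat, rotor-band occupancy, central 95% height interval and
#' height quartiles.
#'
#' @param heights open-habitat heights (m) for the stratum.
#' @param band rotor height band `c(lo, hi)` (m).
#' @param sex stratum label.
#' @param coverage central interval coverage (default 0.95).
#' @return list of class `exposure_report`.
#' @export
exposure_report <- function(heights, band, sex = NA_character_,
                            coverage = 0.95) {
  occ <- band_occupancy(heights, band)
  h <- as.numeric(heights); h <- h[!is.na(h)]
  structure(list(sex = sex, n_open = length(h), band = band,
                 occupancy = occ,
                 central_interval = if (length(h) >= 20)
                   height_interval(h, coverage) else c(NA_real_, NA_real_),
                 quartiles = if (length(h))
                   unname(stats::quantile(h, c(0.25, 0.5, 0.75))) else rep(NA_real_, 3),
                 coverage = coverage),
            class = "exposure_report")
}

#' @export
print.exposure_report <- function(x, ...) {
  cat(sprintf("Exposure (%s): %d open-habitat fixes\n",
              if (is.na(x$sex)) "all" else x$sex, x$n_open))
  cat("  rotor band: ", x$occupancy$label, "\n", sep = "")
  cat(sprintf("  central %.0f%% heights: %.1f-%.1f m; quartiles %.1f/%.1f/%.1f m\n",
              100 * x$coverage, x$central_interval[1], x$central_interval[2],
              x$quartiles[1], x$quartiles[2], x$quartiles[3]))
  invisible(x)
}
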