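# Ingestion and segmentation of 30-s GPS fix streams into evening/morning
# trips, and per-trip movement metrics.

#' Read a GPS track table and project it around the roost
#'
#' Reads a CSV with columns `id`, `timestamp` (ISO-8601, UTC), `lon`, `lat`
#' and optionally `height_agl` (metres above ground). Fixes are sorted by
#' individual and time and given planar coordinates in the local
#' azimuthal-equidistant projection centred on the roost. Malformed rows
#' (unparseable timestamp or out-of-range coordinates) are reported in a
#' warning with their row numbers and returned in the `"malformed"`
#' attribute; they are never silently dropped.
#'
#' @param path CSV file path, or a data.frame already holding the columns.
#' @param roost `c(lon, lat)` of the roost (WGS84 degrees).
#' @return data.frame of fixes: `individual_id`, `timestamp` (POSIXct UTC),
#'   `lon`, `lat`, `x`, `y` (metres), `height_agl` (NA when absent), with
#'   attributes `roost` (planar origin) and `roost_lonlat`.
#' @export
read_tracks <- function(path, roost) {
  stopifnot(length(roost) == 2)
  raw <- if (is.data.frame(path)) path else
    utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("id", "timestamp", "lon", "lat")
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols))
    stop("track file lacks mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  ts <- as.POSIXct(raw$timestamp, tz = "UTC", format = "%Y-%m-%dT%H:%M:%OS")
  ts2 <- as.POSIXct(raw$timestamp, tz = "UTC", format = "%Y-%m-%d %H:%M:%OS")
  ts[is.na(ts)] <- ts2[is.na(ts)]
  lon <- suppressWarnings(as.numeric(raw$lon))
  lat <- suppressWarnings(as.numeric(raw$lat))
  bad <- is.na(ts) | is.na(lon) | is.na(lat) |
    abs(lat) > 90 | abs(lon) > 180
  if (any(bad))
    warning(sum(bad), " malformed row(s) excluded (rows ",
            paste(utils::head(which(bad), 10), collapse = ", "), ")")
  fx <- data.frame(
    individual_id = as.character(raw$id)[!bad],
    timestamp = ts[!bad], lon = lon[!bad], lat = lat[!bad],
    height_agl = if ("height_agl" %in% names(raw))
      suppressWarnings(as.numeric(raw$height_agl))[!bad] else NA_real_,
    stringsAsFactors = FALSE)
  fx <- fx[order(fx$individual_id, fx$timestamp), , drop = FALSE]
  dup <- stats::ave(as.numeric(fx$timestamp), fx$individual_id,
                    FUN = function(t) c(1, diff(t))) <= 0
  if (any(dup))
    stop("non-increasing timestamps for individual ",
         fx$individual_id[which(dup)[1]], " at row ", which(dup)[1])
  xy <- lonlat_to_planar(fx$lon, fx$lat, roost)
  fx$x <- xy[, 1]; fx$y <- xy[, 2]
  rownames(fx) <- NULL
  attr(fx, "roost") <- c(x = 0, y = 0)
  attr(fx, "roost_lonlat") <- roost
  attr(fx, "malformed") <- which(bad)
  fx
}

#' Solar events for every night spanned by a fix table
#'
#' @param fixes fix data.frame (see [read_tracks()]).
#' @param lon,lat site coordinates used for the solar computation (the
#'   roost; at a 20-km study scale one site suffices).
#' @return data.frame with `night` (Date of the evening), `sunset`,
#'   `sunrise` (POSIXct UTC).
#' @export
night_solar <- function(fixes, lon, lat) {
  dates <- sort(unique(c(as.Date(fixes$timestamp), as.Date(fixes$timestamp) - 1)))
  ev <- lapply(dates, solar_events, lon = lon, lat = lat)
  data.frame(night = dates,
             sunset = as.POSIXct(vapply(ev, function(e) as.numeric(e$sunset), 0),
                                 origin = "1970-01-01", tz = "UTC"),
             sunrise = as.POSIXct(vapply(ev, function(e) as.numeric(e$sunrise), 0),
                                  origin = "1970-01-01", tz = "UTC"))
}

# night (row of the solar table) a timestamp belongs to: the 24-h cycle from
# local noon to noon, keyed by the date of (timestamp - 12 h); NA when the
# solar table does not cover that date
match_night <- function(ts, solar) {
  match(as.Date(ts - 43200, tz = "UTC"), solar$night)
}

#' Segment a fix stream into evening and morning trips
#'
#' Per individual, maximal runs of consecutive fixes with inter-fix gap at
#' most `gap_tol` seconds become candidate trips (at least two fixes). A run
#' is an *evening* trip if its first fix falls between one hour before
#' sunset and solar midnight (midpoint of sunset and sunrise), a *morning*
#' trip if its last fix falls within `morning_window` minutes before
#' sunrise. Runs matching neither are excluded from downstream analysis;
#' their count is reported in a message and in the `"n_excluded"` attribute.
#'
#' @param fixes fix data.frame from [read_tracks()].
#' @param solar per-night solar table from [night_solar()].
#' @param meta optional data.frame with `individual_id`, `sex` (`"F"`/`"M"`)
#'   and `season` (`"early_summer"`/`"midsummer"`) carried onto each trip.
#' @param gap_tol maximum inter-fix gap in seconds treated as continuous;
#'   default 150 s = five nominal 30-s intervals, so an isolated GPS dropout
#'   does not split a trip.
#' @param morning_window minutes before sunrise within which a run must end
#'   to count as a morning trip (default 180).
#' @return list of trips (class `bat_trips`); each element is a `bat_trip`
#'   list with `trip_id`, `individual_id`, `sex`, `season`, `trip_type`,
#'   `night`, `sunset`, `sunrise` and `fixes`.
#' @export
segment_trips <- function(fixes, solar, meta = NULL, gap_tol = 150,
                          morning_window = 180) {
  stopifnot(!is.unsorted(order(fixes$individual_id, fixes$timestamp)))
  night_idx <- match_night(fixes$timestamp, solar)
  if (anyNA(night_idx))
    stop("no solar events cover the night of fix at row ",
         which(is.na(night_idx))[1], " (", fixes$timestamp[which(is.na(night_idx))[1]],
         "); extend the solar table")
  trips <- list()
  n_excluded <- 0L
  for (id in unique(fixes$individual_id)) {
    fx <- fixes[fixes$individual_id == id, , drop = FALSE]
    nx <- night_idx[fixes$individual_id == id]
    gaps <- c(Inf, diff(as.numeric(fx$timestamp)))
    run <- cumsum(gaps > gap_tol | c(FALSE, diff(nx) != 0))
    for (r in unique(run)) {
      sel <- run == r
      if (sum(sel) < 2) { n_excluded <- n_excluded + 1L; next }
      seg <- fx[sel, , drop = FALSE]
      ni <- nx[sel][1]
      sunset <- solar$sunset[ni]; sunrise <- solar$sunrise[ni]
      midnight <- sunset + as.numeric(difftime(sunrise, sunset, units = "secs")) / 2
      type <- if (seg$timestamp[1] >= sunset - 3600 && seg$timestamp[1] < midnight)
        "evening"
      else if (seg$timestamp[nrow(seg)] >= sunrise - morning_window * 60 &&
               seg$timestamp[nrow(seg)] <= sunrise)
        "morning"
      else "other"
      if (type == "other") { n_excluded <- n_excluded + 1L; next }
      mrow <- if (!is.null(meta)) meta[match(id, meta$individual_id), ] else NULL
      trips[[length(trips) + 1L]] <- structure(list(
        trip_id = sprintf("%s_%s_%s", id, format(solar$night[ni]), type),
        individual_id = id,
        sex = if (!is.null(mrow)) as.character(mrow$sex) else NA_character_,
        season = if (!is.null(mrow)) as.character(mrow$season) else NA_character_,
        trip_type = type, night = solar$night[ni],
        sunset = sunset, sunrise = sunrise,
        fixes = seg), class = "bat_trip")
    }
  }
  if (n_excluded > 0)
    message(n_excluded, " fix run(s) matched neither trip window and were excluded")
  structure(trips, class = "bat_trips", n_excluded = n_excluded)
}

#' @export
print.bat_trip <- function(x, ...) {
  cat(sprintf("<bat_trip %s: %s, %d fixes, %s>\n", x$trip_id, x$trip_type,
              nrow(x$fixes), format(x$night)))
  invisible(x)
}

#' @export
print.bat_trips <- function(x, ...) {
  cat(sprintf("<bat_trips: %d trips (%d evening, %d morning), %d run(s) excluded>\n",
              length(x), sum(vapply(x, `[[`, "", "trip_type") == "evening"),
              sum(vapply(x, `[[`, "", "trip_type") == "morning"),
              attr(x, "n_excluded")))
  invisible(x)
}

#' Movement metrics for one trip
#'
#' Minimum travel speeds are straight-line displacement between consecutive
#' fixes divided by elapsed time; each speed is assigned the land-use class
#' of the segment midpoint. Roost distances are planar. Flight-height
#' summaries use only fixes over open habitat (conventional cropland,
#' organic cropland, grassland), where on-board heights are trustworthy.
#'
#' @param trip a `bat_trip`.
#' @param landscape optional [landscape] used for per-class speeds and the
#'   open-habitat height summary; without it those fields are `NULL`.
#' @return list of class `trip_metrics`: `duration` (min), `cum_distance`
#'   (km), `max_roost_distance` (km), `q95_roost_distance` (km),
#'   `emergence_offset` (min after sunset; evening trips),
#'   `return_offset` (min before sunrise; morning trips),
#'   `mean_speed_by_class` (m/s), `height_summary_open` (quantiles, m) or
#'   `NA` with attribute `absent` when no open-habitat heights exist.
#' @export
trip_metrics <- function(trip, landscape = NULL) {
  fx <- trip$fixes
  dt <- diff(as.numeric(fx$timestamp))
  if (any(dt <= 0)) stop("non-positive time step within trip ", trip$trip_id)
  dx <- diff(fx$x); dy <- diff(fx$y)
  step <- sqrt(dx^2 + dy^2)
  speed <- step / dt
  rd <- sqrt(fx$x^2 + fx$y^2)
  out <- list(
    trip_id = trip$trip_id, individual_id = trip$individual_id,
    sex = trip$sex, trip_type = trip$trip_type,
    n_fixes = nrow(fx),
    duration = as.numeric(difftime(fx$timestamp[nrow(fx)], fx$timestamp[1],
                                   units = "mins")),
    cum_distance = sum(step) / 1000,
    max_roost_distance = max(rd) / 1000,
    q95_roost_distance = unname(stats::quantile(rd, 0.95)) / 1000,
    emergence_offset = if (trip$trip_type == "evening")
      as.numeric(difftime(fx$timestamp[1], trip$sunset, units = "mins")) else NA_real_,
    return_offset = if (trip$trip_type == "morning")
      as.numeric(difftime(trip$sunrise, fx$timestamp[nrow(fx)], units = "mins")) else NA_real_,
    mean_speed_by_class = NULL, height_summary_open = NULL)
  if (!is.null(landscape)) {
    mid <- annotate(landscape, cbind((fx$x[-1] + fx$x[-nrow(fx)]) / 2,
                                     (fx$y[-1] + fx$y[-nrow(fx)]) / 2))
    out$mean_speed_by_class <- tapply(speed, mid$land_class, mean)
    cls <- annotate(landscape, cbind(fx$x, fx$y))$land_class
    open <- cls %in% open_classes() & !is.na(fx$height_agl)
    if (any(open)) {
      out$height_summary_open <- stats::quantile(
        fx$height_agl[open], c(0, 0.25, 0.5, 0.75, 0.95, 1))
    } else {
      out$height_summary_open <- structure(NA_real_, absent = TRUE)
    }
  }
  structure(out, class = "trip_metrics")
}

# land-use classes where device heights are trusted and rotor exposure applies
open_classes <- function() c("conventional_cropland", "organic_cropland", "grassland")

#' Metrics table for a trip collection
#'
#' @param trips `bat_trips` list.
#' @param landscape optional [landscape].
#' @return data.frame, one row per trip (scalar metrics only).
#' @export
trips_metrics <- function(trips, landscape = NULL) {
  rows <- lapply(trips, function(tr) {
    m <- trip_metrics(tr, landscape)
    data.frame(trip_id = m$trip_id, individual_id = m$individual_id,
               sex = m$sex, trip_type = m$trip_type, n_fixes = m$n_fixes,
               duration = m$duration, cum_distance = m$cum_distance,
               max_roost_distance = m$max_roost_distance,
               q95_roost_distance = m$q95_roost_distance,
               emergence_offset = m$emergence_offset,
               return_offset = m$return_offset,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
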