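# Landscape container: land-use classes, turbine registry, linear features
# and the roost, with point annotation into the selection model's covariates.

#' The seven land-use classes
#'
#' Land use is compressed into seven categories; the vector also fixes the
#' integer coding used by the ASCII-grid representation.
#' @return character vector of class labels.
#' @export
land_classes <- function() c("conventional_cropland", "organic_cropland",
                             "grassland", "forest", "urban", "open_water",
                             "shrubland")

#' Build a landscape object
#'
#' @param land_use either a polygon layer — a list of `list(class =, ring =)`
#'   entries, `ring` a two-column matrix of planar vertices, with *layer
#'   order* resolving overlap and shared edges (first polygon listed wins) —
#'   or a class grid: `list(x0 =, y0 =, cellsize =, classes =)` with
#'   `classes` a character matrix indexed `[ix, iy]` from the lower-left
#'   corner `(x0, y0)`.
#' @param turbines data.frame with `x`, `y`, `hub_height`, `rotor_radius`
#'   (metres); may have zero rows.
#' @param linear list of two-column matrices (polyline vertices); the merged
#'   linear-structure layer (roads, treelines, hedgerows, ...).
#' @param roost planar `c(x, y)` of the roost.
#' @param extent bounding ring (two-column matrix); defaults to the grid
#'   rectangle or the bounding box of the polygon layer.
#' @param default_class class assigned where the polygon layer has a gap.
#' @return object of class `landscape`.
#' @export
landscape <- function(land_use, turbines, linear, roost, extent = NULL,
                      default_class = "conventional_cropland") {
  grid <- is.list(land_use) && !is.null(land_use$classes)
  labs <- if (grid) unique(as.vector(land_use$classes)) else
    vapply(land_use, `[[`, "", "class")
  bad <- setdiff(c(labs, default_class), land_classes())
  if (length(bad)) stop("unknown land-use class label(s): ",
                        paste(bad, collapse = ", "))
  turbines <- as.data.frame(turbines)
  if (nrow(turbines)) {
    stopifnot(all(c("x", "y", "hub_height", "rotor_radius") %in% names(turbines)))
    if (any(turbines$rotor_radius <= 0) ||
        any(turbines$hub_height <= turbines$rotor_radius))
      stop("turbines must satisfy hub_height > rotor_radius > 0")
  } else {
    message("empty turbine layer: turbine distances will be +Inf")
  }
  if (is.null(extent)) {
    extent <- if (grid) {
      with(land_use, {
        x1 <- x0 + ncol_or(classes, 1) * 0; NULL })  # placeholder, set below
    } else NULL
    if (grid) {
      nx <- nrow(land_use$classes); ny <- ncol(land_use$classes)
      x1 <- land_use$x0 + nx * land_use$cellsize
      y1 <- land_use$y0 + ny * land_use$cellsize
      extent <- cbind(c(land_use$x0, x1, x1, land_use$x0),
                      c(land_use$y0, land_use$y0, y1, y1))
    } else {
      allv <- do.call(rbind, lapply(land_use, `[[`, "ring"))
      extent <- cbind(c(min(allv[, 1]), max(allv[, 1]), max(allv[, 1]), min(allv[, 1])),
                      c(min(allv[, 2]), min(allv[, 2]), max(allv[, 2]), max(allv[, 2])))
    }
  }
  structure(list(land_use = land_use, grid = grid, turbines = turbines,
                 linear = linear, roost = roost, extent = extent,
                 default_class = default_class),
            class = "landscape")
}

ncol_or <- function(m, d) if (is.matrix(m)) ncol(m) else d

#' @export
print.landscape <- function(x, ...) {
  cat(sprintf("<landscape: %s land use, %d turbine(s), %d linear feature(s)>\n",
              if (x$grid) sprintf("%dx%d grid (%.0f m cells)",
                                  nrow(x$land_use$classes), ncol(x$land_use$classes),
                                  x$land_use$cellsize)
              else sprintf("%d polygon(s)", length(x$land_use)),
              nrow(x$turbines), length(x$linear)))
  invisible(x)
}

# class of each point under the layer rules; first polygon in layer order
# wins on overlap/shared edges, gaps get the default class
lookup_class <- function(ls, px, py) {
  if (ls$grid) {
    g <- ls$land_use
    nx <- nrow(g$classes); ny <- ncol(g$classes)
    ix <- floor((px - g$x0) / g$cellsize) + 1
    iy <- floor((py - g$y0) / g$cellsize) + 1
    outside <- ix < 1 | ix > nx | iy < 1 | iy > ny
    if (any(outside))
      warning(sum(outside), " point(s) outside the landscape extent; ",
              "annotated with the nearest cell's class")
    ix <- pmin(pmax(ix, 1), nx); iy <- pmin(pmax(iy, 1), ny)
    g$classes[cbind(ix, iy)]
  } else {
    cls <- rep(NA_character_, length(px))
    for (p in ls$land_use) {
      hit <- is.na(cls) & point_in_polygon(px, py, p$ring)
      cls[hit] <- p$class
    }
    if (anyNA(cls)) {
      # outside all polygons: inside the extent it is a coverage gap filled
      # by the default class; outside the extent use the nearest polygon
      out_ext <- is.na(cls) & !point_in_polygon(px, py, ls$extent)
      if (any(out_ext)) {
        warning(sum(out_ext), " point(s) outside the landscape extent; ",
                "annotated with the nearest polygon's class")
        for (i in which(out_ext)) {
          d <- vapply(ls$land_use, function(p)
            min(dist_to_polyline(px[i], py[i],
                                 rbind(p$ring, p$ring[1, , drop = FALSE]))), 0)
          cls[i] <- ls$land_use[[which.min(d)]]$class
        }
      }
      cls[is.na(cls)] <- ls$default_class
    }
    cls
  }
}

#' Annotate planar points with the selection covariates
#'
#' For each point: the land-use class of the containing polygon or grid cell
#' (ties on shared polygon edges resolve to the polygon listed first),
#' Euclidean distance to the nearest turbine base, and shortest distance to
#' any linear-feature segment. Points outside the extent are annotated with
#' the nearest class and flagged by a warning rather than dropped, so
#' random-walk vertices near the edge never vanish silently.
#'
#' @param ls a [landscape].
#' @param points two-column matrix (or data.frame with `x`, `y`) of planar
#'   coordinates.
#' @return data.frame: `land_class` (factor over [land_classes()]),
#'   `dist_turbine`, `dist_linear` (metres; `Inf` when the layer is empty).
#' @export
annotate <- function(ls, points) {
  stopifnot(inherits(ls, "landscape"))
  if (is.data.frame(points)) points <- cbind(points$x, points$y)
  px <- points[, 1]; py <- points[, 2]
  dt <- if (nrow(ls$turbines)) {
    d2 <- outer(px, ls$turbines$x, "-")^2 + outer(py, ls$turbines$y, "-")^2
    sqrt(apply(d2, 1, min))
  } else rep(Inf, length(px))
  dl <- if (length(ls$linear)) {
    dm <- vapply(ls$linear, function(pl) dist_to_polyline(px, py, pl),
                 numeric(length(px)))
    if (length(px) == 1) min(dm) else apply(matrix(dm, nrow = length(px)), 1, min)
  } else rep(Inf, length(px))
  data.frame(land_class = factor(lookup_class(ls, px, py), levels = land_classes()),
             dist_turbine = dt, dist_linear = dl)
}

# ---- persistence -----------------------------------------------------------

geojson_feature <- function(geometry, properties) {
  list(type = "Feature", properties = properties, geometry = geometry)
}

#' Load a landscape from files
#'
#' Vector layers are GeoJSON (RFC 7946) in planar coordinates: land use as a
#' FeatureCollection of polygons with a `class` property, turbines as points
#' with `hub_height`/`rotor_radius` properties, linear features as
#' LineStrings, the roost as a single point. Land use may instead be an ESRI
#' ASCII grid whose integer codes index [land_classes()].
#'
#' @param landuse_path GeoJSON polygons or `.asc` class grid.
#' @param turbines_path GeoJSON points or a CSV with columns
#'   `x,y,hub_height_m,rotor_radius_m`.
#' @param linear_path GeoJSON LineStrings (optional).
#' @param roost planar `c(x, y)`, or a GeoJSON point file path.
#' @param default_class gap-filling class for polygon layers.
#' @return a [landscape].
#' @export
load_landscape <- function(landuse_path, turbines_path, linear_path = NULL,
                           roost, default_class = "conventional_cropland") {
  land_use <- if (grepl("\\.asc$", landuse_path)) read_ascii_grid(landuse_path)
  else {
    gj <- jsonlite::fromJSON(landuse_path, simplifyVector = FALSE)
    lapply(gj$features, function(f) {
      ring <- do.call(rbind, lapply(f$geometry$coordinates[[1]], unlist))
      # GeoJSON rings repeat the first vertex; store open rings
      if (all(ring[1, ] == ring[nrow(ring), ])) ring <- ring[-nrow(ring), , drop = FALSE]
      list(class = f$properties$class, ring = ring)
    })
  }
  turbines <- if (grepl("\\.csv$", turbines_path)) {
    tb <- utils::read.csv(turbines_path)
    data.frame(x = tb$x, y = tb$y, hub_height = tb$hub_height_m,
               rotor_radius = tb$rotor_radius_m)
  } else {
    gj <- jsonlite::fromJSON(turbines_path, simplifyVector = FALSE)
    do.call(rbind, lapply(gj$features, function(f)
      data.frame(x = f$geometry$coordinates[[1]], y = f$geometry$coordinates[[2]],
                 hub_height = f$properties$hub_height,
                 rotor_radius = f$properties$rotor_radius)))
  }
  linear <- if (is.null(linear_path)) list() else {
    gj <- jsonlite::fromJSON(linear_path, simplifyVector = FALSE)
    lapply(gj$features, function(f)
      do.call(rbind, lapply(f$geometry$coordinates, unlist)))
  }
  if (is.character(roost)) {
    gj <- jsonlite::fromJSON(roost, simplifyVector = FALSE)
    roost <- unlist(gj$features[[1]]$geometry$coordinates)
  }
  landscape(land_use, turbines, linear, roost, default_class = default_class)
}

read_ascii_grid <- function(path) {
  hdr <- utils::read.table(path, nrows = 5)
  h <- stats::setNames(hdr[, 2], tolower(hdr[, 1]))
  codes <- as.matrix(utils::read.table(path, skip = 5))
  ny <- nrow(codes); nx <- ncol(codes)
  stopifnot(nx == h[["ncols"]], ny == h[["nrows"]])
  # ASCII grids list rows north to south; classes[ix, iy] counts from SW
  cls <- matrix(land_classes()[t(codes[ny:1, , drop = FALSE])], nrow = nx)
  list(x0 = unname(h[["xllcorner"]]), y0 = unname(h[["yllcorner"]]),
       cellsize = unname(h[["cellsize"]]), classes = cls)
}

#' Write a landscape to files
#'
#' Inverse of [load_landscape()]: grid land use goes to an ESRI ASCII grid,
#' polygon land use and linear features to GeoJSON, turbines to the registry
#' CSV (`id,x,y,hub_height_m,rotor_radius_m`), the roost to a GeoJSON point.
#' Output is deterministic byte for byte for a given landscape.
#'
#' @param ls a [landscape].
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of file paths written.
#' @export
write_landscape <- function(ls, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c()
  if (ls$grid) {
    g <- ls$land_use
    p <- file.path(dir, "land_use.asc")
    nx <- nrow(g$classes); ny <- ncol(g$classes)
    codes <- matrix(match(g$classes, land_classes()), nrow = nx)
    lines <- c(sprintf("ncols %d", nx), sprintf("nrows %d", ny),
               sprintf("xllcorner %.6f", g$x0), sprintf("yllcorner %.6f", g$y0),
               sprintf("cellsize %.6f", g$cellsize),
               vapply(ny:1, function(iy) paste(codes[, iy], collapse = " "), ""))
    writeLines(lines, p)
    paths["land_use"] <- p
  } else {
    p <- file.path(dir, "land_use.geojson")
    feats <- lapply(ls$land_use, function(pl) {
      ring <- rbind(pl$ring, pl$ring[1, , drop = FALSE])
      geojson_feature(list(type = "Polygon",
                           coordinates = list(lapply(seq_len(nrow(ring)),
                                                     function(i) ring[i, ]))),
                      list(class = pl$class))
    })
    jsonlite::write_json(list(type = "FeatureCollection", features = feats), p,
                         auto_unbox = TRUE, digits = 8)
    paths["land_use"] <- p
  }
  p <- file.path(dir, "turbines.csv")
  tb <- ls$turbines
  utils::write.csv(data.frame(id = seq_len(nrow(tb)), x = tb$x, y = tb$y,
                              hub_height_m = tb$hub_height,
                              rotor_radius_m = tb$rotor_radius),
                   p, row.names = FALSE)
  paths["turbines"] <- p
  p <- file.path(dir, "linear.geojson")
  feats <- lapply(ls$linear, function(pl)
    geojson_feature(list(type = "LineString",
                         coordinates = lapply(seq_len(nrow(pl)), function(i) pl[i, ])),
                    list(kind = "linear_structure")))
  jsonlite::write_json(list(type = "FeatureCollection", features = feats), p,
                       auto_unbox = TRUE, digits = 8)
  paths["linear"] <- p
  p <- file.path(dir, "roost.geojson")
  jsonlite::write_json(list(type = "FeatureCollection", features = list(
    geojson_feature(list(type = "Point", coordinates = ls$roost),
                    list(kind = "roost")))), p, auto_unbox = TRUE, digits = 8)
  paths["roost"] <- p
  invisible(paths)
}
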