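# Orchestration: the analysis stages chained over a single configuration
# with deterministic seeding and a checksum manifest. Stages: simulate,
# segment, nullmodel, fit (design + screen + GLMM + curves), exposure,
# report.

#' Pipeline configuration
#'
#' @param scenario a [scenario_config()] for the simulate stage.
#' @param seed root seed; each stage derives its own seed by stable hashing
#'   of (root, stage name).
#' @param gap_tol trip-continuity gap tolerance, seconds.
#' @param n_crw random walks per trip (default 5).
#' @param crw_mode `"reject"` or `"stepwise"` (see [generate_crw()]).
#' @param cor_threshold collinearity limit (default 0.25).
#' @param cor_override proceed despite flagged covariate pairs (default
#'   FALSE, i.e. the run halts as the screen demands).
#' @param candidate_terms named list of fixed-term vectors compared by AIC.
#' @param height_band rotor band `c(lo, hi)` m, or `NULL` to take the
#'   fleet's peak band from [peak_blade_band()].
#' @param coverage central height-interval coverage (default 0.95).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(scenario = scenario_config(), seed = 1,
                            gap_tol = 150, n_crw = 5, crw_mode = "reject",
                            cor_threshold = 0.25, cor_override = FALSE,
                            candidate_terms = list(
                              main = c("land_class", "dist_turbine_s",
                                       "dist_linear_s"),
                              sex_interactions = c("land_class", "dist_turbine_s",
                                                   "dist_linear_s",
                                                   "land_class:sex",
                                                   "dist_turbine_s:sex",
                                                   "dist_linear_s:sex")),
                            height_band = NULL, coverage = 0.95) {
  structure(list(scenario = scenario, seed = seed, gap_tol = gap_tol,
                 n_crw = n_crw, crw_mode = crw_mode,
                 cor_threshold = cor_threshold, cor_override = cor_override,
                 candidate_terms = candidate_terms,
                 height_band = height_band, coverage = coverage),
            class = c("pipeline_config", "list"))
}

#' Read a pipeline configuration from YAML
#'
#' Scalar fields override [pipeline_config()] defaults; a `scenario` block
#' overrides [scenario_config()] fields.
#'
#' @param path YAML file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  sc <- do.call(scenario_config, if (is.null(y$scenario)) list() else y$scenario)
  y$scenario <- NULL
  do.call(pipeline_config, c(list(scenario = sc), y))
}

# stable stage seed below 2^31
stage_seed <- function(root, stage) {
  (root * 131 + sum(utf8ToInt(stage)) * 7919) %% .Machine$integer.max
}

#' Run the analysis pipeline
#'
#' Executes the requested stages, writing each stage's artifacts under
#' `out_dir` and a `manifest.json` with parameters, seeds and an MD5
#' checksum for every output file. Stages read their inputs from earlier
#' stages' artifacts, so re-running a single stage against an existing
#' output directory works; re-running the whole pipeline with an identical
#' configuration reproduces identical outputs.
#'
#' @param config a [pipeline_config()] or the path to a YAML file.
#' @param out_dir output directory.
#' @param stages character vector out of `"simulate"`, `"segment"`,
#'   `"nullmodel"`, `"fit"`, `"exposure"`, `"report"`, or `"all"`.
#' @return invisibly, a list with the in-memory stage results.
#' @export
run_pipeline <- function(config, out_dir, stages = "all") {
  if (is.character(config)) config <- read_pipeline_config(config)
  all_stages <- c("simulate", "segment", "nullmodel", "fit", "exposure", "report")
  if (identical(stages, "all")) stages <- all_stages
  stopifnot(all(stages %in% all_stages))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  st <- new.env(parent = emptyenv())
  for (s in stages) {
    switch(s,
           simulate = stage_simulate(config, out_dir, st),
           segment = stage_segment(config, out_dir, st),
           nullmodel = stage_nullmodel(config, out_dir, st),
           fit = stage_fit(config, out_dir, st),
           exposure = stage_exposure(config, out_dir, st),
           report = stage_report(config, out_dir, st))
  }
  write_manifest(config, out_dir, stages)
  invisible(as.list(st))
}

need_file <- function(path) {
  if (!file.exists(path))
    stop("missing pipeline input: ", path,
         " (run the earlier stage or point out_dir at its outputs)")
  path
}

get_landscape <- function(out_dir, st) {
  if (is.null(st$ls))
    st$ls <- load_landscape(need_file(file.path(out_dir, "land_use.asc")),
                            need_file(file.path(out_dir, "turbines.csv")),
                            need_file(file.path(out_dir, "linear.geojson")),
                            roost = need_file(file.path(out_dir, "roost.geojson")))
  st$ls
}

stage_simulate <- function(config, out_dir, st) {
  seed <- stage_seed(config$seed, "simulate")
  st$ls <- gen_landscape(config$scenario, seed)
  sim <- gen_tracks(st$ls, config$scenario, seed)
  st$tracks <- sim$tracks; st$meta <- sim$meta; st$truth <- sim$truth
  write_landscape(st$ls, out_dir)
  utils::write.csv(sim$tracks, file.path(out_dir, "tracks.csv"), row.names = FALSE)
  utils::write.csv(sim$meta, file.path(out_dir, "meta.csv"), row.names = FALSE)
  jsonlite::write_json(sim$truth, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = 10)
}

stage_segment <- function(config, out_dir, st) {
  roost <- config$scenario$roost_lonlat
  if (is.null(st$tracks))
    st$tracks <- utils::read.csv(need_file(file.path(out_dir, "tracks.csv")))
  if (is.null(st$meta))
    st$meta <- utils::read.csv(need_file(file.path(out_dir, "meta.csv")))
  fixes <- read_tracks(st$tracks, roost)
  solar <- night_solar(fixes, roost[1], roost[2])
  st$trips <- segment_trips(fixes, solar, meta = st$meta,
                            gap_tol = config$gap_tol)
  rows <- do.call(rbind, lapply(st$trips, function(tr) {
    fx <- tr$fixes
    fx$timestamp <- format(fx$timestamp, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
    cbind(trip_id = tr$trip_id, trip_type = tr$trip_type, sex = tr$sex,
          season = tr$season, night = format(tr$night),
          sunset = format(tr$sunset, "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
          sunrise = format(tr$sunrise, "%Y-%m-%dT%H:%M:%S", tz = "UTC"), fx)
  }))
  utils::write.csv(rows, file.path(out_dir, "trips.csv"), row.names = FALSE)
  ls <- get_landscape(out_dir, st)
  utils::write.csv(trips_metrics(st$trips, ls),
                   file.path(out_dir, "trip_metrics.csv"), row.names = FALSE)
}

load_trips <- function(out_dir, st) {
  if (!is.null(st$trips)) return(st$trips)
  rows <- utils::read.csv(need_file(file.path(out_dir, "trips.csv")))
  rows$timestamp <- as.POSIXct(rows$timestamp, tz = "UTC",
                               format = "%Y-%m-%dT%H:%M:%S")
  st$trips <- structure(lapply(split(rows, rows$trip_id), function(df) {
    df <- df[order(df$timestamp), ]
    structure(list(trip_id = df$trip_id[1], individual_id = df$individual_id[1],
                   sex = df$sex[1], season = df$season[1],
                   trip_type = df$trip_type[1], night = as.Date(df$night[1]),
                   sunset = as.POSIXct(df$sunset[1], tz = "UTC",
                                       format = "%Y-%m-%dT%H:%M:%S"),
                   sunrise = as.POSIXct(df$sunrise[1], tz = "UTC",
                                        format = "%Y-%m-%dT%H:%M:%S"),
                   fixes = df[, c("individual_id", "timestamp", "lon", "lat",
                                  "x", "y", "height_agl")]),
              class = "bat_trip")
  }), class = "bat_trips", n_excluded = NA_integer_)
  st$trips
}

stage_nullmodel <- function(config, out_dir, st) {
  trips <- load_trips(out_dir, st)
  ls <- get_landscape(out_dir, st)
  seed <- stage_seed(config$seed, "nullmodel")
  st$pseudo <- list(); regions <- list()
  for (i in seq_along(trips)) {
    tr <- trips[[i]]
    mcp <- minimum_convex_polygon(cbind(tr$fixes$x, tr$fixes$y))
    buf <- buffer_region(mcp)
    st$pseudo[[i]] <- generate_crw(tr, buf, ls$roost, n_replicates = config$n_crw,
                                   seed = seed + 17 * i, mode = config$crw_mode)
    ring <- rbind(buf$boundary, buf$boundary[1, , drop = FALSE])
    regions[[i]] <- geojson_feature(
      list(type = "Polygon",
           coordinates = list(lapply(seq_len(nrow(ring)), function(j) ring[j, ]))),
      list(trip_id = tr$trip_id, buffer_width = buf$buffer_width,
           mcp_area = mcp$area))
  }
  utils::write.csv(do.call(rbind, lapply(st$pseudo, pseudo_trips_table)),
                   file.path(out_dir, "pseudo_trips.csv"), row.names = FALSE)
  jsonlite::write_json(list(type = "FeatureCollection", features = regions),
                       file.path(out_dir, "regions.geojson"),
                       auto_unbox = TRUE, digits = 8)
}

load_pseudo <- function(out_dir, st) {
  if (!is.null(st$pseudo)) return(st$pseudo)
  tab <- utils::read.csv(need_file(file.path(out_dir, "pseudo_trips.csv")))
  st$pseudo <- lapply(split(tab, list(tab$source_trip_id, tab$replicate),
                            drop = TRUE), function(df)
    structure(list(source_trip_id = df$source_trip_id[1],
                   replicate = df$replicate[1], seed = NA_integer_,
                   fixes = cbind(df$x, df$y), mode_used = NA_character_),
              class = "pseudo_trip"))
  st$pseudo
}

stage_fit <- function(config, out_dir, st) {
  trips <- load_trips(out_dir, st)
  pseudo <- load_pseudo(out_dir, st)
  ls <- get_landscape(out_dir, st)
  st$design <- assemble_design(trips, pseudo, ls)
  utils::write.csv(st$design, file.path(out_dir, "design.csv"), row.names = FALSE)
  screen <- correlation_screen(st$design, threshold = config$cor_threshold,
                               override = config$cor_override)
  utils::write.csv(screen, file.path(out_dir, "correlation_screen.csv"),
                   row.names = FALSE)
  st$fits <- lapply(config$candidate_terms, function(tt) fit_rsf(st$design, tt))
  st$aic <- if (length(st$fits) >= 2) select_by_aic(st$fits) else
    structure(data.frame(model = names(st$fits), k = st$fits[[1]]$k,
                         loglik = st$fits[[1]]$loglik, aic = st$fits[[1]]$aic,
                         converged = st$fits[[1]]$converged, delta_aic = 0,
                         stringsAsFactors = FALSE),
              class = c("aic_table", "data.frame"))
  utils::write.csv(st$aic, file.path(out_dir, "aic_table.csv"), row.names = FALSE)
  st$best <- st$fits[[st$aic$model[1]]]
  jsonlite::write_json(
    list(formula = st$best$formula,
         coefficients = as.list(st$best$coefficients),
         se = as.list(st$best$se),
         variances = as.list(st$best$variances),
         loglik = st$best$loglik, aic = st$best$aic,
         converged = st$best$converged, pi0 = st$best$pi0, n = st$best$n),
    file.path(out_dir, "fit.json"), auto_unbox = TRUE, digits = 10)
  curves <- list()
  for (sx in st$best$xlevels$sex)
    for (v in c("land_class", "dist_turbine", "dist_linear"))
      curves[[paste(v, sx)]] <- effect_curve(st$best, v, sex = sx)
  st$curves <- do.call(rbind, curves)
  utils::write.csv(st$curves, file.path(out_dir, "effect_curves.csv"),
                   row.names = FALSE)
}

stage_exposure <- function(config, out_dir, st) {
  trips <- load_trips(out_dir, st)
  ls <- get_landscape(out_dir, st)
  profile <- blade_density(ls$turbines)
  utils::write.csv(profile, file.path(out_dir, "blade_profile.csv"),
                   row.names = FALSE)
  band <- config$height_band
  peak <- if (nrow(profile)) peak_blade_band(profile) else NULL
  if (is.null(band)) band <- peak$band
  fx <- do.call(rbind, lapply(trips, function(tr)
    cbind(tr$fixes, sex = tr$sex)))
  cls <- annotate(ls, cbind(fx$x, fx$y))$land_class
  open <- as.character(cls) %in% open_classes()
  reps <- lapply(unique(fx$sex), function(sx)
    exposure_report(fx$height_agl[open & fx$sex == sx], band, sex = sx,
                    coverage = config$coverage))
  all_rep <- exposure_report(fx$height_agl[open], band, sex = "all",
                             coverage = config$coverage)
  st$exposure <- c(reps, list(all_rep))
  jsonlite::write_json(lapply(st$exposure, function(r)
    list(sex = r$sex, n_open = r$n_open, band = r$band,
         n_in_band = r$occupancy$n_in, percent_in_band = r$occupancy$percent,
         label = r$occupancy$label, central_interval = r$central_interval,
         quartiles = r$quartiles,
         peak_band_fraction = if (is.null(peak)) NA else peak$fraction)),
    file.path(out_dir, "exposure.json"), auto_unbox = TRUE, digits = 10)
}

stage_report <- function(config, out_dir, st) {
  lines <- c("Pipeline report", "===============")
  if (!is.null(st$aic))
    lines <- c(lines, "", "AIC table:",
               utils::capture.output(print.data.frame(st$aic)))
  if (!is.null(st$exposure))
    lines <- c(lines, "", "Exposure:",
               unlist(lapply(st$exposure, function(r)
                 utils::capture.output(print(r)))))
  writeLines(lines, file.path(out_dir, "report.txt"))
}

write_manifest <- function(config, out_dir, stages) {
  files <- setdiff(list.files(out_dir), "manifest.json")
  sums <- tools::md5sum(file.path(out_dir, files))
  cfg <- config
  cfg$scenario$individuals <- NULL  # keep the manifest compact
  jsonlite::write_json(
    list(package_version = as.character(utils::packageVersion("batselect")),
         stages = stages, seed = config$seed, parameters = cfg,
         outputs = lapply(seq_along(files), function(i)
           list(file = files[i], md5 = unname(sums[i])))),
    file.path(out_dir, "manifest.json"), auto_unbox = TRUE, digits = 10)
}
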