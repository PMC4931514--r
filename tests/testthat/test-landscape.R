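# Landscape container, class lookup rules and covariate annotation.

simple_polys <- function() list(
  list(class = "open_water", ring = cbind(c(1000, 2000, 2000, 1000),
                                          c(1000, 1000, 2000, 2000))),
  list(class = "grassland", ring = cbind(c(2000, 4000, 4000, 2000),
                                         c(0, 0, 2000, 2000))),
  list(class = "conventional_cropland", ring = cbind(c(0, 5000, 5000, 0),
                                                     c(0, 0, 5000, 5000))))

test_that("polygon landscape resolves classes with first-listed-wins ties", {
  ls <- landscape(simple_polys(),
                  turbines = data.frame(x = 3000, y = 3000,
                                        hub_height = 100, rotor_radius = 33),
                  linear = list(cbind(c(0, 5000), c(4000, 4000))),
                  roost = c(500, 500))
  a <- annotate(ls, cbind(c(1500, 3000, 500), c(1500, 500, 4500)))
  expect_equal(as.character(a$land_class),
               c("open_water", "grassland", "conventional_cropland"))
  # a point on the shared edge x = 2000 resolves to the polygon listed first
  onedge <- annotate(ls, cbind(2000, 1500))
  expect_equal(as.character(onedge$land_class), "open_water")
  # gaps outside listed polygons fall back to the default class
  ls2 <- landscape(simple_polys()[1:2],
                   turbines = ls$turbines, linear = ls$linear,
                   roost = c(500, 500), default_class = "forest",
                   extent = cbind(c(0, 5000, 5000, 0), c(0, 0, 5000, 5000)))
  expect_equal(as.character(annotate(ls2, cbind(200, 4000))$land_class),
               "forest")
})

test_that("turbine registry is validated and may be empty", {
  expect_error(landscape(simple_polys(),
                         data.frame(x = 0, y = 0, hub_height = 30,
                                    rotor_radius = 40),
                         list(), c(0, 0)),
               "hub_height > rotor_radius")
  expect_message(ls <- landscape(simple_polys(),
                                 data.frame(x = numeric(), y = numeric(),
                                            hub_height = numeric(),
                                            rotor_radius = numeric()),
                                 list(), c(0, 0)),
                 "empty turbine layer")
  expect_equal(annotate(ls, cbind(100, 100))$dist_turbine, Inf)
  expect_error(landscape(list(list(class = "lava", ring = cbind(0:2, c(0, 1, 0)))),
                         data.frame(), list(), c(0, 0)),
               "unknown land-use class")
})

test_that("distances match exhaustive brute-force minima", {
  set.seed(14)
  turbines <- data.frame(x = runif(7, 0, 5000), y = runif(7, 0, 5000),
                         hub_height = 100, rotor_radius = 33)
  lines <- lapply(1:4, function(i) cbind(runif(4, 0, 5000), runif(4, 0, 5000)))
  ls <- landscape(simple_polys(), turbines, lines, roost = c(500, 500))
  pts <- cbind(runif(1000, 0, 5000), runif(1000, 0, 5000))
  a <- annotate(ls, pts)
  # brute force over every turbine and every segment
  seg_dist <- function(p, a1, a2) {
    v <- a2 - a1; t <- sum((p - a1) * v) / sum(v^2)
    t <- min(1, max(0, t)); sqrt(sum((a1 + t * v - p)^2))
  }
  for (i in sample(1000, 60)) {
    expect_equal(a$dist_turbine[i],
                 min(sqrt((turbines$x - pts[i, 1])^2 + (turbines$y - pts[i, 2])^2)))
    dmin <- Inf
    for (pl in lines)
      for (s in seq_len(nrow(pl) - 1))
        dmin <- min(dmin, seg_dist(pts[i, ], pl[s, ], pl[s + 1, ]))
    expect_equal(a$dist_linear[i], dmin)
  }
  # trivial anchors
  t1 <- annotate(ls, cbind(turbines$x[1] + 250, turbines$y[1]))
  expect_lte(t1$dist_turbine, 250)  # some other turbine may be closer
  only <- landscape(simple_polys(), turbines[1, ], lines, roost = c(500, 500))
  expect_equal(annotate(only, cbind(turbines$x[1] + 250, turbines$y[1]))$dist_turbine,
               250)
  expect_equal(annotate(ls, cbind(lines[[1]][1, 1], lines[[1]][1, 2]))$dist_linear, 0)
})

test_that("turbine distance is monotone under layer growth", {
  set.seed(4)
  tb <- data.frame(x = runif(6, 0, 5000), y = runif(6, 0, 5000),
                   hub_height = 100, rotor_radius = 33)
  ls_small <- landscape(simple_polys(), tb[1:2, ], list(), c(500, 500))
  ls_big <- landscape(simple_polys(), tb, list(), c(500, 500))
  pts <- cbind(runif(100, 0, 5000), runif(100, 0, 5000))
  expect_true(all(annotate(ls_big, pts)$dist_turbine <=
                    annotate(ls_small, pts)$dist_turbine + 1e-9))
})

test_that("annotation is deterministic and batch-order independent", {
  ls <- landscape(simple_polys(),
                  data.frame(x = 3000, y = 3000, hub_height = 100,
                             rotor_radius = 33),
                  list(cbind(c(0, 5000), c(4000, 4000))), c(500, 500))
  set.seed(2)
  pts <- cbind(runif(50, 0, 5000), runif(50, 0, 5000))
  whole <- annotate(ls, pts)
  single <- do.call(rbind, lapply(seq_len(50), function(i)
    annotate(ls, pts[i, , drop = FALSE])))
  expect_equal(whole$land_class, single$land_class)
  expect_equal(whole$dist_turbine, single$dist_turbine)
  shuffled <- annotate(ls, pts[50:1, ])
  expect_equal(shuffled$dist_linear, rev(whole$dist_linear))
})

test_that("grid and polygon representations of one map agree", {
  # rectangles aligned to the 50-m grid, rasterised by cell centre
  polys <- simple_polys()
  cs <- 50; n <- 100
  centres <- (seq_len(n) - 0.5) * cs
  cls <- matrix("conventional_cropland", n, n)
  for (ix in seq_len(n)) for (iy in seq_len(n)) {
    p <- c(centres[ix], centres[iy])
    for (pl in polys)
      if (batselect:::point_in_polygon(p[1], p[2], pl$ring)) {
        cls[ix, iy] <- pl$class; break
      }
  }
  tb <- data.frame(x = 2500, y = 2500, hub_height = 100, rotor_radius = 33)
  ls_poly <- landscape(polys, tb, list(), c(500, 500))
  ls_grid <- landscape(list(x0 = 0, y0 = 0, cellsize = cs, classes = cls),
                       tb, list(), c(500, 500))
  set.seed(77)
  # probe away from the polygon edges (which are grid-aligned)
  pts <- cbind(floor(runif(1000, 0, 5000) / cs) * cs + runif(1000, 5, 45),
               floor(runif(1000, 0, 5000) / cs) * cs + runif(1000, 5, 45))
  expect_equal(annotate(ls_poly, pts)$land_class,
               annotate(ls_grid, pts)$land_class)
})

test_that("landscape files round-trip through write/load", {
  tb <- data.frame(x = c(2500, 100), y = c(2500, 900), hub_height = 100,
                   rotor_radius = 33)
  lines <- list(cbind(c(0, 5000), c(4000, 4100)))
  ls <- landscape(simple_polys(), tb, lines, roost = c(500, 500))
  dir <- tempfile(); dir.create(dir)
  paths <- write_landscape(ls, dir)
  back <- load_landscape(paths["land_use"], paths["turbines"],
                         paths["linear"], paths["roost"])
  set.seed(3)
  pts <- cbind(runif(200, 0, 5000), runif(200, 0, 5000))
  expect_equal(annotate(back, pts), annotate(ls, pts), tolerance = 1e-6)

  # grid representation round-trips through the ASCII grid too
  lsg <- iid_landscape(c(conventional_cropland = 0.7, open_water = 0.3),
                       half = 1000, cellsize = 100, seed = 5)
  dir2 <- tempfile(); dir.create(dir2)
  p2 <- write_landscape(lsg, dir2)
  backg <- load_landscape(p2["land_use"], p2["turbines"], p2["linear"],
                          p2["roost"])
  pts2 <- cbind(runif(200, -1000, 1000), runif(200, -1000, 1000))
  expect_equal(annotate(backg, pts2)$land_class, annotate(lsg, pts2)$land_class)
})
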