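# Design assembly, collinearity screen, the selection GLMM and its displays.

# simulated design table with known coefficients (covariates already on the
# model scale: centre 0, scale 1)
sim_design <- function(n_ind = 10, n_trip = 2, rows = 60, beta0 = -1.6,
                       beta_class = c(conventional_cropland = 0,
                                      grassland = 0.8, open_water = 1.6),
                       b_dt = 0.8, b_dl = -0.5, sd_ind = 0, sd_trip = 0,
                       seed = 1) {
  set.seed(seed)
  ind <- rep(sprintf("I%02d", seq_len(n_ind)), each = n_trip * rows)
  trip <- rep(sprintf("T%02d", seq_len(n_ind * n_trip)), each = rows)
  n <- length(ind)
  d <- data.frame(
    individual_id = ind, trip_id = trip,
    land_class = factor(sample(names(beta_class), n, TRUE),
                        levels = land_classes()),
    dist_turbine_s = rnorm(n), dist_linear_s = rnorm(n),
    sex = factor(rep(c("F", "M"), length.out = n_ind)[match(ind, unique(ind))]),
    stringsAsFactors = FALSE)
  b_i <- rnorm(n_ind, 0, sd_ind)[match(ind, unique(ind))]
  b_t <- rnorm(n_ind * n_trip, 0, sd_trip)[match(trip, unique(trip))]
  eta <- beta0 + beta_class[as.character(d$land_class)] +
    b_dt * d$dist_turbine_s + b_dl * d$dist_linear_s + b_i + b_t
  d$presence <- rbinom(n, 1, plogis(eta))
  d$dist_turbine <- d$dist_turbine_s
  d$dist_linear <- d$dist_linear_s
  structure(d, class = c("rsf_design", "data.frame"),
            standardization = list(center = c(dist_turbine = 0, dist_linear = 0),
                                   scale = c(dist_turbine = 1, dist_linear = 1)))
}

test_that("design assembly counts rows and inherits grouping ids", {
  ls <- iid_landscape(c(conventional_cropland = 0.5, grassland = 0.3,
                        open_water = 0.2), half = 8000, seed = 3)
  xy <- rw_xy(10, seed = 4)
  tr <- make_trip(xy)
  trips <- structure(list(tr), class = "bat_trips")
  crw <- generate_crw(tr, buffer_region(minimum_convex_polygon(xy)),
                      roost = c(0, 0), n_replicates = 5, seed = 2)
  des <- assemble_design(trips, list(crw), ls)
  expect_equal(nrow(des), 10 + 50)
  expect_equal(sum(des$presence), 10)
  expect_true(all(des$trip_id == tr$trip_id))
  expect_true(all(des$individual_id == tr$individual_id))
  expect_equal(attr(des, "standardization")$scale[["dist_turbine"]],
               sd(des$dist_turbine))
  # an orphan pseudo-trip is a consistency error
  orphan <- crw; orphan[[1]]$source_trip_id <- "nonexistent"
  expect_error(assemble_design(trips, list(orphan), ls), "no source trip")
})

test_that("pseudo-absence class frequencies match availability in the buffer", {
  props <- c(conventional_cropland = 0.5, grassland = 0.3, open_water = 0.2)
  ls <- iid_landscape(props, half = 20000, cellsize = 50, seed = 8)
  xy <- rw_xy(200, seed = 6, step_mean = 250)
  tr <- make_trip(xy)
  buf <- buffer_region(minimum_convex_polygon(xy))
  crw <- generate_crw(tr, buf, roost = c(0, 0), n_replicates = 50, seed = 40)
  verts <- do.call(rbind, lapply(crw, `[[`, "fixes"))
  expect_gte(nrow(verts), 1e4)
  use <- table(annotate(ls, verts)$land_class)[names(props)]
  # availability: uniform sampling of the buffered region
  set.seed(99)
  bb <- apply(buf$boundary, 2, range)
  cand <- cbind(runif(4e4, bb[1, 1], bb[2, 1]), runif(4e4, bb[1, 2], bb[2, 2]))
  cand <- cand[region_contains(buf, cand), , drop = FALSE]
  avail <- table(annotate(ls, cand)$land_class)[names(props)]
  p_avail <- as.numeric(avail) / sum(avail)
  chi <- suppressWarnings(chisq.test(as.numeric(use), p = p_avail))
  expect_gt(chi$p.value, 0.01)
})

test_that("correlation screen flags collinear pairs and halts", {
  set.seed(10)
  d <- data.frame(a = rnorm(1e4))
  d$b <- 2 * d$a
  d$c <- -d$a
  d$e <- rnorm(1e4)
  expect_error(correlation_screen(d, vars = c("a", "b")), "collinear")
  rep1 <- correlation_screen(d, vars = c("a", "b"), override = TRUE)
  expect_equal(rep1$r, 1)
  expect_true(rep1$flagged)
  # negative correlation is flagged by absolute value
  rep2 <- correlation_screen(d, vars = c("a", "c"), override = TRUE)
  expect_equal(rep2$r, -1)
  expect_true(rep2$flagged)
  # independent covariates at n = 1e4 pass the 0.25 threshold
  rep3 <- correlation_screen(d, vars = c("a", "e"))
  expect_false(any(rep3$flagged))
  # constant covariate: undefined correlation
  d$k <- 1
  expect_error(correlation_screen(d, vars = c("a", "k")), "constant")
})

test_that("with variances pinned at zero the GLMM equals plain logistic ML", {
  des <- sim_design(n_ind = 8, rows = 40, seed = 21)
  fit0 <- fit_rsf(des, terms = c("land_class", "dist_turbine_s", "dist_linear_s"),
                  variance_structure = "none")
  ref <- glm(presence ~ land_class + dist_turbine_s + dist_linear_s,
             data = transform(as.data.frame(des),
                              land_class = relevel(droplevels(land_class),
                                                   "conventional_cropland")),
             family = binomial())
  expect_equal(unname(fit0$coefficients), unname(coef(ref)), tolerance = 1e-4)
  expect_equal(fit0$loglik, as.numeric(logLik(ref)), tolerance = 1e-6)
  expect_equal(fit0$variances, c(individual = 0, trip_within_individual = 0))
})

test_that("intercept-only fit without grouping signal recovers logit(1/6)", {
  d <- sim_design(n_ind = 6, rows = 100, seed = 2)
  d$presence <- rep(c(1, 0, 0, 0, 0, 0), length.out = nrow(d))
  fit <- fit_rsf(d, terms = "1", variance_structure = "none")
  expect_equal(unname(fit$coefficients["(Intercept)"]), qlogis(1 / 6),
               tolerance = 1e-6)
  expect_equal(fit$pi0, 1 / 6)
})

test_that("nested random-intercept fit stores a consistent AIC", {
  des <- sim_design(n_ind = 10, rows = 40, sd_ind = 0.8, sd_trip = 0.3,
                    seed = 31)
  fit <- fit_rsf(des, terms = c("land_class", "dist_turbine_s"))
  expect_true(fit$converged)
  expect_equal(fit$aic, 2 * fit$k - 2 * fit$loglik)
  expect_equal(fit$k, length(fit$coefficients) + 2)
  expect_true(all(fit$variances >= 0))
  # matches lme4's own AIC accounting
  expect_equal(fit$aic, AIC(fit$model))
  s <- summary(fit)
  expect_equal(unname(s$coefficients[, "Estimate"]), unname(fit$coefficients))
})

test_that("near-complete separation is flagged", {
  des <- sim_design(n_ind = 6, rows = 30, seed = 5)
  des$presence <- as.integer(des$dist_turbine_s > 0)
  # one overlapping observation keeps the MLE finite but enormous
  flip <- which.min(abs(des$dist_turbine_s))
  des$presence[flip] <- 1L - des$presence[flip]
  fit <- suppressWarnings(fit_rsf(des, terms = "dist_turbine_s",
                                  variance_structure = "none"))
  expect_true(fit$separation)
})

test_that("effect curves: offset construction, direction, CI ordering", {
  des <- sim_design(n_ind = 8, rows = 50, b_dt = -1, b_dl = 0.6, seed = 42)
  fit <- fit_rsf(des, terms = c("land_class", "dist_turbine_s", "dist_linear_s"),
                 variance_structure = "none")
  # uninformative model: all coefficients zero except intercept = logit(pi0)
  null_fit <- fit
  null_fit$coefficients[] <- 0
  null_fit$coefficients["(Intercept)"] <- qlogis(fit$pi0)
  ec0 <- effect_curve(null_fit, "dist_turbine")
  expect_equal(ec0$estimate, rep(0.5, nrow(ec0)))
  # monotone: direction matches the coefficient sign
  ec_dn <- effect_curve(fit, "dist_turbine")
  expect_true(all(diff(ec_dn$estimate) < 0))
  ec_up <- effect_curve(fit, "dist_linear")
  expect_true(all(diff(ec_up$estimate) > 0))
  # CI bounds bracket the estimate inside (0, 1)
  expect_true(all(ec_dn$lower <= ec_dn$estimate & ec_dn$estimate <= ec_dn$upper))
  expect_true(all(ec_dn$lower >= 0 & ec_dn$upper <= 1))
  # grid beyond the observed range warns
  expect_warning(effect_curve(fit, "dist_turbine", grid = c(0, 99)),
                 "extrapolat")
  expect_error(effect_curve(fit, "elevation"), "not in the model")
})

test_that("effect curves are invariant to standardization constants", {
  ls <- iid_landscape(c(conventional_cropland = 0.5, grassland = 0.3,
                        open_water = 0.2), half = 9000, seed = 13,
                      turbines = data.frame(x = c(2000, -3000), y = c(1500, 500),
                                            hub_height = 100, rotor_radius = 33),
                      linear = list(cbind(c(-9000, 9000), c(-2000, -2500))))
  xy <- rw_xy(150, seed = 14, step_mean = 200)
  tr <- make_trip(xy)
  trips <- structure(list(tr), class = "bat_trips")
  crw <- generate_crw(tr, buffer_region(minimum_convex_polygon(xy)),
                      roost = c(0, 0), n_replicates = 5, seed = 3)
  des_s <- assemble_design(trips, list(crw), ls, scale = TRUE)
  des_r <- assemble_design(trips, list(crw), ls, scale = FALSE)
  terms <- c("land_class", "dist_turbine_s", "dist_linear_s")
  fit_s <- fit_rsf(des_s, terms, variance_structure = "none")
  fit_r <- fit_rsf(des_r, terms, variance_structure = "none")
  grid <- seq(500, 4000, length.out = 20)
  ec_s <- effect_curve(fit_s, "dist_turbine", grid = grid)
  ec_r <- effect_curve(fit_r, "dist_turbine", grid = grid)
  expect_equal(ec_s$estimate, ec_r$estimate, tolerance = 1e-6)
  expect_equal(ec_s$lower, ec_r$lower, tolerance = 1e-6)
})

test_that("AIC ranking is ascending with a parsimony tie-break", {
  des <- sim_design(n_ind = 8, rows = 40, sd_ind = 0.5, seed = 7)
  f1 <- fit_rsf(des, terms = c("land_class", "dist_turbine_s"))
  f2 <- fit_rsf(des, terms = c("land_class", "dist_turbine_s"))
  f3 <- fit_rsf(des, terms = c("land_class", "dist_turbine_s", "dist_linear_s",
                               "dist_linear_s:sex"))
  tab <- select_by_aic(list(small_a = f1, small_b = f2, large = f3))
  expect_equal(tab$aic, sort(tab$aic))
  expect_equal(tab$delta_aic[1], 0)
  # identical duplicate formulas tie exactly, and the ranking is stable
  dup <- tab[tab$model %in% c("small_a", "small_b"), ]
  expect_equal(dup$aic[1], dup$aic[2])
  expect_equal(dup$model, c("small_a", "small_b"))
  expect_error(select_by_aic(list(f1)), "length")
  bad1 <- f1; bad1$converged <- FALSE
  bad2 <- f2; bad2$converged <- FALSE
  expect_error(select_by_aic(list(a = bad1, b = bad2)),
               "no candidate model converged")
})

test_that("AIC selection prefers parsimony under noise and finds true interactions", {
  run_pair <- function(seed, interaction) {
    set.seed(seed)
    n <- 2000
    d <- data.frame(
      individual_id = rep(sprintf("I%d", 1:10), each = n / 10),
      trip_id = rep(sprintf("T%d", 1:20), each = n / 20),
      land_class = factor(sample(c("conventional_cropland", "grassland"),
                                 n, TRUE), levels = land_classes()),
      dist_turbine_s = rnorm(n), dist_linear_s = rnorm(n),
      sex = factor(sample(c("F", "M"), n, TRUE)))
    b_int <- if (interaction) 1 else 0  # sex-specific turbine effect
    eta <- -1 + 0.5 * d$dist_turbine_s +
      b_int * d$dist_turbine_s * (d$sex == "M")
    d$presence <- rbinom(n, 1, plogis(eta))
    d$dist_turbine <- d$dist_turbine_s; d$dist_linear <- d$dist_linear_s
    attr(d, "standardization") <- list(
      center = c(dist_turbine = 0, dist_linear = 0),
      scale = c(dist_turbine = 1, dist_linear = 1))
    class(d) <- c("rsf_design", "data.frame")
    if (interaction) {
      small <- fit_rsf(d, terms = "dist_turbine_s", variance_structure = "none")
      large <- fit_rsf(d, terms = c("dist_turbine_s", "dist_turbine_s:sex"),
                       variance_structure = "none")
    } else {
      small <- fit_rsf(d, terms = "dist_turbine_s", variance_structure = "none")
      large <- fit_rsf(d, terms = c("dist_turbine_s", "dist_linear_s"),
                       variance_structure = "none")  # pure-noise covariate
    }
    select_by_aic(list(small = small, large = large))$model[1]
  }
  # a pure-noise covariate: the smaller model should win most of the time
  noise_win <- vapply(1:50, function(s) run_pair(s, FALSE) == "small", TRUE)
  expect_gte(mean(noise_win), 0.7)
  # a real sex-specific effect: the interaction model should win
  int_win <- vapply(101:150, function(s) run_pair(s, TRUE) == "large", TRUE)
  expect_gte(mean(int_win), 0.8)
})

test_that("predict() mirrors the effect-curve machinery", {
  des <- sim_design(n_ind = 8, rows = 40, b_dt = -1, seed = 3)
  fit <- fit_rsf(des, terms = c("land_class", "dist_turbine_s"),
                 variance_structure = "none")
  nd <- data.frame(land_class = "open_water",
                   dist_turbine = c(-1, 0, 1), dist_linear = 0, sex = "F")
  pr <- predict(fit, nd, type = "selection")
  expect_true(all(diff(pr) < 0))  # negative turbine-distance coefficient
  expect_equal(predict(fit, nd, type = "response"),
               plogis(predict(fit, nd, type = "link")))
  # selection probabilities differ from response by the logit(pi0) offset
  expect_equal(qlogis(pr), predict(fit, nd, type = "link") - qlogis(fit$pi0))
})
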