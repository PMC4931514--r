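# Use-availability habitat selection: presence/pseudo-absence design
# assembly, collinearity screen, the binomial random-intercept GLMM (trips
# nested within individuals), AIC model selection, and probability effect
# curves displayed against the 0.5 "use equals availability" benchmark.

#' Assemble the presence/pseudo-absence design table
#'
#' One row per bat fix (`presence = 1`) and per correlated-random-walk
#' vertex (`presence = 0`), annotated with the landscape covariates.
#' Pseudo-absence rows inherit `trip_id`, `individual_id`, `sex` and
#' `season` from their source trip, so with five walks per trip the
#' absence:presence ratio is exactly 5:1. Continuous covariates are centred
#' and scaled (`*_s` columns); the constants are kept so effect curves can
#' be drawn in raw units.
#'
#' @param trips `bat_trips` list.
#' @param pseudo list of `pseudo_trips` (one element per trip, as returned
#'   by [generate_crw()]), or a flat list of `pseudo_trip` objects.
#' @param ls a [landscape].
#' @param scale centre/scale the distance covariates (default TRUE).
#' @return data.frame of class `rsf_design` with attribute
#'   `standardization` (`center`, `scale` for each distance covariate).
#' @export
assemble_design <- function(trips, pseudo, ls, scale = TRUE) {
  if (length(pseudo) && inherits(pseudo[[1]], "pseudo_trips"))
    pseudo <- unlist(pseudo, recursive = FALSE)
  trip_ids <- vapply(trips, `[[`, "", "trip_id")
  orphan <- setdiff(vapply(pseudo, `[[`, "", "source_trip_id"), trip_ids)
  if (length(orphan))
    stop("pseudo-trip(s) with no source trip in `trips`: ",
         paste(orphan, collapse = ", "))
  rows <- list()
  for (tr in trips) {
    cov <- annotate(ls, cbind(tr$fixes$x, tr$fixes$y))
    rows[[length(rows) + 1]] <- data.frame(
      presence = 1L, cov, sex = tr$sex, season = tr$season,
      trip_id = tr$trip_id, individual_id = tr$individual_id,
      stringsAsFactors = FALSE)
  }
  for (ps in pseudo) {
    tr <- trips[[match(ps$source_trip_id, trip_ids)]]
    cov <- annotate(ls, ps$fixes)
    rows[[length(rows) + 1]] <- data.frame(
      presence = 0L, cov, sex = tr$sex, season = tr$season,
      trip_id = tr$trip_id, individual_id = tr$individual_id,
      stringsAsFactors = FALSE)
  }
  d <- do.call(rbind, rows)
  d$sex <- factor(d$sex)
  ctr <- c(dist_turbine = 0, dist_linear = 0)
  scl <- c(dist_turbine = 1, dist_linear = 1)
  if (scale) {
    for (v in c("dist_turbine", "dist_linear")) {
      ctr[v] <- mean(d[[v]][is.finite(d[[v]])])
      s <- stats::sd(d[[v]][is.finite(d[[v]])])
      scl[v] <- if (is.finite(s) && s > 0) s else 1
    }
  }
  d$dist_turbine_s <- (d$dist_turbine - ctr["dist_turbine"]) / scl["dist_turbine"]
  d$dist_linear_s <- (d$dist_linear - ctr["dist_linear"]) / scl["dist_linear"]
  structure(d, class = c("rsf_design", "data.frame"),
            standardization = list(center = ctr, scale = scl))
}

#' Pairwise collinearity screen for continuous covariates
#'
#' Pearson correlations among the continuous covariates; any pair with
#' `|r| >= threshold` is flagged and, unless `override = TRUE`, stops the
#' analysis — collinear predictors make the selection coefficients
#' uninterpretable.
#'
#' @param design an `rsf_design` (or data.frame).
#' @param vars continuous covariate columns (default the distance
#'   covariates).
#' @param threshold absolute-correlation limit (default 0.25).
#' @param override proceed despite flagged pairs (default FALSE).
#' @return data.frame of class `correlation_screen`: `var1`, `var2`, `r`,
#'   `flagged`.
#' @export
correlation_screen <- function(design, vars = c("dist_turbine", "dist_linear"),
                               threshold = 0.25, override = FALSE) {
  stopifnot(length(vars) >= 2)
  for (v in vars)
    if (stats::sd(design[[v]]) == 0)
      stop("undefined correlation: covariate '", v, "' is constant")
  pairs <- utils::combn(vars, 2)
  rep <- data.frame(var1 = pairs[1, ], var2 = pairs[2, ],
                    r = apply(pairs, 2, function(p)
                      stats::cor(design[[p[1]]], design[[p[2]]])),
                    stringsAsFactors = FALSE)
  rep$flagged <- abs(rep$r) >= threshold
  if (any(rep$flagged) && !override)
    stop("collinear covariates (|r| >= ", threshold, "): ",
         paste(sprintf("%s~%s (r = %.2f)", rep$var1[rep$flagged],
                       rep$var2[rep$flagged], rep$r[rep$flagged]),
               collapse = ", "),
         "; set override = TRUE to proceed")
  structure(rep, class = c("correlation_screen", "data.frame"),
            threshold = threshold)
}

#' Fit the binomial habitat-selection GLMM
#'
#' Maximum-likelihood fit (Laplace approximation) of
#' `logit P(presence) = fixed terms + b_individual + b_trip(individual)`,
#' with both random intercepts Normal(0, sigma^2). Fixed terms are given as
#' a character vector of model terms over the design columns (`land_class`,
#' `dist_turbine_s`, `dist_linear_s`, interactions with `sex`, ...). The
#' land-use reference level is conventional cropland, the dominant class.
#'
#' `variance_structure = "none"` pins both random-effect variances to zero
#' and maximises the same Laplace deviance over the fixed effects only; the
#' result then coincides with an ordinary logistic regression.
#'
#' @param design an `rsf_design` from [assemble_design()].
#' @param terms character vector of fixed-effect terms; the default is the
#'   full structure: land use, both distances, and their sex interactions.
#' @param variance_structure `"nested"` (default) or `"none"`.
#' @param reference_class land-use reference level.
#' @return object of class `rsf_fit`; see [summary.rsf_fit()]. Fields
#'   include `coefficients`, `se`, `vcov`, `variances`, `loglik`, `aic`,
#'   `k`, `converged`, `separation`, `pi0` (presence fraction),
#'   `standardization`, and the underlying lme4 fit as `model` (nested
#'   structure only).
#' @export
fit_rsf <- function(design,
                    terms = c("land_class", "dist_turbine_s", "dist_linear_s",
                              "land_class:sex", "dist_turbine_s:sex",
                              "dist_linear_s:sex"),
                    variance_structure = c("nested", "none"),
                    reference_class = "conventional_cropland") {
  variance_structure <- match.arg(variance_structure)
  d <- as.data.frame(design)
  d$land_class <- stats::relevel(factor(d$land_class), ref = reference_class)
  d <- droplevels(d)
  bad <- !is.finite(d$dist_turbine_s) | !is.finite(d$dist_linear_s)
  if (any(bad)) stop("non-finite distance covariates (empty turbine or ",
                     "linear layer?); cannot fit")
  fixed_formula <- stats::reformulate(terms, response = "presence")
  std <- attr(design, "standardization")
  if (variance_structure == "nested") {
    fml <- stats::update(fixed_formula, . ~ . + (1 | individual_id / trip_id))
    fit <- lme4::glmer(fml, data = d, family = stats::binomial(),
                       control = lme4::glmerControl(calc.derivs = FALSE))
    beta <- lme4::fixef(fit)
    V <- as.matrix(stats::vcov(fit))
    vc <- lme4::VarCorr(fit)
    variances <- c(
      individual = unname(vc$individual_id[1, 1]),
      trip_within_individual = unname(vc$`trip_id:individual_id`[1, 1]))
    ll <- as.numeric(stats::logLik(fit))
    k <- length(beta) + 2L
    conv <- fit@optinfo$conv$opt == 0 &&
      length(fit@optinfo$conv$lme4$messages) == 0
    model <- fit
  } else {
    # with both variances pinned at zero the marginal (Laplace) likelihood
    # reduces exactly to the Bernoulli likelihood of the fixed effects;
    # maximise that deviance directly (BFGS with analytic gradient on
    # internally whitened columns)
    X <- stats::model.matrix(fixed_formula, d)
    y <- d$presence
    sc <- apply(X, 2, stats::sd)
    sc[sc == 0 | !is.finite(sc)] <- 1
    Xs <- sweep(X, 2, sc, "/")
    dev <- function(g) {
      eta <- drop(Xs %*% g)
      -2 * sum(y * eta - (pmax(eta, 0) + log1p(exp(-abs(eta)))))
    }
    grad <- function(g) drop(-2 * crossprod(Xs, y - stats::plogis(Xs %*% g)))
    opt <- stats::optim(numeric(ncol(X)), dev, grad, method = "BFGS",
                        control = list(maxit = 1000, reltol = 1e-14))
    opt <- stats::optim(opt$par, dev, grad, method = "BFGS",
                        control = list(maxit = 1000, reltol = 1e-14))
    beta <- stats::setNames(opt$par / sc, colnames(X))
    p_hat <- stats::plogis(drop(X %*% beta))
    H <- crossprod(X, X * (p_hat * (1 - p_hat)))  # observed = expected info
    V <- solve(H)
    dimnames(V) <- list(names(beta), names(beta))
    variances <- c(individual = 0, trip_within_individual = 0)
    ll <- -opt$value / 2
    k <- length(beta)
    conv <- opt$convergence == 0
    model <- NULL
  }
  if (!conv)
    warning("selection model did not converge cleanly; inspect the fit")
  separation <- any(abs(beta) > 15)
  if (separation)
    warning("possible complete separation: |coefficient| > 15 on the ",
            "standardized scale")
  structure(list(
    coefficients = beta, se = sqrt(diag(V)), vcov = V,
    variances = variances, loglik = ll, aic = 2 * k - 2 * ll, k = k,
    converged = conv, separation = separation,
    formula = deparse(fixed_formula), terms = terms,
    fixed_formula = fixed_formula,
    pi0 = mean(d$presence),
    n = nrow(d),
    reference_class = reference_class,
    xlevels = list(land_class = levels(d$land_class), sex = levels(d$sex)),
    ranges = list(dist_turbine = range(d$dist_turbine),
                  dist_linear = range(d$dist_linear)),
    means = c(dist_turbine = mean(d$dist_turbine),
              dist_linear = mean(d$dist_linear)),
    standardization = std,
    variance_structure = variance_structure,
    model = model), class = "rsf_fit")
}

#' @export
print.rsf_fit <- function(x, ...) {
  cat("Use-availability selection GLMM (binomial, logit link)\n")
  cat("  fixed:", x$formula, "\n")
  cat(sprintf("  random intercepts: individual (sigma^2 = %.3f), trip within individual (sigma^2 = %.3f)\n",
              x$variances["individual"], x$variances["trip_within_individual"]))
  cat(sprintf("  n = %d (presence fraction %.3f), logLik = %.2f, AIC = %.2f%s\n",
              x$n, x$pi0, x$loglik, x$aic,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  invisible(x)
}

#' @export
coef.rsf_fit <- function(object, ...) object$coefficients

#' @export
logLik.rsf_fit <- function(object, ...) {
  structure(object$loglik, df = object$k, class = "logLik")
}

#' Coefficient table for a selection fit
#'
#' @param object an `rsf_fit`.
#' @param ... unused.
#' @return list of class `summary.rsf_fit` with a Wald coefficient table
#'   (`Estimate`, `SE`, `z`, `p`) and the variance components.
#' @export
summary.rsf_fit <- function(object, ...) {
  z <- object$coefficients / object$se
  tab <- cbind(Estimate = object$coefficients, SE = object$se, z = z,
               p = 2 * stats::pnorm(-abs(z)))
  structure(list(coefficients = tab, variances = object$variances,
                 loglik = object$loglik, aic = object$aic,
                 converged = object$converged, formula = object$formula,
                 n = object$n), class = "summary.rsf_fit")
}

#' @export
print.summary.rsf_fit <- function(x, ...) {
  cat("Use-availability selection GLMM\n  fixed:", x$formula, "\n\n")
  stats::printCoefmat(x$coefficients, P.values = TRUE, has.Pvalue = TRUE)
  cat(sprintf("\nsigma^2 individual = %.3f, sigma^2 trip:individual = %.3f\n",
              x$variances[1], x$variances[2]))
  cat(sprintf("logLik = %.2f, AIC = %.2f, n = %d%s\n", x$loglik, x$aic, x$n,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  invisible(x)
}

# fixed-effect design matrix for new data, aligned to the fit's coefficients
rsf_model_matrix <- function(fit, newdata) {
  newdata$land_class <- factor(newdata$land_class, levels = fit$xlevels$land_class)
  if (!is.null(fit$xlevels$sex) && length(fit$xlevels$sex))
    newdata$sex <- factor(newdata$sex, levels = fit$xlevels$sex)
  X <- stats::model.matrix(fit$fixed_formula[-2], newdata)
  miss <- setdiff(names(fit$coefficients), colnames(X))
  if (length(miss)) stop("cannot build design columns: ",
                         paste(miss, collapse = ", "))
  X[, names(fit$coefficients), drop = FALSE]
}

#' Predict from a selection fit
#'
#' Population-level prediction (random effects at zero). `type =
#' "selection"` removes the design's presence:absence imbalance with the
#' fixed offset `logit(pi0)` so that an uninformative model predicts 0.5:
#' values above 0.5 mean use exceeds availability.
#'
#' @param object an `rsf_fit`.
#' @param newdata data.frame with the model's covariate columns (`*_s`
#'   columns are recomputed from raw `dist_turbine`/`dist_linear` when
#'   absent).
#' @param type `"link"`, `"response"`, or `"selection"`.
#' @param ... unused.
#' @export
predict.rsf_fit <- function(object, newdata,
                            type = c("selection", "response", "link"), ...) {
  type <- match.arg(type)
  std <- object$standardization
  if (is.null(newdata$dist_turbine_s) && !is.null(newdata$dist_turbine))
    newdata$dist_turbine_s <-
      (newdata$dist_turbine - std$center["dist_turbine"]) / std$scale["dist_turbine"]
  if (is.null(newdata$dist_linear_s) && !is.null(newdata$dist_linear))
    newdata$dist_linear_s <-
      (newdata$dist_linear - std$center["dist_linear"]) / std$scale["dist_linear"]
  eta <- drop(rsf_model_matrix(object, newdata) %*% object$coefficients)
  switch(type,
         link = eta,
         response = stats::plogis(eta),
         selection = stats::plogis(eta - stats::qlogis(object$pi0)))
}

#' Rank candidate selection models by AIC
#'
#' @param fits list of `rsf_fit` objects (give it names for readable
#'   labels).
#' @return data.frame of class `aic_table` sorted by AIC (ties broken by
#'   fewer parameters): `model`, `k`, `loglik`, `aic`, `delta_aic`,
#'   `converged`.
#' @export
select_by_aic <- function(fits) {
  stopifnot(length(fits) >= 2)
  if (all(!vapply(fits, `[[`, TRUE, "converged")))
    stop("no candidate model converged")
  labels <- names(fits)
  if (is.null(labels)) labels <- paste0("model_", seq_along(fits))
  tab <- data.frame(model = labels,
                    k = vapply(fits, `[[`, 0L, "k"),
                    loglik = vapply(fits, `[[`, 0, "loglik"),
                    aic = vapply(fits, `[[`, 0, "aic"),
                    converged = vapply(fits, `[[`, TRUE, "converged"),
                    stringsAsFactors = FALSE)
  tab <- tab[order(tab$aic, tab$k), , drop = FALSE]
  tab$delta_aic <- tab$aic - tab$aic[1]
  rownames(tab) <- NULL
  structure(tab, class = c("aic_table", "data.frame"))
}

#' Selection-probability effect curve with 95% CI
#'
#' Selection probability along a covariate grid (or across land-use
#' classes) for one sex stratum, other covariates held at reference values
#' (mean distances, reference land class) and random effects at zero. The
#' presence:absence imbalance is removed via the `logit(pi0)` offset, so
#' 0.5 is the "use equals availability" benchmark. CIs are Wald 95% on the
#' logit scale, then transformed — bounds always stay in (0, 1) and bracket
#' the estimate.
#'
#' @param fit an `rsf_fit`.
#' @param variable `"land_class"`, `"dist_turbine"` or `"dist_linear"`.
#' @param grid covariate values in raw metres (continuous variables);
#'   default 100 points over the observed range. Values outside the
#'   observed range trigger an extrapolation warning.
#' @param sex stratum level; default the model's first.
#' @return data.frame of class `effect_curve`: `variable`, `value` (or
#'   class level), `sex`, `estimate`, `lower`, `upper`.
#' @export
effect_curve <- function(fit, variable, grid = NULL, sex = NULL) {
  stopifnot(inherits(fit, "rsf_fit"))
  if (is.null(sex)) sex <- fit$xlevels$sex[1]
  std <- fit$standardization
  # reference values: the mean raw distance, mapped through this fit's own
  # standardization (so curves agree whether the fit used raw or scaled
  # covariates)
  ref <- (fit$means - std$center[names(fit$means)]) / std$scale[names(fit$means)]
  if (variable == "land_class") {
    vals <- fit$xlevels$land_class
    newdata <- data.frame(land_class = vals,
                          dist_turbine_s = ref[["dist_turbine"]],
                          dist_linear_s = ref[["dist_linear"]], sex = sex)
  } else if (variable %in% c("dist_turbine", "dist_linear")) {
    rng <- fit$ranges[[variable]]
    if (is.null(grid)) grid <- seq(rng[1], rng[2], length.out = 100)
    if (any(grid < rng[1] - 1e-9 | grid > rng[2] + 1e-9))
      warning("grid extends beyond the observed ", variable, " range; ",
              "curve extrapolates")
    vals <- grid
    s <- (grid - std$center[variable]) / std$scale[variable]
    newdata <- data.frame(land_class = fit$reference_class,
                          dist_turbine_s = if (variable == "dist_turbine") s
                          else ref[["dist_turbine"]],
                          dist_linear_s = if (variable == "dist_linear") s
                          else ref[["dist_linear"]],
                          sex = sex)
  } else stop("variable '", variable, "' is not in the model")
  X <- rsf_model_matrix(fit, newdata)
  eta <- drop(X %*% fit$coefficients) - stats::qlogis(fit$pi0)
  se <- sqrt(rowSums((X %*% fit$vcov) * X))
  structure(data.frame(variable = variable, value = vals, sex = sex,
                       estimate = stats::plogis(eta),
                       lower = stats::plogis(eta - 1.96 * se),
                       upper = stats::plogis(eta + 1.96 * se),
                       stringsAsFactors = FALSE),
            class = c("effect_curve", "data.frame"))
}

#' Plot an effect curve (or one straight from a fit)
#'
#' @param x an `rsf_fit`.
#' @param variable,sex passed to [effect_curve()].
#' @param ... further graphics arguments.
#' @export
plot.rsf_fit <- function(x, variable = "land_class", sex = NULL, ...) {
  ec <- effect_curve(x, variable, sex = sex)
  if (variable == "land_class") {
    n <- nrow(ec)
    graphics::plot(seq_len(n), ec$estimate, ylim = c(0, 1), xaxt = "n",
                   xlab = "", ylab = "selection probability", pch = 19, ...)
    graphics::axis(1, at = seq_len(n), labels = ec$value, las = 2, cex.axis = 0.7)
    graphics::arrows(seq_len(n), ec$lower, seq_len(n), ec$upper,
                     angle = 90, code = 3, length = 0.04)
  } else {
    graphics::plot(ec$value, ec$estimate, type = "l", ylim = c(0, 1),
                   xlab = paste(variable, "(m)"), ylab = "selection probability", ...)
    graphics::lines(ec$value, ec$lower, lty = 2)
    graphics::lines(ec$value, ec$upper, lty = 2)
  }
  graphics::abline(h = 0.5, col = "grey")
  invisible(ec)
}
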