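#' Semivariogram model
#'
#' Parametric isotropic semivariogram `gamma(h) = nugget + psill * f(h/range)`
#' for `h > 0` and `gamma(0) = 0`, with `f` the exponential
#' (`1 - exp(-h/range)`), spherical, or gaussian unit curve.
#'
#' @param family One of `"exponential"`, `"spherical"`, `"gaussian"`.
#' @param nugget Nugget variance ((ug/m3)^2), >= 0.
#' @param psill Partial sill ((ug/m3)^2), >= 0.
#' @param range Range parameter (km), > 0.
#' @param convergence Optional fit-convergence flag carried from [fit_variogram()].
#' @return An object of class `variogram_model`.
#' @export
variogram_model <- function(family = c("exponential", "spherical", "gaussian"),
                            nugget = 0, psill = 1, range = 10,
                            convergence = NA) {
  family <- match.arg(family)
  stopifnot(nugget >= 0, psill >= 0, range > 0)
  structure(list(family = family, nugget = nugget, psill = psill,
                 range = range, convergence = convergence),
            class = "variogram_model")
}

#' @export
print.variogram_model <- function(x, ...) {
  cat(sprintf("variogram_model: %s, nugget %.4g, partial sill %.4g, range %.4g km\n",
              x$family, x$nugget, x$psill, x$range))
  invisible(x)
}

# unit semivariance curve, f(0) = 0, f(inf) = 1
unit_gamma <- function(h, family, range) {
  switch(family,
    exponential = 1 - exp(-h / range),
    gaussian = 1 - exp(-(h / range)^2),
    spherical = ifelse(h >= range, 1, 1.5 * h / range - 0.5 * (h / range)^3)
  )
}

#' Evaluate a semivariogram model
#'
#' @param vm A [variogram_model()].
#' @param h Distances (km).
#' @return Semivariances; exactly 0 at `h = 0`.
#' @export
semivariance <- function(vm, h) {
  ifelse(h <= 0, 0, vm$nugget + vm$psill * unit_gamma(h, vm$family, vm$range))
}

#' Pooled empirical semivariogram of daily station measurements
#'
#' Classical Matheron estimator on station pairs, pooled across days after
#' removing each day's cross-station mean (so day-to-day regional swings do
#' not inflate the spatial structure). Bins with fewer than 30 pairs are
#' flagged.
#'
#' @param stations Long data.frame: `station_id`, `x_km`, `y_km`, `date`, and
#'   a value column.
#' @param n_bins Number of distance bins.
#' @param max_dist Maximum pair distance (km); default half the largest
#'   station separation... times 1.5 (covers sparse networks).
#' @param value_col Name of the value column (default `"pm25"`).
#' @param demean Remove each day's station mean before pairing?
#' @return data.frame `dist` (mean pair distance per bin), `gamma`,
#'   `n_pairs`, `flagged`; empty bins are dropped.
#' @export
empirical_variogram <- function(stations, n_bins = 15, max_dist = NULL,
                                value_col = "pm25", demean = TRUE) {
  if (length(unique(stations$station_id)) < 2) {
    stop("need at least 2 stations to form pairs")
  }
  days <- split(stations, stations$date)
  # pair distances are the same whenever the station set repeats; cache by key
  acc_d <- list(); acc_g <- list()
  for (dd in days) {
    n <- nrow(dd)
    if (n < 2) next
    z <- dd[[value_col]]
    if (demean) z <- z - mean(z)
    dmat <- euclid(rep(dd$x_km, times = n), rep(dd$y_km, times = n),
                   rep(dd$x_km, each = n), rep(dd$y_km, each = n))
    dmat <- matrix(dmat, n, n)
    ut <- upper.tri(dmat)
    acc_d[[length(acc_d) + 1L]] <- dmat[ut]
    acc_g[[length(acc_g) + 1L]] <- (outer(z, z, "-")[ut])^2 / 2
  }
  d <- unlist(acc_d); gsq <- unlist(acc_g)
  if (is.null(max_dist)) max_dist <- max(d)
  keep <- d <= max_dist & d > 0
  d <- d[keep]; gsq <- gsq[keep]
  bin <- pmin(ceiling(d / max_dist * n_bins), n_bins)
  out <- data.frame(
    dist = as.vector(tapply(d, bin, mean)),
    gamma = as.vector(tapply(gsq, bin, mean)),
    n_pairs = as.vector(tapply(gsq, bin, length))
  )
  out <- out[!is.na(out$gamma), ]
  out$flagged <- out$n_pairs < 30
  rownames(out) <- NULL
  out
}

#' Fit a semivariogram model to binned semivariances
#'
#' Weighted least squares with pair-count weights; parameters constrained
#' non-negative. A fit collapsing to zero partial sill falls back to a
#' nugget-only model with a warning.
#'
#' @param emp Binned semivariances (see [empirical_variogram()]).
#' @param family Model family.
#' @return A [variogram_model()] with a `convergence` flag.
#' @export
fit_variogram <- function(emp, family = c("exponential", "spherical", "gaussian")) {
  family <- match.arg(family)
  stopifnot(nrow(emp) >= 3)
  w <- emp$n_pairs / sum(emp$n_pairs)
  obj <- function(p) {
    vm <- list(family = family, nugget = p[1], psill = p[2], range = p[3])
    sum(w * (emp$gamma - (p[1] + p[2] * unit_gamma(emp$dist, family, p[3])))^2)
  }
  sill0 <- max(emp$gamma)
  start <- c(nugget = max(min(emp$gamma), 0), psill = max(sill0 - min(emp$gamma), 1e-8),
             range = max(emp$dist) / 3)
  fit <- stats::optim(start, obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-14))
  fit <- stats::optim(fit$par, obj, method = "L-BFGS-B",
                      lower = c(0, 0, 1e-6),
                      upper = c(Inf, Inf, 10 * max(emp$dist)),
                      control = list(factr = 10))
  p <- fit$par
  if (p[2] <= 1e-10 * max(sill0, 1)) {
    warning("degenerate variogram fit (zero partial sill); falling back to nugget-only model")
    return(variogram_model(family, nugget = stats::weighted.mean(emp$gamma, w),
                           psill = 0, range = max(emp$dist),
                           convergence = fit$convergence))
  }
  variogram_model(family, nugget = unname(p[1]), psill = unname(p[2]),
                  range = max(unname(p[3]), 1e-6),
                  convergence = fit$convergence)
}

# Ordinary-kriging solve in semivariance form with a Lagrange multiplier.
# stations: data.frame x_km, y_km, value (one day, deduplicated).
# Returns predictions, kriging variances, and (optionally) the weight matrix.
ok_predict <- function(stations, vm, px, py, return_weights = FALSE) {
  n <- nrow(stations)
  if (n == 1) {
    warning("single station: ordinary kriging degenerates to a constant surface")
    return(list(pred = rep(stations$value, length(px)),
                var = rep(vm$nugget + vm$psill, length(px)),
                weights = matrix(1, 1, length(px))))
  }
  dmat <- matrix(euclid(rep(stations$x_km, times = n), rep(stations$y_km, times = n),
                        rep(stations$x_km, each = n), rep(stations$y_km, each = n)),
                 n, n)
  A <- rbind(cbind(semivariance(vm, dmat), 1), c(rep(1, n), 0))
  m <- length(px)
  d0 <- matrix(euclid(rep(stations$x_km, times = m), rep(stations$y_km, times = m),
                      rep(px, each = n), rep(py, each = n)), n, m)
  B <- rbind(semivariance(vm, d0), rep(1, m))
  W <- solve(A, B)
  pred <- as.vector(crossprod(W[seq_len(n), , drop = FALSE], stations$value))
  kvar <- pmax(colSums(W * B), 0)
  list(pred = pred, var = kvar,
       weights = if (return_weights) W[seq_len(n), , drop = FALSE] else NULL,
       lagrange = W[n + 1, ])
}

# average duplicate station coordinates for one day's table
dedupe_stations <- function(st) {
  key <- paste(signif(st$x_km, 12), signif(st$y_km, 12))
  if (anyDuplicated(key)) {
    warning("duplicate station coordinates; averaging their values")
    st <- do.call(rbind, lapply(split(st, key), function(s) {
      s$value[1] <- mean(s$value); s[1, , drop = FALSE]
    }))
  }
  st
}

#' Ordinary-kriging daily surface (single-sourced model)
#'
#' Predicts every grid cell center from one day's station values by ordinary
#' kriging with a global neighbourhood: the full kriging system with a
#' Lagrange multiplier is solved, so weights sum to one at every cell and
#' the predictor interpolates the stations exactly. Negative predictions are
#' clipped to zero.
#'
#' @param stations_day One day's station rows (`x_km`, `y_km`, `pm25`, `date`).
#' @param vm A [variogram_model()].
#' @param grid Target [pm_grid()].
#' @param value_col Value column name.
#' @return A [pm_surface()] with `model_tag = 0`; attribute `kriging_var`
#'   holds the per-cell kriging variance.
#' @export
krige_surface <- function(stations_day, vm, grid, value_col = "pm25") {
  st <- data.frame(x_km = stations_day$x_km, y_km = stations_day$y_km,
                   value = stations_day[[value_col]])
  st <- dedupe_stations(st)
  cc <- grid_centers(grid)
  ok <- ok_predict(st, vm, cc$x, cc$y)
  vals <- pmax(ok$pred, 0)
  surf <- pm_surface(grid, matrix(vals, grid$ny, grid$nx, byrow = TRUE),
                     date = stations_day$date[1], model_tag = 0L)
  attr(surf, "kriging_var") <- matrix(ok$var, grid$ny, grid$nx, byrow = TRUE)
  surf
}

# covariate design matrix at arbitrary points
covariate_matrix <- function(covariates, x, y) {
  if (is.null(covariates) || !length(covariates)) {
    return(matrix(numeric(0), nrow = length(x), ncol = 0))
  }
  X <- vapply(covariates, function(s) surface_value_at(s, x, y, clamp = TRUE),
              numeric(length(x)))
  matrix(X, nrow = length(x),
         dimnames = list(NULL, names(covariates)))
}

#' Pooled covariate-trend coefficients
#'
#' Regresses station values on time-invariant covariates pooled across all
#' days, with one intercept per day (equivalently, a within-day demeaned
#' regression). Pooling borrows strength across the record — essential when
#' the daily network has only a handful of stations. Collinear covariate
#' columns are dropped with a warning (zero coefficient).
#'
#' @param stations Long station data.frame covering all days.
#' @param covariates Named list of covariate [pm_surface()]s.
#' @param value_col Value column name.
#' @return Named coefficient vector (one per covariate, no intercept).
#' @export
fit_pooled_trend <- function(stations, covariates, value_col = "pm25") {
  X <- covariate_matrix(covariates, stations$x_km, stations$y_km)
  z <- stations[[value_col]]
  for (rows in split(seq_len(nrow(stations)), stations$date)) {
    z[rows] <- z[rows] - mean(z[rows])
    X[rows, ] <- sweep(X[rows, , drop = FALSE], 2, colMeans(X[rows, , drop = FALSE]))
  }
  fit <- stats::lm.fit(X, z)
  beta <- fit$coefficients
  if (anyNA(beta)) {
    warning("rank-deficient covariates; dropping aliased columns")
    beta[is.na(beta)] <- 0
  }
  stats::setNames(as.vector(beta), colnames(X))
}

#' Regression-kriging daily surface (multi-sourced model)
#'
#' Covariate trend plus ordinary kriging of the trend residuals:
#' `surface = a_d + X beta + OK(residuals_d)`, where `beta` are the covariate
#' coefficients (pooled across days by default, see [fit_pooled_trend()])
#' and `a_d` is the day's intercept given `beta`. Because the residuals are
#' kriged exactly at the stations, the surface interpolates the station
#' values. A `NULL` residual variogram reduces the surface to the trend
#' alone; with no covariates the result equals [krige_surface()].
#'
#' @param stations_day One day's station rows.
#' @param covariates Named list of covariate [pm_surface()]s aligned to `grid`.
#' @param grid Target [pm_grid()].
#' @param vm Residual [variogram_model()] (typically fitted on pooled
#'   residuals, see [fit_surface_variogram()]); `NULL` for trend-only.
#' @param beta Trend coefficients; fitted from this single day when `NULL`
#'   (needs at least p + 2 stations).
#' @param value_col Value column name.
#' @return A [pm_surface()] with `model_tag = 1`.
#' @export
multisource_surface <- function(stations_day, covariates, grid, vm,
                                beta = NULL, value_col = "pm25") {
  st <- data.frame(x_km = stations_day$x_km, y_km = stations_day$y_km,
                   value = stations_day[[value_col]])
  st <- dedupe_stations(st)
  X <- covariate_matrix(covariates, st$x_km, st$y_km)
  if (ncol(X) == 0) {
    surf <- krige_surface(stations_day, vm, grid, value_col)
    surf$model_tag <- 1L
    return(surf)
  }
  if (is.null(beta)) {
    if (nrow(st) < ncol(X) + 2) {
      stop("need at least p + 2 stations for ", ncol(X), " covariates")
    }
    fit <- stats::lm.fit(cbind(1, X), st$value)
    beta <- fit$coefficients[-1]
    if (anyNA(beta)) {
      warning("rank-deficient covariates; dropping aliased columns")
      beta[is.na(beta)] <- 0
    }
  }
  a_d <- mean(st$value - as.vector(X %*% beta))
  resid <- st$value - a_d - as.vector(X %*% beta)
  cc <- grid_centers(grid)
  Xg <- covariate_matrix(covariates, cc$x, cc$y)
  trend <- a_d + as.vector(Xg %*% beta)
  resid_pred <- 0
  if (!is.null(vm) && (vm$psill > 0 || vm$nugget > 0)) {
    stres <- st; stres$value <- resid
    resid_pred <- ok_predict(stres, vm, cc$x, cc$y)$pred
  }
  vals <- pmax(trend + resid_pred, 0)
  pm_surface(grid, matrix(vals, grid$ny, grid$nx, byrow = TRUE),
             date = stations_day$date[1], model_tag = 1L)
}

#' Fit the pooled surface variogram for one exposure-model scenario
#'
#' For the single-sourced model the empirical variogram pools daily-demeaned
#' station values; for the multi-sourced model it pools the residuals of the
#' per-day covariate regressions. One pooled fit is used for all days, which
#' is far more stable than daily fits on a handful of stations.
#'
#' @param stations Long station data.frame.
#' @param covariates Covariate rasters (multi-sourced) or `NULL` (single).
#' @param family Variogram family.
#' @param n_bins,max_dist Passed to [empirical_variogram()].
#' @return A [variogram_model()].
#' @export
fit_surface_variogram <- function(stations, covariates = NULL,
                                  family = "exponential",
                                  n_bins = 15, max_dist = NULL) {
  st <- stations
  if (!is.null(covariates) && length(covariates)) {
    beta <- fit_pooled_trend(st, covariates)
    X <- covariate_matrix(covariates, st$x_km, st$y_km)
    st$pm25 <- st$pm25 - as.vector(X %*% beta)
  }
  emp <- empirical_variogram(st, n_bins = n_bins, max_dist = max_dist)
  fit_variogram(emp, family = family)
}

#' Build the daily surface stack for one exposure-model scenario
#'
#' @param stations Long station data.frame covering all days.
#' @param grid Target [pm_grid()].
#' @param model `"single"` (ordinary kriging) or `"multi"`
#'   (regression-kriging on `covariates`).
#' @param covariates Covariate rasters for the multi-sourced model.
#' @param family Variogram family.
#' @param vm Optional pre-fitted [variogram_model()]; fitted from the data
#'   when `NULL`.
#' @return list with `surfaces` (list of [pm_surface()] by date), `dates`,
#'   and `variogram`.
#' @export
build_surfaces <- function(stations, grid, model = c("single", "multi"),
                           covariates = NULL, family = "exponential",
                           vm = NULL) {
  model <- match.arg(model)
  if (is.null(vm)) {
    vm <- fit_surface_variogram(stations,
                                if (model == "multi") covariates else NULL,
                                family = family)
  }
  beta <- NULL
  if (model == "multi" && !is.null(covariates) && length(covariates)) {
    beta <- fit_pooled_trend(stations, covariates)
  }
  days <- split(stations, stations$date)
  surfaces <- lapply(days, function(dd) {
    if (model == "single") krige_surface(dd, vm, grid)
    else multisource_surface(dd, covariates, grid, vm, beta = beta)
  })
  list(surfaces = unname(surfaces),
       dates = as.Date(names(days)), variogram = vm, trend_beta = beta)
}

#' Spatial k-fold cross-validation of a surface model
#'
#' Stations (not station-days) are randomly partitioned into `k` folds; each
#' fold's station-days are predicted from the remaining stations' data, with
#' the variogram refitted on training stations only. Errors are pooled over
#' all held-out station-days. `mpe` is signed as predicted minus observed.
#'
#' @param stations Long station data.frame.
#' @param model `"single"` or `"multi"`.
#' @param covariates Covariate rasters (multi-sourced model).
#' @param k Number of folds.
#' @param seed Integer seed for the fold assignment.
#' @param family Variogram family.
#' @return list of class `cv_report`: `rmse`, `mpe`, `r2` (pooled
#'   `1 - SSE/SST`), `n_folds`, `fold_assignment`.
#' @export
spatial_cv <- function(stations, model = c("single", "multi"),
                       covariates = NULL, k = 10, seed = 1L,
                       family = "exponential") {
  model <- match.arg(model)
  ids <- sort(unique(stations$station_id))
  if (k > length(ids)) stop("k = ", k, " exceeds ", length(ids), " stations")
  fold <- with_seed(seed, {
    f <- rep(seq_len(k), length.out = length(ids))
    sample(f)
  })
  names(fold) <- ids
  pred_all <- obs_all <- numeric(0)
  for (f in seq_len(k)) {
    test_ids <- ids[fold == f]
    train <- stations[!stations$station_id %in% test_ids, ]
    test <- stations[stations$station_id %in% test_ids, ]
    vm <- fit_surface_variogram(train,
                                if (model == "multi") covariates else NULL,
                                family = family)
    beta <- NULL
    if (model == "multi" && !is.null(covariates) && length(covariates)) {
      beta <- fit_pooled_trend(train, covariates)
    }
    for (dd in split(train, train$date)) {
      te <- test[test$date == dd$date[1], ]
      if (!nrow(te)) next
      if (model == "single") {
        st <- dedupe_stations(data.frame(x_km = dd$x_km, y_km = dd$y_km,
                                         value = dd$pm25))
        p <- ok_predict(st, vm, te$x_km, te$y_km)$pred
      } else {
        X <- covariate_matrix(covariates, dd$x_km, dd$y_km)
        a_d <- mean(dd$pm25 - as.vector(X %*% beta))
        Xt <- covariate_matrix(covariates, te$x_km, te$y_km)
        trend <- a_d + as.vector(Xt %*% beta)
        st <- dedupe_stations(data.frame(
          x_km = dd$x_km, y_km = dd$y_km,
          value = dd$pm25 - a_d - as.vector(X %*% beta)))
        p <- trend + ok_predict(st, vm, te$x_km, te$y_km)$pred
      }
      pred_all <- c(pred_all, pmax(p, 0))
      obs_all <- c(obs_all, te$pm25)
    }
  }
  err <- pred_all - obs_all
  structure(list(
    rmse = sqrt(mean(err^2)),
    mpe = mean(err),
    r2 = 1 - sum(err^2) / sum((obs_all - mean(obs_all))^2),
    n_folds = k,
    fold_assignment = fold
  ), class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("spatial %d-fold CV: RMSE %.3f, MPE %+.3f ug/m3, R2 %.3f\n",
              x$n_folds, x$rmse, x$mpe, x$r2))
  invisible(x)
}

#' Daily spatial mean/SD comparison of two surface stacks
#'
#' Quantifies the smoothing behaviour of the two exposure models: per day,
#' the spatial mean and spatial standard deviation of each stack, plus a
#' quantile summary of both distributions.
#'
#' @param surfaces_a,surfaces_b Lists of [pm_surface()] on identical dates
#'   and grids.
#' @param labels Stack labels.
#' @return list with `daily` (per-day table) and `summary`
#'   (model x statistic quantile table).
#' @export
smoothing_diagnostic <- function(surfaces_a, surfaces_b,
                                 labels = c("single", "multi")) {
  da <- vapply(surfaces_a, function(s) as.character(s$date), character(1))
  db <- vapply(surfaces_b, function(s) as.character(s$date), character(1))
  if (!identical(da, db)) stop("surface stacks cover different dates")
  sa <- t(vapply(surfaces_a, surface_spatial_summary, numeric(2)))
  sb <- t(vapply(surfaces_b, surface_spatial_summary, numeric(2)))
  daily <- data.frame(date = as.Date(da),
                      mean_a = sa[, 1], sd_a = sa[, 2],
                      mean_b = sb[, 1], sd_b = sb[, 2])
  names(daily)[2:5] <- c(paste0("mean_", labels[1]), paste0("sd_", labels[1]),
                         paste0("mean_", labels[2]), paste0("sd_", labels[2]))
  qs <- function(v) c(mean = mean(v), sd = stats::sd(v),
                      stats::quantile(v, c(0, .25, .5, .75, 1)))
  summary <- rbind(
    data.frame(model = labels[1], stat = c("daily_mean", "daily_sd"),
               rbind(qs(sa[, 1]), qs(sa[, 2]))),
    data.frame(model = labels[2], stat = c("daily_mean", "daily_sd"),
               rbind(qs(sb[, 1]), qs(sb[, 2])))
  )
  names(summary)[3:9] <- c("mean", "sd", "min", "q1", "median", "q3", "max")
  rownames(summary) <- NULL
  list(daily = daily, summary = summary)
}
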