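test_that("semivariance models behave at the origin, range, and sill", {
  for (fam in c("exponential", "spherical", "gaussian")) {
    vm <- variogram_model(fam, nugget = 0.3, psill = 2, range = 5)
    expect_equal(semivariance(vm, 0), 0)
    expect_gte(semivariance(vm, 1e-9), 0.3)  # nugget discontinuity
    expect_equal(semivariance(vm, 1e4), 2.3, tolerance = 1e-6)
    h <- seq(0.1, 20, by = 0.1)
    expect_true(all(diff(semivariance(vm, h)) >= -1e-12))  # monotone
  }
  expect_equal(semivariance(variogram_model("spherical", 0, 2, 5), 5), 2)
  expect_error(variogram_model("exponential", nugget = -1))
})

test_that("empirical_variogram matches the hand-computed Matheron estimator", {
  st <- data.frame(station_id = c("a", "b", "c"),
                   x_km = c(0, 3, 0), y_km = c(0, 0, 4),
                   date = as.Date("2016-12-01"),
                   pm25 = c(1, 5, 2))
  emp <- empirical_variogram(st, n_bins = 1, demean = FALSE)
  expect_equal(emp$dist, mean(c(3, 4, 5)))
  expect_equal(emp$gamma, mean(c((1 - 5)^2, (1 - 2)^2, (5 - 2)^2)) / 2)
  expect_equal(emp$n_pairs, 3L)
  expect_true(emp$flagged)  # fewer than 30 pairs
  # day demeaning removes a pure regional shift entirely
  st2 <- rbind(st, transform(st, date = as.Date("2016-12-02"), pm25 = pm25 + 50))
  emp2 <- empirical_variogram(st2, n_bins = 1)
  expect_equal(emp2$gamma, emp$gamma)
  expect_equal(emp2$n_pairs, 6L)
  expect_error(empirical_variogram(st[1, ]), "2 stations")
})

test_that("fit_variogram recovers parameters from clean binned data", {
  vm0 <- variogram_model("exponential", nugget = 0.2, psill = 1.5, range = 6)
  emp <- data.frame(dist = seq(0.5, 18, length.out = 14))
  emp$gamma <- semivariance(vm0, emp$dist)
  emp$n_pairs <- rep(100L, 14)
  vm <- fit_variogram(emp, "exponential")
  expect_equal(vm$nugget, 0.2, tolerance = 1e-3)
  expect_equal(vm$psill, 1.5, tolerance = 1e-3)
  expect_equal(vm$range, 6, tolerance = 1e-2)
  # a flat variogram falls back to nugget-only with a warning
  flat <- data.frame(dist = 1:10, gamma = 1, n_pairs = 100L)
  expect_warning(vmf <- fit_variogram(flat), "nugget")
  expect_equal(semivariance(vmf, 5), semivariance(vmf, 50))  # flat beyond 0
})

test_that("ordinary kriging matches an independent linear-algebra solve", {
  set.seed(42)
  vm <- variogram_model("exponential", nugget = 0.1, psill = 1, range = 7)
  for (i in 1:20) {
    n <- sample(3:8, 1)
    sx <- runif(n, 0, 20); sy <- runif(n, 0, 20); sz <- runif(n, 4, 12)
    px <- runif(1, 0, 20); py <- runif(1, 0, 20)
    st <- data.frame(x_km = sx, y_km = sy, value = sz)
    got <- mobilexpo:::ok_predict(st, vm, px, py, return_weights = TRUE)
    ref <- ok_oracle(sx, sy, sz, px, py, vm)
    expect_equal(got$pred, ref$pred, tolerance = 1e-8)
    expect_equal(got$var, max(ref$var, 0), tolerance = 1e-8)
    expect_equal(sum(got$weights[, 1]), 1, tolerance = 1e-10)
    # exact interpolation at a station
    at <- mobilexpo:::ok_predict(st, vm, sx[1], sy[1])
    expect_equal(at$pred, sz[1], tolerance = 1e-8)
  }
})

test_that("krige_surface interpolates stations exactly and clips at zero", {
  g <- pm_grid(0, 0, 2, 8, 8)
  vm <- variogram_model("exponential", nugget = 0, psill = 1, range = 6)
  st <- data.frame(x_km = c(3, 11, 7), y_km = c(3, 5, 13),
                   pm25 = c(5, -8, 9), date = as.Date("2016-12-01"))
  s <- krige_surface(st, vm, g)
  expect_s3_class(s, "pm_surface")
  expect_equal(s$model_tag, 0L)
  # stations sit at cell centers: the surface reproduces non-negative values
  expect_equal(surface_value_at(s, 3, 3), 5, tolerance = 1e-8)
  expect_equal(surface_value_at(s, 7, 13), 9, tolerance = 1e-8)
  expect_true(all(s$values >= 0))
  expect_equal(dim(attr(s, "kriging_var")), c(8, 8))
})

test_that("fit_pooled_trend recovers known coefficients exactly", {
  f <- small_fields(n_days = 5, seed = 31)
  cov <- f$covariates
  cc <- grid_centers(f$params$grid)
  set.seed(3)
  pick <- cc[sample.int(nrow(cc), 6), ]
  beta0 <- c(urban = 2.5, terrain = -0.7)
  st <- do.call(rbind, lapply(1:5, function(d) {
    X <- mobilexpo:::covariate_matrix(cov, pick$x, pick$y)
    data.frame(station_id = sprintf("s%d", 1:6), x_km = pick$x, y_km = pick$y,
               date = as.Date("2016-12-01") + d,
               pm25 = 3 * d + as.vector(X %*% beta0))
  }))
  expect_equal(fit_pooled_trend(st, cov), beta0, tolerance = 1e-8)
})

test_that("regression-kriging nests ordinary kriging and interpolates exactly", {
  f <- small_fields(n_days = 1, seed = 31)
  g <- f$params$grid
  vm <- variogram_model("exponential", nugget = 0.05, psill = 1, range = 6)
  st <- data.frame(station_id = sprintf("s%d", 1:5),
                   x_km = c(3, 11, 7, 19, 15), y_km = c(3, 5, 13, 17, 9),
                   pm25 = c(5, 7, 9, 6, 8), date = as.Date("2016-12-01"))
  # zero covariates: multi-sourced equals single-sourced cell for cell
  zero_cov <- list(flat = pm_surface(g, matrix(0, g$ny, g$nx)))
  expect_warning(m0 <- multisource_surface(st, zero_cov, g, vm),
                 "rank-deficient")
  s0 <- krige_surface(st, vm, g)
  expect_equal(m0$values, s0$values, tolerance = 1e-10)
  # with real covariates the stations are still interpolated exactly
  m1 <- multisource_surface(st, f$covariates, g, vm)
  expect_equal(surface_value_at(m1, st$x_km, st$y_km), st$pm25, tolerance = 1e-8)
  expect_equal(m1$model_tag, 1L)
})

test_that("spatial_cv is seed-deterministic and validates its inputs", {
  # this seed clips >1% of cell-days, which the generator reports
  f <- suppressWarnings(small_fields(n_days = 6, seed = 13))
  st <- generate_stations(f, n_stations = 8, noise_sd = 0.3, seed = 4)
  # tiny training folds may legitimately fall back to nugget-only variograms
  cv1 <- suppressWarnings(spatial_cv(st, "single", k = 4, seed = 9))
  cv2 <- suppressWarnings(spatial_cv(st, "single", k = 4, seed = 9))
  expect_identical(cv1$rmse, cv2$rmse)
  cv3 <- suppressWarnings(spatial_cv(st, "single", k = 4, seed = 10))
  expect_false(identical(cv1$fold_assignment, cv3$fold_assignment))
  expect_error(spatial_cv(st, "single", k = 50), "exceeds")
  expect_s3_class(cv1, "cv_report")
  expect_true(is.finite(cv1$rmse) && cv1$rmse > 0)
})

test_that("smoothing_diagnostic summarizes daily spatial spread", {
  g <- pm_grid(0, 0, 1, 4, 4)
  mk <- function(v, d) pm_surface(g, matrix(v, 4, 4), date = d)
  a <- list(mk(rep(5, 16), as.Date("2016-12-01")),
            mk(rep(6, 16), as.Date("2016-12-02")))
  b <- list(mk(1:16, as.Date("2016-12-01")),
            mk(16:1, as.Date("2016-12-02")))
  sm <- smoothing_diagnostic(a, b)
  expect_equal(sm$daily$sd_single, c(0, 0))
  expect_equal(sm$daily$sd_multi, rep(sd(1:16), 2))
  expect_equal(nrow(sm$summary), 4)
  b2 <- b; b2[[2]]$date <- as.Date("2020-01-01")
  expect_error(smoothing_diagnostic(a, b2), "dates")
})
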