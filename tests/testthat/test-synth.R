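test_that("field_params validates inputs", {
  expect_error(field_params(temporal_ar = 1))
  expect_error(field_params(corr_range = 0))
  expect_error(field_params(grid = pm_grid(nx = 200, ny = 200)), "1e4|10000|cells")
})

test_that("generate_fields is deterministic in the seed and well-formed", {
  f1 <- small_fields(n_days = 4, seed = 7)
  f2 <- small_fields(n_days = 4, seed = 7)
  f3 <- small_fields(n_days = 4, seed = 8)
  expect_identical(f1$surfaces[[2]]$values, f2$surfaces[[2]]$values)
  expect_false(identical(f1$surfaces[[2]]$values, f3$surfaces[[2]]$values))
  expect_length(f1$surfaces, 4)
  expect_equal(f1$dates, as.Date("2016-12-01") + 0:3)
  expect_true(all(vapply(f1$surfaces, function(s) all(s$values >= 0), logical(1))))
  # urban covariate peaks at the attractor and decays outward
  urb <- f1$covariates$urban
  att <- f1$params$attractor
  cc <- grid_centers(f1$params$grid)
  v <- surface_value_at(urb, cc$x, cc$y)
  d <- sqrt((cc$x - att[1])^2 + (cc$y - att[2])^2)
  expect_true(min(d[v == max(v)]) <= sqrt(2) * f1$params$grid$cell_size)
  expect_true(cor(v, d, method = "spearman") < -0.99)
})

test_that("daily fields share the fitted spatial structure but differ by day", {
  f <- small_fields(n_days = 3, seed = 9)
  expect_false(identical(f$surfaces[[1]]$values, f$surfaces[[2]]$values))
  expect_length(f$daily_offsets, 3)
})

test_that("stations sample the truth plus independent noise", {
  f <- small_fields(n_days = 3, seed = 5)
  st0 <- generate_stations(f, n_stations = 4, noise_sd = 0, seed = 3)
  expect_equal(st0$pm25, st0$truth)
  expect_equal(st0$truth,
               mapply(function(x, y, d) {
                 surface_value_at(f$surfaces[[match(d, as.character(f$dates))]], x, y)
               }, st0$x_km, st0$y_km, as.character(st0$date)))
  st1 <- generate_stations(f, n_stations = 4, noise_sd = 0.5, seed = 3)
  expect_false(any(st1$pm25 == st1$truth))
  expect_error(generate_stations(f, n_stations = 1e5), "exceeds")
})

test_that("cohort archetype mix is apportioned exactly and homes avoid the core", {
  f <- small_fields(n_days = 3, seed = 5)
  cp <- cohort_params(n_participants = 31, n_days = 3, seed = 44,
                      home_exclusion_km = 5)
  co <- generate_cohort(cp, f)
  counts <- table(co$archetypes$archetype)
  expect_equal(sort(as.vector(counts)), c(10, 10, 11))
  att <- f$params$attractor
  d_att <- sqrt((co$anchors$home_x_km - att[1])^2 +
                (co$anchors$home_y_km - att[2])^2)
  expect_true(all(d_att >= 5))
})

test_that("cohort trajectories sit on the tick lattice with dropout gaps", {
  f <- small_fields(n_days = 4, seed = 5)
  cp <- cohort_params(n_participants = 10, n_days = 4, seed = 9, dropout = 0.3)
  co <- generate_cohort(cp, f)
  secs <- as.numeric(co$fixes$timestamp) %% (30 * 60)
  expect_true(all(secs == 0))
  n_days_obs <- tapply(as.Date(co$fixes$timestamp, tz = "UTC"),
                       co$fixes$participant_id,
                       function(d) length(unique(d)))
  expect_true(any(n_days_obs < 4))  # dropout removed some participant-days
  expect_equal(nrow(co$dropped) + sum(n_days_obs), 10 * 4)
})

test_that("the truth ledger covers observed participant-days", {
  f <- small_fields(n_days = 3, seed = 5)
  co <- generate_cohort(cohort_params(n_participants = 5, n_days = 3, seed = 2), f)
  expect_true(all(c("participant_id", "date", "true_mobility", "true_residence")
                  %in% names(co$ledger)))
  # residence truth equals the surface at the home cell
  i <- 7
  pid <- co$ledger$participant_id[i]
  home <- co$anchors[co$anchors$participant_id == pid, ]
  day <- match(co$ledger$date[i], f$dates)
  expect_equal(co$ledger$true_residence[i],
               surface_value_at(f$surfaces[[day]], home$home_x_km, home$home_y_km))
})

test_that("cohort generation is reproducible", {
  f <- small_fields(n_days = 3, seed = 5)
  c1 <- generate_cohort(cohort_params(n_participants = 8, n_days = 3, seed = 3), f)
  c2 <- generate_cohort(cohort_params(n_participants = 8, n_days = 3, seed = 3), f)
  expect_identical(c1$fixes, c2$fixes)
  expect_identical(c1$ledger, c2$ledger)
})
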