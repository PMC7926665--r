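test_that("mobility_exposure is the dwell-time-weighted mean of cell values", {
  g <- pm_grid(0, 0, 2, 5, 5)
  s <- pm_surface(g, matrix(seq(1, 25), 5, 5))
  day <- visits_df(c(1, 5, 9), c(1, 5, 9), c(1, 1, 1), c(8, 2, 6))
  C <- surface_value_at(s, day$place_x, day$place_y)
  expect_equal(mobility_exposure(s, day),
               sum(C * day$t_h) / sum(day$t_h))
  # audit mode: unnormalized ug/m3 x hours
  expect_equal(mobility_exposure(s, day, normalize = FALSE), sum(C * day$t_h))
  # zero dwell time is undefined
  expect_true(is.na(mobility_exposure(s, day[0, ])))
  d0 <- day; d0$t_h <- 0
  expect_true(is.na(mobility_exposure(s, d0)))
})

test_that("mobility_exposure is a convex combination of visited concentrations", {
  g <- pm_grid(0, 0, 2, 6, 6)
  set.seed(21)
  s <- pm_surface(g, matrix(runif(36, 2, 15), 6, 6))
  for (i in 1:100) {
    m <- sample(1:6, 1)
    day <- visits_df(runif(m, 0, 12), runif(m, 0, 12),
                     sample(1:3, m, TRUE), runif(m, 0.5, 10))
    y <- mobility_exposure(s, day)
    C <- surface_value_at(s, day$place_x, day$place_y)
    expect_gte(y, min(C) - 1e-12)
    expect_lte(y, max(C) + 1e-12)
  }
  # constant field: exposure equals the constant regardless of the itinerary
  sc <- pm_surface(g, matrix(7.5, 6, 6))
  day <- visits_df(runif(4, 0, 12), runif(4, 0, 12), 1:4, runif(4, 1, 5))
  expect_equal(mobility_exposure(sc, day), 7.5)
})

test_that("all time at home reduces mobility exposure to residence exposure", {
  g <- pm_grid(0, 0, 2, 5, 5)
  set.seed(4)
  s <- pm_surface(g, matrix(runif(25, 3, 12), 5, 5))
  home <- c(4.3, 6.8)
  day <- visits_df(home[1], home[2], 3, 24)
  expect_identical(mobility_exposure(s, day),
                   residence_exposure(s, home))
})

test_that("out-of-grid places clamp with a warning; out-of-grid homes error", {
  g <- pm_grid(0, 0, 2, 5, 5)
  s <- pm_surface(g, matrix(1:25, 5, 5))
  day <- visits_df(c(1, 50), c(1, 50), c(1, 1), c(5, 5))
  expect_warning(y <- mobility_exposure(s, day), "clamping")
  expect_true(is.finite(y))
  expect_error(residence_exposure(s, c(-5, 2), "p9"), "p9")
})

test_that("daily_exposures matches per-day calls to the two exposure functions", {
  f <- small_fields(n_days = 3, seed = 5)
  co <- small_cohort(f, n = 6, n_days = 3)
  dm <- compute_daily_metrics(co$fixes, co$anchors)
  stacks <- list("0" = f$surfaces, "1" = f$surfaces)
  de <- daily_exposures(dm$visits, co$anchors, stacks)
  expect_setequal(unique(de$M), c(0L, 1L))
  expect_setequal(unique(de$S), c(0L, 1L))
  i <- 5
  row <- de[de$M == 1 & de$S == 0, ][i, ]
  day <- dm$visits[dm$visits$participant_id == row$participant_id &
                   dm$visits$date == row$date, ]
  surf <- f$surfaces[[match(row$date, f$dates)]]
  expect_equal(row$y, mobility_exposure(surf, day))
  r0 <- de[de$M == 0 & de$S == 0, ][i, ]
  home <- co$anchors[co$anchors$participant_id == r0$participant_id, ]
  surf0 <- f$surfaces[[match(r0$date, f$dates)]]
  expect_equal(r0$y, residence_exposure(surf0, c(home$home_x_km, home$home_y_km)))
})

test_that("daily_exposures matches activity dates to the stack year by month-day", {
  f <- small_fields(n_days = 3, seed = 5)
  co <- small_cohort(f, n = 4, n_days = 3)
  dm <- compute_daily_metrics(co$fixes, co$anchors)
  shifted <- dm$visits
  shifted$date <- as.Date(sub("^2016", "2017", as.character(shifted$date)))
  stacks <- list("0" = f$surfaces, "1" = f$surfaces)
  de0 <- daily_exposures(dm$visits, co$anchors, stacks)
  de1 <- daily_exposures(shifted, co$anchors, stacks)
  expect_equal(de1$y, de0$y)
})

test_that("longterm averages over the common-day intersection and drops short records", {
  rec <- expand.grid(participant_id = c("a", "b"), date = as.Date("2016-12-01") + 0:4,
                     M = 0:1, S = 0:1, stringsAsFactors = FALSE)
  rec$y <- seq_len(nrow(rec))
  # remove one (M,S) cell of one day for "a": that day must drop from all four
  rec <- rec[!(rec$participant_id == "a" & rec$date == rec$date[1] &
               rec$M == 1 & rec$S == 1), ]
  lt <- longterm(rec, min_days = 3)
  a11 <- lt[lt$participant_id == "a" & lt$M == 1 & lt$S == 1, ]
  expect_equal(a11$n_days, 4)
  keep <- rec[rec$participant_id == "a" & rec$M == 0 & rec$S == 0 &
              rec$date != as.Date("2016-12-01"), ]
  a00 <- lt[lt$participant_id == "a" & lt$M == 0 & lt$S == 0, ]
  expect_equal(a00$Y, mean(keep$y))
  # below min_days the participant is dropped and reported
  expect_message(lt2 <- longterm(rec, min_days = 5), "dropped")
  expect_false("a" %in% lt2$participant_id)
  expect_equal(attr(lt2, "dropped"), "a")
})
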