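test_that("radius_of_gyration matches the brute-force definition", {
  set.seed(11)
  for (i in 1:200) {
    m <- sample(1:8, 1)
    d <- visits_df(runif(m, -50, 50), runif(m, -50, 50),
                   sample(1:5, m, replace = TRUE), runif(m, 0.5, 10))
    expect_equal(radius_of_gyration(d),
                 rog_oracle(d$place_x, d$place_y, d$n_k), tolerance = 1e-12)
  }
})

test_that("radius_of_gyration has the expected invariances and edge cases", {
  d <- visits_df(c(0, 3, 7), c(0, -4, 2), c(2, 1, 3), c(10, 4, 2))
  r0 <- radius_of_gyration(d)
  # translation invariance
  d2 <- d; d2$place_x <- d2$place_x + 100; d2$place_y <- d2$place_y - 7
  expect_equal(radius_of_gyration(d2), r0, tolerance = 1e-12)
  # rotation invariance
  th <- 0.83
  d3 <- d
  d3$place_x <- cos(th) * d$place_x - sin(th) * d$place_y
  d3$place_y <- sin(th) * d$place_x + cos(th) * d$place_y
  expect_equal(radius_of_gyration(d3), r0, tolerance = 1e-12)
  # a single place has zero radius; an empty day is undefined
  expect_equal(radius_of_gyration(visits_df(2, 3, 4, 8)), 0)
  expect_true(is.na(radius_of_gyration(d[0, ])))
  # two equally visited places: half the separation
  expect_equal(radius_of_gyration(visits_df(c(0, 6), c(0, 8), c(2, 2), c(1, 1))),
               5)
})

test_that("build_visits separates dwell places and ignores transit ticks", {
  # 48-tick day: home (ticks 1-9), 1 transit tick, work (11-20), 1 transit,
  # home again (22-48)
  tick_s <- 30 * 60
  t0 <- as.POSIXct("2016-12-01", tz = "UTC")
  xs <- c(rep(0, 9), 5, rep(10, 10), 5, rep(0, 27))
  fixes <- data.frame(participant_id = "p1",
                      timestamp = t0 + (0:47) * tick_s,
                      x_km = xs, y_km = 0)
  v <- build_visits(fixes, merge_radius_km = 0.5, min_dwell_ticks = 2)
  expect_equal(nrow(v), 2)
  home <- v[v$place_x < 1, ]; work <- v[v$place_x > 9, ]
  expect_equal(home$n_k, 2L)          # two arrivals at home
  expect_equal(work$n_k, 1L)
  expect_equal(home$t_h, 36 * 0.5)    # transit ticks carry no dwell
  expect_equal(work$t_h, 10 * 0.5)
  # with min_dwell_ticks = 1 the transit stops become places
  v1 <- build_visits(fixes, merge_radius_km = 0.5, min_dwell_ticks = 1)
  expect_equal(nrow(v1), 3)
})

test_that("nonhome_time uses a strict 2-km buffer", {
  t0 <- as.POSIXct("2016-12-01", tz = "UTC")
  fixes <- data.frame(participant_id = "p1",
                      timestamp = t0 + (0:3) * 1800,
                      x_km = c(0, 2, 2.001, 5), y_km = 0)
  # exactly on the buffer counts as home; beyond it does not
  expect_equal(nonhome_time(fixes, home = c(0, 0), buffer_km = 2), 2 * 0.5)
})

test_that("fill_gaps carries short gaps forward and home-fills long home gaps", {
  t0 <- as.POSIXct("2016-12-01", tz = "UTC")
  anchors <- data.frame(participant_id = "p1", home_x_km = 0, home_y_km = 0)
  full <- data.frame(participant_id = "p1", timestamp = t0 + (0:47) * 1800,
                     x_km = 0, y_km = 0)
  # a 2-tick hole away from home -> carried forward from the last fix
  hole <- full[-(20:21), ]
  hole$x_km[hole$timestamp >= t0 + 18 * 1800 & hole$timestamp <= t0 + 22 * 1800] <- 8
  lat <- fill_gaps(hole, anchors)
  expect_equal(nrow(lat), 48)
  expect_equal(lat$x_km[20:21], c(8, 8))
  expect_equal(lat$source[20:21], c("imputed", "imputed"))
  # a 10-tick hole flanked by home fixes -> filled at home
  hole2 <- full[-(10:19), ]
  lat2 <- fill_gaps(hole2, anchors)
  expect_equal(lat2$x_km[10:19], rep(0, 10))
  # a 10-tick hole flanked by fixes away from home stays missing
  hole3 <- full
  hole3$x_km[c(9, 20)] <- 9
  hole3 <- hole3[-(10:19), ]
  lat3 <- fill_gaps(hole3, anchors)
  expect_true(all(is.na(lat3$x_km[10:19])))
  # duplicated timestamps are an error
  expect_error(fill_gaps(rbind(full, full[5, ]), anchors), "duplicate")
})

test_that("compute_daily_metrics flags days with too few resolvable ticks", {
  f <- small_fields(n_days = 4, seed = 5)
  co <- small_cohort(f, n = 6, n_days = 4)
  dm <- compute_daily_metrics(co$fixes, co$anchors)
  expect_true(all(c("rog_km", "nonhome_h", "valid") %in% names(dm$metrics)))
  expect_true(all(dm$metrics$valid))  # generator days are complete
  # a day that is mostly an unfillable hole (flanked away from home) is invalid
  t0 <- as.POSIXct("2016-12-01", tz = "UTC")
  sparse <- data.frame(participant_id = "q1",
                       timestamp = t0 + c(0:4, 43:47) * 1800,
                       x_km = 9, y_km = 9)
  anch <- data.frame(participant_id = "q1", home_x_km = 0, home_y_km = 0)
  dm2 <- compute_daily_metrics(sparse, anch)
  expect_false(dm2$metrics$valid[1])
})

test_that("summarize_profiles applies the two-threshold classification", {
  mk <- function(pid, r, g) data.frame(participant_id = pid, date = Sys.Date(),
                                       rog_km = r, nonhome_h = g, valid = TRUE)
  metrics <- rbind(mk("a", 1, 1), mk("b", 9, 1), mk("c", 1, 9), mk("d", 9, 9))
  pr <- summarize_profiles(metrics)
  expect_equal(unname(pr$thresholds), c(5, 5))
  got <- setNames(pr$profiles$group, pr$profiles$participant_id)
  expect_equal(unname(got[c("a", "b", "c", "d")]),
               c("Static", "Moderate", "Moderate", "Active"))
  expect_equal(sort(unique(pr$profiles$score)), c(0, 1, 2))
  # at the threshold exactly counts as non-static
  pr2 <- summarize_profiles(metrics, thresholds = c(1, 1))
  got2 <- setNames(pr2$profiles$group, pr2$profiles$participant_id)
  expect_equal(unname(got2["a"]), "Active")
  # pooled thresholds weight by participant-days
  m2 <- rbind(mk("a", 1, 1), mk("a", 1, 1), mk("b", 7, 7))
  expect_equal(unname(summarize_profiles(m2, pooling = "pooled")$thresholds),
               c(3, 3))
  expect_equal(unname(summarize_profiles(m2, pooling = "participant")$thresholds),
               c(4, 4))
})
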