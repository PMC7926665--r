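#' Parameters of the synthetic daily concentration field
#'
#' Describes the "true" ambient PM2.5 field from which stations and exposures
#' are simulated. Each day's field is
#' `mean_level + AR(1) daily offset + Gaussian random field + covariate trend`,
#' clipped at zero from below. The Gaussian random field has an exponential
#' covariance with marginal standard deviation `spatial_sd` and effective
#' decay `corr_range`; it is redrawn independently each day. The covariate
#' trend is time-invariant: covariate 1 is an exponential decay of distance
#' to an "urban" attractor point (unit scale), covariate 2 a standardized
#' smooth random surface. Their weights are `covariate_effects` (ug/m3 per
#' covariate unit).
#'
#' Defaults emulate a winter-to-spring mid-latitude PM2.5 regime: overall
#' level about 7 ug/m3, day-to-day swings of a few ug/m3 with moderate
#' persistence, and within-day spatial standard deviation near 1.2 ug/m3,
#' most of it carried by the urban covariate.
#'
#' @param grid A [pm_grid()] (at most 10^4 cells; fields are drawn by exact
#'   Cholesky factorization of the cell covariance, which caps the grid size).
#' @param n_days Number of daily surfaces.
#' @param start_date First date.
#' @param mean_level Long-run spatial-temporal mean (ug/m3).
#' @param spatial_sd Marginal SD of the daily Gaussian random field (ug/m3).
#' @param corr_range Exponential covariance range parameter (km).
#' @param temporal_ar AR(1) coefficient of the daily regional offset, in `[0, 1)`.
#' @param temporal_sd Stationary SD of the daily regional offset (ug/m3).
#' @param covariate_effects Numeric vector of trend weights (ug/m3 per unit);
#'   length sets the number of covariates (max 2 built-in generators).
#' @param attractor Planar point (km) of the urban covariate peak;
#'   default grid center.
#' @param seed Integer seed; identical seeds give bit-identical output.
#' @return A list of class `field_params`.
#' @export
field_params <- function(grid = pm_grid(nx = 20, ny = 20, cell_size = 2),
                         n_days = 60,
                         start_date = as.Date("2016-12-01"),
                         mean_level = 7,
                         spatial_sd = 0.8,
                         corr_range = 8,
                         temporal_ar = 0.6,
                         temporal_sd = 3,
                         covariate_effects = c(3, 0.5),
                         attractor = NULL,
                         seed = 1L) {
  stopifnot(inherits(grid, "pm_grid"),
            spatial_sd >= 0, corr_range > 0,
            temporal_ar >= 0, temporal_ar < 1, temporal_sd >= 0,
            n_days >= 1, length(covariate_effects) <= 2)
  if (grid$nx * grid$ny > 1e4) {
    stop("grid has more than 10^4 cells; exact Cholesky field simulation is capped there")
  }
  if (is.null(attractor)) {
    attractor <- c(grid$origin_x + grid$nx * grid$cell_size / 2,
                   grid$origin_y + grid$ny * grid$cell_size / 2)
  }
  structure(
    list(grid = grid, n_days = as.integer(n_days), start_date = start_date,
         mean_level = mean_level, spatial_sd = spatial_sd,
         corr_range = corr_range, temporal_ar = temporal_ar,
         temporal_sd = temporal_sd, covariate_effects = covariate_effects,
         attractor = attractor, seed = as.integer(seed)),
    class = "field_params"
  )
}

# Cholesky factor of the exponential-covariance matrix over cell centers.
# sigma2 * exp(-d / range); a small ridge keeps the factorization stable.
grf_chol <- function(coords, sigma2, range_km) {
  d <- as.matrix(stats::dist(coords))
  C <- sigma2 * exp(-d / range_km)
  diag(C) <- diag(C) + 1e-10 * max(sigma2, 1)
  ch <- tryCatch(chol(C), error = function(e) {
    stop("covariance matrix is not positive definite (range ", range_km,
         " km, sd^2 ", sigma2, "): ", conditionMessage(e))
  })
  ch
}

#' Generate daily concentration surfaces with known ground truth
#'
#' Draws `n_days` daily fields per the model described in [field_params()].
#' Negative concentrations are clipped to zero; the number of clipped cells
#' is returned and a warning is raised when more than 1% of cell-days were
#' clipped.
#'
#' @param params A [field_params()] object.
#' @return A list of class `field_stack` with elements `surfaces` (list of
#'   [pm_surface()], `model_tag = NA` marking truth), `covariates` (list of
#'   covariate surfaces), `daily_offsets` (AR(1) regional offsets),
#'   `n_clipped`, `dates`, and `params`.
#' @export
generate_fields <- function(params) {
  stopifnot(inherits(params, "field_params"))
  g <- params$grid
  centers <- grid_centers(g)
  coords <- as.matrix(centers[, c("x", "y")])
  ncell <- nrow(coords)
  dates <- params$start_date + seq_len(params$n_days) - 1L

  with_seed(params$seed, {
    # time-invariant covariates
    p <- length(params$covariate_effects)
    covariates <- list()
    if (p >= 1) {
      d_att <- euclid(coords[, 1], coords[, 2],
                      params$attractor[1], params$attractor[2])
      urb <- exp(-d_att / (0.125 * max(g$nx, g$ny) * g$cell_size))
      covariates$urban <- pm_surface(g, matrix(urb, g$ny, g$nx, byrow = TRUE))
    }
    if (p >= 2) {
      chs <- grf_chol(coords, 1, params$corr_range)
      z <- as.vector(t(chs) %*% stats::rnorm(ncell))
      z <- (z - mean(z)) / max(stats::sd(z), 1e-12)
      covariates$terrain <- pm_surface(g, matrix(z, g$ny, g$nx, byrow = TRUE))
    }
    trend <- rep(0, ncell)
    if (p > 0) {
      X <- sapply(covariates, function(s) as.vector(t(s$values)))
      trend <- as.vector(X %*% params$covariate_effects)
    }

    ch <- if (params$spatial_sd > 0) {
      grf_chol(coords, params$spatial_sd^2, params$corr_range)
    } else NULL

    # AR(1) regional offset with stationary SD temporal_sd
    innov_sd <- params$temporal_sd * sqrt(1 - params$temporal_ar^2)
    offsets <- numeric(params$n_days)
    if (params$temporal_sd > 0) {
      offsets[1] <- stats::rnorm(1, 0, params$temporal_sd)
      if (params$n_days > 1) {
        for (t in 2:params$n_days) {
          offsets[t] <- params$temporal_ar * offsets[t - 1] +
            stats::rnorm(1, 0, innov_sd)
        }
      }
    }

    n_clipped <- 0L
    surfaces <- vector("list", params$n_days)
    for (t in seq_len(params$n_days)) {
      field <- params$mean_level + offsets[t] + trend
      if (!is.null(ch)) field <- field + as.vector(t(ch) %*% stats::rnorm(ncell))
      neg <- field < 0
      n_clipped <- n_clipped + sum(neg)
      field[neg] <- 0
      surfaces[[t]] <- pm_surface(g, matrix(field, g$ny, g$nx, byrow = TRUE),
                                  date = dates[t], model_tag = NA_integer_)
    }
    frac <- n_clipped / (ncell * params$n_days)
    if (frac > 0.01) {
      warning(sprintf("%.1f%% of cell-days clipped at 0; consider raising mean_level",
                      100 * frac))
    }
    structure(
      list(surfaces = surfaces, covariates = covariates,
           daily_offsets = offsets, n_clipped = n_clipped,
           dates = dates, params = params),
      class = "field_stack"
    )
  })
}

#' Generate a sparse monitoring-station network with daily measurements
#'
#' Stations sit at the centers of distinct interior grid cells; each daily
#' measurement is the true field value at the station cell plus independent
#' Gaussian noise.
#'
#' @param fields A `field_stack` from [generate_fields()].
#' @param n_stations Number of stations (>= 1; must fit in the interior cells).
#' @param noise_sd Measurement-noise SD (ug/m3).
#' @param seed Integer seed.
#' @return A data.frame with columns `station_id`, `x_km`, `y_km`, `date`,
#'   `pm25`, and `truth` (the noiseless field value, kept for validation).
#' @export
generate_stations <- function(fields, n_stations, noise_sd = 0.5, seed = 1L) {
  stopifnot(inherits(fields, "field_stack"), n_stations >= 1, noise_sd >= 0)
  g <- fields$params$grid
  interior <- grid_centers(g)
  interior <- interior[interior$ix > 1 & interior$ix < g$nx &
                       interior$iy > 1 & interior$iy < g$ny, ]
  if (n_stations > nrow(interior)) {
    stop("n_stations (", n_stations, ") exceeds interior grid cells (",
         nrow(interior), ")")
  }
  with_seed(seed, {
    pick <- interior[sample.int(nrow(interior), n_stations), ]
    n_days <- length(fields$surfaces)
    truth <- vapply(fields$surfaces,
                    function(s) surface_value_at(s, pick$x, pick$y),
                    numeric(n_stations))
    truth <- matrix(truth, nrow = n_stations)  # stations x days
    noise <- matrix(stats::rnorm(n_stations * n_days, 0, noise_sd),
                    n_stations, n_days)
    data.frame(
      station_id = rep(sprintf("st%02d", seq_len(n_stations)), times = n_days),
      x_km = rep(pick$x, times = n_days),
      y_km = rep(pick$y, times = n_days),
      date = rep(fields$dates, each = n_stations),
      pm25 = as.vector(truth + noise),
      truth = as.vector(truth)
    )
  })
}

#' Parameters of the synthetic cohort
#'
#' Agents are drawn from three travel archetypes — `static`, `moderate`, and
#' `active` — differing in commute distance and daily non-home duration.
#' Defaults give commute-distance means of 2/8/8 km and non-home-duration
#' means of 2/2/8 h for the three archetypes, an equal mix, and a regular
#' 30-minute position lattice; at those settings the cohort-level mean radius
#' of gyration and non-home time sit near the few-km / few-hour scale typical
#' of a mid-sized metropolitan cohort.
#'
#' @param n_participants Number of agents.
#' @param n_days Days simulated per agent.
#' @param tick_minutes Lattice spacing in minutes (must divide 1440).
#' @param archetype_mix Proportions over (static, moderate, active); must sum
#'   to 1.
#' @param commute_mean_km,commute_sd_km Commute-distance distribution per
#'   archetype (lognormal on this mean/sd scale).
#' @param nonhome_mean_h,nonhome_sd_h Daily non-home-duration distribution per
#'   archetype (normal, truncated to `[0, 14]` h).
#' @param dropout Probability a participant-day is unobserved.
#' @param home_exclusion_km Radius of the commercial core around the urban
#'   attractor that holds no homes (km); workplaces may sit inside it.
#' @param work_toward_attractor Fraction of agents whose workplace direction
#'   points at the field's urban attractor (the rest are isotropic). Couples
#'   active agents to high-concentration zones.
#' @param jitter_sd_km Positional noise added to every fix (km).
#' @param seed Integer seed.
#' @return A list of class `cohort_params`.
#' @export
cohort_params <- function(n_participants = 2000,
                          n_days = 120,
                          tick_minutes = 30,
                          archetype_mix = c(static = 1/3, moderate = 1/3, active = 1/3),
                          commute_mean_km = c(static = 2, moderate = 8, active = 8),
                          commute_sd_km = c(static = 0.5, moderate = 1, active = 1),
                          nonhome_mean_h = c(static = 2, moderate = 2, active = 8),
                          nonhome_sd_h = c(static = 1, moderate = 1, active = 2),
                          dropout = 0.05,
                          home_exclusion_km = 8,
                          work_toward_attractor = 0.8,
                          jitter_sd_km = 0.05,
                          seed = 1L) {
  stopifnot(abs(sum(archetype_mix) - 1) < 1e-8,
            1440 %% tick_minutes == 0,
            dropout >= 0, dropout < 1,
            all(nonhome_mean_h <= 24))
  if (any(nonhome_mean_h + 2 * nonhome_sd_h > 24)) {
    stop("non-home duration distribution extends beyond 24 h")
  }
  structure(
    list(n_participants = as.integer(n_participants),
         n_days = as.integer(n_days),
         tick_minutes = as.integer(tick_minutes),
         archetype_mix = archetype_mix,
         commute_mean_km = commute_mean_km,
         commute_sd_km = commute_sd_km,
         nonhome_mean_h = nonhome_mean_h,
         nonhome_sd_h = nonhome_sd_h,
         dropout = dropout,
         home_exclusion_km = home_exclusion_km,
         work_toward_attractor = work_toward_attractor,
         jitter_sd_km = jitter_sd_km,
         seed = as.integer(seed)),
    class = "cohort_params"
  )
}

# lognormal parameters from mean/sd on the natural scale
lnorm_pars <- function(m, s) {
  sigma2 <- log(1 + (s / m)^2)
  list(meanlog = log(m) - sigma2 / 2, sdlog = sqrt(sigma2))
}

#' Generate agent trajectories, anchors, and a ground-truth exposure ledger
#'
#' Each agent gets a home anchor (uniform over grid cells) and a work anchor
#' at the archetype's commute distance, oriented toward the field's urban
#' attractor for a configurable fraction of agents. Each observed day is a
#' regular tick sequence: home dwell, straight-line travel ticks (30 km/h),
#' work dwell of the archetype's non-home duration, travel back, home dwell.
#' Days with zero non-home duration stay at home throughout. The ledger
#' records, per participant-day, the exact time-weighted mean of the true
#' field over the day's tick positions and the true field value at home.
#'
#' @param params A [cohort_params()] object.
#' @param fields A `field_stack` from [generate_fields()]; trajectories are
#'   simulated over its dates and ground truth uses its surfaces.
#' @return A list of class `synthetic_cohort` with `fixes` (trajectory
#'   data.frame: `participant_id`, `timestamp`, `x_km`, `y_km`, `source`),
#'   `anchors`, `ledger` (per participant-day truth), `dropped`
#'   (participant-days removed by dropout), and `params`.
#' @export
generate_cohort <- function(params, fields) {
  stopifnot(inherits(params, "cohort_params"), inherits(fields, "field_stack"))
  g <- fields$params$grid
  n_days <- min(params$n_days, length(fields$surfaces))
  ticks_per_day <- 1440L %/% params$tick_minutes
  tick_h <- params$tick_minutes / 60
  xmin <- g$origin_x; xmax <- g$origin_x + g$nx * g$cell_size
  ymin <- g$origin_y; ymax <- g$origin_y + g$ny * g$cell_size
  att <- fields$params$attractor
  speed_kmh <- 30

  with_seed(params$seed, {
    n <- params$n_participants
    # the mix is a composition: apportion exact counts (largest remainder),
    # then shuffle the assignment
    mix <- params$archetype_mix / sum(params$archetype_mix)
    cnt <- floor(n * mix)
    rem <- n - sum(cnt)
    if (rem > 0) {
      extra <- order(n * mix - cnt, decreasing = TRUE)[seq_len(rem)]
      cnt[extra] <- cnt[extra] + 1L
    }
    arche <- sample(rep(names(mix), cnt))
    # homes: uniform over the residential ring (off the outer margin and
    # outside the commercial core around the attractor)
    home_x <- home_y <- rep(NA_real_, n)
    todo <- seq_len(n)
    while (length(todo)) {
      home_x[todo] <- stats::runif(length(todo), xmin + g$cell_size, xmax - g$cell_size)
      home_y[todo] <- stats::runif(length(todo), ymin + g$cell_size, ymax - g$cell_size)
      todo <- todo[euclid(home_x[todo], home_y[todo], att[1], att[2]) <
                     params$home_exclusion_km]
    }
    lp <- lapply(seq_len(n), function(i) {
      a <- arche[i]
      d <- stats::rlnorm(1, lnorm_pars(params$commute_mean_km[[a]],
                                       params$commute_sd_km[[a]])$meanlog,
                         lnorm_pars(params$commute_mean_km[[a]],
                                    params$commute_sd_km[[a]])$sdlog)
      if (stats::runif(1) < params$work_toward_attractor) {
        theta <- atan2(att[2] - home_y[i], att[1] - home_x[i]) +
          stats::rnorm(1, 0, 0.3)
        # commutes run into the urban core, not past it
        d <- min(d, euclid(home_x[i], home_y[i], att[1], att[2]))
      } else {
        theta <- stats::runif(1, 0, 2 * pi)
      }
      wx <- home_x[i] + d * cos(theta)
      wy <- home_y[i] + d * sin(theta)
      # shrink the commute until the workplace is inside the grid
      sh <- 1
      while ((wx <= xmin || wx >= xmax || wy <= ymin || wy >= ymax) && sh > 0.05) {
        sh <- sh * 0.8
        wx <- home_x[i] + sh * d * cos(theta)
        wy <- home_y[i] + sh * d * sin(theta)
      }
      c(wx, wy)
    })
    work_x <- vapply(lp, `[`, numeric(1), 1)
    work_y <- vapply(lp, `[`, numeric(1), 2)

    pid <- sprintf("p%04d", seq_len(n))
    anchors <- data.frame(participant_id = pid,
                          home_x_km = home_x, home_y_km = home_y,
                          work_x_km = work_x, work_y_km = work_y)

    dates <- fields$dates[seq_len(n_days)]
    tick_offsets <- (seq_len(ticks_per_day) - 1L) * params$tick_minutes * 60

    fixes_list <- vector("list", n)
    ledger_list <- vector("list", n)
    dropped_list <- vector("list", n)

    for (i in seq_len(n)) {
      a <- arche[i]
      obs <- stats::runif(n_days) >= params$dropout
      day_x <- matrix(home_x[i], nrow = ticks_per_day, ncol = n_days)
      day_y <- matrix(home_y[i], nrow = ticks_per_day, ncol = n_days)
      commute_d <- euclid(home_x[i], home_y[i], work_x[i], work_y[i])
      travel_ticks <- max(1L, ceiling(commute_d / (speed_kmh * tick_h)))
      nh_h <- pmin(pmax(stats::rnorm(n_days, params$nonhome_mean_h[[a]],
                                     params$nonhome_sd_h[[a]]), 0), 14)
      nh_ticks <- round(nh_h / tick_h)
      for (j in which(obs & nh_ticks > 0)) {
        # a trip, once made, involves at least a one-hour stay: the lattice
        # cannot resolve shorter stops
        nh_ticks[j] <- max(nh_ticks[j], 2L)
        total <- 2L * travel_ticks + nh_ticks[j]
        latest <- ticks_per_day - total - 1L
        if (latest < 2L) { nh_ticks[j] <- 0L; next }
        s <- sample(seq(2L, min(latest, 20L)), 1L)  # depart in the morning
        fr_out <- seq_len(travel_ticks) / (travel_ticks + 1)
        idx_out <- s + seq_len(travel_ticks) - 1L
        idx_work <- s + travel_ticks + seq_len(nh_ticks[j]) - 1L
        idx_back <- s + travel_ticks + nh_ticks[j] + seq_len(travel_ticks) - 1L
        day_x[idx_out, j] <- home_x[i] + fr_out * (work_x[i] - home_x[i])
        day_y[idx_out, j] <- home_y[i] + fr_out * (work_y[i] - home_y[i])
        day_x[idx_work, j] <- work_x[i]
        day_y[idx_work, j] <- work_y[i]
        day_x[idx_back, j] <- work_x[i] + fr_out * (home_x[i] - work_x[i])
        day_y[idx_back, j] <- work_y[i] + fr_out * (home_y[i] - work_y[i])
      }
      if (params$jitter_sd_km > 0) {
        day_x <- day_x + stats::rnorm(length(day_x), 0, params$jitter_sd_km)
        day_y <- day_y + stats::rnorm(length(day_y), 0, params$jitter_sd_km)
      }
      day_x <- pmin(pmax(day_x, xmin), xmax - 1e-9)
      day_y <- pmin(pmax(day_y, ymin), ymax - 1e-9)

      true_mob <- rep(NA_real_, n_days)
      true_res <- rep(NA_real_, n_days)
      for (j in seq_len(n_days)) {
        s_j <- fields$surfaces[[j]]
        true_res[j] <- surface_value_at(s_j, home_x[i], home_y[i])
        if (obs[j]) {
          true_mob[j] <- mean(surface_value_at(s_j, day_x[, j], day_y[, j],
                                               clamp = TRUE))
        }
      }

      keep <- which(obs)
      if (length(keep)) {
        ts <- rep(as.POSIXct(dates[keep], tz = "UTC"), each = ticks_per_day) +
          rep(tick_offsets, times = length(keep))
        fixes_list[[i]] <- data.frame(
          participant_id = pid[i],
          timestamp = ts,
          x_km = as.vector(day_x[, keep]),
          y_km = as.vector(day_y[, keep]),
          source = "observed"
        )
      }
      ledger_list[[i]] <- data.frame(
        participant_id = pid[i], date = dates[keep],
        archetype = a,
        true_mobility = true_mob[keep], true_residence = true_res[keep]
      )
      if (any(!obs)) {
        dropped_list[[i]] <- data.frame(participant_id = pid[i],
                                        date = dates[!obs])
      }
    }

    structure(
      list(fixes = do.call(rbind, fixes_list),
           anchors = anchors,
           ledger = do.call(rbind, ledger_list),
           dropped = if (length(dl <- Filter(Negate(is.null), dropped_list)))
             do.call(rbind, dl)
           else data.frame(participant_id = character(), date = as.Date(character())),
           archetypes = data.frame(participant_id = pid, archetype = arche),
           params = params),
      class = "synthetic_cohort"
    )
  })
}
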