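#' Fill trajectory gaps onto a regular tick lattice
#'
#' Snaps fixes to a regular lattice of `tick_minutes` per participant-day and
#' fills missing ticks: gaps of at most `max_gap_ticks` are filled by
#' last-observation-carried-forward; longer gaps are filled with the home
#' anchor when both flanking fixes lie within `home_radius_km` of home,
#' and are otherwise left missing (coordinates `NA`). Filled ticks carry
#' `source = "imputed"`.
#'
#' @param fixes data.frame with `participant_id`, `timestamp` (POSIXct),
#'   `x_km`, `y_km`, `source`; sorted within participant.
#' @param anchors Optional data.frame with `participant_id`, `home_x_km`,
#'   `home_y_km` enabling home-filling of long gaps.
#' @param tick_minutes Lattice spacing (minutes).
#' @param max_gap_ticks Longest gap filled by carry-forward.
#' @param home_radius_km Distance within which a fix counts as "at home".
#' @return data.frame on the full lattice with `source` in
#'   `{observed, imputed, missing}`; missing ticks have `NA` coordinates.
#' @export
fill_gaps <- function(fixes, anchors = NULL, tick_minutes = 30,
                      max_gap_ticks = 4, home_radius_km = 0.5) {
  stopifnot(all(c("participant_id", "timestamp", "x_km", "y_km") %in% names(fixes)))
  tick_s <- tick_minutes * 60
  ticks_per_day <- 1440L %/% tick_minutes
  fixes$.day <- as.Date(fixes$timestamp, tz = "UTC")
  fixes$.tick <- as.integer(round(
    as.numeric(fixes$timestamp) %% 86400 / tick_s)) %% ticks_per_day + 1L

  home_lookup <- NULL
  if (!is.null(anchors)) {
    home_lookup <- anchors[, c("participant_id", "home_x_km", "home_y_km")]
    rownames(home_lookup) <- home_lookup$participant_id
  }

  key <- paste(fixes$participant_id, fixes$.day)
  if (anyDuplicated(paste(key, fixes$.tick))) {
    stop("duplicate timestamps within a participant-day")
  }
  n_per_day <- stats::ave(fixes$.tick, key, FUN = length)

  # fast path: days already on the complete lattice pass through untouched
  done <- n_per_day == ticks_per_day
  complete <- NULL
  if (any(done)) {
    cd <- fixes[done, ]
    complete <- data.frame(
      participant_id = cd$participant_id,
      timestamp = as.POSIXct(cd$.day, tz = "UTC") + (cd$.tick - 1L) * tick_s,
      x_km = cd$x_km, y_km = cd$y_km,
      source = if ("source" %in% names(cd)) cd$source else "observed"
    )
  }
  if (all(done)) {
    res <- complete[order(complete$participant_id, complete$timestamp), ,
                    drop = FALSE]
    rownames(res) <- NULL
    return(res)
  }

  fixes <- fixes[!done, ]
  key <- key[!done]
  idx <- split(seq_len(nrow(fixes)), key)
  out <- vector("list", length(idx))
  for (g in seq_along(idx)) {
    rows <- fixes[idx[[g]], ]
    rows <- rows[order(rows$.tick), ]
    x <- rep(NA_real_, ticks_per_day)
    y <- rep(NA_real_, ticks_per_day)
    src <- rep("missing", ticks_per_day)
    x[rows$.tick] <- rows$x_km
    y[rows$.tick] <- rows$y_km
    src[rows$.tick] <- if ("source" %in% names(rows)) rows$source else "observed"

    if (anyNA(x)) {
      home <- NULL
      if (!is.null(home_lookup) &&
          rows$participant_id[1] %in% rownames(home_lookup)) {
        h <- home_lookup[rows$participant_id[1], ]
        home <- c(h$home_x_km, h$home_y_km)
      }
      miss <- is.na(x)
      r <- rle(miss)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      for (k in which(r$values)) {
        a <- starts[k]; b <- ends[k]
        prev <- if (a > 1L) a - 1L else NA_integer_
        nxt <- if (b < ticks_per_day) b + 1L else NA_integer_
        len <- b - a + 1L
        if (!is.na(prev) && len <= max_gap_ticks) {
          x[a:b] <- x[prev]; y[a:b] <- y[prev]; src[a:b] <- "imputed"
        } else if (!is.null(home)) {
          at_home_prev <- is.na(prev) ||
            euclid(x[prev], y[prev], home[1], home[2]) <= home_radius_km
          at_home_nxt <- is.na(nxt) ||
            euclid(x[nxt], y[nxt], home[1], home[2]) <= home_radius_km
          if (at_home_prev && at_home_nxt) {
            x[a:b] <- home[1]; y[a:b] <- home[2]; src[a:b] <- "imputed"
          }
        }
      }
    }
    out[[g]] <- data.frame(
      participant_id = rows$participant_id[1],
      timestamp = as.POSIXct(rows$.day[1], tz = "UTC") +
        (seq_len(ticks_per_day) - 1L) * tick_s,
      x_km = x, y_km = y, source = src
    )
  }
  res <- rbind(complete, do.call(rbind, out))
  res <- res[order(res$participant_id, res$timestamp), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# sequential place extraction for one day's tick positions; returns a list
# of parallel vectors (kept data.frame-free: this runs once per
# participant-day)
extract_places <- function(x, y, merge_radius, min_dwell = 2L) {
  n <- length(x)
  # segment ticks by a running centroid
  seg <- integer(n)
  cx <- x[1]; cy <- y[1]; cs <- 1L; s <- 1L
  seg[1] <- 1L
  if (n > 1) for (t in 2:n) {
    dx <- x[t] - cx; dy <- y[t] - cy
    if (dx * dx + dy * dy <= merge_radius^2) {
      cx <- (cx * cs + x[t]) / (cs + 1L)
      cy <- (cy * cs + y[t]) / (cs + 1L)
      cs <- cs + 1L
    } else {
      s <- s + 1L
      cx <- x[t]; cy <- y[t]; cs <- 1L
    }
    seg[t] <- s
  }
  # merge segments revisiting the same place; segments dwelling fewer than
  # min_dwell ticks are transit, not stops, and do not form places
  px <- numeric(0); py <- numeric(0); pt <- integer(0); pn <- integer(0)
  for (k in seq_len(s)) {
    sel <- seg == k
    mx <- mean(x[sel]); my <- mean(y[sel]); m <- sum(sel)
    if (m < min_dwell) next
    hit <- 0L
    if (length(px)) {
      d2 <- (mx - px)^2 + (my - py)^2
      if (min(d2) <= merge_radius^2) hit <- which.min(d2)
    }
    if (hit > 0L) {
      px[hit] <- (px[hit] * pt[hit] + mx * m) / (pt[hit] + m)
      py[hit] <- (py[hit] * pt[hit] + my * m) / (pt[hit] + m)
      pt[hit] <- pt[hit] + m
      pn[hit] <- pn[hit] + 1L
    } else {
      px <- c(px, mx); py <- c(py, my)
      pt <- c(pt, m); pn <- c(pn, 1L)
    }
  }
  list(place_x = px, place_y = py, n_k = pn, ticks = pt)
}

#' Build daily visit tables from lattice trajectories
#'
#' Collapses each participant-day's tick sequence into discrete places:
#' consecutive ticks within `merge_radius_km` of a running centroid form a
#' dwell segment, and segments whose centroids fall within `merge_radius_km`
#' of an earlier place are counted as revisits. Segments dwelling fewer than
#' `min_dwell_ticks` ticks are treated as transit between places rather than
#' stops and form no place (their time is excluded from `t_h`; exposure
#' weights renormalize over dwell time). `n_k` counts distinct arrivals at a
#' place (visits); `t_h` is the dwell time in hours (ticks x tick length).
#' Missing ticks are skipped; fully missing days yield no rows.
#'
#' @param fixes Lattice trajectory data.frame (see [fill_gaps()]).
#' @param merge_radius_km Place-merge radius (km).
#' @param tick_minutes Lattice spacing (minutes).
#' @param min_dwell_ticks Minimum consecutive ticks for a segment to count
#'   as a place (stay-point threshold); shorter segments are transit.
#' @return data.frame with `participant_id`, `date`, `place_x`, `place_y`,
#'   `n_k`, `t_h`.
#' @export
build_visits <- function(fixes, merge_radius_km = 0.5, tick_minutes = 30,
                         min_dwell_ticks = 2L) {
  tick_h <- tick_minutes / 60
  fixes <- fixes[!is.na(fixes$x_km), ]
  if (!nrow(fixes)) {
    return(data.frame(participant_id = character(), date = as.Date(character()),
                      place_x = numeric(), place_y = numeric(),
                      n_k = integer(), t_h = numeric()))
  }
  day <- as.Date(fixes$timestamp, tz = "UTC")
  key <- paste(fixes$participant_id, day)
  idx <- split(seq_len(nrow(fixes)), key)
  xs <- fixes$x_km; ys <- fixes$y_km
  out <- vector("list", length(idx))
  for (g in seq_along(idx)) {
    rows <- idx[[g]]
    pl <- extract_places(xs[rows], ys[rows], merge_radius_km, min_dwell_ticks)
    pl$row1 <- rows[1]
    out[[g]] <- pl
  }
  nk <- vapply(out, function(p) length(p$n_k), integer(1))
  row1 <- rep(vapply(out, `[[`, integer(1), "row1"), nk)
  res <- data.frame(
    participant_id = fixes$participant_id[row1],
    date = day[row1],
    place_x = unlist(lapply(out, `[[`, "place_x")),
    place_y = unlist(lapply(out, `[[`, "place_y")),
    n_k = unlist(lapply(out, `[[`, "n_k")),
    t_h = unlist(lapply(out, `[[`, "ticks")) * tick_h
  )
  res <- res[order(res$participant_id, res$date), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Daily radius of gyration
#'
#' Visit-weighted root-mean-square distance of a day's places from their
#' visit-weighted center of mass:
#' `sqrt( (1/N) * sum_k n_k * ||u_k - u_c||^2 )` with `N = sum_k n_k`,
#' the characteristic daily travel distance.
#'
#' @param day data.frame for a single participant-day with columns
#'   `place_x`, `place_y`, `n_k` (see [build_visits()]).
#' @return Radius of gyration in km; `NA` for an empty day (an empty day is
#'   undefined, not zero, and is excluded from averaging upstream).
#' @export
radius_of_gyration <- function(day) {
  if (is.null(day) || nrow(day) == 0) return(NA_real_)
  n <- day$n_k
  N <- sum(n)
  ucx <- sum(n * day$place_x) / N
  ucy <- sum(n * day$place_y) / N
  sqrt(sum(n * ((day$place_x - ucx)^2 + (day$place_y - ucy)^2)) / N)
}

#' Daily non-home time
#'
#' Hours spent beyond a buffer around the home anchor: the count of lattice
#' ticks strictly farther than `buffer_km` from home, times the tick length.
#' A tick exactly at the buffer distance counts as inside (home) time.
#' Missing ticks contribute nothing.
#'
#' @param fixes Lattice trajectory rows of a single participant (any number
#'   of days); `NA` coordinates are skipped.
#' @param home Numeric length-2, home `(x, y)` in km.
#' @param buffer_km Home-buffer radius (km); default 2.
#' @param tick_minutes Lattice spacing (minutes).
#' @return If `fixes` spans one day, a single number of hours; otherwise a
#'   data.frame `date`, `nonhome_h`.
#' @export
nonhome_time <- function(fixes, home, buffer_km = 2, tick_minutes = 30) {
  if (is.null(home) || anyNA(home)) stop("missing home anchor")
  tick_h <- tick_minutes / 60
  ok <- !is.na(fixes$x_km)
  d <- euclid(fixes$x_km[ok], fixes$y_km[ok], home[1], home[2])
  day <- as.Date(fixes$timestamp[ok], tz = "UTC")
  agg <- tapply(d > buffer_km, day, sum) * tick_h
  if (length(agg) == 1) return(unname(agg[1]))
  data.frame(date = as.Date(names(agg)), nonhome_h = unname(as.vector(agg)))
}

#' Per participant-day travel metrics
#'
#' Convenience driver: fills gaps, builds visit tables, and computes the
#' daily radius of gyration and non-home time for every participant-day.
#' A day is `valid` when at least `min_valid_frac` of its lattice ticks are
#' resolvable after gap filling; invalid days are excluded from profile
#' averaging and from exposure downstream.
#'
#' @param fixes Raw trajectory data.frame.
#' @param anchors Anchor data.frame (`participant_id`, `home_x_km`, `home_y_km`, ...).
#' @param tick_minutes Lattice spacing (minutes).
#' @param buffer_km Home-buffer radius for non-home time (km).
#' @param merge_radius_km Place-merge radius (km).
#' @param max_gap_ticks Longest carry-forward gap (ticks).
#' @param min_valid_frac Minimum resolvable-tick fraction for a valid day.
#' @param min_dwell_ticks Stay-point threshold passed to [build_visits()].
#' @return list with `metrics` (`participant_id`, `date`, `rog_km`,
#'   `nonhome_h`, `valid`), `visits` (valid days only), and `lattice`
#'   (the gap-filled fixes).
#' @export
compute_daily_metrics <- function(fixes, anchors, tick_minutes = 30,
                                  buffer_km = 2, merge_radius_km = 0.5,
                                  max_gap_ticks = 4, min_valid_frac = 0.5,
                                  min_dwell_ticks = 2L) {
  lattice <- fill_gaps(fixes, anchors, tick_minutes = tick_minutes,
                       max_gap_ticks = max_gap_ticks)
  ticks_per_day <- 1440L %/% tick_minutes
  tick_h <- tick_minutes / 60
  day <- as.Date(lattice$timestamp, tz = "UTC")
  key <- paste(lattice$participant_id, day)
  ok <- !is.na(lattice$x_km)

  n_ok <- tapply(ok, key, sum)
  valid <- n_ok / ticks_per_day >= min_valid_frac

  homes <- anchors
  rownames(homes) <- homes$participant_id

  # non-home: vectorized over all ticks at once
  hx <- homes[lattice$participant_id, "home_x_km"]
  hy <- homes[lattice$participant_id, "home_y_km"]
  far <- ok & euclid(lattice$x_km, lattice$y_km, hx, hy) > buffer_km
  nonhome_h <- tapply(far, key, sum) * tick_h

  visits <- build_visits(lattice, merge_radius_km = merge_radius_km,
                         tick_minutes = tick_minutes,
                         min_dwell_ticks = min_dwell_ticks)
  vkey <- paste(visits$participant_id, visits$date)
  rogs <- vapply(split(visits, vkey), radius_of_gyration, numeric(1))

  keys <- names(n_ok)
  sp <- regmatches(keys, regexpr(" ", keys), invert = TRUE)
  metrics <- data.frame(
    participant_id = vapply(sp, `[`, character(1), 1),
    date = as.Date(vapply(sp, `[`, character(1), 2)),
    rog_km = unname(rogs[keys]),
    nonhome_h = unname(as.vector(nonhome_h)),
    valid = unname(as.vector(valid))
  )
  metrics <- metrics[order(metrics$participant_id, metrics$date), ]
  rownames(metrics) <- NULL
  visits <- visits[paste(visits$participant_id, visits$date) %in%
                     keys[valid], , drop = FALSE]
  list(metrics = metrics, visits = visits, lattice = lattice)
}

#' Routine travel-pattern profiles and cohort stratification
#'
#' Averages each participant's valid-day radius of gyration and non-home
#' time, derives the cohort thresholds, and stratifies the cohort:
#' participants below both thresholds are `Static` (score 0), at or above
#' both are `Active` (score 2), and mixed cases are `Moderate` (score 1).
#' The non-static direction uses `>=` at the threshold.
#'
#' @param metrics Per participant-day metrics (see [compute_daily_metrics()]).
#' @param pooling `"participant"` (default): thresholds are means of the
#'   participant-level means; `"pooled"`: means over all participant-days.
#' @param thresholds Optional fixed `c(Rc, Gc)` (km, hours) overriding the
#'   cohort-derived thresholds.
#' @return list with `profiles` (`participant_id`, `n_days`, `rog_km`,
#'   `nonhome_h`, `group`, `score`) and `thresholds` (`Rc` km, `Gc` hours).
#' @export
summarize_profiles <- function(metrics, pooling = c("participant", "pooled"),
                               thresholds = NULL) {
  pooling <- match.arg(pooling)
  m <- metrics[metrics$valid & !is.na(metrics$rog_km), ]
  dropped <- setdiff(unique(metrics$participant_id), unique(m$participant_id))
  if (length(dropped)) {
    message(length(dropped), " participant(s) dropped: no valid days")
  }
  r_i <- tapply(m$rog_km, m$participant_id, mean)
  tau_i <- tapply(m$nonhome_h, m$participant_id, mean)
  n_i <- tapply(m$rog_km, m$participant_id, length)
  if (is.null(thresholds)) {
    if (pooling == "participant") {
      Rc <- mean(r_i); Gc <- mean(tau_i)
    } else {
      Rc <- mean(m$rog_km); Gc <- mean(m$nonhome_h)
    }
  } else {
    Rc <- thresholds[1]; Gc <- thresholds[2]
  }
  hi_r <- r_i >= Rc
  hi_t <- tau_i >= Gc
  score <- ifelse(hi_r & hi_t, 2L, ifelse(!hi_r & !hi_t, 0L, 1L))
  profiles <- data.frame(
    participant_id = names(r_i),
    n_days = as.integer(n_i),
    rog_km = as.vector(r_i),
    nonhome_h = as.vector(tau_i),
    group = c("Static", "Moderate", "Active")[score + 1L],
    score = as.integer(score)
  )
  rownames(profiles) <- NULL
  list(profiles = profiles, thresholds = c(Rc = unname(Rc), Gc = unname(Gc)))
}
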