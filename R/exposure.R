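#' Residence-based daily exposure
#'
#' The concentration of the cell containing the home anchor (nearest-cell
#' lookup, no interpolation).
#'
#' @param surface A [pm_surface()].
#' @param home Numeric length-2 `(x, y)` in km.
#' @param participant_id Used in the error message for out-of-grid homes.
#' @return Concentration (ug/m3).
#' @export
residence_exposure <- function(surface, home, participant_id = "?") {
  v <- surface_value_at(surface, home[1], home[2])
  if (is.na(v)) {
    stop("home of participant ", participant_id, " at (", home[1], ", ",
         home[2], ") lies outside the surface grid")
  }
  v
}

#' Mobility-based (time-weighted) daily exposure
#'
#' Time-weighted average of the surface concentration over the day's visited
#' places: `sum_k C_k * w_k` with `w_k = t_k / sum_k t_k`, where `C_k` is the
#' nearest-cell concentration at place `k` and `t_k` the dwell time there.
#' Weights are normalized so the result stays on the concentration scale; an
#' unnormalized mode (`normalize = FALSE`, units ug/m3 x hours) exists for
#' audit. Places outside the grid are clamped to the nearest border cell
#' with a warning.
#'
#' @param surface A [pm_surface()].
#' @param day Visit rows of one participant-day (`place_x`, `place_y`, `t_h`).
#' @param normalize Normalize time weights to sum to 1 (default).
#' @return Exposure (ug/m3); `NA` for a day with zero total dwell time.
#' @export
mobility_exposure <- function(surface, day, normalize = TRUE) {
  tt <- sum(day$t_h)
  if (!nrow(day) || tt <= 0) return(NA_real_)
  C <- surface_value_at(surface, day$place_x, day$place_y)
  if (anyNA(C)) {
    warning("place outside grid; clamping to the nearest border cell")
    C <- surface_value_at(surface, day$place_x, day$place_y, clamp = TRUE)
  }
  if (normalize) sum(C * day$t_h / tt) else sum(C * day$t_h)
}

#' All four daily exposure series for a cohort
#'
#' For every valid participant-day, computes residence-based (M = 0) and
#' mobility-based (M = 1) exposure against both surface stacks
#' (S = 0 single-sourced, S = 1 multi-sourced). Trajectory dates absent from
#' a stack are matched by calendar month-day to the stack's year, mirroring
#' designs where activity data span the year boundary of the concentration
#' record.
#'
#' @param visits Valid-day visit table (see [compute_daily_metrics()]).
#' @param anchors Anchor data.frame.
#' @param surfaces_by_s Named list `list("0" = ..., "1" = ...)` of surface
#'   lists indexed by date.
#' @return data.frame `participant_id`, `date`, `M`, `S`, `y`.
#' @export
daily_exposures <- function(visits, anchors, surfaces_by_s) {
  homes <- anchors
  rownames(homes) <- homes$participant_id
  # index surfaces by date string
  stacks <- lapply(surfaces_by_s, function(ss) {
    names(ss) <- vapply(ss, function(s) as.character(s$date), character(1))
    ss
  })
  match_date <- function(stack, d) {
    key <- as.character(d)
    if (!key %in% names(stack)) {
      yr <- as.integer(format(as.Date(names(stack)[1]), "%Y"))
      key <- format(as.Date(d), paste0(yr, "-%m-%d"))
    }
    stack[[key]]
  }
  out <- vector("list", 0)
  for (rows in split(seq_len(nrow(visits)), visits$date)) {
    d <- visits$date[rows[1]]
    vd <- visits[rows, ]
    pid <- unique(vd$participant_id)
    hx <- homes[pid, "home_x_km"]; hy <- homes[pid, "home_y_km"]
    for (S in names(stacks)) {
      surf <- match_date(stacks[[S]], d)
      if (is.null(surf)) next
      y0 <- surface_value_at(surf, hx, hy)
      if (anyNA(y0)) {
        stop("home of participant ", pid[which(is.na(y0))[1]],
             " lies outside the surface grid")
      }
      # time-weighted Eq.-2 exposure, all participants of this day at once
      C <- surface_value_at(surf, vd$place_x, vd$place_y, clamp = TRUE)
      num <- rowsum(C * vd$t_h, vd$participant_id)
      den <- rowsum(vd$t_h, vd$participant_id)
      y1 <- (num / den)[pid, 1]
      out[[length(out) + 1L]] <- data.frame(
        participant_id = rep(pid, 2L), date = d,
        M = rep(c(0L, 1L), each = length(pid)),
        S = as.integer(S), y = c(y0, y1))
    }
  }
  res <- do.call(rbind, out)
  res <- res[!is.na(res$y), ]
  res <- res[order(res$participant_id, res$date, res$S, res$M), ]
  rownames(res) <- NULL
  res
}

#' Long-term exposure aggregation
#'
#' Per participant and (M, S) series, the unweighted mean of daily exposures
#' over retained days. The same retained-day set (the intersection of days
#' present in all four series) is used for every series of a participant, so
#' the four long-term values are directly comparable. Participants with
#' fewer retained days than `min_days` are dropped and reported.
#'
#' @param records Daily exposure data.frame (see [daily_exposures()]).
#' @param min_days Minimum retained days per participant.
#' @return data.frame `participant_id`, `M`, `S`, `Y`, `n_days`; dropped
#'   participants in `attr(, "dropped")`.
#' @export
longterm <- function(records, min_days = 60) {
  out <- vector("list", 0)
  dropped <- character(0)
  for (pp in split(records, records$participant_id)) {
    tab <- table(pp$date)
    common <- names(tab)[tab == 4L]  # day present in all four (M, S) series
    if (length(common) < nrow(pp) / 4) {
      pp <- pp[as.character(pp$date) %in% common, ]
    }
    if (length(common) < min_days) {
      dropped <- c(dropped, pp$participant_id[1])
      next
    }
    agg <- stats::aggregate(y ~ M + S, data = pp, FUN = mean)
    out[[length(out) + 1L]] <- data.frame(
      participant_id = pp$participant_id[1],
      M = agg$M, S = agg$S, Y = agg$y, n_days = length(common))
  }
  res <- do.call(rbind, out)
  if (!is.null(res)) rownames(res) <- NULL
  if (length(dropped)) {
    message(length(dropped), " participant(s) below the ", min_days,
            "-day minimum dropped from long-term aggregation")
  }
  attr(res, "dropped") <- dropped
  res
}
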