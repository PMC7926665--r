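#' Assemble a full run configuration
#'
#' One serializable list holding every parameter of the pipeline; a run
#' writes its resolved configuration next to its outputs so any run can be
#' reproduced from that file alone. A single global seed fans out to fixed
#' per-stage substreams, so stages are independently reproducible.
#'
#' @param seed Global integer seed.
#' @param field,stations,cohort,mobility,surfaces,exposure,model Named lists
#'   overriding stage defaults (see the corresponding stage functions).
#' @return list of class `run_config`.
#' @export
run_config <- function(seed = 1L, field = list(), stations = list(),
                       cohort = list(), mobility = list(), surfaces = list(),
                       exposure = list(), model = list()) {
  merge <- function(def, ov) { def[names(ov)] <- ov; def }
  structure(list(
    seed = as.integer(seed),
    field = merge(list(nx = 20, ny = 20, cell_size = 2, origin_x = 0, origin_y = 0,
                       n_days = 60, start_date = "2016-12-01",
                       mean_level = 7, spatial_sd = 0.8, corr_range = 8,
                       temporal_ar = 0.6, temporal_sd = 3,
                       covariate_effects = c(3, 0.5)), field),
    stations = merge(list(n_stations = 5, noise_sd = 0.3), stations),
    cohort = merge(list(n_participants = 200, n_days = 60, tick_minutes = 30,
                        dropout = 0.05, work_toward_attractor = 0.8,
                        jitter_sd_km = 0.05), cohort),
    mobility = merge(list(buffer_km = 2, merge_radius_km = 0.5,
                          max_gap_ticks = 4, min_valid_frac = 0.5,
                          pooling = "participant"), mobility),
    surfaces = merge(list(family = "exponential", cv_folds = 5), surfaces),
    exposure = merge(list(min_days = 30), exposure),
    model = merge(list(steps = 1:3), model)
  ), class = "run_config")
}

#' Desk-scale demo configuration
#'
#' 100 participants over 30 days on a 20 x 20 grid with 5 stations — small
#' enough to run end to end in well under a minute while still showing the
#' moderation structure.
#'
#' @param seed Global integer seed.
#' @return A [run_config()].
#' @export
demo_config <- function(seed = 1L) {
  run_config(seed,
             field = list(n_days = 30),
             cohort = list(n_participants = 100, n_days = 30),
             exposure = list(min_days = 20))
}

#' Load / save a run configuration
#'
#' @param path JSON file path.
#' @param config A `run_config`.
#' @return `read_config` returns a `run_config`; `write_config` returns
#'   `path` invisibly.
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, c(list(seed = raw$seed),
                        raw[setdiff(names(raw), "seed")]))
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

write_json_out <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

write_surface_stack <- function(surfaces, dir, prefix) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- vapply(surfaces, function(s) {
    f <- file.path(dir, sprintf("%s_%s.asc", prefix, format(s$date, "%Y%m%d")))
    write_ascii_grid(s, f)
    basename(f)
  }, character(1))
  manifest <- data.frame(
    date = vapply(surfaces, function(s) as.character(s$date), character(1)),
    model_tag = vapply(surfaces, function(s) s$model_tag, integer(1)),
    file = files)
  utils::write.csv(manifest, file.path(dir, paste0(prefix, "_manifest.csv")),
                   row.names = FALSE)
  manifest
}

#' Run the full pipeline
#'
#' Executes simulate -> travel metrics -> surfaces -> exposure -> models in
#' one deterministic pass and writes every stage product (CSV / JSON / ESRI
#' ASCII grids) plus the resolved configuration and a run log under
#' `outdir`. Re-running with the same configuration reproduces identical
#' data payloads.
#'
#' @param config A [run_config()].
#' @param outdir Output directory (created if needed).
#' @param quiet Suppress progress messages?
#' @return Invisibly, a list with the main in-memory products (`fields`,
#'   `cohort`, `profiles`, `thresholds`, `cv`, `smoothing`, `longterm`,
#'   `fits`, `effects`, `outdir`).
#' @export
run_all <- function(config, outdir, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(outdir, "run.log")
  cat("run started\n", file = logf)
  say <- function(...) {
    msg <- paste0(...)
    cat(msg, "\n", file = logf, append = TRUE)
    if (!quiet) message(msg)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      rec <- list(stage = name, error = conditionMessage(e))
      write_json_out(rec, file.path(outdir, "error.json"))
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }
  write_config(config, file.path(outdir, "config.json"))

  # --- simulate ------------------------------------------------------------
  f <- config$field
  fields <- cohort <- stations <- NULL
  stage("simulate", {
    fp <- field_params(
      grid = pm_grid(f$origin_x, f$origin_y, f$cell_size, f$nx, f$ny),
      n_days = f$n_days, start_date = as.Date(f$start_date),
      mean_level = f$mean_level, spatial_sd = f$spatial_sd,
      corr_range = f$corr_range, temporal_ar = f$temporal_ar,
      temporal_sd = f$temporal_sd, covariate_effects = f$covariate_effects,
      seed = derive_seed(config$seed, "field"))
    fields <- generate_fields(fp)
    stations <- generate_stations(fields, config$stations$n_stations,
                                   config$stations$noise_sd,
                                   seed = derive_seed(config$seed, "stations"))
    cp <- do.call(cohort_params, c(config$cohort,
                                   list(seed = derive_seed(config$seed, "cohort"))))
    cohort <- generate_cohort(cp, fields)
    utils::write.csv(data.frame(
      participant_id = cohort$fixes$participant_id,
      timestamp_iso8601 = format(cohort$fixes$timestamp, "%Y-%m-%dT%H:%M:%SZ",
                                 tz = "UTC"),
      x_km = cohort$fixes$x_km, y_km = cohort$fixes$y_km,
      source = cohort$fixes$source),
      file.path(outdir, "trajectories.csv"), row.names = FALSE)
    utils::write.csv(cohort$anchors, file.path(outdir, "anchors.csv"),
                     row.names = FALSE)
    utils::write.csv(stations[, c("station_id", "x_km", "y_km", "date", "pm25")],
                     file.path(outdir, "stations.csv"), row.names = FALSE)
    utils::write.csv(cohort$ledger, file.path(outdir, "truth_ledger.csv"),
                     row.names = FALSE)
    write_surface_stack(fields$surfaces, file.path(outdir, "surfaces_true"),
                        "true")
    say("simulate: ", length(unique(cohort$anchors$participant_id)),
        " participants, ", f$n_days, " days, ",
        config$stations$n_stations, " stations")
  })

  # --- travel metrics ------------------------------------------------------
  mob <- config$mobility
  metrics <- visits <- profiles <- thresholds <- NULL
  stage("metrics", {
    dm <- compute_daily_metrics(cohort$fixes, cohort$anchors,
                                tick_minutes = config$cohort$tick_minutes,
                                buffer_km = mob$buffer_km,
                                merge_radius_km = mob$merge_radius_km,
                                max_gap_ticks = mob$max_gap_ticks,
                                min_valid_frac = mob$min_valid_frac)
    metrics <- dm$metrics
    visits <- dm$visits
    pr <- summarize_profiles(metrics, pooling = mob$pooling)
    profiles <- pr$profiles
    thresholds <- pr$thresholds
    utils::write.csv(metrics, file.path(outdir, "daily_metrics.csv"),
                     row.names = FALSE)
    utils::write.csv(profiles, file.path(outdir, "profiles.csv"),
                     row.names = FALSE)
    write_json_out(as.list(thresholds), file.path(outdir, "thresholds.json"))
    say("metrics: thresholds Rc = ", round(thresholds["Rc"], 2), " km, Gc = ",
        round(thresholds["Gc"], 2), " h; groups ",
        paste(names(table(profiles$group)), table(profiles$group),
              collapse = ", "))
  })

  # --- surfaces ------------------------------------------------------------
  surf <- config$surfaces
  stacks <- cv <- smoothing <- NULL
  stage("surfaces", {
    grid <- fields$params$grid
    s0 <- build_surfaces(stations, grid, "single", family = surf$family)
    s1 <- build_surfaces(stations, grid, "multi",
                         covariates = fields$covariates, family = surf$family)
    stacks <- list(`0` = s0$surfaces, `1` = s1$surfaces)
    write_surface_stack(s0$surfaces, file.path(outdir, "surfaces_single"),
                        "single")
    write_surface_stack(s1$surfaces, file.path(outdir, "surfaces_multi"),
                        "multi")
    cv <- list(
      single = spatial_cv(stations, "single", k = surf$cv_folds,
                          seed = derive_seed(config$seed, "cv"),
                          family = surf$family),
      multi = spatial_cv(stations, "multi", covariates = fields$covariates,
                         k = surf$cv_folds,
                         seed = derive_seed(config$seed, "cv"),
                         family = surf$family))
    write_json_out(lapply(cv, function(r)
      list(rmse = r$rmse, mpe = r$mpe, r2 = r$r2, n_folds = r$n_folds,
           fold_assignment = as.list(r$fold_assignment))),
      file.path(outdir, "cv_report.json"))
    smoothing <- smoothing_diagnostic(s0$surfaces, s1$surfaces)
    utils::write.csv(smoothing$daily, file.path(outdir, "smoothing_daily.csv"),
                     row.names = FALSE)
    utils::write.csv(smoothing$summary,
                     file.path(outdir, "smoothing_summary.csv"),
                     row.names = FALSE)
    say("surfaces: CV RMSE single ", round(cv$single$rmse, 3), ", multi ",
        round(cv$multi$rmse, 3))
  })

  # --- exposure ------------------------------------------------------------
  daily <- lt <- NULL
  stage("exposure", {
    daily <- daily_exposures(visits, cohort$anchors, stacks)
    lt <- longterm(daily, min_days = config$exposure$min_days)
    utils::write.csv(daily, file.path(outdir, "daily_exposure.csv"),
                     row.names = FALSE)
    utils::write.csv(lt, file.path(outdir, "longterm_exposure.csv"),
                     row.names = FALSE)
    say("exposure: ", nrow(lt) / 4, " participants with all four series")
  })

  # --- models --------------------------------------------------------------
  fits <- effects <- NULL
  stage("model", {
    frame <- build_frame(lt, profiles)
    fits <- lapply(config$model$steps, function(s) fit_step(frame, s))
    for (ft in fits) {
      write_json_out(list(
        step = ft$step, coefficients = ft$coefficients,
        random_intercept_sd = ft$random_intercept_sd,
        residual_sd = ft$residual_sd, aic = ft$aic, bic = ft$bic,
        loglik = ft$loglik, n_participants = ft$n_participants,
        singular = ft$singular),
        file.path(outdir, sprintf("fit_step%d.json", ft$step)))
    }
    utils::write.csv(step_table(fits), file.path(outdir, "model_table.csv"),
                     row.names = FALSE)
    st3 <- Filter(function(f) f$step == 3, fits)
    if (length(st3)) {
      effects <- effect_grid(st3[[1]])
      utils::write.csv(effects, file.path(outdir, "effect_grid.csv"),
                       row.names = FALSE)
    }
    say("model: steps ", paste(config$model$steps, collapse = ","), " fitted")
  })
  say("run complete")
  invisible(list(fields = fields, cohort = cohort, stations = stations,
                 metrics = metrics, visits = visits, profiles = profiles,
                 thresholds = thresholds, stacks = stacks, cv = cv,
                 smoothing = smoothing, daily = daily, longterm = lt,
                 fits = fits, effects = effects, outdir = outdir))
}
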