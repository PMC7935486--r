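#' Re-run the model experiments and report the cross-correlation lags
#'
#' Runs the coupled (closed-feedback) and uncoupled (imposed-wave) chain
#' simulations with the default parameters, computes the peak
#' cross-correlation lag between the extension-shrinkage rate and the ERK
#' activity rate in each regime, and assembles a machine-readable report;
#' optionally writes the report (JSON), trajectories and kymograph CSVs to
#' a directory.
#'
#' @param out_dir optional output directory.
#' @param duration,discard,record_interval simulation protocol, min.
#' @param lag_tolerance_coupled,lag_tolerance_uncoupled reported acceptance
#'   half-widths, min.
#' @param params_coupled,params_uncoupled optional parameter overrides.
#' @return The report list: per-regime lag (min), per-cell lags, wave
#'   period diagnostics, protocol, and tolerances.
#' @export
reproduce_model_figures <- function(out_dir = NULL, duration = 6000,
                                    discard = 2000, record_interval = 1,
                                    lag_tolerance_coupled = 4,
                                    lag_tolerance_uncoupled = 2,
                                    params_coupled = default_params("coupled"),
                                    params_uncoupled = default_params("uncoupled")) {
  run_one <- function(params) {
    traj <- run_chain(params, duration = duration, discard = discard,
                      record_interval = record_interval, record_x = FALSE)
    lag <- model_lag(traj)
    list(traj = traj, lag = lag)
  }
  co <- run_one(params_coupled)
  un <- run_one(params_uncoupled)
  report <- list(
    protocol = list(duration_min = duration, discard_min = discard,
                    record_interval_min = record_interval,
                    analysis_cells = co$lag$cells),
    coupled = list(lag_min = co$lag$lag,
                   per_cell = unname(co$lag$per_cell),
                   tolerance_min = lag_tolerance_coupled),
    uncoupled = list(lag_min = un$lag$lag,
                     per_cell = unname(un$lag$per_cell),
                     tolerance_min = lag_tolerance_uncoupled)
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(report, file.path(out_dir, "model_report.json"),
                         auto_unbox = TRUE, digits = 10, pretty = TRUE)
    for (nm in c("coupled", "uncoupled")) {
      traj <- if (nm == "coupled") co$traj else un$traj
      thin <- seq(1, length(traj$t), by = max(1L, 10L))
      km <- traj$E[thin, ]
      write.csv(data.frame(t_min = traj$t[thin], km),
                file.path(out_dir, sprintf("kymograph_%s.csv", nm)),
                row.names = FALSE)
    }
  }
  report
}

#' Run one pipeline step from a configuration
#'
#' Dispatches to the module operations from a config list (or JSON path):
#' `subcommand` selects the step, the remaining keys are its inputs.
#' Unknown keys are rejected by name. Supported subcommands:
#' `simulate` (chain model -> trajectory CSV + lag JSON),
#' `reproduce` (both regimes -> report), `synth-wave-movie` (synthetic
#' stacks + ground truth), `quantify-flow` (FRET/CFP stacks -> ratio, PIV,
#' elongation and rate series CSVs), `kymo` (ratio stack + line ->
#' kymograph + wave speed), `curvature` (contour CSVs -> curvature and
#' thickness profile CSV).
#'
#' @param config list or path to a JSON config file.
#' @return The step's result, invisibly; artifacts are written under
#'   `config$out_dir`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- jsonlite::read_json(config, simplifyVector = TRUE)
  if (is.null(config$subcommand)) stopf("config lacks required key 'subcommand'")
  sub <- config$subcommand
  known <- list(
    simulate = c("mode", "N", "duration", "discard", "record_interval", "out_dir"),
    reproduce = c("duration", "discard", "record_interval", "out_dir"),
    `synth-wave-movie` = c("seed", "n_frames", "width", "height", "out_dir"),
    `quantify-flow` = c("fret", "cfp", "line", "out_dir"),
    kymo = c("fret", "cfp", "line", "out_dir"),
    curvature = c("apical", "basal", "lumen_x", "lumen_y", "out_dir")
  )
  if (!sub %in% names(known)) stopf("unknown subcommand '%s'", sub)
  extra <- setdiff(names(config), c("subcommand", known[[sub]]))
  if (length(extra))
    stopf("unknown config key '%s' for subcommand '%s'", extra[1], sub)
  out_dir <- config$out_dir %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- switch(sub,
    simulate = pipeline_simulate(config, out_dir),
    reproduce = reproduce_model_figures(
      out_dir,
      duration = config$duration %||% 6000,
      discard = config$discard %||% 2000,
      record_interval = config$record_interval %||% 1),
    `synth-wave-movie` = pipeline_synth(config, out_dir),
    `quantify-flow` = pipeline_quantify(config, out_dir),
    kymo = pipeline_kymo(config, out_dir),
    curvature = pipeline_curvature(config, out_dir)
  )
  prov <- list(subcommand = sub, config = config,
               package_version = as.character(utils::packageVersion("erkwave")))
  jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(res)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

pipeline_simulate <- function(config, out_dir) {
  params <- default_params(config$mode %||% "coupled")
  if (!is.null(config$N)) {
    params$N <- as.integer(config$N)
    params <- do.call(chain_params, unclass(params))
  }
  traj <- run_chain(params, duration = config$duration %||% 6000,
                    discard = config$discard %||% 2000,
                    record_interval = config$record_interval %||% 1)
  lag <- model_lag(traj)
  df <- as.data.frame(traj)
  thin <- df$time %% 10 == df$time[1] %% 10
  write.csv(df[thin, ], file.path(out_dir, "trajectory.csv"), row.names = FALSE)
  jsonlite::write_json(list(lag_min = lag$lag, per_cell = unname(lag$per_cell)),
                       file.path(out_dir, "lag.json"), auto_unbox = TRUE,
                       digits = 10)
  lag
}

pipeline_synth <- function(config, out_dir) {
  spec <- wave_movie_spec(seed = config$seed %||% 1L,
                          n_frames = config$n_frames %||% 30L,
                          width = config$width %||% 512L,
                          height = config$height %||% 64L)
  mv <- make_wave_movie(spec)
  write_stack(mv$fret, file.path(out_dir, "fret.tif"))
  write_stack(mv$cfp, file.path(out_dir, "cfp.tif"))
  write.csv(data.frame(row = mv$line$points[, 1], col = mv$line$points[, 2]),
            file.path(out_dir, "line.csv"), row.names = FALSE)
  jsonlite::write_json(mv$truth, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(mv)
}

pipeline_quantify <- function(config, out_dir) {
  fret <- read_stack(config$fret)
  cfp <- read_stack(config$cfp)
  line <- apex_base_line(read_polyline_csv(config$line), fret$pixel_size)
  rs <- fret_ratio(fret, cfp)
  nt <- dim(cfp$frames)[3]
  rows <- lapply(seq_len(nt - 1), function(k) {
    pf <- piv_pair(cfp$frames[, , k], cfp$frames[, , k + 1],
                   pixel_size = cfp$pixel_size,
                   frame_interval = cfp$frame_interval)
    pf <- median_filter_field(pf)
    pr <- project_onto_line(pf, line)
    er <- extension_shrinkage_rate(pr$s, pr$speed)
    data.frame(t_min = (k - 1) * cfp$frame_interval,
               s_um = er$s, rate_per_min = er$rate,
               speed_um_min = approx(pr$s, pr$speed, xout = er$s)$y)
  })
  out <- do.call(rbind, rows)
  write.csv(out, file.path(out_dir, "flow_series.csv"), row.names = FALSE)
  invisible(out)
}

pipeline_kymo <- function(config, out_dir) {
  fret <- read_stack(config$fret)
  cfp <- read_stack(config$cfp)
  line <- apex_base_line(read_polyline_csv(config$line), fret$pixel_size)
  rs <- fret_ratio(fret, cfp)
  km <- kymograph(rs, line)
  ws <- wave_speed(km)
  write_kymograph(km, file.path(out_dir, "kymograph.csv"),
                  file.path(out_dir, "kymograph.tif"))
  jsonlite::write_json(list(speed_um_min = ws$speed, sd = ws$sd,
                            n_ridges = ws$n_ridges, direction = ws$direction),
                       file.path(out_dir, "wave_speed.json"),
                       auto_unbox = TRUE, digits = 10)
  invisible(ws)
}

pipeline_curvature <- function(config, out_dir) {
  apical <- read_polyline_csv(config$apical)
  basal <- read_polyline_csv(config$basal)
  layer <- traced_layer(apical, basal,
                        c(config$lumen_x %||% 0, config$lumen_y %||% 0))
  mid <- midline(layer)
  pts <- resample_curve(mid, 15)
  sp <- fit_spline(pts)
  prof <- curvature_profile(sp, lumen_point = layer$lumen_point)
  th <- thickness_profile(polyline_at(mid, attr(pts, "s")), layer)
  prof$thickness <- approx(th$arc, th$thickness, xout = prof$arc, rule = 2)$y
  write.csv(prof, file.path(out_dir, "curvature_profile.csv"), row.names = FALSE)
  jsonlite::write_json(list(total_curvature = total_curvature(prof)),
                       file.path(out_dir, "curvature_summary.json"),
                       auto_unbox = TRUE, digits = 10)
  invisible(prof)
}
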