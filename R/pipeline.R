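# End-to-end orchestration: validated config -> synthesize -> track -> fit
# -> normalize -> force report, with a manifest for reproducibility.

config_known_keys <- function() list(
  top = c("seed", "stages", "output_dir", "optics", "deformation", "uptake",
          "pulse_series", "track", "relax", "forces"),
  optics = names(formals(optics_params)),
  deformation = names(formals(deformation_scenario)),
  uptake = names(formals(uptake_scenario)),
  pulse_series = names(formals(pulse_series_scenario)),
  track = names(formals(track_params)),
  relax = c("model", "baseline", "margin"),
  forces = c("R_um", "e", "E_V_per_mm", "duration_s", "penetration_factor",
             "porated", "c0", "d", "l", "k_stretch", "xi_h", "mu_B")
)

#' Validate a pipeline configuration
#'
#' Parses a JSON/YAML config (file path or raw text) into a typed run
#' configuration: unknown keys are rejected by name, units are checked
#' (e.g. non-negative field strengths, positive radii), and defaults are
#' filled in from the corresponding parameter constructors.
#'
#' @param config a file path, raw YAML/JSON text, or a list.
#' @return list of class `run_config`.
#' @export
validate_config <- function(config) {
  raw <- if (is.list(config)) config
  else if (file.exists(config)) yaml::read_yaml(config)
  else yaml::yaml.load(config)
  if (!is.list(raw)) stop("validate_config: config must parse to a mapping")
  known <- config_known_keys()
  unknown <- setdiff(names(raw), known$top)
  if (length(unknown) > 0)
    stop(sprintf("validate_config: unknown key '%s'", unknown[1]))
  for (blk in intersect(names(raw), names(known)[-1])) {
    bad <- setdiff(names(raw[[blk]]), known[[blk]])
    if (length(bad) > 0)
      stop(sprintf("validate_config: unknown key '%s' in block '%s'",
                   bad[1], blk))
  }
  fz <- raw$forces %||% list()
  if (!is.null(fz$E_V_per_mm) && fz$E_V_per_mm < 0)
    stop("validate_config: 'E_V_per_mm' must be >= 0")
  if (!is.null(fz$R_um) && fz$R_um <= 0)
    stop("validate_config: 'R_um' must be > 0")
  seed <- as.integer(raw$seed %||% 1L)
  cfg <- list(
    seed = seed,
    stages = raw$stages %||% c("synth", "track", "relax", "uptake", "pulses",
                               "forces"),
    output_dir = raw$output_dir %||% tempfile("guvepore_run_"),
    optics = do.call(optics_params,
                     utils::modifyList(list(seed = seed), raw$optics %||% list())),
    deformation = do.call(deformation_scenario,
                          utils::modifyList(list(seed = seed),
                                            raw$deformation %||% list())),
    uptake = do.call(uptake_scenario,
                     utils::modifyList(list(seed = seed), raw$uptake %||% list())),
    pulse_series = do.call(pulse_series_scenario,
                           utils::modifyList(list(seed = seed),
                                             raw$pulse_series %||% list())),
    track = do.call(track_params, raw$track %||% list()),
    relax = utils::modifyList(list(model = "auto", baseline = 1, margin = 2),
                              raw$relax %||% list()),
    forces = fz
  )
  structure(cfg, class = "run_config")
}

#' Run the full synthetic analysis pipeline
#'
#' Executes the requested stages in order: `synth` (generate deformation
#' trace, frames, uptake trace and pulse series), `track` (contour tracking
#' of the rendered frames), `relax` (relaxation fit of the tracked trace),
#' `uptake` (uptake kinetics fit), `pulses` (area/bleaching normalization
#' and sigmoid fits), `forces` (actin-cortex force report using the maximum
#' tracked deformation). Outputs are written under `config$output_dir`
#' (CSV traces, JSON fits); a manifest recording the config, seed, package
#' version, per-stage status and output checksums is always written, even
#' on partial failure.
#'
#' @param config a [validate_config()] result, or anything it accepts.
#' @return list of class `run_manifest`; component `results` holds the
#'   in-memory stage outputs.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "run_config")) config <- validate_config(config)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  status <- list()
  results <- list()
  outputs <- character()
  run_stage <- function(name, expr) {
    if (!(name %in% config$stages)) {
      status[[name]] <<- "skipped"
      return(invisible(NULL))
    }
    res <- tryCatch(expr, error = function(e) e)
    if (inherits(res, "error")) {
      status[[name]] <<- paste("failed:", conditionMessage(res))
    } else {
      status[[name]] <<- "ok"
      results[[name]] <<- res
    }
    invisible(NULL)
  }

  run_stage("synth", {
    trace <- generate_deformation_trace(config$deformation, config$optics)
    # render a manageable number of frames around the pulse
    every <- max(1L, nrow(trace) %/% 60L)
    seq_ <- render_sequence(trace, config$optics, every = every)
    tif <- file.path(config$output_dir, "frames.tif")
    write_sequence_tiff(seq_, tif)
    csv <- file.path(config$output_dir, "truth_trace.csv")
    write_trace_csv(trace, csv)
    up <- generate_uptake_trace(config$uptake)
    upcsv <- file.path(config$output_dir, "uptake.csv")
    utils::write.csv(up, upcsv, row.names = FALSE)
    ps <- generate_pulse_series(config$pulse_series)
    pscsv <- file.path(config$output_dir, "pulses.csv")
    utils::write.csv(ps$pulses, pscsv, row.names = FALSE)
    outputs <<- c(outputs, tif, csv, upcsv, pscsv)
    list(trace = trace, sequence = seq_, uptake = up, pulse_series = ps)
  })
  run_stage("track", {
    tracked <- track_sequence(results$synth$sequence, params = config$track)
    csv <- file.path(config$output_dir, "tracked_trace.csv")
    write_trace_csv(tracked, csv)
    outputs <<- c(outputs, csv)
    tracked
  })
  run_stage("relax", {
    trace <- results$track %||% results$synth$trace
    fit <- fit_relaxation(trace, model = config$relax$model,
                          baseline = config$relax$baseline,
                          margin = config$relax$margin)
    path <- file.path(config$output_dir, "relaxation_fit.json")
    write_json_report(unclass(fit), path)
    outputs <<- c(outputs, path)
    fit
  })
  run_stage("uptake", {
    fit <- fit_uptake(results$synth$uptake)
    path <- file.path(config$output_dir, "uptake_fit.json")
    write_json_report(unclass(fit)[c("I_inf", "I0", "tau_s", "rss", "n",
                                     "non_uptake")], path)
    outputs <<- c(outputs, path)
    fit
  })
  run_stage("pulses", {
    an <- analyze_pulse_series(results$synth$pulse_series)
    path <- file.path(config$output_dir, "pulse_series.json")
    write_json_report(list(area = an$area, I_norm = an$I_norm,
                           area_fit = unclass(an$area_fit),
                           actin_fit = unclass(an$actin_fit)), path)
    outputs <<- c(outputs, path)
    an
  })
  run_stage("forces", {
    fz <- config$forces
    e <- fz$e %||% {
      tr <- results$track %||% results$synth$trace
      if (!is.null(tr)) max_deformation(tr)$ab_max else 1.18
    }
    cortex <- do.call(cortex_params,
                      fz[intersect(names(fz), names(formals(cortex_params)))])
    pulse <- do.call(pulse_params,
                     fz[intersect(names(fz), names(formals(pulse_params)))])
    rep <- force_report(R_um = fz$R_um %||% 10, e = e, pulse = pulse,
                        cortex = cortex, porated = fz$porated %||% TRUE)
    path <- file.path(config$output_dir, "force_report.json")
    write_json_report(unclass(rep)[c("R", "e", "porated", "N_f",
                                     "zeta_sphere", "zeta_spheroid",
                                     "delta_zeta", "f_m", "f_electrophoretic",
                                     "verdict_mechanical",
                                     "verdict_electrophoretic")], path)
    outputs <<- c(outputs, path)
    rep
  })

  manifest <- list(
    package_version = as.character(utils::packageVersion("guvepore")),
    seed = config$seed,
    stages = status,
    outputs = outputs,
    checksums = as.list(tools::md5sum(outputs[file.exists(outputs)])),
    config = config[c("seed", "stages", "output_dir")]
  )
  write_json_report(manifest, file.path(config$output_dir, "manifest.json"))
  structure(c(manifest, list(results = results)), class = "run_manifest")
}

write_json_report <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(path)
}
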