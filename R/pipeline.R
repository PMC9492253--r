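#' End-to-end analysis pipeline
#'
#' Runs the full chain on one system: read (or accept) umbrella windows ->
#' WHAM -> minima detection -> NEB snippet graph -> candidate path
#' enumeration and ranking -> 1D projection -> Kramers rate chain -> total
#' rate (with the bound fallback on overflow). Every stage writes its result
#' as plain text into the output directory together with a resolved copy of
#' the configuration, and the run is deterministic for fixed inputs.
#'
#' @name pipeline
NULL

.config_schema <- function() {
  list(
    windows_dir = list(check = is.character),
    metadata = list(default = "windows.meta", check = is.character),
    windows = list(check = is.list),
    out_dir = list(check = is.character),
    seed = list(default = 1L, check = function(x) is.numeric(x) && x == round(x)),
    wham = list(schema = list(
      n_bins = list(default = 100L, check = function(x)
        is.numeric(x) && all(x >= 1) && all(x == round(x))),
      tolerance = list(default = 1e-6, check = function(x)
        is.numeric(x) && x > 0),
      max_iterations = list(default = 100000L, check = function(x)
        is.numeric(x) && x >= 1),
      temperature = list(default = 310, check = function(x)
        is.numeric(x) && x > 0),
      boundaries = list(check = function(x) TRUE))),
    minima = list(schema = list(
      min_separation = list(default = 0.1, check = function(x)
        is.numeric(x) && x >= 0),
      max_energy_offset = list(default = 50, check = function(x)
        is.numeric(x) && x > 0),
      smoothing = list(default = 1.5, check = function(x)
        is.numeric(x) && x >= 0),
      min_prominence = list(default = 3, check = function(x)
        is.numeric(x) && x >= 0))),
    neb = list(schema = list(
      n_images = list(default = 32L, check = function(x)
        is.numeric(x) && x >= 5),
      spring_constant = list(default = 500, check = function(x)
        is.numeric(x) && x > 0),
      max_iterations = list(default = 3000L, check = function(x)
        is.numeric(x) && x >= 1),
      force_tolerance = list(default = 30, check = function(x)
        is.numeric(x) && x > 0),
      smoothing = list(default = 1.5, check = function(x)
        is.numeric(x) && x >= 0))),
    path = list(schema = list(
      start = list(default = "auto", check = function(x)
        identical(x, "auto") || (is.numeric(x) && x >= 1)),
      end = list(default = "auto", check = function(x)
        identical(x, "auto") || (is.numeric(x) && x >= 1)),
      max_paths = list(default = 10L, check = function(x)
        is.numeric(x) && x >= 1),
      rerelax = list(default = TRUE, check = is.logical),
      min_prominence = list(default = 1, check = function(x)
        is.numeric(x) && x >= 0))),
    rates = list(schema = list(
      temperature = list(default = 310, check = function(x)
        is.numeric(x) && x > 0),
      fit_window = list(check = function(x) is.numeric(x) && x > 0),
      omega_convention = list(default = "peak", check = function(x)
        x %in% c("peak", "valley")))))
}

.validate_section <- function(cfg, schema, where) {
  if (is.null(cfg)) cfg <- list()
  unknown <- setdiff(names(cfg), names(schema))
  if (length(unknown))
    stop(sprintf("unknown config key%s in %s: %s",
                 if (length(unknown) > 1) "s" else "", where,
                 paste(unknown, collapse = ", ")), call. = FALSE)
  for (key in names(schema)) {
    spec <- schema[[key]]
    if (!is.null(spec$schema)) {
      cfg[[key]] <- .validate_section(cfg[[key]], spec$schema,
                                      paste0(where, "$", key))
    } else if (is.null(cfg[[key]])) {
      if (!is.null(spec$default)) cfg[[key]] <- spec$default
    } else if (!isTRUE(spec$check(cfg[[key]]))) {
      stop(sprintf("config value %s$%s is out of range or has the wrong type",
                   where, key), call. = FALSE)
    }
  }
  cfg
}

#' Validate and resolve a pipeline configuration
#'
#' @param config a named list, or a path to a YAML file. Unknown keys are
#'   rejected; missing keys take documented defaults.
#' @return the resolved configuration list.
#' @export
pipeline_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- .validate_section(config, .config_schema(), "config")
  if (is.null(cfg[["windows"]]) && is.null(cfg[["windows_dir"]]))
    stop("config needs either 'windows' (in-memory) or 'windows_dir'",
         call. = FALSE)
  if (is.null(cfg$out_dir))
    stop("config needs 'out_dir'", call. = FALSE)
  cfg
}

#' Run the full pipeline on one system
#'
#' @param config configuration list or YAML path; see [pipeline_config()]
#'   for keys and defaults. The start/end states of the conduction path
#'   default to the minima with the largest and smallest first CV (the
#'   outermost and innermost states of an inward conduction coordinate).
#' @return an object of class `ionpmf_report`: list with `wham`, `minima`,
#'   `path_graph`, `paths` (ranked), `profile`, `chain`, `rate`,
#'   `rate_is_bound`, `barriers` (forward steps + cyclic re-entry),
#'   `warnings`, `config`, `files`.
#' @export
run_pipeline <- function(config) {
  cfg <- pipeline_config(if (is.list(config)) config else config)
  out <- cfg$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(out, "pipeline.log")
  cat("", file = logf)
  warn <- character(0)
  note <- function(...) {
    msg <- sprintf(...)
    cat(msg, "\n", file = logf, append = TRUE, sep = "")
    message(msg)
  }
  run_stage <- function(name, expr) {
    withCallingHandlers(
      tryCatch(expr, error = function(e) {
        stop(sprintf("pipeline stage '%s': %s (partial outputs in %s)",
                     name, conditionMessage(e), out), call. = FALSE)
      }),
      warning = function(w) {
        warn <<- c(warn, sprintf("[%s] %s", name, conditionMessage(w)))
        invokeRestart("muffleWarning")
      })
  }
  cfg_plain <- cfg
  cfg_plain[["windows"]] <- if (!is.null(cfg[["windows"]]))
    sprintf("<%d in-memory windows>", length(cfg[["windows"]])) else NULL
  yaml::write_yaml(cfg_plain, file.path(out, "config_resolved.yaml"))
  files <- c(config = file.path(out, "config_resolved.yaml"))

  windows <- run_stage("read_windows", {
    if (!is.null(cfg[["windows"]])) cfg[["windows"]]
    else read_windows(cfg$windows_dir, cfg$metadata)
  })
  note("read_windows: %d windows, %s samples total", length(windows),
       format(sum(vapply(windows, function(w) nrow(w$samples), numeric(1)))))

  fit <- run_stage("wham", wham(
    windows, n_bins = cfg$wham$n_bins, tolerance = cfg$wham$tolerance,
    max_iterations = cfg$wham$max_iterations,
    temperature = cfg$wham$temperature, boundaries = cfg$wham$boundaries))
  note("wham: %d bins/CV, converged in %d iterations (final change %.2g kJ/mol)",
       cfg$wham$n_bins[1], fit$n_iterations, fit$final_change)
  write_pmf(fit$pmf, file.path(out, "pmf.dat"))
  write_offsets(fit, file.path(out, "offsets.csv"))
  files <- c(files, pmf = file.path(out, "pmf.dat"),
             offsets = file.path(out, "offsets.csv"))

  minima <- run_stage("find_minima", find_minima(
    fit$pmf, min_separation = cfg$minima$min_separation,
    max_energy = min(fit$pmf$free_energy, na.rm = TRUE) +
      cfg$minima$max_energy_offset,
    smoothing = cfg$minima$smoothing,
    min_prominence = cfg$minima$min_prominence))
  if (nrow(minima) < 2L)
    stop("pipeline stage 'find_minima': fewer than 2 minima found",
         call. = FALSE)
  note("find_minima: %d minima (smoothing %.2g bins, prominence >= %.2g kJ/mol)",
       nrow(minima), cfg$minima$smoothing, cfg$minima$min_prominence)
  write_minima(minima, file.path(out, "minima.csv"))
  files <- c(files, minima = file.path(out, "minima.csv"))

  itp_raw <- attr(minima, "interpolant")
  neb_surface <- if (cfg$neb$smoothing > 0)
    interpolate_pmf(fit$pmf, smoothing = cfg$neb$smoothing) else itp_raw

  pg <- run_stage("build_path_graph", build_path_graph(
    neb_surface, minima,
    neb_settings = cfg$neb[c("n_images", "spring_constant",
                             "max_iterations", "force_tolerance")]))
  note("build_path_graph: %d snippets, %d excluded",
       if (is.null(pg$edges)) 0L else nrow(pg$edges),
       if (is.null(pg$excluded)) 0L else nrow(pg$excluded))

  s_idx <- if (identical(cfg$path$start, "auto"))
    minima$index[which.max(minima$z1)] else as.integer(cfg$path$start)
  e_idx <- if (identical(cfg$path$end, "auto"))
    minima$index[which.min(minima$z1)] else as.integer(cfg$path$end)
  paths <- run_stage("enumerate_paths", enumerate_paths(
    pg, s_idx, e_idx, max_paths = cfg$path$max_paths,
    rerelax = cfg$path$rerelax))
  rk <- attr(paths, "ranking")
  note("enumerate_paths: %d candidate path(s), best via %s",
       length(paths), rk$via[1])
  for (i in seq_along(paths))
    write_path(paths[[i]], file.path(out, sprintf("path_%d.csv", i)))
  files <- c(files, paths = file.path(out, "path_1.csv"))

  profile <- run_stage("project_1d", {
    best <- path_energies(paths[[1]], itp_raw)
    project_1d(best, min_prominence = cfg$path$min_prominence)
  })
  nstate <- sum(profile$markers$kind == "valley")
  note("project_1d: %d states over %.2f nm", nstate, profile$length)
  utils::write.csv(
    data.frame(lambda = profile$lambda, F = profile$free_energy),
    file.path(out, "profile.csv"), row.names = FALSE, quote = FALSE)
  files <- c(files, profile = file.path(out, "profile.csv"))

  chain <- run_stage("build_chain", build_chain(
    profile, temperature = cfg$rates$temperature,
    fit_window = cfg$rates$fit_window,
    omega_convention = cfg$rates$omega_convention))
  rate <- run_stage("rates", tryCatch(
    total_rate(solve_chain(chain)),
    ionpmf_overflow_error = function(e) {
      warn <<- c(warn, paste("[rates]", conditionMessage(e)))
      rate_limiting_bound(chain)
    }))
  note("rates: total rate %s%.4g (friction-scaled)%s",
       if (rate$is_bound) "<= " else "", rate$rate,
       if (rate$is_bound) " [rate-limiting bound]" else "")

  fsteps <- chain$rates[chain$rates$to == chain$rates$from + 1L, ]
  barriers <- list(
    forward = fsteps[, c("from", "to", "barrier")],
    reentry_cyclic = barrier(profile, nstate, 1L))
  report_json <- list(
    n_windows = length(windows),
    states = profile$markers,
    forward_barriers = fsteps$barrier,
    reentry_barrier_cyclic = barriers$reentry_cyclic,
    rates = chain$rates,
    total_rate = rate$rate,
    log_total_rate = rate$log_rate,
    mfpt = rate$mfpt,
    rate_is_bound = rate$is_bound,
    omega_convention = chain$omega_convention,
    temperature = cfg$rates$temperature,
    warnings = warn)
  jsonlite::write_json(report_json, file.path(out, "rates.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null", dataframe = "rows")
  files <- c(files, rates = file.path(out, "rates.json"))
  if (length(warn)) note("warnings: %s", paste(warn, collapse = " | "))

  structure(list(wham = fit, minima = minima, path_graph = pg,
                 paths = paths, profile = profile, chain = chain,
                 rate = rate, rate_is_bound = rate$is_bound,
                 barriers = barriers, warnings = warn, config = cfg,
                 files = files),
            class = "ionpmf_report")
}

#' @export
print.ionpmf_report <- function(x, ...) {
  cat("<ionpmf_report>\n")
  cat(sprintf("  %d minima; best path via %s\n", nrow(x$minima),
              paste(x$paths[[1]]$via, collapse = ">")))
  cat(sprintf("  forward barriers (kJ/mol): %s\n",
              paste(sprintf("%.1f", x$barriers$forward$barrier),
                    collapse = ", ")))
  cat(sprintf("  cyclic re-entry barrier: %.1f kJ/mol\n",
              x$barriers$reentry_cyclic))
  cat(sprintf("  total rate: %s%.4g (friction-scaled)\n",
              if (x$rate_is_bound) "<= " else "", x$rate$rate))
  if (length(x$warnings))
    cat("  warnings:", length(x$warnings), "\n")
  invisible(x)
}
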