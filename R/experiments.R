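# Experiment presets, configuration, and result reporting.
#
# Presets hard-code the published hyperparameters of the four benchmark
# inverse problems (architectures, loss weights, bounds, learning-rate
# schedules, iteration counts, collocation sizes), so a full-scale run is
# one `scale = 1` away from the quick desk-scale defaults used in tests.

#' Experiment presets
#'
#' @return Character vector of available preset names.
#' @export
experiment_presets <- function() {
  c("cylinder", "plate", "cone", "valve-neohookean", "valve-leesacks")
}

#' Build an experiment configuration
#'
#' @param preset One of [experiment_presets()].
#' @param scale Scale factor applied to iterations, seed count and
#'   collocation sizes (see [scale_config()]); `scale = 1` reproduces the
#'   full published configuration.
#' @param seeds Optional explicit seed vector (overrides the scaled count).
#' @param out_dir Optional output directory for [run_experiment()].
#' @return An `experiment_config` list.
#' @export
experiment_config <- function(preset = experiment_presets(), scale = 1,
                              seeds = NULL, out_dir = NULL) {
  preset <- match.arg(preset)
  base <- switch(preset,
    cylinder = list(
      preset = "cylinder",
      geometry = list(r_inner = 1, r_outer = 5),
      pressure = 1e-5,
      truth = list(E = 0.135, nu = 0.3),
      bounds = list(E = c(0, 1), nu = c(0, 0.5)),
      widths = rep(45L, 5L),
      weights = c(pde = 1, mat = 10, trac = 1, data = 1),
      n_pde = 1500L, n_data = 1500L, n_boundary = 150L, n_outer = 150L,
      iterations = 100000L, n_seeds = 10L,
      lr0 = 1e-3, decay_rate = 0.15, decay_interval = 15000L),
    plate = list(
      preset = "plate",
      geometry = list(radius = 1, thickness = 0.1),
      pressure = 1,
      truth = list(E = 1, nu = 0.3),
      bounds = list(E = c(0, 2), nu = c(0, 0.5)),
      widths = rep(24L, 3L),
      weights = c(pde = 1, data = 1000),
      n_pde = 5000L, n_data = 5000L,
      iterations = 100000L, n_seeds = 10L,
      lr0 = 1e-3, decay_rate = 0.15, decay_interval = 15000L),
    cone = list(
      preset = "cone",
      geometry = list(height = 1, top_diameter = 2, bottom_diameter = 1,
                      wall_thickness = 0.1),
      pressure = 0.01,
      truth = list(E = 5, nu = 0.3),
      bounds = list(E = c(1.5, 7.5), nu = c(0, 0.5)),
      widths = c(32L, 16L, 8L),
      weights = c(pde = 1e-4, mat = 1e-4, data = 1),
      n_pde = 4096L,
      fe = list(n_r = 2L, n_theta = 24L, n_z = 10L),
      iterations = 250000L, n_seeds = 10L, freeze_frac = 0.3,
      lr0 = 1e-3, decay_rate = 0.66, decay_interval = 5000L),
    "valve-neohookean" = list(
      preset = "valve-neohookean",
      geometry = list(height = 10, top_diameter = 20, bottom_diameter = 10,
                      wall_thickness = 1),
      pressure = 0.0129,        # 97 mmHg in MPa
      rho = 1e-3, t_end = 2,
      truth = list(E = 0.52684, nu = 0.317),
      bounds = list(E = c(0, 0.8), nu = c(0, 0.5)),
      widths = c(32L, 16L, 8L),
      weights = c(pde = 10, mat = 10, data = 1),
      n_pde = 4096L,
      fe = list(n_r = 1L, n_theta = 16L, n_z = 6L, nsteps = 20L),
      iterations = 250000L, n_seeds = 10L, freeze_frac = 0.3,
      lr0 = 1e-3, decay_rate = 0.45, decay_interval = 15000L),
    "valve-leesacks" = list(
      preset = "valve-leesacks",
      geometry = list(height = 10, top_diameter = 20, bottom_diameter = 10,
                      wall_thickness = 1),
      pressure = 0.0129,
      rho = 1e-3, t_end = 2,
      truth = list(c0 = 0.16557, c1 = 0.01868, c2 = 2.09),
      bounds = list(c0 = c(0, 0.2), c1 = c(0, 0.2), c2 = c(0, 20)),
      widths = c(32L, 16L, 8L),
      weights = c(pde = 1e-3, mat = 1e-3, data = 1),
      n_pde = 4096L,
      fe = list(n_r = 1L, n_theta = 16L, n_z = 6L, nsteps = 20L),
      iterations = 250000L, n_seeds = 10L, freeze_frac = 0.3,
      lr0 = 1e-3, decay_rate = 0.62, decay_interval = 15000L))
  cfg <- structure(base, class = "experiment_config")
  cfg <- scale_config(cfg, scale)
  if (!is.null(seeds)) cfg$seeds <- seeds
  cfg$out_dir <- out_dir
  cfg
}

#' Scale an experiment configuration down (or up)
#'
#' Proportionally reduces iterations, number of seeds and collocation
#' counts; geometry, physics, bounds, weights and schedules are untouched.
#' The applied factor is recorded in the configuration.
#'
#' @param config An [experiment_config()].
#' @param factor Positive scale factor (1 = unchanged).
#' @return The scaled configuration.
#' @export
scale_config <- function(config, factor) {
  stopifnot(factor > 0)
  config$iterations <- max(1L, as.integer(round(config$iterations * factor)))
  config$n_seeds <- max(1L, as.integer(round(config$n_seeds * factor)))
  for (f in c("n_pde", "n_data", "n_boundary", "n_outer"))
    if (!is.null(config[[f]]))
      config[[f]] <- max(16L, as.integer(round(config[[f]] * factor)))
  config$seeds <- seq_len(config$n_seeds) - 1L
  config$scale <- if (is.null(config$scale)) factor else config$scale * factor
  config
}

#' Save / load an experiment configuration (YAML)
#'
#' @param config An [experiment_config()].
#' @param path File path (`.yaml`/`.yml` or `.json`).
#' @return `path` invisibly; `load_experiment_config` returns the config.
#' @export
save_experiment_config <- function(config, path) {
  obj <- unclass(config)
  # keep names on the weight vector through YAML/JSON (both serializers
  # drop names from atomic vectors)
  if (!is.null(obj$weights)) obj$weights <- as.list(obj$weights)
  if (grepl("\\.json$", path))
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         null = "null")
  else yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname save_experiment_config
#' @export
load_experiment_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  obj <- if (grepl("\\.json$", path)) jsonlite::read_json(path,
                                                          simplifyVector = TRUE)
  else yaml::read_yaml(path)
  for (f in c("widths", "seeds"))
    if (!is.null(obj[[f]])) obj[[f]] <- as.integer(unlist(obj[[f]]))
  for (f in c("weights"))
    if (!is.null(obj[[f]])) obj[[f]] <- unlist(obj[[f]])
  obj$bounds <- lapply(obj$bounds, unlist)
  structure(obj, class = "experiment_config")
}

# build the pinn problem (and any FE reference) for a configuration
build_problem <- function(config, seed = 0L) {
  gp <- config$geometry
  switch(config$preset,
    cylinder = {
      case <- cylinder_case(gp$r_inner, gp$r_outer, config$pressure,
                            elastic_params(config$truth$E, config$truth$nu))
      list(problem = pinn_cylinder_problem(
        case, config$n_pde, config$n_data, config$n_boundary,
        config$n_outer, config$widths, config$weights, config$bounds,
        seed = seed), case = case)
    },
    plate = {
      case <- plate_case(gp$radius, gp$thickness, config$pressure,
                         elastic_params(config$truth$E, config$truth$nu))
      list(problem = pinn_plate_problem(
        case, config$n_pde, config$n_data, config$widths, config$weights,
        config$bounds, seed = seed), case = case)
    },
    cone = {
      dom <- truncated_cone_shell(gp$height, gp$top_diameter,
                                  gp$bottom_diameter, gp$wall_thickness)
      ref <- cone_reference(dom,
                            elastic_params(config$truth$E, config$truth$nu),
                            config$pressure, config$fe$n_r,
                            config$fe$n_theta, config$fe$n_z)
      list(problem = pinn_cone_problem(
        dom, ref$reference, config$pressure,
        elastic_params(config$truth$E, config$truth$nu),
        config$n_pde, config$widths, config$weights, config$bounds,
        seed = seed), case = ref)
    },
    {
      dom <- truncated_cone_shell(gp$height, gp$top_diameter,
                                  gp$bottom_diameter, gp$wall_thickness)
      kind <- if (config$preset == "valve-neohookean") "neo-hookean"
              else "lee-sacks"
      if (kind == "lee-sacks")
        stop("the transient FE reference generator supports the ",
             "Neo-Hookean fixture; supply a reference field for Lee-Sacks")
      ref <- membrane_reference(dom,
                                elastic_params(config$truth$E,
                                               config$truth$nu),
                                config$pressure, config$rho, config$t_end,
                                config$fe$nsteps, config$fe$n_r,
                                config$fe$n_theta, config$fe$n_z)
      truth <- unlist(config$truth)
      list(problem = pinn_membrane_problem(
        dom, ref$reference, kind, config$pressure, config$rho,
        config$t_end, truth, config$n_pde, config$widths, config$weights,
        config$bounds, seed = seed), case = ref)
    })
}

#' Run a complete inverse experiment
#'
#' Generates (or solves for) the reference displacement data, trains the
#' inverse PINN over all seeds, verifies the recovered parameters with the
#' matching forward solution, and optionally writes the run directory
#' (resolved config, per-seed histories, summary JSON, report table).
#'
#' @param config An [experiment_config()].
#' @param verbose Print training progress.
#' @return A result bundle: list with `estimate` (a `param_estimate`),
#'   `report` (an `agreement_report`), `config`.
#' @export
run_experiment <- function(config, verbose = FALSE) {
  bp <- build_problem(config)
  tc <- train_config(iterations = config$iterations, seeds = config$seeds,
                     lr0 = config$lr0, decay_rate = config$decay_rate,
                     decay_interval = config$decay_interval,
                     freeze_material = round((config$freeze_frac %||% 0) *
                                               config$iterations))
  est <- train_inverse(bp$problem, tc, verbose = verbose)
  example <- switch(config$preset, cylinder = "cylinder", plate = "plate",
                    cone = "cone", "membrane")
  report <- verify_example(example, est, bp$case)
  bundle <- list(estimate = est, report = report, config = config)
  class(bundle) <- "experiment_result"
  if (!is.null(config$out_dir)) write_run_dir(bundle, config$out_dir)
  bundle
}

#' @export
print.experiment_result <- function(x, ...) {
  cat("== experiment:", x$config$preset,
      sprintf("(scale %.3g) ==\n", x$config$scale %||% 1))
  print(x$estimate)
  print(x$report)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_run_dir <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  save_experiment_config(bundle$config, file.path(dir, "config.yaml"))
  est <- bundle$estimate
  for (s in names(est$history))
    write.csv(est$history[[s]],
              file.path(dir, paste0("history_seed", s, ".csv")),
              row.names = FALSE)
  for (s in names(est$trajectory))
    write.csv(est$trajectory[[s]],
              file.path(dir, paste0("trajectory_seed", s, ".csv")),
              row.names = FALSE)
  summ <- list(per_seed = as.data.frame(est$per_seed),
               mean = as.list(est$mean), sd = as.list(est$sd),
               rel_error_pct = as.list(est$rel_error_pct),
               seeds = bundle$config$seeds,
               report = bundle$report[c("l2_pct", "msd", "hd95")])
  jsonlite::write_json(summ, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  write.csv(report_tables(list(bundle)), file.path(dir, "report.csv"),
            row.names = FALSE)
  invisible(dir)
}

#' Tabulate experiment results
#'
#' One row per experiment with `mean+/-sd` formatted parameter estimates,
#' relative errors, and verification metrics.
#'
#' @param bundles List of results from [run_experiment()].
#' @param path Optional CSV path to write.
#' @return A data.frame (invisibly also written to `path` if given).
#' @export
report_tables <- function(bundles, path = NULL) {
  rows <- lapply(bundles, function(b) {
    est <- b$estimate
    pm <- paste(sprintf("%s=%.4g±%.2g", colnames(est$per_seed),
                        est$mean, est$sd), collapse = "; ")
    re <- if (!is.null(est$rel_error_pct))
      paste(sprintf("%s:%.3g%%", names(est$rel_error_pct),
                    est$rel_error_pct), collapse = "; ") else ""
    l2 <- if (!is.null(b$report$l2_pct))
      paste(sprintf("%s:%.3g%%", names(b$report$l2_pct), b$report$l2_pct),
            collapse = "; ") else ""
    data.frame(preset = b$config$preset,
               scale = b$config$scale %||% 1,
               seeds = length(b$config$seeds),
               iterations = b$config$iterations,
               estimate = pm, rel_error = re, l2_error = l2,
               msd = b$report$msd %||% NA, hd95 = b$report$hd95 %||% NA,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(path)) write.csv(out, path, row.names = FALSE)
  if (length(bundles) == 0)
    out <- data.frame(preset = character(), scale = numeric(),
                      seeds = integer(), iterations = integer(),
                      estimate = character(), rel_error = character(),
                      l2_error = character(), msd = numeric(),
                      hd95 = numeric())
  out
}
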