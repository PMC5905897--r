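#' Parse a pipeline configuration file
#'
#' Reads a YAML run configuration, validates it and applies documented
#' defaults (solver fista, theta 0.01, epsilon_irls 0.005, lambda "auto",
#' flat 1% noise, seed 1). The returned object drives [run_pipeline()].
#'
#' Recognized keys: `output_dir` (required); `seed`; `phantom` (passed to
#' [phantom_spec()]; inclusions as a list of center/radius/delta entries);
#' `noise` (`mode`, `level`, `seed`); `solver` (`method`, `theta`,
#' `epsilon_irls`, `tol`, `max_inner_iter`); `lambda` (number or "auto");
#' `max_outer_iter`; `data_transform`; and optional input paths
#' `measurements`, `mesh_nodes`, `mesh_elements`, `optodes`, `links`,
#' `extinction` to reconstruct from files instead of simulating.
#'
#' @param path YAML file path.
#' @return an `scdot_config` list.
#' @export
parse_config <- function(path) {
  if (!file.exists(path)) stop_param("config file '%s' does not exist", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw$output_dir)) stop("validation error: missing required key 'output_dir'",
                                    call. = FALSE)
  defaults <- list(seed = 1L, lambda = "auto", max_outer_iter = 10L,
                   data_transform = "log")
  cfg <- modifyList(defaults, raw)
  sv <- cfg$solver %||% list()
  cfg$solver_settings <- solver_settings(
    method = sv$method %||% "fista",
    theta = sv$theta %||% 0.01,
    epsilon_irls = sv$epsilon_irls %||% 0.005,
    tol = sv$tol %||% 1e-6,
    max_inner_iter = sv$max_inner_iter)
  if (!is.null(cfg$noise)) {
    if (!is.null(cfg$noise$level) && cfg$noise$level < 0)
      stop("validation error: key 'noise.level' must be >= 0", call. = FALSE)
    cfg$noise_spec <- noise_spec(mode = cfg$noise$mode %||% "flat",
                                 level = cfg$noise$level %||% 0.01,
                                 seed = cfg$noise$seed %||% cfg$seed)
  }
  ph <- cfg$phantom %||% list()
  inclusions <- lapply(ph$inclusions %||% list(), function(i) {
    i$center <- as.numeric(i$center); i
  })
  cfg$phantom_spec <- phantom_spec(
    radius = ph$radius %||% 25,
    edge_length = ph$edge_length %||% 2.5,
    inclusions = inclusions,
    n_sources = ph$n_sources %||% 16,
    n_detectors = ph$n_detectors %||% 16,
    wavelengths = as.numeric(ph$wavelengths %||% c(750, 850)))
  if (identical(cfg$lambda, "auto")) {
    cfg$lambda_ladder <- NULL   # documented default ladder
  } else if (!is.numeric(cfg$lambda)) {
    stop("validation error: key 'lambda' must be a number or \"auto\"", call. = FALSE)
  }
  structure(cfg, class = "scdot_config")
}

#' Run the full simulate / L-curve / reconstruct / evaluate pipeline
#'
#' Simulates measurements from the configured phantom (or loads them from
#' the configured files), adds noise if requested, selects lambda by
#' L-curve if `lambda` is "auto", reconstructs, evaluates against the
#' ground truth when available, and writes all artifacts into
#' `output_dir`: `measurements.csv`, `lcurve.csv`, `reconstruction.csv`,
#' `metrics.yaml` and a `manifest.yaml` capturing settings, seed, the
#' chosen lambda and the iteration trace. Reruns with the same seed
#' reproduce the measurement file bit for bit.
#'
#' @param config an `scdot_config` from [parse_config()].
#' @return invisibly, a list with the reconstruction, metrics and artifact
#'   paths.
#' @export
run_pipeline <- function(config) {
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  table <- if (!is.null(config$extinction)) read_extinction_table(config$extinction)
           else default_extinction_table()
  set.seed(config$seed)
  if (!is.null(config$measurements)) {
    measured <- read_measurements(config$measurements)
    mesh <- read_mesh(config$mesh_nodes, config$mesh_elements)
    optodes <- read_optodes(config$optodes, config$links)
    phantom <- NULL
  } else {
    phantom <- make_phantom(config$phantom_spec)
    mesh <- phantom$mesh; optodes <- phantom$optodes
    measured <- simulate_experiment(phantom, table)
    if (!is.null(config$noise_spec)) measured <- add_noise(measured, config$noise_spec)
    write_measurements(measured, file.path(config$output_dir, "measurements.csv"))
    write_mesh(mesh, file.path(config$output_dir, "mesh_nodes.txt"),
               file.path(config$output_dir, "mesh_elements.txt"))
    write_optodes(optodes, file.path(config$output_dir, "optodes.csv"),
                  file.path(config$output_dir, "links.csv"))
  }
  bg <- config$phantom_spec$background[[1]]
  scatter_prior <- list(amplitude = bg$scatter_amplitude, power = bg$scatter_power)
  c0 <- c(bg$c1, bg$c2)
  settings <- recon_settings(solver = config$solver_settings,
                             lambda = config$lambda,
                             max_outer_iter = config$max_outer_iter,
                             c0 = c0, data_transform = config$data_transform)
  recon <- scdot_reconstruct(measured, mesh, optodes, table,
                             scatter_prior = scatter_prior, settings = settings,
                             truth = if (!is.null(phantom)) phantom$truth else NULL)
  # L-curve of the first linearized problem for the record (the chosen
  # lambda came from the identical scan inside the reconstruction)
  write_recon_result(recon, file.path(config$output_dir, "reconstruction.csv"))
  lcurve_path <- file.path(config$output_dir, "lcurve.csv")
  if (identical(config$lambda, "auto")) {
    curve <- first_iteration_lcurve(measured, mesh, optodes, table,
                                    scatter_prior, settings)
    write_lcurve(curve, lcurve_path)
  }
  metrics <- NULL
  if (!is.null(phantom)) {
    metrics <- recon_metrics(recon, phantom$truth)
    write_metrics(metrics, file.path(config$output_dir, "metrics.yaml"))
  }
  manifest <- list(seed = config$seed,
                   solver = config$solver_settings$method,
                   lambda = recon$lambda,
                   data_transform = config$data_transform,
                   outer_iterations = recon$iterations,
                   converged = recon$converged,
                   residual_trace = recon$residual_trace,
                   inner_iterations = recon$inner_iterations)
  yaml::write_yaml(manifest, file.path(config$output_dir, "manifest.yaml"))
  invisible(list(recon = recon, metrics = metrics,
                 artifacts = file.path(config$output_dir,
                                       c("measurements.csv", "lcurve.csv",
                                         "reconstruction.csv", "metrics.yaml",
                                         "manifest.yaml"))))
}

# the linearized update problem of the first Gauss-Newton iteration, used
# both for standalone L-curve scans and by the auto-lambda mode
first_iteration_problem <- function(measured, mesh, optodes, table,
                                    scatter_prior, settings) {
  n <- nrow(mesh$nodes)
  wl <- measured$wavelengths
  conc <- init_concentrations(settings$c0, n, length(table$chromophores),
                              table$chromophores)
  log_data <- settings$data_transform == "log"
  states <- lapply(wl, function(w) {
    fld <- optical_field(beer_law_mua(table, conc, w),
                         mie_musp(rep_len(scatter_prior$amplitude, n),
                                  rep_len(scatter_prior$power, n), w), w, n)
    forward_state(mesh, fld, optodes, settings$robin_A)
  })
  amp <- vapply(states, function(s) s$amplitudes, numeric(nrow(measured$links)))
  dphi <- if (log_data) as.numeric(log(measured$amplitudes) - log(amp))
          else as.numeric(measured$amplitudes - amp)
  sub <- lapply(seq_along(wl), function(i) {
    fld <- optical_field(beer_law_mua(table, conc, wl[i]),
                         mie_musp(rep_len(scatter_prior$amplitude, n),
                                  rep_len(scatter_prior$power, n), wl[i]), wl[i], n)
    Jw <- wavelength_jacobian(mesh, fld, optodes, settings$robin_A,
                              state = states[[i]])
    if (log_data) Jw / states[[i]]$amplitudes else Jw
  })
  update_problem(spectral_jacobian(sub, table, wl), dphi, 0)
}

first_iteration_lcurve <- function(measured, mesh, optodes, table,
                                   scatter_prior, settings) {
  pr <- first_iteration_problem(measured, mesh, optodes, table,
                                scatter_prior, settings)
  lcurve_scan(pr, settings$solver, ladder = settings$lambda_ladder)
}
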