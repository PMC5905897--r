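#' Data-model mismatch vector
#'
#' Concatenates the per-wavelength differences measured - computed into the
#' stacked data vector, first wavelength block first. Both sets must share
#' the link table and wavelengths.
#'
#' @param measured,computed `scdot_measurements` objects.
#' @return numeric vector of length n_wavelengths * n_links.
#' @export
data_mismatch <- function(measured, computed) {
  if (!identical(dim(measured$amplitudes), dim(computed$amplitudes)) ||
      !isTRUE(all.equal(measured$wavelengths, computed$wavelengths)) ||
      !identical(measured$links[c("source", "detector")],
                 computed$links[c("source", "detector")]))
    stop_dim("measured and computed sets must share link table and wavelengths")
  as.numeric(measured$amplitudes - computed$amplitudes)
}

#' Reference-phantom calibration of measured amplitudes
#'
#' Scales heterogeneous measurements by the ratio of modelled to measured
#' amplitudes of a homogeneous reference acquisition:
#' calibrated = het_measured * hom_modelled / hom_measured, per link and
#' wavelength. Per-link source/detector coupling gains cancel exactly in
#' the ratio.
#'
#' @param het_measured,hom_measured,hom_modelled `scdot_measurements`
#'   sharing link table and wavelengths; `hom_measured` strictly positive.
#' @return calibrated `scdot_measurements`.
#' @export
calibrate_measurements <- function(het_measured, hom_measured, hom_modelled) {
  if (!identical(dim(het_measured$amplitudes), dim(hom_measured$amplitudes)) ||
      !identical(dim(het_measured$amplitudes), dim(hom_modelled$amplitudes)))
    stop_dim("calibration inputs must share link table and wavelengths")
  if (any(hom_measured$amplitudes == 0))
    stop_numeric("homogeneous measurement contains zero amplitude")
  measurement_set(het_measured$links, het_measured$wavelengths,
                  het_measured$amplitudes * hom_modelled$amplitudes /
                    hom_measured$amplitudes)
}

#' Reconstruction settings
#'
#' @param solver an [solver_settings()].
#' @param lambda regularization weight: a number, or `"auto"` to choose it
#'   by L-curve corner detection on the first outer iteration.
#' @param lambda_ladder optional explicit ladder for the auto mode.
#' @param max_outer_iter maximum Gauss-Newton iterations (default 20).
#' @param outer_tol stopping tolerance on ||dphi_k - dphi_{k-1}||_1;
#'   `NULL` defaults to 1e-6 * ||measured||_1.
#' @param c0 initial concentrations: vector of per-chromophore homogeneous
#'   values (mM) or a full n_nodes x n_chromophores matrix.
#' @param data_transform `"log"` (default) fits log amplitudes, the usual
#'   Rytov-type choice for CW data whose amplitudes span decades across
#'   source-detector separations; `"raw"` fits plain amplitude differences.
#' @param robin_A Robin boundary coefficient.
#' @return an `scdot_recon_settings` list.
#' @export
recon_settings <- function(solver = solver_settings(), lambda = "auto",
                           lambda_ladder = NULL, max_outer_iter = 20,
                           outer_tol = NULL, c0 = NULL,
                           data_transform = c("log", "raw"),
                           robin_A = robin_coefficient()) {
  data_transform <- match.arg(data_transform)
  if (max_outer_iter < 1) stop_param("max_outer_iter must be >= 1")
  if (!identical(lambda, "auto") &&
      (!is.numeric(lambda) || length(lambda) != 1 || lambda < 0))
    stop_param("lambda must be a non-negative number or \"auto\"")
  if (!is.null(outer_tol) && outer_tol <= 0) stop_param("outer_tol must be positive")
  structure(list(solver = solver, lambda = lambda, lambda_ladder = lambda_ladder,
                 max_outer_iter = as.integer(max_outer_iter), outer_tol = outer_tol,
                 c0 = c0, data_transform = data_transform, robin_A = robin_A),
            class = "scdot_recon_settings")
}

#' Spectrally constrained reconstruction (Gauss-Newton outer loop)
#'
#' Fits per-node chromophore concentrations to multispectral boundary
#' measurements. Each outer iteration (i) maps the current concentrations
#' to per-wavelength absorption through Beer's law, with reduced scattering
#' fixed by the Mie prior, (ii) runs the FEM forward model per wavelength
#' and forms the stacked data mismatch, (iii) tests the stopping rule
#' ||dphi_k - dphi_{k-1}||_1 <= outer_tol, (iv) rebuilds the spectral
#' Jacobian by the adjoint method, and (v) solves the regularized update
#' problem with the configured solver and adds the update to the
#' concentrations. The IRLS and FISTA inner solvers take their Tikhonov
#' initialization only on the first outer iteration; later updates start
#' from zero. An update that increases the true data misfit is rejected and
#' the loop stops at the last accepted state, so the residual trace is
#' non-increasing over accepted iterations. For the forward evaluation mua
#' is floored at 1e-6 per mm, so transiently negative concentration
#' iterates cannot produce an unphysical (non-elliptic) diffusion system.
#'
#' @param measured an `scdot_measurements` (strictly positive amplitudes).
#' @param mesh an `scdot_mesh`.
#' @param optodes an `scdot_optodes` matching the measurement link table.
#' @param table an `scdot_extinction` covering the measured wavelengths.
#' @param scatter_prior list with `amplitude` and `power` (scalars or
#'   per-node vectors); held fixed throughout.
#' @param settings an [recon_settings()].
#' @param truth optional ground-truth `scdot_chromophores` carried along
#'   for later evaluation.
#' @return an object of class `scdot_recon`; see [coef.scdot_recon()],
#'   [residuals.scdot_recon()], [fitted.scdot_recon()],
#'   [summary.scdot_recon()], [plot.scdot_recon()].
#' @export
scdot_reconstruct <- function(measured, mesh, optodes, table,
                              scatter_prior = list(amplitude = 1, power = 1),
                              settings = recon_settings(), truth = NULL) {
  if (any(measured$amplitudes <= 0)) stop_param("measured amplitudes must be strictly positive")
  wl <- measured$wavelengths
  n <- nrow(mesh$nodes)
  nc <- length(table$chromophores)
  musp_by_wl <- lapply(wl, function(w)
    mie_musp(rep_len(scatter_prior$amplitude, n), rep_len(scatter_prior$power, n), w))
  conc <- init_concentrations(settings$c0, n, nc, table$chromophores)
  conc0 <- conc
  log_data <- settings$data_transform == "log"
  meas_vec <- if (log_data) as.numeric(log(measured$amplitudes)) else as.numeric(measured$amplitudes)
  outer_tol <- if (is.null(settings$outer_tol)) 1e-6 * sum(abs(meas_vec)) else settings$outer_tol
  lambda <- settings$lambda
  delta_trace <- list()
  residual_trace <- numeric(0)
  inner_trace <- integer(0)
  dphi_prev <- NULL
  dphi <- NULL
  init <- NULL
  fitted_amp <- NULL
  converged <- FALSE
  k_done <- 0
  rejected_step <- FALSE
  conc_prev <- conc
  for (k in seq_len(settings$max_outer_iter)) {
    states <- lapply(seq_along(wl), function(i) {
      fld <- optical_field(pmax(beer_law_mua(table, conc, wl[i]), 1e-6), musp_by_wl[[i]], wl[i], n)
      forward_state(mesh, fld, optodes, settings$robin_A)
    })
    fitted_amp <- vapply(states, function(s) s$amplitudes, numeric(nrow(measured$links)))
    if (any(fitted_amp <= 0) && k == 1)
      stop_numeric("forward model produced non-positive amplitudes at the initial state")
    comp_vec <- if (log_data) as.numeric(log(fitted_amp)) else as.numeric(fitted_amp)
    dphi <- meas_vec - comp_vec
    k_done <- k
    # step control: a Gauss-Newton update that increased the true misfit --
    # or produced an unphysical state (non-positive modelled amplitude) --
    # is rejected and the iteration stops at the last accepted state
    if (k >= 2 && (anyNA(dphi) ||
                   sqrt(sum(dphi^2)) > residual_trace[length(residual_trace)])) {
      conc <- conc_prev
      dphi <- dphi_prev
      fitted_amp <- fitted_prev
      delta_trace[[length(delta_trace)]] <- NULL
      inner_trace <- inner_trace[-length(inner_trace)]
      k_done <- k - 1
      rejected_step <- TRUE
      break
    }
    fitted_prev <- fitted_amp
    residual_trace <- c(residual_trace, sqrt(sum(dphi^2)))
    if (k >= 2 && sum(abs(dphi - dphi_prev)) <= outer_tol) { converged <- TRUE; break }
    dphi_prev <- dphi
    sub <- lapply(seq_along(wl), function(i) {
      fld <- optical_field(pmax(beer_law_mua(table, conc, wl[i]), 1e-6), musp_by_wl[[i]], wl[i], n)
      Jw <- wavelength_jacobian(mesh, fld, optodes, settings$robin_A, state = states[[i]])
      if (log_data) Jw / states[[i]]$amplitudes else Jw
    })
    J <- spectral_jacobian(sub, table, wl)
    if (identical(lambda, "auto")) {
      pr0 <- update_problem(J, dphi, 0)
      curve <- lcurve_scan(pr0, settings$solver, ladder = settings$lambda_ladder)
      lambda <- as.numeric(lcurve_corner(curve))
    }
    problem <- update_problem(J, dphi, lambda)
    sol <- solve_update(problem, settings$solver, init = init)
    # the Tikhonov initialization is only needed on the first outer
    # iteration; afterwards the remaining mismatch is small and the natural
    # starting point for the next update is zero
    init <- numeric(length(sol$delta_c))
    dc <- matrix(sol$delta_c, n, nc, dimnames = list(NULL, table$chromophores))
    conc_prev <- conc
    conc <- conc + dc
    delta_trace[[length(delta_trace) + 1L]] <- dc
    inner_trace <- c(inner_trace, sol$iterations_used)
  }
  structure(list(concentrations = conc, initial = conc0,
                 chromophores = table$chromophores,
                 delta_trace = delta_trace, residual_trace = residual_trace,
                 inner_iterations = inner_trace, lambda = lambda,
                 settings = settings, mesh = mesh, optodes = optodes,
                 measured = measured, fitted_amplitudes = fitted_amp,
                 dphi = dphi, iterations = k_done, converged = converged,
                 rejected_step = rejected_step, truth = truth),
            class = "scdot_recon")
}

init_concentrations <- function(c0, n, nc, chromophores) {
  if (is.null(c0)) stop_param("initial concentrations c0 are required")
  conc <- if (is.matrix(c0)) c0 else matrix(rep(c0, each = n), n, nc)
  if (nrow(conc) != n || ncol(conc) != nc)
    stop_dim("c0 must give one value per chromophore (or per node and chromophore)")
  colnames(conc) <- chromophores
  conc
}

#' @export
print.scdot_recon <- function(x, ...) {
  cat(sprintf("scdot reconstruction (%s, lambda = %.4g)\n",
              x$settings$solver$method, x$lambda))
  cat(sprintf("  %d outer iteration(s), %sconverged; final ||dphi||_2 = %.4g\n",
              x$iterations, if (x$converged) "" else "not ",
              x$residual_trace[length(x$residual_trace)]))
  cat(sprintf("  %d nodes x %d chromophores (%s)\n", nrow(x$concentrations),
              ncol(x$concentrations), paste(x$chromophores, collapse = ", ")))
  invisible(x)
}

#' Reconstruction accessors
#'
#' `coef` returns the final per-node concentration matrix; `residuals` the
#' final data mismatch vector; `fitted` the modelled measurement set of the
#' final iteration; `delta` (via `summary`) the total recovered change.
#'
#' @param object an `scdot_recon`.
#' @param ... unused.
#' @export
coef.scdot_recon <- function(object, ...) object$concentrations

#' @rdname coef.scdot_recon
#' @export
residuals.scdot_recon <- function(object, ...) object$dphi

#' @rdname coef.scdot_recon
#' @export
fitted.scdot_recon <- function(object, ...) {
  measurement_set(object$measured$links, object$measured$wavelengths,
                  object$fitted_amplitudes)
}

#' @rdname coef.scdot_recon
#' @export
summary.scdot_recon <- function(object, ...) {
  delta <- object$concentrations - object$initial
  out <- list(method = object$settings$solver$method, lambda = object$lambda,
              iterations = object$iterations, converged = object$converged,
              residual_trace = object$residual_trace,
              delta_range = apply(delta, 2, range),
              metrics = if (!is.null(object$truth))
                recon_metrics(object, object$truth) else NULL)
  class(out) <- "summary.scdot_recon"
  out
}

#' @export
print.summary.scdot_recon <- function(x, ...) {
  cat(sprintf("scdot reconstruction summary (%s, lambda = %.4g)\n", x$method, x$lambda))
  cat(sprintf("  outer iterations: %d (%sconverged)\n", x$iterations,
              if (x$converged) "" else "not "))
  cat("  residual trace: ", paste(signif(x$residual_trace, 4), collapse = " "), "\n")
  cat("  recovered change range per chromophore:\n")
  print(signif(x$delta_range, 4))
  if (!is.null(x$metrics)) { cat("  image-quality metrics:\n"); print(x$metrics) }
  invisible(x)
}

#' Plot a reconstruction
#'
#' `type = "trace"` plots the residual norm per outer iteration;
#' `type = "map"` draws the recovered concentration change at the mesh
#' nodes, color-coded.
#'
#' @param x an `scdot_recon`.
#' @param type `"trace"` or `"map"`.
#' @param chromophore column index or name for the map.
#' @param ... passed to the base plotting functions.
#' @export
plot.scdot_recon <- function(x, type = c("trace", "map"), chromophore = 1, ...) {
  type <- match.arg(type)
  if (type == "trace") {
    plot(seq_along(x$residual_trace), x$residual_trace, type = "b",
         xlab = "outer iteration", ylab = "||dphi||_2", log = "y", ...)
  } else {
    delta <- (x$concentrations - x$initial)[, chromophore]
    pal <- hcl.colors(64, "viridis")
    col <- pal[pmin(64, pmax(1, findInterval(delta, seq(min(delta), max(delta),
                                                        length.out = 65),
                                             all.inside = TRUE)))]
    plot(x$mesh$nodes[, 1], x$mesh$nodes[, 2], col = col, pch = 19, asp = 1,
         xlab = "x (mm)", ylab = "y (mm)",
         main = sprintf("recovered change, %s", colnames(x$concentrations)[chromophore]),
         ...)
  }
  invisible(x)
}

#' Write reconstruction results as CSV
#'
#' One row per node: `node_index, <chromophore columns>, delta_<columns>`.
#'
#' @param recon an `scdot_recon`.
#' @param path file path.
#' @export
write_recon_result <- function(recon, path) {
  delta <- recon$concentrations - recon$initial
  out <- data.frame(node_index = seq_len(nrow(recon$concentrations)))
  for (j in seq_along(recon$chromophores))
    out[[recon$chromophores[j]]] <- recon$concentrations[, j]
  for (j in seq_along(recon$chromophores))
    out[[paste0("delta_", recon$chromophores[j])]] <- delta[, j]
  write.csv(out, path, row.names = FALSE)
  invisible(recon)
}
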