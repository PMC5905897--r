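#' Default regularization ladder
#'
#' Geometric ladder of lambda values, descending from `lambda_max` by a
#' fixed factor. The default top of the ladder is ||J^T dphi||_inf: under
#' the implemented proximal-gradient convention this is the smallest lambda
#' for which the L1 solution is identically zero, so the scan starts exactly
#' at the all-zero end of the L-curve.
#'
#' @param problem an [update_problem()] (used for the default
#'   `lambda_max`).
#' @param n_points number of ladder points (default 25).
#' @param factor fixed decrease factor between consecutive points (default
#'   10^0.25).
#' @param lambda_max optional explicit ladder top.
#' @return numeric vector, strictly decreasing.
#' @export
lcurve_ladder <- function(problem, n_points = 25, factor = 10^0.25,
                          lambda_max = NULL) {
  if (n_points < 5) stop_param("ladder needs at least 5 points")
  if (factor <= 1) stop_param("ladder factor must exceed 1")
  if (is.null(lambda_max))
    lambda_max <- max(abs(crossprod(problem$J, problem$dphi)))
  if (lambda_max <= 0) stop_param("lambda_max must be positive")
  lambda_max / factor^(seq_len(n_points) - 1)
}

#' L-curve scan over a regularization ladder
#'
#' Solves the update problem once per ladder value with the configured
#' solver, warm-starting each run from the previous solution, and records
#' the data misfit ||dphi - J dc||_2^2 against the regularizer (||dc||_1 for
#' the L1 solvers, ||dc||_2^2 for Tikhonov). Solver failures at individual
#' ladder points are recorded as missing and the scan continues. The scan is
#' intended to be run on the linearized problem of the first outer
#' Gauss-Newton iteration only, and the chosen lambda reused afterwards.
#'
#' @param problem an [update_problem()]; its `lambda` field is ignored.
#' @param settings an [solver_settings()] selecting the solver.
#' @param ladder descending lambda values (default [lcurve_ladder()]).
#' @return an `scdot_lcurve`: data frame of `lambda`, `residual`,
#'   `regularizer`, `curvature` plus the solver method.
#' @export
lcurve_scan <- function(problem, settings = solver_settings(), ladder = NULL) {
  if (is.null(ladder)) ladder <- lcurve_ladder(problem)
  if (length(ladder) < 5) stop_param("ladder needs at least 5 points")
  if (any(diff(ladder) >= 0)) stop_param("ladder must be strictly decreasing")
  J <- problem$J
  res <- reg <- rep(NA_real_, length(ladder))
  init <- NULL
  for (i in seq_along(ladder)) {
    pr <- update_problem(J, problem$dphi, ladder[i])
    sol <- tryCatch(solve_update(pr, settings, init = init),
                    error = function(err) NULL)
    if (is.null(sol)) next
    dc <- sol$delta_c
    init <- dc
    res[i] <- sum((problem$dphi - J %*% dc)^2)
    reg[i] <- if (settings$method == "tikhonov") sum(dc^2) else sum(abs(dc))
  }
  curve <- data.frame(lambda = ladder, residual = res, regularizer = reg)
  curve$curvature <- lcurve_curvature(curve)
  structure(list(points = curve, method = settings$method),
            class = "scdot_lcurve")
}

# finite-difference curvature of the (log10 residual, log10 regularizer)
# polyline parametrized by ladder index; endpoints and non-finite points are
# NA. Sign convention: the elbow of a descending-lambda L-curve is positive.
lcurve_curvature <- function(curve) {
  x <- log10(curve$residual)
  y <- log10(curve$regularizer)
  n <- length(x)
  kappa <- rep(NA_real_, n)
  ok <- is.finite(x) & is.finite(y)
  seg_floor <- 1e-6   # coincident points (stalled solver) give no direction
  for (i in seq_len(n)[-c(1, n)]) {
    if (!all(ok[(i - 1):(i + 1)])) next
    d1 <- sqrt((x[i] - x[i - 1])^2 + (y[i] - y[i - 1])^2)
    d2 <- sqrt((x[i + 1] - x[i])^2 + (y[i + 1] - y[i])^2)
    if (d1 < seg_floor || d2 < seg_floor) next
    xp <- (x[i + 1] - x[i - 1]) / 2
    yp <- (y[i + 1] - y[i - 1]) / 2
    xpp <- x[i + 1] - 2 * x[i] + x[i - 1]
    ypp <- y[i + 1] - 2 * y[i] + y[i - 1]
    denom <- (xp^2 + yp^2)^1.5
    if (denom > 0) kappa[i] <- (yp * xpp - xp * ypp) / denom
  }
  kappa
}

#' L-curve corner (maximum curvature)
#'
#' Returns the ladder value at the point of maximum finite-difference
#' curvature of the log-log L-curve — the "elbow" balancing data misfit
#' against regularization. An optional window restricts the search to a
#' lambda range, supporting manual refinement around the automatic corner.
#' Ties are broken toward larger lambda. If no interior point has positive
#' curvature the curve has no usable elbow and an error is raised.
#'
#' @param curve an `scdot_lcurve` from [lcurve_scan()].
#' @param window optional `c(min, max)` lambda range.
#' @return the selected lambda, with the ladder index in `attr(, "index")`.
#' @export
lcurve_corner <- function(curve, window = NULL) {
  pts <- curve$points
  if (sum(is.finite(pts$residual) & is.finite(pts$regularizer)) < 5)
    stop_param("corner detection needs at least 5 valid L-curve points")
  kappa <- pts$curvature
  if (!is.null(window)) {
    kappa[pts$lambda < min(window) | pts$lambda > max(window)] <- NA_real_
  }
  if (all(is.na(kappa)) || max(kappa, na.rm = TRUE) <= 0)
    stop("no corner: L-curve has no point of positive curvature",
         call. = FALSE)
  idx <- which.max(kappa)   # ladder is descending: first max = largest lambda
  structure(pts$lambda[idx], index = idx)
}

#' @export
print.scdot_lcurve <- function(x, ...) {
  ok <- sum(is.finite(x$points$residual))
  cat(sprintf("scdot L-curve (%s): %d/%d valid points, lambda in [%.3g, %.3g]\n",
              x$method, ok, nrow(x$points),
              min(x$points$lambda), max(x$points$lambda)))
  invisible(x)
}

#' @export
plot.scdot_lcurve <- function(x, ...) {
  pts <- x$points
  plot(pts$residual, pts$regularizer, log = "xy", type = "b",
       xlab = "data misfit ||dphi - J dc||^2",
       ylab = if (x$method == "tikhonov") "||dc||_2^2" else "||dc||_1",
       main = sprintf("L-curve (%s)", x$method), ...)
  corner <- tryCatch(lcurve_corner(x), error = function(err) NULL)
  if (!is.null(corner)) {
    i <- attr(corner, "index")
    points(pts$residual[i], pts$regularizer[i], pch = 19, col = "red")
  }
  invisible(x)
}

#' Write an L-curve as CSV
#'
#' Columns `lambda, residual, regularizer, curvature`.
#'
#' @param curve an `scdot_lcurve`.
#' @param path file path.
#' @export
write_lcurve <- function(curve, path) {
  write.csv(curve$points, path, row.names = FALSE)
  invisible(curve)
}
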