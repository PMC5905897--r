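#' Regularized update problem
#'
#' The linearized inverse problem of one Gauss-Newton iteration: find the
#' concentration update dc minimizing the data misfit ||dphi - J dc||_2^2
#' plus a regularization term weighted by `lambda`.
#'
#' A note on conventions: the solver update equations are implemented
#' exactly in their published forms, and all three L1 solvers then share the
#' same effective regularization. The ADMM and FISTA updates use the
#' half-squared data term (their gradient is J^T (J dc - dphi), without the
#' factor 2), and the IRLS weights w = |dc|^(-1/2) give the quadratic
#' penalty lambda sum(dc^2 / |dc_prev|), whose fixed point satisfies the
#' stationarity condition of an L1 penalty of weight 2 lambda (the gradient
#' of x^2/|x| at the fixed point is 2 sign(x)). Relative to the objective
#' ||dphi - J dc||_2^2 + lambda_eff ||dc||_1 the effective L1 weight is
#' therefore `2 * lambda` for IRLS, ADMM and FISTA alike. Each solver
#' result records its `lambda_eff`; in practice lambda is tuned per solver
#' with the L-curve anyway.
#'
#' @param J the Jacobian: an `scdot_spectral_jacobian` or a plain matrix.
#' @param dphi data-model mismatch vector; length must equal `nrow(J)`.
#' @param lambda_reg regularization weight, >= 0.
#' @return an `scdot_problem` list.
#' @export
update_problem <- function(J, dphi, lambda_reg) {
  Jm <- as_jacobian_matrix(J)
  dphi <- as.numeric(dphi)
  if (nrow(Jm) != length(dphi)) stop_dim("nrow(J) must equal length(dphi)")
  if (!is.numeric(lambda_reg) || length(lambda_reg) != 1 || lambda_reg < 0)
    stop_param("lambda_reg must be a single non-negative number")
  structure(list(J = Jm, dphi = dphi, lambda = lambda_reg),
            class = "scdot_problem")
}

#' Solver settings
#'
#' @param method one of `"tikhonov"`, `"irls"`, `"admm"`, `"fista"`.
#' @param epsilon_irls IRLS weight floor, in (0, 1). A fixed value in
#'   0.001-0.01 is adequate; default 0.005.
#' @param theta ADMM penalty parameter, > 0; default 0.01 (chosen for fast
#'   convergence in this application).
#' @param step_t FISTA step size; `NULL` (default) estimates it from the
#'   Lipschitz constant via [estimate_step()].
#' @param max_inner_iter inner iteration cap; default 200 (20 for IRLS,
#'   which converges in a few reweightings).
#' @param tol inner stopping tolerance on the change in the update vector.
#' @param backtracking enable FISTA backtracking line search (halve the step
#'   until the quadratic majorization of the smooth term holds).
#' @param safety FISTA step safety factor: t = safety / L.
#' @return an `scdot_solver_settings` list.
#' @export
solver_settings <- function(method = c("fista", "tikhonov", "irls", "admm"),
                            epsilon_irls = 0.005, theta = 0.01,
                            step_t = NULL, max_inner_iter = NULL,
                            tol = 1e-6, backtracking = TRUE, safety = 0.9) {
  method <- match.arg(method)
  if (epsilon_irls <= 0 || epsilon_irls >= 1) stop_param("epsilon_irls must be in (0, 1)")
  if (theta <= 0) stop_param("theta must be positive")
  if (tol <= 0) stop_param("tol must be positive")
  if (is.null(max_inner_iter)) max_inner_iter <- if (method == "irls") 20L else 200L
  structure(list(method = method, epsilon_irls = epsilon_irls, theta = theta,
                 step_t = step_t, max_inner_iter = as.integer(max_inner_iter),
                 tol = tol, backtracking = isTRUE(backtracking), safety = safety),
            class = "scdot_solver_settings")
}

solver_result <- function(delta_c, objective_trace, converged, extra = list()) {
  structure(c(list(delta_c = as.numeric(delta_c),
                   objective_trace = objective_trace,
                   iterations_used = length(objective_trace),
                   converged = converged), extra),
            class = "scdot_solver_result")
}

#' @export
print.scdot_solver_result <- function(x, ...) {
  cat(sprintf("scdot solver result: %d unknowns, %d inner iterations, %sconverged\n",
              length(x$delta_c), x$iterations_used, if (x$converged) "" else "NOT "))
  invisible(x)
}

# objective in the printed L1 convention of each solver (see update_problem)
l1_objective <- function(problem, x, lambda_eff) {
  r <- problem$dphi - problem$J %*% x
  sum(r^2) + lambda_eff * sum(abs(x))
}

# direct solve of (A + d I / diag) systems with Cholesky; contract is the
# residual tolerance, not the method
solve_spd <- function(A, b, context = "regularized normal equations") {
  ch <- tryCatch(chol(A), error = function(err) NULL)
  if (is.null(ch)) stop_numeric("singular system in %s", context)
  backsolve(ch, forwardsolve(t(ch), b))
}

#' Tikhonov (L2) update
#'
#' Solves the L2-regularized normal equations
#' (J^T J + lambda I) dc = J^T dphi directly.
#'
#' @param problem an [update_problem()].
#' @return an `scdot_solver_result`.
#' @export
tikhonov_update <- function(problem) {
  J <- problem$J; lam <- problem$lambda
  if (all(problem$dphi == 0))
    return(solver_result(numeric(ncol(J)), numeric(0), TRUE, list(lambda_eff = lam)))
  A <- crossprod(J)
  diag(A) <- diag(A) + lam
  dc <- drop(solve_spd(A, drop(crossprod(J, problem$dphi)),
                       "Tikhonov update (lambda may be too small)"))
  obj <- sum((problem$dphi - J %*% dc)^2) + lam * sum(dc^2)
  solver_result(dc, obj, TRUE, list(lambda_eff = lam))
}

#' IRLS diagonal weights
#'
#' w_s = |dc_s|^(-1/2) when |dc_s| >= epsilon, else 1/epsilon. The squared
#' weights turn the quadratic penalty ||W dc||_2^2 into an approximation of
#' the L1 norm at the previous iterate.
#'
#' @param delta_c current update vector.
#' @param epsilon_irls weight floor, in (0, 1).
#' @return vector of positive weights (all <= 1/epsilon).
#' @export
irls_weights <- function(delta_c, epsilon_irls) {
  if (epsilon_irls <= 0 || epsilon_irls >= 1) stop_param("epsilon_irls must be in (0, 1)")
  a <- abs(delta_c)
  ifelse(a >= epsilon_irls, a^(-0.5), 1 / epsilon_irls)
}

#' Iteratively reweighted least squares for the L1 update
#'
#' Initializes with the Tikhonov solution, then alternates weight updates
#' with solves of the weighted normal equations
#' (J^T J + lambda W^T W) dc = J^T dphi until the L1 change in dc drops
#' below `tol`. With all weights equal to 1 a single iteration reproduces
#' the Tikhonov update exactly.
#'
#' @param problem an [update_problem()].
#' @param settings an [solver_settings()]; uses `epsilon_irls`,
#'   `max_inner_iter`, `tol`.
#' @param init optional warm-start update vector (replaces the Tikhonov
#'   initialization).
#' @param unit_weights force w = 1 (reduces to Tikhonov; used for testing
#'   the published equivalence).
#' @return an `scdot_solver_result` with `lambda_eff = 2 * lambda` (see [update_problem()] on conventions).
#' @export
irls_solve <- function(problem, settings = solver_settings("irls"),
                       init = NULL, unit_weights = FALSE) {
  J <- problem$J; lam <- problem$lambda
  p <- ncol(J)
  if (all(problem$dphi == 0))
    return(solver_result(numeric(p), numeric(0), TRUE, list(lambda_eff = 2 * lam)))
  JtJ <- crossprod(J)
  Jtd <- drop(crossprod(J, problem$dphi))
  dc <- if (is.null(init)) drop(tikhonov_update(problem)$delta_c) else as.numeric(init)
  obj <- numeric(0)
  converged <- FALSE
  for (i in seq_len(settings$max_inner_iter)) {
    w <- if (unit_weights) rep(1, p) else irls_weights(dc, settings$epsilon_irls)
    A <- JtJ
    diag(A) <- diag(A) + lam * w^2
    dc_new <- drop(solve_spd(A, Jtd, "IRLS weighted normal equations"))
    obj <- c(obj, l1_objective(problem, dc_new, 2 * lam))
    if (sum(abs(dc_new - dc)) <= settings$tol) {
      dc <- dc_new; converged <- TRUE; break
    }
    dc <- dc_new
  }
  solver_result(dc, obj, converged, list(lambda_eff = 2 * lam))
}

#' Soft thresholding (L1 proximal operator)
#'
#' sign(x) * max(|x| - tau, 0), componentwise; entries with |x| <= tau are
#' set exactly to zero.
#'
#' @param x numeric vector.
#' @param tau threshold, >= 0.
#' @export
soft_threshold <- function(x, tau) {
  if (length(tau) != 1 || !is.finite(tau) || tau < 0)
    stop_param("threshold tau must be a single non-negative number")
  sign(x) * pmax(abs(x) - tau, 0)
}

#' ADMM for the L1 update
#'
#' Alternating direction method of multipliers with splitting variable v and
#' scaled multiplier b, initialized at v = b = 0: the dc step solves
#' (J^T J + theta I) dc = J^T dphi + theta (v - b) (factorized once), the v
#' step is soft thresholding with threshold lambda / theta, and
#' b <- b + dc - v. Stops when the L1 change in dc drops below `tol`; the
#' primal splitting gap ||dc - v|| is reported as a convergence diagnostic.
#'
#' @param problem an [update_problem()].
#' @param settings an [solver_settings()]; uses `theta`, `max_inner_iter`,
#'   `tol`.
#' @param init optional warm-start value for v.
#' @return an `scdot_solver_result` with `lambda_eff = 2 * lambda` (see
#'   [update_problem()] on conventions) and `splitting_gap`.
#' @export
admm_solve <- function(problem, settings = solver_settings("admm"), init = NULL) {
  J <- problem$J; lam <- problem$lambda; theta <- settings$theta
  p <- ncol(J)
  if (all(problem$dphi == 0))
    return(solver_result(numeric(p), numeric(0), TRUE,
                         list(lambda_eff = 2 * lam, splitting_gap = 0)))
  A <- crossprod(J)
  diag(A) <- diag(A) + theta
  ch <- tryCatch(chol(A), error = function(err)
    stop_numeric("singular system in ADMM dc step"))
  Jtd <- drop(crossprod(J, problem$dphi))
  v <- if (is.null(init)) numeric(p) else as.numeric(init)
  b <- numeric(p)
  dc <- numeric(p)
  obj <- numeric(settings$max_inner_iter)
  converged <- FALSE
  for (i in seq_len(settings$max_inner_iter)) {
    dc_new <- drop(backsolve(ch, forwardsolve(t(ch), Jtd + theta * (v - b))))
    v <- soft_threshold(dc_new + b, lam / theta)
    b <- b + dc_new - v
    obj[i] <- l1_objective(problem, v, 2 * lam)
    if (i > 1 && sum(abs(dc_new - dc)) <= settings$tol) {
      dc <- dc_new; obj <- obj[seq_len(i)]; converged <- TRUE; break
    }
    dc <- dc_new
    if (i == settings$max_inner_iter) obj <- obj[seq_len(i)]
  }
  # report the sparse splitting variable: it carries the exact zeros and at
  # convergence coincides with dc
  solver_result(v, obj, converged,
                list(lambda_eff = 2 * lam, splitting_gap = sqrt(sum((dc - v)^2))))
}

#' Estimate the FISTA step from the Lipschitz constant
#'
#' Estimates L = largest eigenvalue of J^T J by power iteration (relative
#' tolerance `tol`) and returns t = safety / L with safety < 1, as required
#' for convergence of the proximal gradient iteration with gradient
#' J^T (J x - dphi).
#'
#' @param J matrix (or spectral Jacobian).
#' @param safety step safety factor in (0, 1).
#' @param tol relative tolerance of the power iteration.
#' @param max_iter power iteration cap.
#' @return step size t, with the estimated Lipschitz constant in
#'   `attr(, "L")`.
#' @export
estimate_step <- function(J, safety = 0.9, tol = 1e-4, max_iter = 500) {
  J <- as_jacobian_matrix(J)
  if (length(J) == 0 || all(J == 0)) stop_param("cannot estimate a step for a zero matrix")
  if (safety <= 0 || safety >= 1) stop_param("safety must be in (0, 1)")
  p <- ncol(J)
  v <- rep(1 / sqrt(p), p)
  # deterministic start; perturb if unluckily orthogonal to the top eigenvector
  L_old <- 0
  for (i in seq_len(max_iter)) {
    w <- drop(crossprod(J, J %*% v))
    L <- sqrt(sum(w^2))
    if (L == 0) { v <- seq_len(p) / p; v <- v / sqrt(sum(v^2)); next }
    v <- w / L
    if (abs(L - L_old) <= tol * L) break
    L_old <- L
  }
  structure(safety / L, L = L)
}

#' FISTA for the L1 update
#'
#' Fast iterative shrinkage-thresholding: proximal gradient steps on the
#' extrapolated point y with gradient J^T (J y - dphi) and threshold
#' t * lambda, plus Nesterov momentum
#' alpha_i = (1 + sqrt(1 + 4 alpha_{i-1}^2)) / 2,
#' y_{i+1} = dc_i + ((alpha_{i-1} - 1) / alpha_i) (dc_i - dc_{i-1}),
#' initialized from the Tikhonov solution with alpha_0 = 1. The step is
#' t = safety / L by default; with `backtracking = TRUE` the step is halved
#' until the quadratic majorization of the smooth term holds at the accepted
#' point. Stops when the relative change
#' ||dc_i - dc_{i-1}||_2 / max(||dc_{i-1}||_2, floor) falls below `tol`
#' (the published stopping rule leaves "relative residual" undefined; this
#' relative-change rule is the documented choice).
#'
#' @param problem an [update_problem()].
#' @param settings an [solver_settings()]; uses `step_t`, `max_inner_iter`,
#'   `tol`, `backtracking`, `safety`.
#' @param init optional warm-start update vector (replaces the Tikhonov
#'   initialization).
#' @param momentum set `FALSE` for plain ISTA (monotone descent).
#' @return an `scdot_solver_result` with `lambda_eff = 2 * lambda` and the
#'   step actually used in `step_t`.
#' @export
fista_solve <- function(problem, settings = solver_settings("fista"),
                        init = NULL, momentum = TRUE) {
  J <- problem$J; lam <- problem$lambda
  p <- ncol(J)
  if (all(problem$dphi == 0))
    return(solver_result(numeric(p), numeric(0), TRUE,
                         list(lambda_eff = 2 * lam, step_t = NA_real_)))
  st <- estimate_step(J, safety = settings$safety)
  L <- attr(st, "L")
  t_step <- if (is.null(settings$step_t)) as.numeric(st) else settings$step_t
  if (t_step >= 1 / L && !settings$backtracking)
    stop_param("step t = %g >= 1/L = %g requires backtracking", t_step, 1 / L)
  dphi <- problem$dphi
  Fval <- function(x) 0.5 * sum((dphi - J %*% x)^2)
  dc <- if (is.null(init)) drop(tikhonov_update(problem)$delta_c) else as.numeric(init)
  y <- dc
  alpha <- 1
  obj <- numeric(settings$max_inner_iter)
  converged <- FALSE
  for (i in seq_len(settings$max_inner_iter)) {
    g <- drop(crossprod(J, J %*% y - dphi))
    Fy <- Fval(y)
    repeat {
      dc_new <- soft_threshold(y - t_step * g, t_step * lam)
      if (!settings$backtracking) break
      diffv <- dc_new - y
      if (Fval(dc_new) <= Fy + sum(g * diffv) + sum(diffv^2) / (2 * t_step) + 1e-12)
        break
      t_step <- t_step / 2
    }
    obj[i] <- l1_objective(problem, dc_new, 2 * lam)
    rel <- sqrt(sum((dc_new - dc)^2)) / max(sqrt(sum(dc^2)), 1e-12)
    if (momentum) {
      alpha_new <- (1 + sqrt(1 + 4 * alpha^2)) / 2
      y <- dc_new + ((alpha - 1) / alpha_new) * (dc_new - dc)
      alpha <- alpha_new
    } else {
      y <- dc_new
    }
    dc <- dc_new
    if (rel <= settings$tol) { obj <- obj[seq_len(i)]; converged <- TRUE; break }
    if (i == settings$max_inner_iter) obj <- obj[seq_len(i)]
  }
  solver_result(dc, obj, converged, list(lambda_eff = 2 * lam, step_t = t_step))
}

#' Solve an update problem with the configured method
#'
#' Dispatches to [tikhonov_update()], [irls_solve()], [admm_solve()] or
#' [fista_solve()] according to `settings$method`.
#'
#' @param problem an [update_problem()].
#' @param settings an [solver_settings()].
#' @param init optional warm start passed to the iterative solvers.
#' @return an `scdot_solver_result`.
#' @export
solve_update <- function(problem, settings = solver_settings(), init = NULL) {
  switch(settings$method,
         tikhonov = tikhonov_update(problem),
         irls = irls_solve(problem, settings, init = init),
         admm = admm_solve(problem, settings, init = init),
         fista = fista_solve(problem, settings, init = init))
}
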