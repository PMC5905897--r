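test_that("Tikhonov update solves the regularized normal equations", {
  expect_equal(tikhonov_update(update_problem(diag(2), c(1, 1), 1))$delta_c,
               c(0.5, 0.5))
  # orthonormal J, lambda = 0: dc = J^T dphi
  set.seed(3)
  Q <- qr.Q(qr(matrix(rnorm(25), 5, 5)))
  b <- rnorm(5)
  expect_equal(tikhonov_update(update_problem(Q, b, 0))$delta_c,
               drop(crossprod(Q, b)))
  # random problem vs augmented least-squares oracle
  J <- matrix(rnorm(80), 10, 8); b <- rnorm(10); lam <- 0.37
  aug <- qr.solve(rbind(J, sqrt(lam) * diag(8)), c(b, numeric(8)))
  expect_equal(tikhonov_update(update_problem(J, b, lam))$delta_c, aug,
               tolerance = 1e-10)
  expect_error(update_problem(J, b, -1), "parameter")
})

test_that("IRLS weights follow the two-branch rule", {
  expect_equal(irls_weights(0.04, 0.01), 0.04^-0.5)
  expect_equal(irls_weights(0.001, 0.01), 100)
  expect_equal(irls_weights(1, 0.01), 1)
  w <- irls_weights(c(-0.5, 0, 0.02, 3), 0.01)
  expect_true(all(w > 0 & w <= 100))
  expect_error(irls_weights(1, 2), "parameter")
})

test_that("IRLS with unit weights reproduces Tikhonov to machine precision", {
  set.seed(5)
  J <- matrix(rnorm(60), 10, 6); b <- rnorm(10)
  pr <- update_problem(J, b, 0.25)
  ti <- tikhonov_update(pr)$delta_c
  ir <- irls_solve(pr, solver_settings("irls", max_inner_iter = 1),
                   unit_weights = TRUE)$delta_c
  expect_identical(ir, ti)
})

test_that("soft thresholding shrinks toward exact zeros", {
  expect_equal(soft_threshold(0.5, 1), 0)
  expect_equal(soft_threshold(2, 0.5), 1.5)
  expect_equal(soft_threshold(-3, 1), -2)
  expect_identical(soft_threshold(c(0.1, -0.2), 0.3), c(0, 0))
  expect_error(soft_threshold(1, -0.1), "parameter")
})

test_that("ADMM and FISTA recover the least-squares solution at lambda 0", {
  set.seed(9)
  J <- matrix(rnorm(60), 10, 6) + 2 * diag(1, 10, 6)
  b <- rnorm(10)
  ls <- qr.solve(J, b)
  ad <- admm_solve(update_problem(J, b, 0),
                   solver_settings("admm", theta = 1, tol = 1e-12,
                                   max_inner_iter = 5000))
  expect_equal(ad$delta_c, ls, tolerance = 1e-6)
  fi <- fista_solve(update_problem(J, b, 0),
                    solver_settings("fista", tol = 1e-12, max_inner_iter = 20000))
  expect_equal(fi$delta_c, ls, tolerance = 1e-6)
  ir <- irls_solve(update_problem(J, b, 0), solver_settings("irls"))
  expect_equal(ir$delta_c, ls, tolerance = 1e-8)
})

test_that("above the zero-solution threshold the L1 solution collapses to 0", {
  set.seed(13)
  J <- matrix(rnorm(48), 8, 6); b <- rnorm(8)
  # under the implemented (half-squared) convention x = 0 is optimal iff
  # ||J^T b||_inf <= lambda; verified against the oracle at 2*lambda
  lam0 <- max(abs(crossprod(J, b)))
  expect_equal(max(abs(lasso_oracle(J, b, 2 * lam0 * 1.01))), 0)
  ad <- admm_solve(update_problem(J, b, lam0 * 1.01),
                   solver_settings("admm", theta = 1, tol = 1e-12,
                                   max_inner_iter = 5000))
  expect_lt(max(abs(ad$delta_c)), 1e-10)
  fi <- fista_solve(update_problem(J, b, lam0 * 1.01),
                    solver_settings("fista", tol = 1e-12, max_inner_iter = 5000))
  expect_identical(max(abs(fi$delta_c)), 0)
})

test_that("all three L1 solvers reach the oracle objective on random instances", {
  worst <- c(irls = 0, admm = 0, fista = 0)
  for (seed in 1:10) {
    inst <- random_lasso_instance(seed)
    oo <- lasso_objective(inst$J, inst$b, lasso_oracle(inst$J, inst$b, inst$lambda),
                          inst$lambda)
    # lambda/2 mapping: all three printed solvers carry effective weight 2*lambda
    ir <- irls_solve(update_problem(inst$J, inst$b, inst$lambda / 2),
                     solver_settings("irls", epsilon_irls = 1e-5, tol = 1e-12,
                                     max_inner_iter = 2000))
    ad <- admm_solve(update_problem(inst$J, inst$b, inst$lambda / 2),
                     solver_settings("admm", theta = 1, tol = 1e-13,
                                     max_inner_iter = 50000))
    fi <- fista_solve(update_problem(inst$J, inst$b, inst$lambda / 2),
                      solver_settings("fista", tol = 1e-14, max_inner_iter = 20000))
    worst["irls"] <- max(worst["irls"],
                         (lasso_objective(inst$J, inst$b, ir$delta_c, inst$lambda) - oo) / oo)
    worst["admm"] <- max(worst["admm"],
                         (lasso_objective(inst$J, inst$b, ad$delta_c, inst$lambda) - oo) / oo)
    worst["fista"] <- max(worst["fista"],
                          (lasso_objective(inst$J, inst$b, fi$delta_c, inst$lambda) - oo) / oo)
  }
  expect_lt(max(worst), 1e-3)
})

test_that("FISTA momentum sequence and monotone behaviour", {
  # alpha recursion from alpha0 = 1
  a <- 1
  a1 <- (1 + sqrt(1 + 4 * a^2)) / 2
  expect_equal(a1, (1 + sqrt(5)) / 2)
  set.seed(17)
  J <- matrix(rnorm(200), 20, 10); b <- rnorm(20)
  lam <- 0.2 * max(abs(crossprod(J, b)))
  # ISTA (momentum off) objective strictly monotone with a valid step
  is <- fista_solve(update_problem(J, b, lam),
                    solver_settings("fista", tol = 1e-14, max_inner_iter = 300),
                    momentum = FALSE)
  expect_true(all(diff(is$objective_trace) <= 1e-12))
  # FISTA running-best objective non-increasing
  fi <- fista_solve(update_problem(J, b, lam),
                    solver_settings("fista", tol = 1e-14, max_inner_iter = 300))
  expect_true(all(diff(cummin(fi$objective_trace)) <= 0))
})

test_that("step estimation matches a dense eigendecomposition", {
  set.seed(21)
  Q <- qr.Q(qr(matrix(rnorm(100), 10, 10)))
  expect_equal(attr(estimate_step(Q), "L"), 1, tolerance = 1e-3)
  expect_equal(as.numeric(estimate_step(Q, safety = 0.9)), 0.9, tolerance = 1e-3)
  expect_equal(attr(estimate_step(2 * diag(5)), "L"), 4, tolerance = 1e-6)
  J <- matrix(rnorm(200), 20, 10)
  Ld <- max(eigen(crossprod(J), symmetric = TRUE, only.values = TRUE)$values)
  expect_equal(attr(estimate_step(J), "L"), Ld, tolerance = 1e-3)
  expect_error(estimate_step(matrix(0, 3, 3)), "parameter")
  expect_error(fista_solve(update_problem(J, rnorm(20), 0.1),
                           solver_settings("fista", step_t = 1, backtracking = FALSE)),
               "parameter")
})

test_that("regularization path behaviours: shrinkage and sparsity", {
  set.seed(1)
  J <- matrix(rnorm(120), 12, 10); b <- rnorm(12)
  lams <- max(abs(crossprod(J, b))) / 10^seq(0, 3, length.out = 10)
  # Tikhonov: ||dc|| grows as lambda decreases
  norms <- vapply(lams, function(l)
    sqrt(sum(tikhonov_update(update_problem(J, b, l))$delta_c^2)), 0)
  expect_true(all(diff(norms) >= -1e-12))
  # FISTA/ADMM: zero count non-decreasing in lambda
  zf <- vapply(rev(lams), function(l)
    sum(fista_solve(update_problem(J, b, l),
                    solver_settings("fista", tol = 1e-12,
                                    max_inner_iter = 5000))$delta_c == 0), 0)
  expect_true(all(diff(zf) >= 0))
  za <- vapply(rev(lams), function(l)
    sum(admm_solve(update_problem(J, b, l),
                   solver_settings("admm", theta = 1, tol = 1e-13,
                                   max_inner_iter = 20000))$delta_c == 0), 0)
  expect_true(all(diff(za) >= 0))
})

test_that("zero mismatch returns a zero update for every solver", {
  J <- matrix(rnorm(40), 8, 5)
  pr <- update_problem(J, numeric(8), 0.1)
  for (m in c("tikhonov", "irls", "admm", "fista")) {
    sol <- solve_update(pr, solver_settings(m))
    expect_identical(sol$delta_c, numeric(5))
    expect_true(sol$converged)
  }
})
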