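test_that("optical field derives kappa and validates inputs", {
  f <- optical_field(0.01, 1.0, 750, 5)
  expect_equal(f$kappa, rep(1 / (3 * 1.01), 5))
  expect_error(optical_field(-0.01, 1, 750, 5), "parameter")
  expect_error(optical_field(0.01, 0, 750, 5), "parameter")
})

test_that("central-source fluence is positive and peaks at the source", {
  mesh <- build_disk_mesh(20, 2.5)
  f <- optical_field(0.01, 1.0, 750, nrow(mesh$nodes))
  phi <- solve_diffusion(mesh, f, c(0, 0))
  expect_true(all(phi > 0))
  expect_equal(which.max(phi), which.min(rowSums(mesh$nodes^2)))
})

test_that("homogeneous disk matches the infinite-medium Green's function", {
  mesh <- build_disk_mesh(40, 2)
  f <- optical_field(0.01, 1.0, 750, nrow(mesh$nodes))
  phi <- solve_diffusion(mesh, f, c(0, 0))
  r <- sqrt(rowSums(mesh$nodes^2))
  sel <- r >= 5 & r <= 10
  rel <- abs(phi[sel] - greens_2d(r[sel], 0.01, 1.0)) / greens_2d(r[sel], 0.01, 1.0)
  expect_lt(max(rel), 0.05)
})

test_that("mesh refinement reduces the Green's-function error", {
  err <- vapply(c(4, 2), function(h) {
    mesh <- build_disk_mesh(40, h)
    f <- optical_field(0.01, 1.0, 750, nrow(mesh$nodes))
    phi <- solve_diffusion(mesh, f, c(0, 0))
    r <- sqrt(rowSums(mesh$nodes^2))
    sel <- r >= 5 & r <= 10
    max(abs(phi[sel] - greens_2d(r[sel], 0.01, 1.0)) / greens_2d(r[sel], 0.01, 1.0))
  }, 0)
  expect_lt(err[2], err[1])
})

test_that("swapping source and detector points leaves the reading unchanged", {
  cs <- coarse_setup()
  K <- scdot:::assemble_system(cs$mesh, cs$field)
  W <- scdot:::interpolation_matrix(cs$mesh, rbind(c(5, 3), c(-6, 2)))
  sol <- scdot:::fem_solve(scdot:::fem_factor(K), W)
  r1 <- sum(W[, 2] * sol[, 1])
  r2 <- sum(W[, 1] * sol[, 2])
  expect_lt(abs(r1 - r2) / abs(r1), 1e-8)
})

test_that("assembled system is symmetric positive definite", {
  cs <- coarse_setup()
  K <- scdot:::assemble_system(cs$mesh, cs$field)
  expect_true(Matrix::isSymmetric(K))
  ev <- min(eigen(as.matrix(K), symmetric = TRUE, only.values = TRUE)$values)
  expect_gt(ev, 0)
})

test_that("raising mua uniformly decreases every boundary measurement", {
  cs <- coarse_setup()
  a1 <- scdot:::forward_state(cs$mesh, cs$field, cs$optodes)$amplitudes
  f2 <- optical_field(0.02, 1.0, 750, nrow(cs$mesh$nodes))
  a2 <- scdot:::forward_state(cs$mesh, f2, cs$optodes)$amplitudes
  expect_true(all(a2 < a1))
})

test_that("ring optodes are uniformly spaced with shifted interior sources", {
  cs <- coarse_setup()
  opt <- cs$optodes
  ang <- sort(atan2(opt$sources[, 2], opt$sources[, 1]))
  expect_equal(diff(ang), rep(2 * pi / 8, 7), tolerance = 1e-9)
  shift <- sqrt(rowSums((opt$sources - opt$interior_sources)^2))
  expect_equal(shift, rep(1 / opt$musp_background, 8), tolerance = 1e-9)
  # co-located source/detector pairs are excluded from the link table
  opt16 <- position_optodes(build_disk_mesh(25, 3), 16, 16, "ring")
  expect_equal(nrow(opt16$links), 240)
})

test_that("detector readings are barycentric interpolations of the fluence", {
  mesh <- build_disk_mesh(10, 2)
  opt <- position_optodes(mesh, 4, 4, "ring")
  opt <- scdot:::measure_with_mesh(opt, mesh)
  # all-ones fluence interpolates to 1 everywhere
  ones <- matrix(1, nrow(mesh$nodes), 4)
  ms <- boundary_measurements(ones, opt, 750)
  expect_equal(ms$amplitudes[, 1], rep(1, nrow(opt$links)))
  # detector at a mesh node reads that node's value
  node <- which(mesh$boundary)[1]
  opt2 <- opt
  opt2$detectors[1, ] <- mesh$nodes[node, ]
  opt2 <- scdot:::measure_with_mesh(opt2, mesh)
  f <- matrix(seq_len(nrow(mesh$nodes)), ncol = 1)[, rep(1, 4)]
  ms2 <- boundary_measurements(f, opt2, 750)
  l <- which(opt2$links$detector == 1)[1]
  expect_equal(ms2$amplitudes[l, 1], node)
  # interior point: hand-computed barycentric combination
  p <- c(1.234, -0.618)
  loc <- scdot:::locate_point(mesh, p)
  opt3 <- opt
  opt3$detectors[2, ] <- p
  opt3 <- scdot:::measure_with_mesh(opt3, mesh)
  g <- rnorm(nrow(mesh$nodes))
  ms3 <- boundary_measurements(matrix(g, ncol = 1)[, rep(1, 4)], opt3, 750)
  l <- which(opt3$links$detector == 2)[1]
  expect_equal(ms3$amplitudes[l, 1], sum(loc$weights * g[loc$nodes]))
})

test_that("measurement and optode files round-trip", {
  ph <- standard_phantom()
  ms <- standard_clean_measurements()
  path <- tempfile(fileext = ".csv")
  write_measurements(ms, path)
  back <- read_measurements(path)
  expect_equal(back$amplitudes, ms$amplitudes)
  expect_equal(back$wavelengths, ms$wavelengths)
  of <- tempfile(fileext = ".csv"); lf <- tempfile(fileext = ".csv")
  write_optodes(ph$optodes, of, lf)
  back_opt <- read_optodes(of, lf, musp_background = ph$optodes$musp_background)
  expect_equal(back_opt$sources, ph$optodes$sources)
  expect_equal(back_opt$links$source, ph$optodes$links$source)
  expect_equal(back_opt$interior_sources, ph$optodes$interior_sources,
               tolerance = 1e-12)
})

test_that("diffusion solve works on a 3D tetrahedral mesh", {
  # structured cube [0,10]^3 split into tetrahedra
  g <- expand.grid(x = seq(0, 10, 2.5), y = seq(0, 10, 2.5), z = seq(0, 10, 2.5))
  nodes <- as.matrix(g)
  nx <- 5
  id <- function(i, j, k) (k - 1) * nx * nx + (j - 1) * nx + i
  tets <- list()
  for (i in 1:(nx - 1)) for (j in 1:(nx - 1)) for (k in 1:(nx - 1)) {
    v <- c(id(i, j, k), id(i + 1, j, k), id(i, j + 1, k), id(i + 1, j + 1, k),
           id(i, j, k + 1), id(i + 1, j, k + 1), id(i, j + 1, k + 1), id(i + 1, j + 1, k + 1))
    tets[[length(tets) + 1]] <- rbind(v[c(1, 2, 4, 8)], v[c(1, 2, 8, 6)], v[c(1, 6, 8, 5)],
                                      v[c(1, 4, 3, 8)], v[c(1, 3, 7, 8)], v[c(1, 7, 5, 8)])
  }
  elements <- do.call(rbind, tets)
  boundary <- nodes[, 1] %in% c(0, 10) | nodes[, 2] %in% c(0, 10) | nodes[, 3] %in% c(0, 10)
  mesh <- structure(list(nodes = nodes, elements = elements, boundary = boundary,
                         region = rep(1L, nrow(nodes)), dim = 3L),
                    class = "scdot_mesh")
  expect_true(all(scdot:::element_measures(mesh) > 0))
  f <- optical_field(0.01, 1.0, 750, nrow(nodes))
  phi <- solve_diffusion(mesh, f, c(5, 5, 5))
  # this mesh is deliberately coarse: positivity is only guaranteed near the
  # source (far corners can undershoot slightly on coarse tetrahedra)
  near <- rowSums((nodes - 5)^2) <= 25
  expect_true(all(phi[near] > 0))
  expect_gt(min(phi), -0.01 * max(phi))
  expect_equal(unname(which.max(phi)), id(3, 3, 3))
})
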