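#' Nodal optical property field
#'
#' Bundles per-node absorption and reduced scattering at one wavelength; the
#' diffusion coefficient kappa = 1/(3 (mua + musp)) is derived automatically.
#'
#' @param mua absorption coefficient per node (mm^-1), strictly positive.
#' @param musp reduced scattering coefficient per node (mm^-1), strictly
#'   positive. Scalars are recycled to all nodes.
#' @param wavelength wavelength in nm (bookkeeping only).
#' @param n_nodes number of mesh nodes (used to recycle scalars).
#' @return an `scdot_optical_field` list with `mua`, `musp`, `kappa`,
#'   `wavelength`.
#' @export
optical_field <- function(mua, musp, wavelength = NA_real_, n_nodes = length(mua)) {
  mua <- rep_len(as.numeric(mua), n_nodes)
  musp <- rep_len(as.numeric(musp), n_nodes)
  if (any(!is.finite(mua)) || any(mua <= 0)) stop_param("mua must be positive everywhere")
  if (any(!is.finite(musp)) || any(musp <= 0)) stop_param("musp must be positive everywhere")
  structure(list(mua = mua, musp = musp, kappa = 1 / (3 * (mua + musp)),
                 wavelength = wavelength),
            class = "scdot_optical_field")
}

#' Robin boundary coefficient for an index-mismatched surface
#'
#' The type III boundary term is phi/(2A) with A accounting for internal
#' reflection at the refractive-index mismatch. A is computed from the
#' effective reflection coefficient approximation
#' R_eff = -1.440 n^-2 + 0.710 n^-1 + 0.668 + 0.0636 n,
#' A = (1 + R_eff) / (1 - R_eff). `robin_coefficient(1)` is close to the
#' matched case; pass `A = 1` directly to the assembly for the idealized
#' matched boundary.
#'
#' @param n_rel relative refractive index tissue/medium (default 1.33).
#' @return the dimensionless coefficient A.
#' @export
robin_coefficient <- function(n_rel = 1.33) {
  if (!is.numeric(n_rel) || n_rel <= 0) stop_param("n_rel must be positive")
  r_eff <- -1.440 / n_rel^2 + 0.710 / n_rel + 0.668 + 0.0636 * n_rel
  (1 + r_eff) / (1 - r_eff)
}

# P1 finite-element assembly of the CW diffusion operator:
#   stiffness  int kappa grad(u).grad(v)   (kappa elementwise-linear, exact)
#   absorption int mua u v                 (mua elementwise-linear, exact)
#   Robin      int_bnd u v / (2A)
# Returns a symmetric sparse matrix. Both kappa and mua are interpolated in
# the P1 basis, so the derivative of the system with respect to nodal mua is
# the exact third-order basis product integral used by the adjoint Jacobian.
assemble_system <- function(mesh, field, robin_A = robin_coefficient()) {
  n <- nrow(mesh$nodes)
  if (length(field$mua) != n) stop_dim("optical field not defined on every node")
  e <- mesh$elements
  meas <- element_measures(mesh)
  nep <- ncol(e)
  kbar <- rowMeans(matrix(field$kappa[e], nrow(e), nep))
  if (mesh$dim == 2L) {
    nd <- mesh$nodes
    # constant P1 gradients: grad(phi_i) = (b_i, c_i) / (2 area)
    b <- cbind(nd[e[, 2], 2] - nd[e[, 3], 2],
               nd[e[, 3], 2] - nd[e[, 1], 2],
               nd[e[, 1], 2] - nd[e[, 2], 2])
    cc <- cbind(nd[e[, 3], 1] - nd[e[, 2], 1],
                nd[e[, 1], 1] - nd[e[, 3], 1],
                nd[e[, 2], 1] - nd[e[, 1], 1])
    ii <- jj <- vv <- vector("list", nep * nep)
    idx <- 0
    mu <- matrix(field$mua[e], nrow(e), nep)
    S <- rowSums(mu)
    for (i in seq_len(nep)) for (j in seq_len(nep)) {
      stiff <- kbar * (b[, i] * b[, j] + cc[, i] * cc[, j]) / (4 * meas)
      mass <- if (i == j) meas / 60 * (4 * mu[, i] + 2 * S)
              else meas / 60 * (mu[, i] + mu[, j] + S)
      idx <- idx + 1
      ii[[idx]] <- e[, i]; jj[[idx]] <- e[, j]; vv[[idx]] <- stiff + mass
    }
  } else {
    grads <- tet_gradients(mesh)
    ii <- jj <- vv <- vector("list", nep * nep)
    idx <- 0
    mu <- matrix(field$mua[e], nrow(e), nep)
    S <- rowSums(mu)
    for (i in seq_len(nep)) for (j in seq_len(nep)) {
      stiff <- kbar * meas * rowSums(grads[[i]] * grads[[j]])
      mass <- if (i == j) meas / 120 * (4 * mu[, i] + 2 * S)
              else meas / 120 * (mu[, i] + mu[, j] + S)
      idx <- idx + 1
      ii[[idx]] <- e[, i]; jj[[idx]] <- e[, j]; vv[[idx]] <- stiff + mass
    }
  }
  ii <- unlist(ii); jj <- unlist(jj); vv <- unlist(vv)
  # Robin term on boundary facets
  bf <- boundary_facets(mesh)
  if (nrow(bf) > 0) {
    if (mesh$dim == 2L) {
      len <- sqrt(rowSums((mesh$nodes[bf[, 1], , drop = FALSE] -
                           mesh$nodes[bf[, 2], , drop = FALSE])^2))
      w <- 1 / (2 * robin_A)
      ii <- c(ii, bf[, 1], bf[, 2], bf[, 1], bf[, 2])
      jj <- c(jj, bf[, 1], bf[, 2], bf[, 2], bf[, 1])
      vv <- c(vv, w * len / 3, w * len / 3, w * len / 6, w * len / 6)
    } else {
      v1 <- mesh$nodes[bf[, 2], , drop = FALSE] - mesh$nodes[bf[, 1], , drop = FALSE]
      v2 <- mesh$nodes[bf[, 3], , drop = FALSE] - mesh$nodes[bf[, 1], , drop = FALSE]
      cr <- cbind(v1[, 2] * v2[, 3] - v1[, 3] * v2[, 2],
                  v1[, 3] * v2[, 1] - v1[, 1] * v2[, 3],
                  v1[, 1] * v2[, 2] - v1[, 2] * v2[, 1])
      af <- sqrt(rowSums(cr^2)) / 2
      w <- 1 / (2 * robin_A)
      for (i in 1:3) for (j in 1:3) {
        ii <- c(ii, bf[, i]); jj <- c(jj, bf[, j])
        vv <- c(vv, w * af / ifelse(i == j, 6, 12))
      }
    }
  }
  K <- Matrix::sparseMatrix(i = ii, j = jj, x = vv, dims = c(n, n), symmetric = FALSE)
  Matrix::forceSymmetric((K + Matrix::t(K)) / 2)
}

tet_gradients <- function(mesh) {
  e <- mesh$elements; nd <- mesh$nodes
  grads <- vector("list", 4)
  for (i in 1:4) grads[[i]] <- matrix(0, nrow(e), 3)
  for (k in seq_len(nrow(e))) {
    A <- cbind(1, nd[e[k, ], ])
    Ainv <- solve(A)                 # rows of Ainv[-1, ]: gradients
    for (i in 1:4) grads[[i]][k, ] <- Ainv[2:4, i]
  }
  grads
}

# Cholesky factor wrapper; CHOLMOD supernodal factorization of the SPD system
fem_factor <- function(K) {
  tryCatch(Matrix::Cholesky(K, LDL = FALSE),
           error = function(err) stop_numeric(
             "assembled diffusion system is singular (%s)", conditionMessage(err)))
}

fem_solve <- function(factor_or_K, B) {
  as.matrix(Matrix::solve(factor_or_K, B))
}

#' Solve the CW diffusion equation for a point source
#'
#' Solves -div(kappa grad(phi)) + mua phi = q0 on the mesh with the Robin
#' boundary term, where q0 is a unit point load at `source_point`
#' (distributed to the nodes of the containing element by barycentric
#' weights). The assembled system is symmetric positive definite and solved
#' by sparse Cholesky factorization; the relative residual of the solve is
#' checked against `residual_tol`.
#'
#' @param mesh an `scdot_mesh`.
#' @param field an [optical_field()] defined on every mesh node.
#' @param source_point numeric position (mm) inside the mesh.
#' @param robin_A Robin index-mismatch coefficient (see
#'   [robin_coefficient()]).
#' @param residual_tol maximum allowed relative residual of the linear solve.
#' @return numeric vector of nodal fluence values (arbitrary units).
#' @export
solve_diffusion <- function(mesh, field, source_point,
                            robin_A = robin_coefficient(), residual_tol = 1e-10) {
  K <- assemble_system(mesh, field, robin_A)
  loc <- locate_point(mesh, source_point)
  b <- numeric(nrow(mesh$nodes))
  b[loc$nodes] <- loc$weights
  phi <- drop(fem_solve(fem_factor(K), b))
  res <- sqrt(sum((as.numeric(K %*% phi) - b)^2)) / sqrt(sum(b^2))
  if (!is.finite(res) || res > residual_tol)
    stop_numeric("diffusion solve residual %.3e exceeds tolerance", res)
  phi
}

#' Place optodes on the mesh boundary
#'
#' Distributes sources and detectors on the boundary of a 2D mesh, either on
#' the full circumference (`ring`) or in a transmission arrangement with
#' sources on the lower and detectors on the upper semicircle
#' (`grid-top-bottom`). Each source position is also moved one transport
#' length `1/musp_background` along the inward normal; these interior points
#' are where the point loads of the forward model are applied, following the
#' usual CW convention for collimated sources. The link table contains every
#' source-detector pair except co-located ones.
#'
#' @param mesh an `scdot_mesh` (2D).
#' @param n_sources,n_detectors optode counts (>= 1).
#' @param layout `"ring"` or `"grid-top-bottom"`.
#' @param musp_background background reduced scattering (mm^-1) used for the
#'   one-transport-length inward shift.
#' @return an `scdot_optodes` list with `sources`, `detectors`,
#'   `interior_sources` (matrices of positions) and `links` (data frame with
#'   columns `source`, `detector`, `distance`).
#' @export
position_optodes <- function(mesh, n_sources, n_detectors,
                             layout = c("ring", "grid-top-bottom"),
                             musp_background = 1.0) {
  layout <- match.arg(layout)
  if (n_sources < 1 || n_detectors < 1) stop_param("optode counts must be >= 1")
  if (mesh$dim != 2L) stop_param("layout '%s' requires a 2D mesh", layout)
  R <- max(sqrt(rowSums(mesh$nodes^2)))
  if (layout == "ring") {
    sa <- (seq_len(n_sources) - 1) * 2 * pi / n_sources
    da <- (seq_len(n_detectors) - 1) * 2 * pi / n_detectors
  } else {
    sa <- pi + seq_len(n_sources) * pi / (n_sources + 1)
    da <- seq_len(n_detectors) * pi / (n_detectors + 1)
  }
  src <- R * cbind(cos(sa), sin(sa))
  det <- R * cbind(cos(da), sin(da))
  shift <- 1 / musp_background
  interior <- src * (1 - shift / R)   # radial inward normal on the disk
  links <- expand.grid(source = seq_len(n_sources), detector = seq_len(n_detectors))
  d <- sqrt(rowSums((src[links$source, , drop = FALSE] -
                     det[links$detector, , drop = FALSE])^2))
  keep <- d > 1e-6
  links <- links[keep, , drop = FALSE]
  links$distance <- d[keep]
  rownames(links) <- NULL
  structure(list(sources = src, detectors = det, interior_sources = interior,
                 links = links, layout = layout,
                 musp_background = musp_background),
            class = "scdot_optodes")
}

#' @export
print.scdot_optodes <- function(x, ...) {
  cat(sprintf("scdot optodes: %d sources, %d detectors, %d links (%s layout)\n",
              nrow(x$sources), nrow(x$detectors), nrow(x$links), x$layout))
  invisible(x)
}

# interpolation (extraction) matrix: n_nodes x n_points, column p holds the
# barycentric weights of point p
interpolation_matrix <- function(mesh, points) {
  n <- nrow(mesh$nodes)
  ii <- jj <- vv <- vector("list", nrow(points))
  for (p in seq_len(nrow(points))) {
    loc <- locate_point(mesh, points[p, ])
    ii[[p]] <- loc$nodes; jj[[p]] <- rep(p, length(loc$nodes)); vv[[p]] <- loc$weights
  }
  Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(vv),
                       dims = c(n, nrow(points)))
}

#' Sample boundary measurements from nodal fluence fields
#'
#' Interpolates each source's nodal fluence field at the detector positions
#' (linear interpolation in the containing element) and assembles the
#' amplitudes into a measurement set ordered like the link table.
#'
#' @param fluence_by_source matrix (n_nodes x n_sources) of nodal fluence
#'   vectors, one column per source in the link table.
#' @param optodes an `scdot_optodes`.
#' @param wavelength wavelength in nm recorded in the measurement set.
#' @return an `scdot_measurements` object (single wavelength).
#' @export
boundary_measurements <- function(fluence_by_source, optodes, wavelength) {
  fluence_by_source <- as.matrix(fluence_by_source)
  ns <- max(optodes$links$source)
  if (ncol(fluence_by_source) < ns)
    stop_dim("need one fluence vector per source in the link table")
  W <- attr(optodes, "det_interp")
  if (is.null(W)) stop_dim("optodes lack detector interpolation weights; use measure_with_mesh()")
  amp <- vapply(seq_len(nrow(optodes$links)), function(l) {
    s <- optodes$links$source[l]; d <- optodes$links$detector[l]
    sum(W[, d] * fluence_by_source[, s])
  }, 0)
  measurement_set(optodes$links, wavelength, matrix(amp, ncol = 1))
}

# attach detector interpolation weights for a given mesh (cached on the
# optode object); boundary_measurements needs them
measure_with_mesh <- function(optodes, mesh) {
  attr(optodes, "det_interp") <- interpolation_matrix(mesh, optodes$detectors)
  optodes
}

#' Multispectral measurement set
#'
#' Container for per-link boundary fluence amplitudes at one or more
#' wavelengths. Amplitudes are stored as an n_links x n_wavelengths matrix
#' whose column order follows `wavelengths`; the concatenated data vector
#' used by the inverse model stacks wavelength blocks in that order.
#'
#' @param links data frame with columns `source`, `detector` (and optionally
#'   `distance` in mm).
#' @param wavelengths numeric vector of wavelengths (nm).
#' @param amplitudes matrix n_links x n_wavelengths of positive amplitudes.
#' @return an `scdot_measurements` object.
#' @export
measurement_set <- function(links, wavelengths, amplitudes) {
  amplitudes <- as.matrix(amplitudes)
  if (nrow(amplitudes) != nrow(links) || ncol(amplitudes) != length(wavelengths))
    stop_dim("amplitude matrix must be n_links x n_wavelengths")
  structure(list(links = links, wavelengths = as.numeric(wavelengths),
                 amplitudes = unname(amplitudes)),
            class = "scdot_measurements")
}

#' @export
print.scdot_measurements <- function(x, ...) {
  cat(sprintf("scdot measurements: %d links x %d wavelength(s) [%s nm]\n",
              nrow(x$links), length(x$wavelengths),
              paste(x$wavelengths, collapse = ", ")))
  invisible(x)
}

#' Read and write measurement sets as CSV
#'
#' Long format with columns `wavelength_nm, source_index, detector_index,
#' amplitude` (plus `distance_mm` when available).
#'
#' @param ms an `scdot_measurements`.
#' @param path file path.
#' @export
write_measurements <- function(ms, path) {
  rows <- do.call(rbind, lapply(seq_along(ms$wavelengths), function(w) {
    data.frame(wavelength_nm = ms$wavelengths[w],
               source_index = ms$links$source,
               detector_index = ms$links$detector,
               amplitude = ms$amplitudes[, w],
               distance_mm = if (!is.null(ms$links$distance)) ms$links$distance else NA)
  }))
  write.csv(rows, path, row.names = FALSE)
  invisible(ms)
}

#' @rdname write_measurements
#' @export
read_measurements <- function(path) {
  d <- read.csv(path)
  wl <- sort(unique(d$wavelength_nm))
  d1 <- d[d$wavelength_nm == wl[1], ]
  links <- data.frame(source = d1$source_index, detector = d1$detector_index)
  if (!all(is.na(d1$distance_mm))) links$distance <- d1$distance_mm
  amp <- vapply(wl, function(w) {
    dw <- d[d$wavelength_nm == w, ]
    if (nrow(dw) != nrow(links)) stop_dim("unequal link counts across wavelengths")
    dw$amplitude[order(match(paste(dw$source_index, dw$detector_index),
                             paste(links$source, links$detector)))]
  }, numeric(nrow(links)))
  measurement_set(links, wl, amp)
}

#' Read and write optode layouts as CSV
#'
#' Optode file columns: `kind` (source/detector), `x`, `y` (and `z` in 3D);
#' link file columns: `source_index`, `detector_index` (1-based).
#'
#' @param optodes an `scdot_optodes`.
#' @param optode_file,link_file file paths.
#' @export
write_optodes <- function(optodes, optode_file, link_file) {
  pos <- rbind(data.frame(kind = "source", x = optodes$sources[, 1], y = optodes$sources[, 2]),
               data.frame(kind = "detector", x = optodes$detectors[, 1], y = optodes$detectors[, 2]))
  write.csv(pos, optode_file, row.names = FALSE)
  write.csv(data.frame(source_index = optodes$links$source,
                       detector_index = optodes$links$detector),
            link_file, row.names = FALSE)
  invisible(optodes)
}

#' @rdname write_optodes
#' @export
read_optodes <- function(optode_file, link_file, musp_background = 1.0,
                         center = c(0, 0)) {
  pos <- read.csv(optode_file)
  lk <- read.csv(link_file)
  src <- as.matrix(pos[pos$kind == "source", c("x", "y")])
  det <- as.matrix(pos[pos$kind == "detector", c("x", "y")])
  if (any(lk$source_index > nrow(src)) || any(lk$detector_index > nrow(det)))
    stop_param("link table refers to a non-existent optode")
  dimnames(src) <- dimnames(det) <- NULL
  dir <- sweep(src, 2, center)                     # inward = toward center
  dir <- dir / sqrt(rowSums(dir^2))
  interior <- src - dir / musp_background
  links <- data.frame(source = lk$source_index, detector = lk$detector_index)
  links$distance <- sqrt(rowSums((src[links$source, , drop = FALSE] -
                                  det[links$detector, , drop = FALSE])^2))
  structure(list(sources = src, detectors = det, interior_sources = interior,
                 links = links, layout = "custom", musp_background = musp_background),
            class = "scdot_optodes")
}
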