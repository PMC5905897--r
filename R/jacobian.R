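# Forward solves + adjoint solves + measurement extraction for one
# wavelength. Returns the pieces the reconstruction loop and the Jacobian
# both need, so the expensive factorization is done once.
forward_state <- function(mesh, field, optodes, robin_A = robin_coefficient()) {
  K <- assemble_system(mesh, field, robin_A)
  fac <- fem_factor(K)
  n <- nrow(mesh$nodes)
  Q <- interpolation_matrix(mesh, optodes$interior_sources)  # source loads
  W <- interpolation_matrix(mesh, optodes$detectors)         # extraction
  Phi <- fem_solve(fac, Q)       # n x n_sources forward fluence
  Psi <- fem_solve(fac, W)       # n x n_detectors adjoint fluence
  amp <- as.matrix(Matrix::t(W) %*% Phi)  # n_det x n_src
  links <- optodes$links
  amplitudes <- amp[cbind(links$detector, links$source)]
  list(K = K, Phi = Phi, Psi = Psi, amplitudes = amplitudes)
}

#' Absorption Jacobian at a single wavelength (adjoint method)
#'
#' Computes J[m, n] = d(amplitude of link m) / d(mua at node n) for every
#' link in the optode table, using the adjoint method: the derivative of the
#' FEM system with respect to nodal mua is the third-order P1 basis product
#' integral, and each Jacobian entry is minus the forward fluence of the
#' link's source integrated against the adjoint fluence of its detector
#' over the support of the node's basis function. Because the diffusion
#' coefficient kappa = 1/(3 (mua + musp)) itself depends on mua, the
#' derivative of the stiffness term is included as well; the result is the
#' exact derivative of the discrete forward model, so it agrees with finite
#' differences to linearization order. A faster diagonally lumped variant
#' (`lumped = TRUE`) keeps only the lumped absorption-mass sensitivity and
#' is approximate.
#'
#' @param mesh an `scdot_mesh`.
#' @param field an [optical_field()] at the wavelength of interest.
#' @param optodes an `scdot_optodes`.
#' @param robin_A Robin coefficient used by the forward model.
#' @param lumped if `TRUE` use nodal lumping of the basis product integral.
#' @param state optional precomputed [forward_state] (internal reuse).
#' @return matrix n_links x n_nodes; all entries are <= 0 for raw amplitude
#'   data (absorption can only reduce transmitted light).
#' @export
wavelength_jacobian <- function(mesh, field, optodes,
                                robin_A = robin_coefficient(),
                                lumped = FALSE, state = NULL) {
  if (is.null(state)) state <- forward_state(mesh, field, optodes, robin_A)
  links <- optodes$links
  if (max(links$source) > ncol(state$Phi) || max(links$detector) > ncol(state$Psi))
    stop_dim("link table refers to optodes without solves")
  Phi <- state$Phi[, links$source, drop = FALSE]   # n x L
  Psi <- state$Psi[, links$detector, drop = FALSE] # n x L
  e <- mesh$elements
  nep <- ncol(e)
  meas <- element_measures(mesh)
  scale <- meas / if (mesh$dim == 2L) 60 else 120
  L <- nrow(links); n <- nrow(mesh$nodes)
  if (lumped) {
    # nodal lumping: dM/dmua_n collapsed to vol_n at node n, with
    # vol_n = int phi_n = sum over incident elements of measure / nep
    vol <- numeric(n)
    for (i in seq_len(nep)) {
      agg <- rowsum(meas / nep, e[, i])
      ids <- as.integer(rownames(agg))
      vol[ids] <- vol[ids] + agg[, 1]
    }
    return(-t(Psi * Phi) * rep(vol, each = L))
  }
  J <- matrix(0, L, n)
  # S_ij = Psi[e_i, ] * Phi[e_j, ] per element (n_e x L), 9 (or 16) products
  PsiE <- lapply(seq_len(nep), function(i) Psi[e[, i], , drop = FALSE])
  PhiE <- lapply(seq_len(nep), function(j) Phi[e[, j], , drop = FALSE])
  Sij <- vector("list", nep * nep)
  for (i in seq_len(nep)) for (j in seq_len(nep))
    Sij[[(i - 1) * nep + j]] <- PsiE[[i]] * PhiE[[j]]
  # stiffness sensitivity: kappa = 1/(3 (mua + musp)) depends on mua, so the
  # diffusion term contributes d(stiffness)/dmua_n = (dkappa_n/dmua_n / nep)
  # times the unit-kappa element stiffness (kbar is the nodal mean)
  Gij <- element_unit_stiffness(mesh)     # list of nep x nep vectors (n_e)
  dkappa <- -3 * field$kappa^2
  for (nl in seq_len(nep)) {
    contrib <- 0
    for (i in seq_len(nep)) for (j in seq_len(nep)) {
      cf <- if (i == j) { if (i == nl) 6 else 2 } else { if (nl == i || nl == j) 2 else 1 }
      contrib <- contrib + (cf * scale + (dkappa[e[, nl]] / nep) *
                              Gij[[(i - 1) * nep + j]]) * Sij[[(i - 1) * nep + j]]
    }
    agg <- rowsum(contrib, e[, nl])
    cols <- as.integer(rownames(agg))
    J[, cols] <- J[, cols] - t(agg)
  }
  J
}

# per-element stiffness integrals with kappa = 1: int grad(phi_i).grad(phi_j)
element_unit_stiffness <- function(mesh) {
  e <- mesh$elements; nep <- ncol(e)
  meas <- element_measures(mesh)
  out <- vector("list", nep * nep)
  if (mesh$dim == 2L) {
    nd <- mesh$nodes
    b <- cbind(nd[e[, 2], 2] - nd[e[, 3], 2],
               nd[e[, 3], 2] - nd[e[, 1], 2],
               nd[e[, 1], 2] - nd[e[, 2], 2])
    cc <- cbind(nd[e[, 3], 1] - nd[e[, 2], 1],
                nd[e[, 1], 1] - nd[e[, 3], 1],
                nd[e[, 2], 1] - nd[e[, 1], 1])
    for (i in seq_len(nep)) for (j in seq_len(nep))
      out[[(i - 1) * nep + j]] <- (b[, i] * b[, j] + cc[, i] * cc[, j]) / (4 * meas)
  } else {
    grads <- tet_gradients(mesh)
    for (i in seq_len(nep)) for (j in seq_len(nep))
      out[[(i - 1) * nep + j]] <- meas * rowSums(grads[[i]] * grads[[j]])
  }
  out
}

#' Spectral (block) Jacobian coupling wavelengths to chromophores
#'
#' Assembles the sensitivity of the stacked multispectral data vector to the
#' stacked chromophore concentration vector: block (i, j) is the absorption
#' Jacobian at wavelength i scaled by the extinction coefficient of
#' chromophore j at that wavelength. Row blocks follow the wavelength order,
#' column blocks the chromophore order of the extinction table.
#'
#' @param sub_jacobians list of per-wavelength Jacobians (n_links x
#'   n_nodes), one per wavelength, all the same shape.
#' @param table an `scdot_extinction`.
#' @param wavelengths wavelengths of the sub-Jacobians (default: all table
#'   wavelengths, in order).
#' @return an `scdot_spectral_jacobian`: the dense block matrix plus block
#'   bookkeeping; retrieve blocks with [jacobian_block()].
#' @export
spectral_jacobian <- function(sub_jacobians, table,
                              wavelengths = table$wavelengths) {
  if (length(sub_jacobians) != length(wavelengths))
    stop_dim("one sub-Jacobian per wavelength required")
  dims <- vapply(sub_jacobians, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop_dim("sub-Jacobians differ in shape across wavelengths")
  eps <- epsilon_rows(table, wavelengths)
  nl <- dims[1, 1]; nn <- dims[2, 1]; nc <- ncol(eps)
  Jm <- matrix(0, nl * length(wavelengths), nn * nc)
  for (i in seq_along(wavelengths)) for (j in seq_len(nc)) {
    Jm[(i - 1) * nl + seq_len(nl), (j - 1) * nn + seq_len(nn)] <-
      sub_jacobians[[i]] * eps[i, j]
  }
  structure(list(matrix = Jm, n_links = nl, n_nodes = nn,
                 wavelengths = wavelengths, chromophores = colnames(eps)),
            class = "scdot_spectral_jacobian")
}

#' @rdname spectral_jacobian
#' @param J an `scdot_spectral_jacobian`.
#' @param wavelength_index,chromophore_index block indices.
#' @export
jacobian_block <- function(J, wavelength_index, chromophore_index) {
  J$matrix[(wavelength_index - 1) * J$n_links + seq_len(J$n_links),
           (chromophore_index - 1) * J$n_nodes + seq_len(J$n_nodes), drop = FALSE]
}

#' @export
print.scdot_spectral_jacobian <- function(x, ...) {
  cat(sprintf("scdot spectral Jacobian: (%d wavelengths x %d links) x (%d chromophores x %d nodes)\n",
              length(x$wavelengths), x$n_links, length(x$chromophores), x$n_nodes))
  invisible(x)
}

# coerce problem matrices: accept spectral Jacobian or plain matrix
as_jacobian_matrix <- function(J) {
  if (inherits(J, "scdot_spectral_jacobian")) J$matrix else as.matrix(J)
}
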