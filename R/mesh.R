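#' Triangulated disk mesh
#'
#' Builds a 2D triangular mesh of a disk of the given radius, using
#' concentric rings of nodes spaced approximately `edge_length` apart both
#' radially and circumferentially. Nodes on the outer ring are flagged as
#' boundary nodes. This is the standard desk-scale test geometry for
#' circular tissue phantoms.
#'
#' @param radius disk radius in mm.
#' @param edge_length target element edge length in mm; must be positive and
#'   smaller than `radius`.
#' @return an object of class `scdot_mesh`: a list with `nodes` (n x 2
#'   matrix, mm), `elements` (m x 3 integer matrix, 1-based), `boundary`
#'   (logical per node), `region` (integer per node) and `dim`.
#' @export
build_disk_mesh <- function(radius, edge_length) {
  if (!is.numeric(radius) || length(radius) != 1 || !is.finite(radius) || radius <= 0)
    stop_param("radius must be a positive number")
  if (!is.numeric(edge_length) || length(edge_length) != 1 || !is.finite(edge_length) ||
      edge_length <= 0 || edge_length >= radius)
    stop_param("edge_length must satisfy 0 < edge_length < radius")
  ring_mesh(ring_radii = seq_len(max(2L, round(radius / edge_length))) *
              (radius / max(2L, round(radius / edge_length))))
}

#' Layered (annular) disk mesh
#'
#' As [build_disk_mesh()] but with concentric tissue layers: `radii` is a
#' strictly decreasing list of layer outer radii and every node is labelled
#' with the innermost annulus containing it (label 1 = outermost annulus,
#' label `length(radii)` = central disk). Ring radii are snapped so each
#' layer interface coincides with a node ring.
#'
#' @param radii strictly decreasing vector of positive layer radii (mm).
#' @param edge_length target element edge length in mm.
#' @return an `scdot_mesh` with `region` labels in `1:length(radii)`.
#' @export
build_layered_disk_mesh <- function(radii, edge_length) {
  if (!is.numeric(radii) || length(radii) < 1 || any(!is.finite(radii)) || any(radii <= 0))
    stop_param("radii must be positive numbers")
  if (length(radii) > 1 && any(diff(radii) >= 0))
    stop_param("radii must be strictly decreasing (outermost first)")
  if (!is.numeric(edge_length) || length(edge_length) != 1 || edge_length <= 0 ||
      edge_length >= max(radii))
    stop_param("edge_length must satisfy 0 < edge_length < max(radii)")
  interfaces <- sort(radii)           # ascending
  rings <- numeric(0)
  r0 <- 0
  for (ri in interfaces) {
    nseg <- max(1L, round((ri - r0) / edge_length))
    rings <- c(rings, r0 + seq_len(nseg) * (ri - r0) / nseg)
    r0 <- ri
  }
  mesh <- ring_mesh(ring_radii = rings)
  r <- sqrt(rowSums(mesh$nodes^2))
  tol <- 1e-9 * max(radii)
  # label = number of layer radii >= node radius (innermost annulus)
  mesh$region <- as.integer(vapply(r, function(x) sum(radii >= x - tol), 0L))
  mesh$region[mesh$region == 0L] <- 1L
  mesh
}

# Core ring-based disk triangulation. ring_radii ascending, outermost = disk
# boundary; a center node is always included. Consecutive rings are stitched
# by an angular merge, which yields a valid conforming triangulation with
# positively oriented elements.
ring_mesh <- function(ring_radii) {
  stopifnot(all(diff(ring_radii) > 0))
  h <- ring_radii[length(ring_radii)] / length(ring_radii)
  nodes <- matrix(0, 1, 2)
  ring_start <- integer(length(ring_radii))   # index of first node in each ring
  ring_n <- integer(length(ring_radii))
  for (j in seq_along(ring_radii)) {
    n_j <- max(6L, round(2 * pi * ring_radii[j] / h))
    ang <- (seq_len(n_j) - 1) * 2 * pi / n_j
    ring_start[j] <- nrow(nodes) + 1L
    ring_n[j] <- n_j
    nodes <- rbind(nodes, ring_radii[j] * cbind(cos(ang), sin(ang)))
  }
  elems <- vector("list", length(ring_radii))
  # center fan
  n1 <- ring_n[1]; s1 <- ring_start[1]
  elems[[1]] <- cbind(1L, s1 + (seq_len(n1) - 1L), s1 + (seq_len(n1) %% n1))
  # annulus stitching by two-pointer angular merge
  for (j in seq_along(ring_radii)[-1]) {
    ni <- ring_n[j - 1]; no <- ring_n[j]
    si <- ring_start[j - 1]; so <- ring_start[j]
    tri <- matrix(0L, ni + no, 3)
    i <- 0L; o <- 0L; t <- 0L
    while (i < ni || o < no) {
      adv_outer <- if (o >= no) FALSE
        else if (i >= ni) TRUE
        else ((o + 1) / no) <= ((i + 1) / ni)   # compare next fractional angles
      t <- t + 1L
      if (adv_outer) {
        tri[t, ] <- c(si + (i %% ni), so + (o %% no), so + ((o + 1L) %% no))
        o <- o + 1L
      } else {
        tri[t, ] <- c(si + (i %% ni), so + (o %% no), si + ((i + 1L) %% ni))
        i <- i + 1L
      }
    }
    elems[[j]] <- tri[seq_len(t), , drop = FALSE]
  }
  elements <- do.call(rbind, elems)
  storage.mode(elements) <- "integer"
  # enforce positive orientation
  a <- signed_areas(nodes, elements)
  flip <- a < 0
  if (any(flip)) elements[flip, 2:3] <- elements[flip, 3:2]
  if (any(abs(signed_areas(nodes, elements)) < 1e-12 * h^2))
    stop_numeric("degenerate element produced by mesh generator")
  boundary <- rep(FALSE, nrow(nodes))
  boundary[ring_start[length(ring_radii)] - 1L + seq_len(ring_n[length(ring_radii)])] <- TRUE
  structure(list(nodes = nodes, elements = elements, boundary = boundary,
                 region = rep(1L, nrow(nodes)), dim = 2L),
            class = "scdot_mesh")
}

signed_areas <- function(nodes, elements) {
  x1 <- nodes[elements[, 1], 1]; y1 <- nodes[elements[, 1], 2]
  x2 <- nodes[elements[, 2], 1]; y2 <- nodes[elements[, 2], 2]
  x3 <- nodes[elements[, 3], 1]; y3 <- nodes[elements[, 3], 2]
  0.5 * ((x2 - x1) * (y3 - y1) - (x3 - x1) * (y2 - y1))
}

#' @export
print.scdot_mesh <- function(x, ...) {
  cat(sprintf("scdot mesh: %d nodes, %d elements (%dD), %d boundary nodes, %d region(s)\n",
              nrow(x$nodes), nrow(x$elements), x$dim, sum(x$boundary),
              length(unique(x$region))))
  invisible(x)
}

# element areas (2D) or volumes (3D), strictly positive for valid meshes
element_measures <- function(mesh) {
  if (mesh$dim == 2L) return(abs(signed_areas(mesh$nodes, mesh$elements)))
  e <- mesh$elements; p <- mesh$nodes
  v1 <- p[e[, 2], ] - p[e[, 1], ]
  v2 <- p[e[, 3], ] - p[e[, 1], ]
  v3 <- p[e[, 4], ] - p[e[, 1], ]
  abs(v1[, 1] * (v2[, 2] * v3[, 3] - v2[, 3] * v3[, 2]) -
      v1[, 2] * (v2[, 1] * v3[, 3] - v2[, 3] * v3[, 1]) +
      v1[, 3] * (v2[, 1] * v3[, 2] - v2[, 2] * v3[, 1])) / 6
}

# Boundary edges (2D) / faces (3D): facets incident to exactly one element.
boundary_facets <- function(mesh) {
  e <- mesh$elements
  if (mesh$dim == 2L) {
    fac <- rbind(e[, c(1, 2)], e[, c(2, 3)], e[, c(3, 1)])
  } else {
    fac <- rbind(e[, c(1, 2, 3)], e[, c(1, 2, 4)], e[, c(1, 3, 4)], e[, c(2, 3, 4)])
  }
  key <- apply(t(apply(fac, 1, sort)), 1, paste, collapse = "-")
  fac[key %in% names(which(table(key) == 1)), , drop = FALSE]
}

# Barycentric location of point p in the mesh. Returns the element index and
# the interpolation weights on its nodes. Points slightly outside the mesh
# (e.g. optodes on the circumscribing circle, outside the polygonal hull by
# the chord sagitta) are clipped onto the nearest element.
locate_point <- function(mesh, p, tol = 1e-8) {
  if (mesh$dim != 2L) return(locate_point_3d(mesh, p, tol))
  e <- mesh$elements; nd <- mesh$nodes
  x1 <- nd[e[, 1], 1]; y1 <- nd[e[, 1], 2]
  x2 <- nd[e[, 2], 1]; y2 <- nd[e[, 2], 2]
  x3 <- nd[e[, 3], 1]; y3 <- nd[e[, 3], 2]
  det <- (y2 - y3) * (x1 - x3) + (x3 - x2) * (y1 - y3)
  l1 <- ((y2 - y3) * (p[1] - x3) + (x3 - x2) * (p[2] - y3)) / det
  l2 <- ((y3 - y1) * (p[1] - x3) + (x1 - x3) * (p[2] - y3)) / det
  l3 <- 1 - l1 - l2
  score <- pmin(l1, l2, l3)
  best <- which.max(score)
  if (score[best] < -0.1)
    stop("geometry error: point (", paste(signif(p, 6), collapse = ", "),
         ") lies outside the mesh", call. = FALSE)
  w <- c(l1[best], l2[best], l3[best])
  if (score[best] < -tol) { w <- pmax(w, 0); w <- w / sum(w) }
  list(element = best, nodes = e[best, ], weights = w)
}

locate_point_3d <- function(mesh, p, tol = 1e-8) {
  e <- mesh$elements; nd <- mesh$nodes
  best <- NULL; best_score <- -Inf
  for (k in seq_len(nrow(e))) {
    v <- nd[e[k, ], ]
    A <- cbind(1, v)                 # 4x4: barycentric via linear solve
    w <- tryCatch(solve(t(A), c(1, p)), error = function(err) NULL)
    if (is.null(w)) next
    s <- min(w)
    if (s > best_score) { best_score <- s; best <- k; best_w <- w }
    if (s >= -tol) break
  }
  if (is.null(best) || best_score < -0.1)
    stop("geometry error: point lies outside the mesh", call. = FALSE)
  w <- best_w
  if (best_score < -tol) { w <- pmax(w, 0); w <- w / sum(w) }
  list(element = best, nodes = e[best, ], weights = w)
}

#' Read and write meshes in the plain-text node/element format
#'
#' The node file has one line per node: `x y [z] boundary_flag region_label`;
#' the element file has one line per element with 1-based node indices.
#' Writing then reading reproduces the mesh exactly.
#'
#' @param mesh an `scdot_mesh`.
#' @param node_file,element_file file paths.
#' @return `read_mesh` returns an `scdot_mesh`; `write_mesh` returns the
#'   mesh invisibly.
#' @export
write_mesh <- function(mesh, node_file, element_file) {
  nd <- cbind(mesh$nodes, as.integer(mesh$boundary), mesh$region)
  write.table(format(nd, digits = 17, trim = TRUE, scientific = FALSE),
              node_file, row.names = FALSE, col.names = FALSE, quote = FALSE)
  write.table(mesh$elements, element_file, row.names = FALSE,
              col.names = FALSE, quote = FALSE)
  invisible(mesh)
}

#' @rdname write_mesh
#' @export
read_mesh <- function(node_file, element_file) {
  nd <- as.matrix(read.table(node_file))
  el <- as.matrix(read.table(element_file))
  dim <- ncol(nd) - 2L
  if (!dim %in% c(2L, 3L)) stop_param("node file must have 4 or 5 columns")
  storage.mode(el) <- "integer"
  mesh <- structure(list(nodes = unname(nd[, seq_len(dim), drop = FALSE]),
                         elements = unname(el),
                         boundary = nd[, dim + 1L] != 0,
                         region = as.integer(nd[, dim + 2L]),
                         dim = dim),
                    class = "scdot_mesh")
  validate_mesh(mesh)
  mesh
}

validate_mesh <- function(mesh) {
  if (any(mesh$elements < 1L) || any(mesh$elements > nrow(mesh$nodes)))
    stop_param("element refers to a non-existent node")
  if (any(element_measures(mesh) <= 0))
    stop_numeric("mesh has degenerate (zero-measure) elements")
  if (!any(mesh$boundary))
    stop_param("mesh has no flagged boundary nodes")
  invisible(mesh)
}
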