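#' Phantom specification
#'
#' Describes a synthetic circular phantom: a disk (or layered disk), a
#' homogeneous chromophore background per region, a list of focal
#' inclusions, and a ring of optodes. Defaults emulate a desk-scale tissue
#' phantom: a 25 mm disk with gray-matter-like background concentrations
#' and scattering, 16 co-located source and detector positions, and the
#' 750/850 nm wavelength pair.
#'
#' @param radius disk radius (mm); ignored when `layer_radii` is given.
#' @param layer_radii optional strictly decreasing layer radii for a
#'   layered phantom.
#' @param edge_length mesh edge length (mm).
#' @param background list (single region) or list of lists (one per layer,
#'   outermost first) with entries `c1`, `c2` (mM), `scatter_amplitude`,
#'   `scatter_power`.
#' @param inclusions list of inclusions, each a list with `center` (mm),
#'   `radius` (mm), and either `delta_c1`/`delta_c2` (additive change, mM)
#'   or `factor_c1`/`factor_c2` (multiplicative contrast).
#' @param n_sources,n_detectors,layout optode layout (see
#'   [position_optodes()]).
#' @param wavelengths measurement wavelengths (nm).
#' @return an `scdot_phantom_spec` list.
#' @export
phantom_spec <- function(radius = 25, layer_radii = NULL, edge_length = 2.5,
                         background = list(c1 = 0.0548, c2 = 0.0354,
                                           scatter_amplitude = 0.5040,
                                           scatter_power = 1.7757),
                         inclusions = list(),
                         n_sources = 16, n_detectors = 16, layout = "ring",
                         wavelengths = c(750, 850)) {
  geom_r <- if (is.null(layer_radii)) radius else max(layer_radii)
  bg <- if (!is.null(background$c1)) list(background) else background
  for (b in bg) {
    if (b$c1 <= 0 || b$c2 <= 0) stop_param("background concentrations must be positive")
    if (b$scatter_amplitude <= 0) stop_param("scattering amplitude must be positive")
  }
  for (inc in inclusions) {
    if (sqrt(sum(inc$center^2)) + inc$radius > geom_r)
      stop("spec error: inclusion lies outside the phantom geometry", call. = FALSE)
  }
  structure(list(radius = radius, layer_radii = layer_radii,
                 edge_length = edge_length, background = bg,
                 inclusions = inclusions, n_sources = n_sources,
                 n_detectors = n_detectors, layout = layout,
                 wavelengths = wavelengths),
            class = "scdot_phantom_spec")
}

#' Realize a phantom: mesh, ground truth and optodes
#'
#' Builds the mesh from the spec, assigns each node its regional background
#' concentrations and scattering, applies the inclusions (additive deltas or
#' multiplicative factors inside each inclusion radius) and places the
#' optodes, using the background Mie scattering at the first wavelength for
#' the one-transport-length source shift.
#'
#' @param spec an [phantom_spec()].
#' @param edge_length optional override of the spec's mesh resolution (used
#'   for inverse-crime control: simulate on a finer mesh than the
#'   reconstruction uses).
#' @return list with `mesh`, `truth` (an `scdot_chromophores`) and
#'   `optodes`.
#' @export
make_phantom <- function(spec, edge_length = spec$edge_length) {
  mesh <- if (is.null(spec$layer_radii)) build_disk_mesh(spec$radius, edge_length)
          else build_layered_disk_mesh(spec$layer_radii, edge_length)
  n <- nrow(mesh$nodes)
  bg <- spec$background
  reg <- pmin(mesh$region, length(bg))
  c1 <- vapply(reg, function(r) bg[[r]]$c1, 0)
  c2 <- vapply(reg, function(r) bg[[r]]$c2, 0)
  sa <- vapply(reg, function(r) bg[[r]]$scatter_amplitude, 0)
  sp <- vapply(reg, function(r) bg[[r]]$scatter_power, 0)
  for (inc in spec$inclusions) {
    inside <- sqrt((mesh$nodes[, 1] - inc$center[1])^2 +
                   (mesh$nodes[, 2] - inc$center[2])^2) <= inc$radius
    if (!is.null(inc$factor_c1)) c1[inside] <- c1[inside] * inc$factor_c1
    if (!is.null(inc$factor_c2)) c2[inside] <- c2[inside] * inc$factor_c2
    if (!is.null(inc$delta_c1)) c1[inside] <- c1[inside] + inc$delta_c1
    if (!is.null(inc$delta_c2)) c2[inside] <- c2[inside] + inc$delta_c2
  }
  truth <- chromophore_field(cbind(HbO2 = c1, Hb = c2),
                             scatter_amplitude = sa, scatter_power = sp)
  musp_bg <- mie_musp(bg[[1]]$scatter_amplitude, bg[[1]]$scatter_power,
                      spec$wavelengths[1])
  optodes <- position_optodes(mesh, spec$n_sources, spec$n_detectors,
                              spec$layout, musp_background = musp_bg)
  list(mesh = mesh, truth = truth, optodes = optodes, spec = spec)
}

#' Simulate noise-free multispectral measurements from a phantom
#'
#' Runs the forward model per wavelength on the phantom's ground truth:
#' absorption from Beer's law, reduced scattering from the Mie prior, one
#' diffusion solve per source, and detector readings for every link.
#'
#' @param phantom result of [make_phantom()].
#' @param table an `scdot_extinction`.
#' @param robin_A Robin boundary coefficient.
#' @return an `scdot_measurements` with strictly positive amplitudes.
#' @export
simulate_experiment <- function(phantom, table = default_extinction_table(),
                                robin_A = robin_coefficient()) {
  mesh <- phantom$mesh; truth <- phantom$truth; optodes <- phantom$optodes
  wl <- phantom$spec$wavelengths
  n <- nrow(mesh$nodes)
  amp <- vapply(wl, function(w) {
    fld <- optical_field(beer_law_mua(table, truth, w),
                         mie_musp(truth$scatter_amplitude, truth$scatter_power, w),
                         w, n)
    forward_state(mesh, fld, optodes, robin_A)$amplitudes
  }, numeric(nrow(optodes$links)))
  ms <- measurement_set(optodes$links, wl, amp)
  if (any(ms$amplitudes <= 0))
    stop_numeric("forward model produced non-positive amplitudes")
  ms
}

#' Noise specification
#'
#' Proportional (multiplicative) Gaussian measurement noise: each amplitude
#' is scaled by (1 + level * z) with independent standard normal z. The
#' level is either flat across all links or binned by source-detector
#' distance, emulating the distance-dependent noise of high-density
#' imaging arrays (nearest-neighbour separations get less noise). The
#' default bins place their edges midway between nominal neighbour
#' distances of 13, 30, 40 and 48 mm with levels 0.12%, 0.15%, 0.41% and
#' 1.42%.
#'
#' @param mode `"flat"` or `"distance_binned"`.
#' @param level flat fractional noise level (e.g. 0.01 for 1%).
#' @param bin_edges increasing distance bin edges (mm), first 0, last Inf.
#' @param bin_levels fractional noise level per bin.
#' @param seed optional RNG seed for reproducible noise.
#' @return an `scdot_noise_spec` list.
#' @export
noise_spec <- function(mode = c("flat", "distance_binned"), level = 0.01,
                       bin_edges = c(0, 21.5, 35, 44, Inf),
                       bin_levels = c(0.0012, 0.0015, 0.0041, 0.0142),
                       seed = NULL) {
  mode <- match.arg(mode)
  if (level < 0 || any(bin_levels < 0)) stop_param("noise levels must be >= 0")
  if (any(diff(bin_edges) <= 0)) stop_param("bin edges must be increasing")
  if (length(bin_levels) != length(bin_edges) - 1)
    stop_param("need one noise level per distance bin")
  structure(list(mode = mode, level = level, bin_edges = bin_edges,
                 bin_levels = bin_levels, seed = seed),
            class = "scdot_noise_spec")
}

#' Corrupt measurements with proportional Gaussian noise
#'
#' @param measurements an `scdot_measurements`.
#' @param noise an [noise_spec()]. In `distance_binned` mode the link table
#'   must carry distances and every distance must fall in a bin.
#' @return noisy `scdot_measurements`; amplitudes that would become
#'   non-positive are clipped to a small positive floor with a warning.
#' @export
add_noise <- function(measurements, noise = noise_spec()) {
  amp <- measurements$amplitudes
  if (noise$mode == "flat") {
    lev <- matrix(noise$level, nrow(amp), ncol(amp))
  } else {
    d <- measurements$links$distance
    if (is.null(d)) stop("spec error: distance-binned noise needs link distances", call. = FALSE)
    bin <- findInterval(d, noise$bin_edges, rightmost.closed = FALSE)
    if (any(bin < 1) || any(bin > length(noise$bin_levels)))
      stop("spec error: link distance outside all noise bins", call. = FALSE)
    lev <- matrix(noise$bin_levels[bin], nrow(amp), ncol(amp))
  }
  if (!is.null(noise$seed)) {
    if (exists(".Random.seed", globalenv())) {
      old <- get(".Random.seed", globalenv())
      on.exit(assign(".Random.seed", old, globalenv()))
    }
    set.seed(noise$seed)
  }
  z <- matrix(rnorm(length(amp)), nrow(amp), ncol(amp))
  noisy <- amp * (1 + lev * z)
  if (any(noisy <= 0)) {
    warning("noise drove ", sum(noisy <= 0), " amplitude(s) non-positive; clipped")
    floor_val <- 1e-12 * max(amp)
    noisy[noisy <= 0] <- floor_val
  }
  measurement_set(measurements$links, measurements$wavelengths, noisy)
}
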