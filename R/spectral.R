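#' Chromophore extinction table
#'
#' Holds the extinction coefficients epsilon (mm^-1 mM^-1) linking
#' chromophore concentrations to absorption through Beer's law. Stored as a
#' wavelengths x chromophores matrix. Every entry must be non-negative and,
#' for any wavelength pair used in a two-chromophore reconstruction, the 2x2
#' submatrix must be well-conditioned, otherwise Beer's law cannot be
#' inverted.
#'
#' @param wavelengths numeric vector (nm).
#' @param chromophores character vector of chromophore names.
#' @param epsilon matrix (length(wavelengths) x length(chromophores)).
#' @return an `scdot_extinction` object.
#' @export
extinction_table <- function(wavelengths, chromophores, epsilon) {
  epsilon <- as.matrix(epsilon)
  if (nrow(epsilon) != length(wavelengths) || ncol(epsilon) != length(chromophores))
    stop_dim("epsilon must be wavelengths x chromophores")
  if (any(epsilon < 0)) stop_param("extinction coefficients must be non-negative")
  dimnames(epsilon) <- list(as.character(wavelengths), chromophores)
  structure(list(wavelengths = as.numeric(wavelengths),
                 chromophores = chromophores, epsilon = epsilon),
            class = "scdot_extinction")
}

#' Default hemoglobin extinction coefficients
#'
#' Standard molar extinction values for oxyhemoglobin (HbO2) and
#' deoxyhemoglobin (Hb) at 750 and 850 nm, converted to mm^-1 mM^-1 (natural
#' log convention, i.e. mua = epsilon * concentration). These are the widely
#' used tabulated hemoglobin spectra adopted by the functional neuroimaging
#' DOT literature.
#'
#' @return an `scdot_extinction` with wavelengths 750 and 850 nm.
#' @export
default_extinction_table <- function() {
  extinction_table(c(750, 850), c("HbO2", "Hb"),
                   matrix(c(0.1198, 0.3226,
                            0.2436, 0.1596), 2, 2, byrow = TRUE))
}

#' @export
print.scdot_extinction <- function(x, ...) {
  cat("scdot extinction table (mm^-1 mM^-1):\n")
  print(x$epsilon)
  invisible(x)
}

#' Read and write extinction tables
#'
#' CSV with columns `wavelength_nm, chromophore, epsilon_mm_per_mM`.
#'
#' @param table an `scdot_extinction`.
#' @param path file path.
#' @export
write_extinction_table <- function(table, path) {
  rows <- expand.grid(wavelength_nm = table$wavelengths,
                      chromophore = table$chromophores,
                      stringsAsFactors = FALSE)
  rows$epsilon_mm_per_mM <- table$epsilon[cbind(match(rows$wavelength_nm, table$wavelengths),
                                                match(rows$chromophore, table$chromophores))]
  write.csv(rows, path, row.names = FALSE)
  invisible(table)
}

#' @rdname write_extinction_table
#' @export
read_extinction_table <- function(path) {
  d <- read.csv(path)
  wl <- sort(unique(d$wavelength_nm))
  ch <- unique(d$chromophore)
  eps <- matrix(NA_real_, length(wl), length(ch))
  eps[cbind(match(d$wavelength_nm, wl), match(d$chromophore, ch))] <- d$epsilon_mm_per_mM
  if (any(is.na(eps))) stop_param("extinction table is missing entries")
  extinction_table(wl, ch, eps)
}

# epsilon rows for specific wavelengths, with presence check
epsilon_rows <- function(table, wavelengths) {
  idx <- match(wavelengths, table$wavelengths)
  if (any(is.na(idx)))
    stop("lookup error: wavelength(s) ", paste(wavelengths[is.na(idx)], collapse = ", "),
         " nm not in extinction table", call. = FALSE)
  table$epsilon[idx, , drop = FALSE]
}

#' Mie-type reduced scattering model
#'
#' musp(lambda) = amplitude * (lambda / 1000)^(-power), i.e. a power law in
#' the wavelength expressed in micrometers. With the scattering amplitude
#' and power pairs tabulated for head tissues this reproduces the published
#' reduced scattering coefficients at 750 and 850 nm.
#'
#' @param amplitude scattering amplitude (dimensionless), > 0.
#' @param power scattering power (dimensionless).
#' @param wavelength wavelength in nm, > 0. Vectorized over all arguments.
#' @return reduced scattering coefficient musp in mm^-1.
#' @export
mie_musp <- function(amplitude, power, wavelength) {
  if (any(!is.finite(amplitude)) || any(amplitude <= 0))
    stop_param("scattering amplitude must be positive")
  if (any(!is.finite(wavelength)) || any(wavelength <= 0))
    stop_param("wavelength must be positive")
  amplitude * (wavelength / 1000)^(-power)
}

#' Chromophore concentration field
#'
#' The unknowns of the spectral reconstruction: per-node concentrations of
#' each chromophore (mM) plus the scattering prior (amplitude and power per
#' node), which is held fixed by the reconstruction.
#'
#' @param concentrations n_nodes x n_chromophores matrix (mM); column names
#'   are the chromophore names.
#' @param scatter_amplitude,scatter_power scattering prior per node (scalars
#'   are recycled).
#' @param chromophores chromophore names (defaults to the column names).
#' @return an `scdot_chromophores` object.
#' @export
chromophore_field <- function(concentrations,
                              scatter_amplitude = 1, scatter_power = 1,
                              chromophores = colnames(concentrations)) {
  concentrations <- as.matrix(concentrations)
  if (is.null(chromophores)) chromophores <- paste0("c", seq_len(ncol(concentrations)))
  n <- nrow(concentrations)
  scatter_amplitude <- rep_len(scatter_amplitude, n)
  scatter_power <- rep_len(scatter_power, n)
  if (any(scatter_amplitude <= 0)) stop_param("scattering amplitude must be positive")
  colnames(concentrations) <- chromophores
  structure(list(concentrations = concentrations, chromophores = chromophores,
                 scatter_amplitude = scatter_amplitude, scatter_power = scatter_power),
            class = "scdot_chromophores")
}

#' Beer's law: concentrations to absorption
#'
#' mua(node) = sum_c epsilon_{c,lambda} concentration_c(node), for one
#' wavelength present in the extinction table.
#'
#' @param table an `scdot_extinction`.
#' @param field an `scdot_chromophores` (or bare concentration matrix with
#'   chromophore column names).
#' @param wavelength wavelength in nm, must be present in the table.
#' @return numeric vector of per-node mua (mm^-1).
#' @export
beer_law_mua <- function(table, field, wavelength) {
  conc <- if (inherits(field, "scdot_chromophores")) field$concentrations else as.matrix(field)
  eps <- epsilon_rows(table, wavelength)
  ch <- colnames(conc)
  if (!is.null(ch) && all(ch %in% table$chromophores)) eps <- eps[, ch, drop = FALSE]
  else if (ncol(conc) != ncol(eps)) stop_dim("concentration columns do not match table chromophores")
  unname(drop(conc %*% t(eps)))
}

#' Inverse Beer's law: absorption to concentrations
#'
#' Solves the (square) extinction system for the concentrations that produce
#' the given per-wavelength absorption values; used to assign ground-truth
#' concentrations from tabulated tissue optical properties.
#'
#' @param table an `scdot_extinction`.
#' @param mua_by_wavelength matrix n_nodes x n_wavelengths (columns ordered
#'   like `wavelengths`), or a vector of per-wavelength mua for one node.
#' @param wavelengths the wavelengths of the columns (default: all table
#'   wavelengths).
#' @return matrix n_nodes x n_chromophores of concentrations (mM).
#' @export
invert_beer_law <- function(table, mua_by_wavelength, wavelengths = table$wavelengths) {
  mua <- if (is.matrix(mua_by_wavelength)) mua_by_wavelength else matrix(mua_by_wavelength, nrow = 1)
  eps <- epsilon_rows(table, wavelengths)
  if (ncol(mua) != nrow(eps)) stop_dim("one mua column per wavelength required")
  if (nrow(eps) != ncol(eps))
    stop_param("need as many wavelengths as chromophores to invert Beer's law")
  if (rcond(eps) < 1e-12)
    stop_numeric("extinction submatrix is singular; Beer's law not invertible")
  conc <- t(solve(eps, t(mua)))
  colnames(conc) <- table$chromophores
  conc
}
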