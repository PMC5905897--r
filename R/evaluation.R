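#' Activation region by fractional thresholding
#'
#' Nodes whose absolute recovered change reaches `fraction` of the maximum
#' absolute change (default 50%). Using |value| handles negative
#' activations (deoxyhemoglobin decreases) symmetrically.
#'
#' @param delta_field per-node recovered change.
#' @param fraction threshold fraction of the maximum, in (0, 1].
#' @return integer vector of node indices (empty, with a warning, for an
#'   all-zero field).
#' @export
activation_region <- function(delta_field, fraction = 0.5) {
  if (length(delta_field) == 0) stop_param("field must be non-empty")
  m <- max(abs(delta_field))
  if (m == 0) {
    warning("all-zero field: empty activation region")
    return(integer(0))
  }
  which(abs(delta_field) >= fraction * m)
}

#' Average contrast (AC)
#'
#' Mean recovered value over the activation region divided by the ground
#' truth value there; 1 for a perfect reconstruction.
#'
#' @param recon per-node recovered values.
#' @param truth_value scalar ground-truth value in the activation region
#'   (non-zero).
#' @param region node index set (non-empty).
#' @export
average_contrast <- function(recon, truth_value, region) {
  if (length(region) == 0) stop("metric error: empty activation region", call. = FALSE)
  if (truth_value == 0) stop("metric error: zero truth value", call. = FALSE)
  mean(recon[region]) / truth_value
}

#' Pearson correlation (PC) between reconstruction and truth
#'
#' @param recon,truth per-node fields of equal length with non-zero
#'   standard deviation.
#' @export
pearson_correlation <- function(recon, truth) {
  if (length(recon) != length(truth)) stop_dim("fields must have equal length")
  if (sd(recon) == 0 || sd(truth) == 0)
    stop("metric error: zero variance makes the correlation undefined", call. = FALSE)
  cor(recon, truth)
}

#' Peak signal-to-noise ratio (PSNR, dB)
#'
#' 10 log10(MAX^2 / MSE) with MSE the mean squared error over all nodes and
#' MAX the maximum of the ground-truth field (so PSNR is comparable across
#' methods on one phantom). A perfect reconstruction is flagged `Inf`.
#'
#' @param recon,truth per-node fields of equal length.
#' @param max_value reference peak; default `max(abs(truth))`.
#' @export
psnr <- function(recon, truth, max_value = max(abs(truth))) {
  if (length(recon) != length(truth)) stop_dim("fields must have equal length")
  mse <- mean((recon - truth)^2)
  if (mse == 0) return(Inf)
  10 * log10(max_value^2 / mse)
}

#' Image-quality metrics for a reconstruction
#'
#' Computes AC, PC and PSNR per chromophore on the recovered concentration
#' changes against the ground truth changes. The AC activation region is
#' thresholded on the recovered change at 50% of its maximum magnitude; the
#' truth contrast is the truth value of largest magnitude.
#'
#' @param recon an `scdot_recon` or a matrix of recovered changes (nodes x
#'   chromophores).
#' @param truth an `scdot_chromophores` ground truth, a matrix of true
#'   changes, or (for a recon object carrying initial concentrations) the
#'   truth concentration field.
#' @param fraction AC threshold fraction.
#' @return an `scdot_metrics` data frame with one row per chromophore.
#' @export
recon_metrics <- function(recon, truth, fraction = 0.5) {
  if (inherits(recon, "scdot_recon")) {
    delta_rec <- recon$concentrations - recon$initial
    truth_conc <- if (inherits(truth, "scdot_chromophores")) truth$concentrations else as.matrix(truth)
    delta_true <- truth_conc - recon$initial
  } else {
    delta_rec <- as.matrix(recon)
    delta_true <- if (inherits(truth, "scdot_chromophores")) truth$concentrations else as.matrix(truth)
  }
  if (!identical(dim(delta_rec), dim(delta_true)))
    stop_dim("recovered and true fields must have equal shape")
  rows <- lapply(seq_len(ncol(delta_rec)), function(j) {
    dr <- delta_rec[, j]; dt <- delta_true[, j]
    region <- activation_region(dr, fraction)
    tv <- dt[which.max(abs(dt))]
    data.frame(chromophore = colnames(delta_rec)[j] %||% paste0("c", j),
               AC = if (length(region) && tv != 0) average_contrast(dr, tv, region) else NA_real_,
               PC = if (sd(dr) > 0 && sd(dt) > 0) cor(dr, dt) else NA_real_,
               PSNR = psnr(dr, dt),
               n_region = length(region))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("scdot_metrics", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.scdot_metrics <- function(x, ...) {
  cat("scdot image-quality metrics:\n")
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Write a metrics report as structured text
#'
#' @param metrics an `scdot_metrics`.
#' @param path file path (YAML).
#' @export
write_metrics <- function(metrics, path) {
  rows <- lapply(seq_len(nrow(metrics)), function(i) as.list(metrics[i, , drop = FALSE]))
  names(rows) <- metrics$chromophore
  yaml::write_yaml(rows, path)
  invisible(metrics)
}
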