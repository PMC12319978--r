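#' Signal-implanting specification
#'
#' A set of spatial maps and time courses whose product, scaled to a small
#' fraction of the data's temporal standard deviation, is added to real (or
#' synthetic) data to benchmark denoising models. "Scaled to x% of the
#' temporal standard deviation" uses the scan-global normalisation: the
#' spatial mean of the voxel-wise temporal SDs, which preserves the maps'
#' spatial shape.
#'
#' @param maps `n_voxels x K` matrix of spatial maps (masked voxels).
#' @param tcs `n_volumes x K` matrix of time courses.
#' @param scale Fraction of the data temporal SD, typically 0.03 or 0.06.
#' @param mask 3D logical mask locating the map voxels.
#' @return Object of class `implant_spec`.
#' @export
implant_spec <- function(maps, tcs, scale = 0.03, mask) {
  maps <- as.matrix(maps); tcs <- as.matrix(tcs)
  if (ncol(maps) != ncol(tcs)) stop("maps and tcs must agree in component count")
  if (nrow(maps) != sum(mask)) stop("maps rows must match mask voxels")
  if (all(maps == 0)) stop("degenerate implant: all-zero maps")
  if (scale < 0) stop("scale must be non-negative")
  structure(list(maps = maps, tcs = tcs, scale = scale, mask = mask),
            class = "implant_spec")
}

mean_temporal_sd <- function(Y) mean(apply(Y, 2, stats::sd))

#' Implant a known signal into a BOLD series
#'
#' Adds `scale x sd(data) / sd(product)` times the maps-by-time-courses
#' product to the data, so that the implanted signal's mean temporal SD is
#' exactly `scale` times that of the data. The ground-truth implant is
#' returned alongside.
#'
#' @param ts A [bold_ts()].
#' @param spec An [implant_spec()].
#' @return List with `ts` (the series plus implant) and `implant`
#'   (`n_volumes x n_voxels` ground-truth matrix over the spec mask).
#' @export
implant <- function(ts, spec) {
  stopifnot(inherits(spec, "implant_spec"))
  Y <- bold_matrix(ts, spec$mask)
  if (nrow(Y) != nrow(spec$tcs)) stop("time course length must match the series")
  sd_data <- mean_temporal_sd(Y)
  if (sd_data == 0) stop("zero-variance data")
  P <- spec$tcs %*% t(spec$maps)
  sd_imp <- mean_temporal_sd(P)
  imp <- if (spec$scale == 0 || sd_imp == 0) P * 0 else
    P * (spec$scale * sd_data / sd_imp)
  list(ts = bold_unmatrix(ts, Y + imp, spec$mask), implant = imp)
}

#' Signal-implanting test of a denoising model
#'
#' Implants the spec's signal into the series, denoises with the candidate
#' model, then estimates the component time courses by spatial regression of
#' the maps (plus an intercept map) against (a) the residual series and (b)
#' the removed series. The correlation between each vectorised
#' maps-by-estimated-time-courses product and the vectorised implant gives
#' the signal recovery statistic (from the residual) and the signal loss
#' statistic (from the removed component): high loss correlation means the
#' model inadvertently removes signal.
#'
#' @param ts A [bold_ts()].
#' @param spec An [implant_spec()].
#' @param model A [denoise_model()].
#' @return Object of class `implant_result`: list with `recovery_corr`,
#'   `loss_corr`, `tag`.
#' @export
implant_test <- function(ts, spec, model) {
  imp <- implant(ts, spec)
  fit <- denoise_fit(imp$ts, model, mask = spec$mask)
  X <- cbind(1, spec$maps)
  est_product <- function(series) {
    Y <- bold_matrix(series, spec$mask)
    tcs_est <- t(stats::lm.fit(X, t(Y))$coefficients[-1, , drop = FALSE])
    tcs_est %*% t(spec$maps)
  }
  rec <- stats::cor(as.vector(est_product(fit$residual)), as.vector(imp$implant))
  loss <- stats::cor(as.vector(est_product(fit$removed)), as.vector(imp$implant))
  structure(list(recovery_corr = rec, loss_corr = loss, tag = model$tag),
            class = "implant_result")
}

#' @export
print.implant_result <- function(x, ...) {
  cat("Signal-implanting test [", x$tag, "]\n", sep = "")
  cat(sprintf("  recovery correlation: %.3f\n", x$recovery_corr))
  cat(sprintf("  loss correlation:     %.3f\n", x$loss_corr))
  invisible(x)
}
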