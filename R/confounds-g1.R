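#' Discrete cosine detrending basis
#'
#' The first `n_comp` non-constant columns of the orthonormal type-II
#' discrete cosine basis over the scan duration; the k-th column completes
#' k/2 cycles over `n_volumes * tr` seconds. With the default cutoff of
#' 150 s this acts as a high-pass filter at 0.0067 Hz; for a 350-volume scan
#' at TR 2.2 s that yields 10 columns. The constant (DC) term is excluded —
#' GLMs built here carry an explicit intercept instead.
#'
#' @param n_volumes Number of volumes.
#' @param tr Repetition time (seconds).
#' @param n_comp Number of columns; default `floor(2 * n_volumes * tr /
#'   cutoff)`.
#' @param cutoff High-pass cutoff period in seconds (used only when
#'   `n_comp` is `NULL`).
#' @return `n_volumes x n_comp` matrix with orthonormal columns.
#' @export
dct_detrend_basis <- function(n_volumes, tr, n_comp = NULL, cutoff = 150) {
  if (is.null(n_comp)) n_comp <- floor(2 * n_volumes * tr / cutoff)
  n_comp <- as.integer(n_comp)
  if (n_comp >= n_volumes) stop("n_comp must be smaller than n_volumes")
  if (n_comp < 1L) stop("n_comp must be at least 1")
  t0 <- seq_len(n_volumes) - 0.5
  X <- vapply(seq_len(n_comp),
              function(k) sqrt(2 / n_volumes) * cos(pi * k * t0 / n_volumes),
              numeric(n_volumes))
  colnames(X) <- paste0("dct", seq_len(n_comp))
  X
}

#' Per-volume RMSD similarity series
#'
#' The censoring metric: for each volume t,
#' `d_t = sqrt( mean_i ((f_{t,i} - M_i) / M)^2 )` over mask voxels, where
#' `M_i` is the temporal median of voxel i and `M` the spatial mean of the
#' `M_i`. Scale-invariant: multiplying all intensities by a constant leaves
#' `d` unchanged.
#'
#' @param ts A [bold_ts()].
#' @param mask Optional 3D logical mask (defaults to the brain mask).
#' @return Numeric vector of length `n_volumes`.
#' @export
rmsd_series <- function(ts, mask = NULL) {
  Y <- bold_matrix(ts, mask)
  if (ncol(Y) == 0) stop("mask is empty")
  Mi <- apply(Y, 2, stats::median)
  M <- mean(Mi)
  if (M == 0) stop("degenerate intensities: spatial mean of temporal medians is 0")
  sqrt(rowMeans(sweep(Y, 2, Mi)^2) / M^2)
}

#' Volume censoring from the RMSD series
#'
#' A volume t is censored if `d_t - median(d) > threshold` (strict), and
#' every volume immediately following a threshold-censored volume is also
#' censored (without itself propagating further). Errors if all volumes
#' would be censored.
#'
#' @param d Per-volume RMSD values from [rmsd_series()].
#' @param threshold Censoring threshold (default 0.05).
#' @return Object of class `censor_mask`: list with `censored` (logical per
#'   volume), `d`, and `threshold`.
#' @export
censor_volumes <- function(d, threshold = 0.05) {
  if (threshold <= 0) stop("threshold must be positive")
  above <- (d - stats::median(d)) > threshold
  censored <- above
  follows <- which(above) + 1L
  follows <- follows[follows <= length(d)]
  censored[follows] <- TRUE
  if (all(censored)) stop("all volumes censored: unusable scan")
  structure(list(censored = censored, d = d, threshold = threshold),
            class = "censor_mask")
}

#' @export
print.censor_mask <- function(x, ...) {
  cat("Censor mask: ", sum(x$censored), " of ", length(x$censored),
      " volumes censored (threshold ", x$threshold, ")\n", sep = "")
  invisible(x)
}

#' Spike regressors for censored volumes
#'
#' One indicator column per censored volume (1 at that volume, 0 elsewhere).
#' In a GLM these equate each censored volume to the temporal average: the
#' residual at a censored volume is exactly zero.
#'
#' @param mask A [censor_volumes()] censor mask.
#' @return `n_volumes x n_censored` indicator matrix (0 columns if nothing
#'   is censored).
#' @export
spike_regressors <- function(mask) {
  stopifnot(inherits(mask, "censor_mask"))
  idx <- which(mask$censored)
  out <- matrix(0, length(mask$censored), length(idx))
  for (j in seq_along(idx)) out[idx[j], j] <- 1
  if (length(idx)) colnames(out) <- paste0("spike", idx - 1L)
  out
}

#' Voxel-wise confound map container
#'
#' @param data 4D array matching the target series shape.
#' @param kind One of `"folding"`, `"density"`, `"mp"`, `"mp_slice_diff"`.
#' @param provenance Free-text description.
#' @return Object of class `voxelwise_map`.
#' @export
voxelwise_map <- function(data, kind = c("folding", "density", "mp", "mp_slice_diff"),
                          provenance = "") {
  kind <- match.arg(kind)
  stopifnot(length(dim(data)) == 4L)
  if (!all(is.finite(data))) stop("confound map values must be finite")
  structure(list(data = data, kind = kind, provenance = provenance),
            class = "voxelwise_map")
}

#' @export
print.voxelwise_map <- function(x, ...) {
  cat("Voxel-wise confound map (", x$kind, "): ",
      paste(dim(x$data), collapse = " x "), "\n", sep = "")
  if (nzchar(x$provenance)) cat("  ", x$provenance, "\n", sep = "")
  invisible(x)
}

#' Folding maps: time courses of simultaneously acquired voxels
#'
#' For each of the `mb_factor - 1` partner offsets, assigns to every voxel
#' the time course of the voxel simultaneously acquired with it (same
#' in-plane location, partner slice), capturing residual multiband leakage.
#' The positional shift is applied in acquisition space; the supplied
#' transform then brings the maps into the anatomically consistent space
#' with the same interpolation as applied to the data.
#'
#' @param ts A [bold_ts()] in acquisition space.
#' @param scheme An [acq_scheme()].
#' @param xform Optional [spatial_transform()]; `NULL` keeps the maps in
#'   acquisition space.
#' @return List of `mb_factor - 1` [voxelwise_map()] objects (empty for
#'   MB = 1).
#' @export
folding_maps <- function(ts, scheme, xform = NULL) {
  if (ts$space != "acquisition")
    stop("folding maps must be formed in acquisition space")
  if (scheme$mb_factor == 1L) return(list())
  if (dim(ts$data)[3] != scheme$n_slices)
    stop("slice count does not match the scheme")
  ne <- scheme$n_excitations
  out <- vector("list", scheme$mb_factor - 1L)
  for (k in seq_len(scheme$mb_factor - 1L)) {
    shifted <- ts$data
    src <- ((seq_len(scheme$n_slices) - 1L + k * ne) %% scheme$n_slices) + 1L
    shifted <- ts$data[, , src, , drop = FALSE]
    if (!is.null(xform))
      shifted <- apply_transform(shifted, xform, scheme, ts$affine)
    out[[k]] <- voxelwise_map(shifted, "folding",
                              paste0("partner offset +", k * ne, " slices"))
  }
  out
}

#' Density map: transformed uniform image carrying the Jacobian modulation
#'
#' Pushes a 4D image of uniform unit intensity through the distortion- and
#' motion-correction transform, scaling by the Jacobian modulation, so the
#' resulting confound map carries any temporal dependence induced by the
#' correction itself.
#'
#' @param xform A [spatial_transform()].
#' @param shape Spatial shape `c(nx, ny, n_slices)`.
#' @param n_volumes Number of volumes.
#' @param scheme An [acq_scheme()].
#' @param affine Voxel-to-world matrix.
#' @return A [voxelwise_map()] of kind `"density"`.
#' @export
density_map <- function(xform, shape, n_volumes, scheme,
                        affine = diag(c(2.2, 2.2, 2.2, 1))) {
  if (!all(xform$jacobian > 0)) stop("jacobian modulation must be positive everywhere")
  ones <- array(1, c(shape, n_volumes))
  voxelwise_map(apply_transform(ones, xform, scheme, affine), "density",
                "uniform image under distortion/motion correction + modulation")
}
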