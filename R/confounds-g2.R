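#' Motion-parameter voxel-wise maps
#'
#' Builds the 12 motion-parameter (MP) confound maps: for each of the 6
#' rigid parameters, the per-excitation value is broadcast to all voxels of
#' that excitation's slices; the other 6 are the corresponding differentials
#' in the slice direction, computed as `S_{t+1} - S_t` on the simultaneously
#' excited slice-state rearrangement of the series (before any transform),
#' enriching the regressors with dynamics along the intrinsic dimension of
#' spin-history effects. When a transform is supplied, the maps are
#' resampled into the anatomically consistent space, after which values are
#' no longer identical within a slice.
#'
#' Without a transform the maps are stored compactly (one series per
#' excitation), since all voxels of an excitation share the same values.
#'
#' @param motion A [motion_trace()] (`n_volumes x n_excitations x 6`).
#' @param scheme An [acq_scheme()].
#' @param xform Optional [spatial_transform()].
#' @param shape Spatial shape, required when `xform` is supplied.
#' @param affine Voxel-to-world matrix for the resampling.
#' @return Object of class `mp_maps`: compact (`$values`, an
#'   `n_volumes x n_excitations x 12` array) or expanded (`$maps`, a list of
#'   12 [voxelwise_map()]).
#' @export
mp_voxel_maps <- function(motion, scheme, xform = NULL, shape = NULL,
                          affine = diag(c(2.2, 2.2, 2.2, 1))) {
  stopifnot(inherits(motion, "motion_trace"))
  d <- dim(motion)
  if (d[2] != scheme$n_excitations)
    stop("motion trace excitation count does not match the scheme")
  nv <- d[1]; ne <- d[2]
  vals <- array(0, c(nv, ne, 12))
  vals[, , 1:6] <- unclass(motion)
  # slice differentials on the acquisition-state sequence S_1..S_{nv*ne}:
  # state k = (t-1)*ne + e carries S_{k+1} - S_k; the final state gets 0
  for (p in 1:6) {
    s <- as.vector(t(unclass(motion)[, , p]))      # state order, excitation fastest
    ds <- c(diff(s), 0)
    vals[, , 6 + p] <- matrix(ds, nv, ne, byrow = TRUE)
  }
  obj <- structure(list(values = vals, scheme = scheme, compact = TRUE),
                   class = "mp_maps")
  if (is.null(xform)) return(obj)
  if (is.null(shape)) stop("shape is required to expand MP maps under a transform")
  kinds <- c(rep("mp", 6), rep("mp_slice_diff", 6))
  maps <- vector("list", 12)
  for (p in 1:12) {
    arr <- array(0, c(shape, nv))
    for (e in seq_len(ne) - 1L)
      for (s in scheme$order[[e + 1L]])
        arr[, , s + 1L, ] <- rep(vals[, e + 1L, p], each = shape[1] * shape[2])
    arr <- apply_transform(arr, xform, scheme, affine)
    maps[[p]] <- voxelwise_map(arr, kinds[p], paste0("MP ", p))
  }
  structure(list(maps = maps, scheme = scheme, compact = FALSE), class = "mp_maps")
}

#' Rearrange a 4D map into the slice-state series (and back)
#'
#' Rearranges a volume-ordered 4D array into the simultaneously excited
#' slices-to-slices sequence `S_1, S_2, ..., S_{n_volumes x n_excitations}`,
#' each state holding the voxels of one excitation's slices. The operation is
#' exactly invertible via [slice_restore()].
#'
#' @param map4d 4D array (x, y, slice, volume).
#' @param scheme An [acq_scheme()].
#' @return `n_states x (nx * ny * mb_factor)` matrix, one row per state, in
#'   acquisition order (excitation fastest).
#' @export
slice_rearrange <- function(map4d, scheme) {
  d <- dim(map4d)
  stopifnot(length(d) == 4L)
  if (d[3] != scheme$n_slices) stop("slice count does not match the scheme")
  nv <- d[4]; ne <- scheme$n_excitations
  out <- matrix(0, nv * ne, d[1] * d[2] * scheme$mb_factor)
  for (t in seq_len(nv))
    for (e in seq_len(ne) - 1L)
      out[(t - 1L) * ne + e + 1L, ] <-
        as.vector(map4d[, , scheme$order[[e + 1L]] + 1L, t])
  out
}

#' @rdname slice_rearrange
#' @param states Matrix produced by [slice_rearrange()].
#' @param shape Spatial shape `c(nx, ny, n_slices)`.
#' @export
slice_restore <- function(states, scheme, shape) {
  ne <- scheme$n_excitations
  nv <- nrow(states) %/% ne
  out <- array(0, c(shape, nv))
  for (t in seq_len(nv))
    for (e in seq_len(ne) - 1L)
      out[, , scheme$order[[e + 1L]] + 1L, t] <-
        array(states[(t - 1L) * ne + e + 1L, ],
              c(shape[1], shape[2], scheme$mb_factor))
  out
}

mp_series_compact <- function(maps, excitation) {
  cbind(maps$values[, excitation + 1L, 1:6, drop = TRUE],
        maps$values[, excitation + 1L, 7:12, drop = TRUE])
}

mp_series_voxel <- function(maps, voxel) {
  vapply(maps$maps, function(m) m$data[voxel[1], voxel[2], voxel[3], ],
         numeric(dim(maps$maps[[1]]$data)[4]))
}

# backward volume difference, zero-padded at the first volume
diff_v <- function(X) rbind(0, diff(X))

#' 60-column MP regressor design for one voxel
#'
#' Builds the complete per-voxel MP regressor set from the 12 MP series: the
#' 6 parameter values, their squares, first- and second-order volume
#' differentials with squares, the slice differentials with squares, and the
#' volume differential of the slice differentials with squares — 10 blocks
#' of 6, i.e. 60 columns.
#'
#' @param maps An [mp_voxel_maps()] object.
#' @param voxel For compact maps, a 0-based excitation index (scalar); for
#'   expanded maps, a voxel index `c(x, y, slice)` (1-based).
#' @return `n_volumes x 60` matrix (raw, not yet z-scored).
#' @export
mp_design <- function(maps, voxel) {
  stopifnot(inherits(maps, "mp_maps"))
  ser <- if (maps$compact) {
    stopifnot(length(voxel) == 1L)
    mp_series_compact(maps, as.integer(voxel))
  } else {
    stopifnot(length(voxel) == 3L)
    mp_series_voxel(maps, voxel)
  }
  if (nrow(ser) < 3L) stop("at least 3 volumes are required for second differentials")
  M <- ser[, 1:6, drop = FALSE]
  Ds <- ser[, 7:12, drop = FALSE]
  DvM <- diff_v(M)
  D2vM <- diff_v(DvM)
  DvDs <- diff_v(Ds)
  blocks <- list(M, M^2, DvM, DvM^2, D2vM, D2vM^2, Ds, Ds^2, DvDs, DvDs^2)
  X <- do.call(cbind, blocks)
  colnames(X) <- paste0(rep(c("m", "m2", "dv", "dv2", "d2v", "d2v2",
                              "ds", "ds2", "dvds", "dvds2"), each = 6),
                        "_p", rep(1:6, 10))
  X
}

#' Z-score design columns over non-censored volumes
#'
#' Statistics are computed over non-censored volumes only and applied to all
#' volumes; all-zero (degenerate) columns are left at zero and flagged.
#'
#' @param X Design matrix.
#' @param censor Optional [censor_volumes()] mask.
#' @return Matrix with attribute `degenerate` (logical per column).
#' @export
mp_zscore <- function(X, censor = NULL) {
  keep <- if (is.null(censor)) rep(TRUE, nrow(X)) else !censor$censored
  mu <- colMeans(X[keep, , drop = FALSE])
  sd <- apply(X[keep, , drop = FALSE], 2, stats::sd)
  degenerate <- !is.finite(sd) | sd < .Machine$double.eps^0.5
  Z <- sweep(X, 2, mu)
  Z[, !degenerate] <- sweep(Z[, !degenerate, drop = FALSE], 2, sd[!degenerate], "/")
  Z[, degenerate] <- 0
  attr(Z, "degenerate") <- degenerate
  Z
}

#' Per-voxel MP regressor stack
#'
#' Assembles the z-scored 60-column MP design for every distinct voxel
#' group. Without a spatial transform all voxels of an excitation share one
#' design, so the stack holds `n_excitations` designs plus the voxel-to-group
#' map; with expanded maps each masked voxel gets its own design.
#'
#' @param maps An [mp_voxel_maps()] object.
#' @param censor Optional [censor_volumes()] mask (z-scoring statistics use
#'   non-censored volumes only).
#' @param mask 3D logical mask (required for expanded maps; for compact maps
#'   it only defines the voxel-to-group lookup).
#' @return Object of class `mp_regressor_stack` with `$designs` (list of
#'   `n_volumes x 60` matrices), `$n_columns = 60`, and `$group_of_slice`
#'   (compact) or `$voxels` (expanded).
#' @export
mp_stack <- function(maps, censor = NULL, mask = NULL) {
  stopifnot(inherits(maps, "mp_maps"))
  if (maps$compact) {
    ne <- maps$scheme$n_excitations
    designs <- lapply(seq_len(ne) - 1L,
                      function(e) mp_zscore(mp_design(maps, e), censor))
    structure(list(designs = designs, n_columns = 60L,
                   group_of_slice = excitation_of(seq_len(maps$scheme$n_slices) - 1L,
                                                  maps$scheme) + 1L,
                   scheme = maps$scheme, compact = TRUE),
              class = "mp_regressor_stack")
  } else {
    if (is.null(mask)) stop("mask is required for expanded MP maps")
    vox <- which(mask, arr.ind = TRUE)
    designs <- lapply(seq_len(nrow(vox)),
                      function(i) mp_zscore(mp_design(maps, vox[i, ]), censor))
    structure(list(designs = designs, n_columns = 60L, voxels = vox,
                   scheme = maps$scheme, compact = FALSE),
              class = "mp_regressor_stack")
  }
}

#' @export
print.mp_regressor_stack <- function(x, ...) {
  cat("MP regressor stack: ", length(x$designs),
      if (x$compact) " excitation-wise" else " voxel-wise",
      " designs of ", x$n_columns, " columns\n", sep = "")
  invisible(x)
}

#' PCA reduction of an MP design
#'
#' Fits PCA on the non-censored volumes of a (z-scored) design and retains
#' the smallest number of components whose cumulative explained variance
#' reaches `var_kept`; loadings are applied to the full-length columns so
#' the reduced design covers all volumes. An all-degenerate design yields 0
#' components.
#'
#' @param X `n_volumes x p` design matrix (use [mp_zscore()] output), or an
#'   `mp_regressor_stack` to reduce every group design.
#' @param censor Optional [censor_volumes()] mask.
#' @param var_kept Fraction of variance to retain (default 0.99).
#' @return For a matrix: list with `scores` (`n_volumes x k`),
#'   `n_components`, `explained`. For a stack: the stack with `$designs`
#'   replaced by score matrices, `$n_components` per group and
#'   `$mean_components` (their spatial mean over groups).
#' @export
mp_pca <- function(X, censor = NULL, var_kept = 0.99) {
  if (inherits(X, "mp_regressor_stack")) {
    red <- lapply(X$designs, mp_pca, censor = censor, var_kept = var_kept)
    X$designs <- lapply(red, `[[`, "scores")
    X$n_components <- vapply(red, `[[`, integer(1), "n_components")
    X$mean_components <- mean(X$n_components)
    return(X)
  }
  keep <- if (is.null(censor)) rep(TRUE, nrow(X)) else !censor$censored
  if (sum(keep) < 2L) stop("at least 2 non-censored volumes are required")
  Xk <- X[keep, , drop = FALSE]
  Xk <- sweep(Xk, 2, colMeans(Xk))
  sv <- svd(Xk)
  ev <- sv$d^2
  if (sum(ev) < .Machine$double.eps)
    return(list(scores = matrix(0, nrow(X), 0), n_components = 0L,
                explained = numeric(0)))
  cum <- cumsum(ev) / sum(ev)
  tol <- max(dim(Xk)) * .Machine$double.eps * sv$d[1]
  rank <- sum(sv$d > tol)
  k <- min(which(cum >= var_kept - 1e-12), rank)
  scores <- sweep(X, 2, colMeans(Xk)) %*% sv$v[, seq_len(k), drop = FALSE]
  colnames(scores) <- paste0("mp_pc", seq_len(k))
  list(scores = scores, n_components = as.integer(k), explained = cum[seq_len(k)])
}

#' Data-derived non-grey-matter ICA regressors
#'
#' Runs spatial ICA on the time courses within the WM + CSF mask (eroded by
#' one voxel, 6-connectivity, to reduce partial voluming), after the series
#' has been residualised against the Group 1 design. The component time
#' courses serve as data-derived nuisance regressors. Dimensionality is
#' either fixed or estimated by the Minka Laplace-evidence criterion, capped
#' at `cap` components.
#'
#' @param ts A [bold_ts()] (already residualised, or supply `g1_design`).
#' @param wm_csf_mask 3D logical mask of WM + ventricular/subarachnoid CSF.
#' @param dim `"auto"` or an integer dimensionality (e.g. 6 or 24).
#' @param g1_design Optional matrix of Group 1 regressors to residualise
#'   against first (an intercept is always included).
#' @param seed Integer seed (ICA is deterministic given the seed).
#' @param cap Upper bound for the automatic dimensionality (default 90).
#' @return List with `tcs` (`n_volumes x K` unit-variance time courses),
#'   `maps` (`K x n_mask_voxels` spatial maps), `dim` (K) and `mask` (the
#'   eroded mask).
#' @export
nongm_ica <- function(ts, wm_csf_mask, dim = "auto", g1_design = NULL,
                      seed = 1L, cap = 90L) {
  er <- erode_mask(wm_csf_mask)
  if (!any(er)) stop("WM/CSF mask is empty after one-voxel erosion")
  Y <- bold_matrix(ts, er)
  X <- cbind(intercept = rep(1, nrow(Y)), g1_design)
  Y <- stats::lm.fit(X, Y)$residuals
  K <- if (identical(dim, "auto")) {
    C <- Y %*% t(Y) / ncol(Y)
    spec <- pmax(eigen(C, symmetric = TRUE, only.values = TRUE)$values, 0)
    rank <- sum(spec > 1e-10 * spec[1])
    min(minka_dimension(spec, n_samples = ncol(Y)), cap, rank - 1L)
  } else as.integer(dim)
  if (K < 1L) stop("ICA dimensionality must be at least 1")
  ic <- spatial_ica(Y, K, seed = seed)
  tcs <- scale(ic$tcs)
  attr(tcs, "scaled:center") <- attr(tcs, "scaled:scale") <- NULL
  colnames(tcs) <- paste0("nongm", seq_len(K))
  list(tcs = tcs, maps = ic$maps, dim = K, mask = er)
}
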