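#' Slab-artefact component estimation (single-subject spatial ICA)
#'
#' Estimates candidate sampling-scheme artefact components: the series
#' (already residualised against the Group 1 + Group 2 model) is lightly
#' smoothed with a 1 mm FWHM 3D Gaussian and decomposed by single-subject
#' spatial ICA with dimensionality 30. Components whose maps show slab-like
#' patterns repeating across the multiband stack width (`n_excitations`
#' slices) are candidates for removal; rating is manual (two raters), with
#' [slab_score()] available as an advisory aid only.
#'
#' @param ts A [bold_ts()] in the anatomically consistent space.
#' @param fwhm Smoothing FWHM in mm (0 disables smoothing).
#' @param dim Number of components (default 30).
#' @param seed Integer seed.
#' @param mask Optional 3D logical mask (defaults to the brain mask).
#' @return Object of class `component_set`: `maps` (`dim x n_voxels`, unit
#'   norm), `tcs` (`n_volumes x dim`), `labels` (all `"unrated"`), `mask`.
#' @export
g3_ica <- function(ts, fwhm = 1, dim = 30L, seed = 1L, mask = NULL) {
  if (is.null(mask)) mask <- ts$brain_mask
  if (sum(mask) < dim) stop("fewer mask voxels than components")
  voxdim <- sqrt(colSums(ts$affine[1:3, 1:3]^2))
  data <- if (fwhm > 0) gaussian_smooth(ts$data, fwhm, voxdim) else ts$data
  sm <- ts; sm$data <- data
  Y <- bold_matrix(sm, mask)
  ic <- spatial_ica(Y, dim, seed = seed)
  structure(list(maps = ic$maps, tcs = ic$tcs,
                 labels = rep("unrated", dim), mask = mask),
            class = "component_set")
}

#' @export
print.component_set <- function(x, ...) {
  cat("Component set: ", nrow(x$maps), " components over ",
      ncol(x$maps), " voxels\n", sep = "")
  cat("  labels: ", paste(sprintf("%s=%d", names(table(x$labels)),
                                  table(x$labels)), collapse = ", "), "\n", sep = "")
  invisible(x)
}

RATING_LEVELS <- c("remove", "equivocal", "keep", "unrated")

#' Two-rater consensus removal rule
#'
#' A component enters the removal set if it was rated `"remove"` by both
#' raters, or `"remove"` by one and `"equivocal"` by the other.
#'
#' @param labels_rater1,labels_rater2 Character vectors of per-component
#'   ratings (`"remove"`, `"equivocal"`, `"keep"`).
#' @return Integer vector of component indices (1-based) to remove.
#' @export
consensus <- function(labels_rater1, labels_rater2) {
  if (length(labels_rater1) != length(labels_rater2))
    stop("rater label vectors must have equal length")
  bad <- setdiff(unique(c(labels_rater1, labels_rater2)), RATING_LEVELS)
  if (length(bad)) stop("unknown rating label(s): ", paste(bad, collapse = ", "))
  both <- labels_rater1 == "remove" & labels_rater2 == "remove"
  mixed <- (labels_rater1 == "remove" & labels_rater2 == "equivocal") |
    (labels_rater1 == "equivocal" & labels_rater2 == "remove")
  which(both | mixed)
}

#' Partial regression removal of flagged components
#'
#' Because component time courses are not constrained to be orthogonal, the
#' regression coefficients of the components to remove are estimated jointly
#' with all other components' time courses (plus an intercept); only the
#' flagged components' fitted contribution is subtracted.
#'
#' @param ts A [bold_ts()].
#' @param component_tcs `n_volumes x K` matrix of all component time courses.
#' @param flagged Integer indices (1-based) of components to remove; empty
#'   returns the series unchanged.
#' @param mask Optional 3D logical mask (defaults to the brain mask).
#' @return The residual [bold_ts()].
#' @export
partial_regress_out <- function(ts, component_tcs, flagged, mask = NULL) {
  K <- ncol(component_tcs)
  flagged <- as.integer(flagged)
  if (length(flagged) && (min(flagged) < 1L || max(flagged) > K))
    stop("flagged indices out of range")
  if (length(flagged) == 0L) return(ts)
  if (is.null(mask)) mask <- ts$brain_mask
  X <- cbind(1, component_tcs)
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) {
    drop_cols <- qrx$pivot[-seq_len(qrx$rank)] - 1L   # excluding intercept
    stop("rank-deficient component design; collinear columns: ",
         paste(drop_cols, collapse = ", "))
  }
  Y <- bold_matrix(ts, mask)
  beta <- qr.coef(qrx, Y)
  removed <- X[, flagged + 1L, drop = FALSE] %*% beta[flagged + 1L, , drop = FALSE]
  bold_unmatrix(ts, Y - removed, mask)
}

#' Advisory slab score of a spatial map
#'
#' Fraction of the spectral power of the map's slice profile (in-plane mean
#' per slice, demeaned) concentrated at a spatial period of `n_excitations`
#' slices, i.e. at `mb_factor` cycles across the stack — the signature of a
#' sampling-scheme slab artefact. Purely advisory: it never removes
#' components; removal requires rater consensus.
#'
#' @param map 3D array (or a vector over a component set's mask placed back
#'   in 3D by the caller).
#' @param scheme An [acq_scheme()].
#' @return Scalar in `[0, 1]` (0 for a flat map).
#' @export
slab_score <- function(map, scheme) {
  stopifnot(length(dim(map)) == 3L)
  profile <- apply(map, 3, mean)
  profile <- profile - mean(profile)
  if (sum(profile^2) < .Machine$double.eps) return(0)
  p <- Mod(stats::fft(profile))^2
  n <- length(profile)
  half <- p[2:(floor(n / 2) + 1)]
  target <- scheme$mb_factor            # mb cycles <=> period n_excitations slices
  if (target > length(half)) return(0)
  half[target] / sum(half)
}
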