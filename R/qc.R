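#' Temporal signal-to-noise ratio
#'
#' Per-voxel `M_i / SD_i` over the uncensored volumes, where `M_i` is the
#' temporal mean and `SD_i` the population standard deviation (divide by T),
#' plus the spatial mean over the (tight) mask. Voxels with `SD_i = 0` are
#' excluded from the spatial mean and flagged.
#'
#' @param ts A [bold_ts()].
#' @param mask 3D logical mask (a tight anatomical mask excluding non-brain
#'   tissue); defaults to the brain mask.
#' @param censor Optional [censor_volumes()] mask; censored volumes are
#'   disregarded.
#' @return List with `map` (3D array, `NA` outside the mask and at zero-SD
#'   voxels), `mean` (spatial mean TSNR), `n_zero_sd` (flagged voxel count).
#' @export
tsnr <- function(ts, mask = NULL, censor = NULL) {
  if (is.null(mask)) mask <- ts$brain_mask
  keep <- if (is.null(censor)) rep(TRUE, n_volumes(ts)) else !censor$censored
  if (sum(keep) < 2L) stop("at least 2 uncensored volumes are required")
  Y <- bold_matrix(ts, mask)[keep, , drop = FALSE]
  T <- nrow(Y)
  Mi <- colMeans(Y)
  SDi <- sqrt(colMeans(Y^2) - Mi^2)
  val <- ifelse(SDi > 0, Mi / SDi, NA_real_)
  map <- array(NA_real_, dim(ts$data)[1:3])
  map[mask] <- val
  list(map = map, mean = mean(val, na.rm = TRUE), n_zero_sd = sum(SDi == 0))
}

#' DVARS: mean RMS frame-to-frame intensity difference
#'
#' Mean over consecutive pairs of uncensored volumes of
#' `sqrt(mean_i (f_{t,i} - f_{t-1,i})^2)`; pairs with a censored member are
#' disregarded.
#'
#' @inheritParams tsnr
#' @return Scalar DVARS value.
#' @export
dvars <- function(ts, mask = NULL, censor = NULL) {
  if (is.null(mask)) mask <- ts$brain_mask
  keep <- if (is.null(censor)) rep(TRUE, n_volumes(ts)) else !censor$censored
  pairs <- which(keep[-1] & keep[-length(keep)])   # t-1 index of valid (t-1, t)
  if (length(pairs) == 0L) stop("no consecutive pair of uncensored volumes")
  Y <- bold_matrix(ts, mask)
  mean(sqrt(rowMeans((Y[pairs + 1L, , drop = FALSE] - Y[pairs, , drop = FALSE])^2)))
}

#' Scan-level pass/fail decision from visual scores, DVARS and TSNR
#'
#' Implements the combined decision rule. Over the subset of scans with
#' visual score > 1 (high score), outlier fences are computed per metric
#' using the 25th/75th percentiles and 1.5 x IQR (linear-interpolation
#' percentiles). High-score scans pass unless they are positive `dvars`
#' outliers (`dvars > P75 + 1.5 IQR`) or negative `tsnr` outliers
#' (`tsnr < P25 - 1.5 IQR`). Low-score scans (score <= 1) are rescued and
#' pass if both their `dvars < P75` and `tsnr > P25` of the high-score
#' subset.
#'
#' @param records Data frame with columns `visual_score` (integer 0-4),
#'   `dvars`, `mean_tsnr`.
#' @return The data frame with added logical `pass` and character `reason`
#'   columns, in the input row order.
#' @export
qc_decide <- function(records) {
  need <- c("visual_score", "dvars", "mean_tsnr")
  if (!all(need %in% names(records)))
    stop("records must have columns: ", paste(need, collapse = ", "))
  high <- records$visual_score > 1
  if (sum(high) < 4L)
    stop("at least 4 high-score (visual score > 1) records are required")
  qd <- stats::quantile(records$dvars[high], c(0.25, 0.75), type = 7)
  qt <- stats::quantile(records$mean_tsnr[high], c(0.25, 0.75), type = 7)
  iqr_d <- qd[2] - qd[1]
  iqr_t <- qt[2] - qt[1]
  dvars_out <- records$dvars > qd[2] + 1.5 * iqr_d
  tsnr_out <- records$mean_tsnr < qt[1] - 1.5 * iqr_t

  pass <- logical(nrow(records))
  reason <- character(nrow(records))
  pass[high] <- !(dvars_out[high] | tsnr_out[high])
  reason[high & pass] <- "high score, no metric outlier"
  reason[high & !pass & dvars_out] <- "high score but positive dvars outlier"
  reason[high & !pass & tsnr_out & !dvars_out] <- "high score but negative tsnr outlier"
  rescue <- !high & records$dvars < qd[2] & records$mean_tsnr > qt[1]
  pass[!high] <- rescue[!high]
  reason[!high & pass] <- "low score rescued: dvars < P75 and tsnr > P25"
  reason[!high & !pass] <- "low score, metrics not within rescue bounds"
  records$pass <- pass
  records$reason <- reason
  records
}
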