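#' Denoising model specification
#'
#' Bundles the shared design matrix (applied to every voxel) with optional
#' voxel-specific designs for the per-voxel GLM engine. Voxel-specific
#' designs are supplied per group of voxels sharing a design: either an
#' [mp_stack()]/[mp_pca()] regressor stack, or an explicit list of matrices
#' plus a voxel-to-group map, or a function `voxel_design(i)` returning the
#' design of the i-th masked voxel.
#'
#' @param shared `n_volumes x p` matrix of shared regressors (the intercept
#'   is added automatically at fit time; do not include one).
#' @param voxel_designs Optional list of `n_volumes x q_g` matrices, one per
#'   group, or a function of the masked-voxel index.
#' @param groups Integer vector mapping each masked voxel to an entry of
#'   `voxel_designs` (ignored when `voxel_designs` is a function).
#' @param tag Model label, e.g. `"mcdc"`, `"G1"`, `"G1+2"`, `"G1+2+3"`.
#' @return Object of class `denoise_model`.
#' @export
denoise_model <- function(shared = NULL, voxel_designs = NULL, groups = NULL,
                          tag = "model") {
  if (!is.null(shared)) {
    shared <- as.matrix(shared)
    if (!all(is.finite(shared))) stop("shared design must be finite")
  }
  if (is.list(voxel_designs) && is.null(groups))
    stop("groups must map voxels to the voxel_designs list")
  structure(list(shared = shared, voxel_designs = voxel_designs,
                 groups = groups, tag = tag),
            class = "denoise_model")
}

#' @export
print.denoise_model <- function(x, ...) {
  cat("Denoising model [", x$tag, "]: ",
      if (is.null(x$shared)) 0 else ncol(x$shared), " shared regressors",
      if (!is.null(x$voxel_designs)) " + voxel-specific designs", "\n", sep = "")
  invisible(x)
}

fit_group <- function(X, Y, tol = 1e-10) {
  # pivoted QR; collinear columns dropped, rank recorded
  qrx <- qr(X, tol = tol)
  r <- qrx$rank
  fitted <- qr.fitted(qrx, Y)
  beta <- qr.coef(qrx, Y)
  dropped <- integer(0)
  if (r < ncol(X)) {
    dropped <- qrx$pivot[-seq_len(r)]
    beta[dropped, ] <- 0          # coefficients of dropped columns
    beta[is.na(beta)] <- 0
  }
  list(fitted = fitted, beta = beta, rank = r, dropped = dropped)
}

#' Fit a denoising model voxel-wise
#'
#' Ordinary least squares of every masked voxel's time course on the
#' concatenation of intercept, shared design and (if present) the voxel's
#' group-specific design. Returns residual and removed components satisfying
#' `residual + removed + intercept fit = input` exactly, with the residual
#' orthogonal to the design columns. Rank-deficient designs have their
#' collinear columns dropped with a warning; the per-voxel degrees of
#' freedom lost equal the design rank (intercept and spike columns
#' included).
#'
#' @param ts A [bold_ts()].
#' @param model A [denoise_model()].
#' @param mask Optional 3D logical mask (defaults to the brain mask).
#' @return Object of class `denoise_fit` with fields `residual` and
#'   `removed` ([bold_ts()] objects), `intercept_fit` (matrix), `dof_lost`
#'   (per masked voxel), `tag`, `mask`, `n_volumes`.
#' @export
denoise_fit <- function(ts, model, mask = NULL) {
  stopifnot(inherits(ts, "bold_ts"), inherits(model, "denoise_model"))
  if (is.null(mask)) mask <- ts$brain_mask
  Y <- bold_matrix(ts, mask)
  nt <- nrow(Y); nv <- ncol(Y)
  if (!is.null(model$shared) && nrow(model$shared) != nt)
    stop("shared design has ", nrow(model$shared), " rows; series has ", nt, " volumes")
  shared <- cbind(intercept = rep(1, nt), model$shared)

  resid <- matrix(0, nt, nv)
  removed <- matrix(0, nt, nv)
  icept <- matrix(0, nt, nv)
  dof <- integer(nv)
  any_dropped <- FALSE

  get_design <- function(g) {
    vd <- model$voxel_designs
    if (is.null(vd)) NULL
    else if (is.function(vd)) vd(g)
    else vd[[g]]
  }

  groups <- if (is.null(model$voxel_designs)) rep(1L, nv)
  else if (is.function(model$voxel_designs)) seq_len(nv)
  else {
    if (length(model$groups) != nv)
      stop("groups length (", length(model$groups), ") must match masked voxels (", nv, ")")
    model$groups
  }

  for (g in unique(groups)) {
    cols <- which(groups == g)
    Xg <- cbind(shared, get_design(g))
    if (ncol(Xg) > nt - 1L)
      stop("design has ", ncol(Xg), " regressors for ", nt, " volumes")
    f <- fit_group(Xg, Y[, cols, drop = FALSE])
    if (length(f$dropped)) any_dropped <- TRUE
    fitted <- f$fitted
    ic <- outer(Xg[, 1], as.vector(f$beta[1, ]))
    resid[, cols] <- Y[, cols, drop = FALSE] - fitted
    icept[, cols] <- ic
    removed[, cols] <- fitted - ic
    dof[cols] <- f$rank
  }
  if (any_dropped)
    warning("rank-deficient design(s): collinear columns dropped")

  res_ts <- bold_unmatrix(ts, resid, mask)
  rem_ts <- ts; rem_ts$data[] <- 0
  rem_ts <- bold_unmatrix(rem_ts, removed, mask)
  structure(list(residual = res_ts, removed = rem_ts, intercept_fit = icept,
                 dof_lost = dof, tag = model$tag, mask = mask, n_volumes = nt),
            class = "denoise_fit")
}

#' @export
print.denoise_fit <- function(x, ...) {
  cat("Denoise fit [", x$tag, "]: ", sum(x$mask), " voxels, ",
      x$n_volumes, " volumes\n", sep = "")
  cat("  DOFs lost per voxel: mean ", round(mean(x$dof_lost), 2),
      " (", round(100 * mean(x$dof_lost) / x$n_volumes, 1), "% of volumes)\n",
      sep = "")
  invisible(x)
}

#' @export
summary.denoise_fit <- function(object, ...) {
  rv <- apply(bold_matrix(object$residual, object$mask), 2, stats::var)
  out <- list(tag = object$tag,
              dof = dof_report(object),
              residual_variance = summary(rv))
  class(out) <- "summary.denoise_fit"
  out
}

#' @export
print.summary.denoise_fit <- function(x, ...) {
  cat("Model:", x$tag, "\n")
  cat("Mean DOFs lost:", round(x$dof$mean_dof_lost, 2),
      sprintf("(%.1f%% of volumes)\n", 100 * x$dof$fraction_of_volumes))
  cat("Residual variance across voxels:\n")
  print(x$residual_variance)
  invisible(x)
}

#' @export
residuals.denoise_fit <- function(object, ...) object$residual

#' @export
fitted.denoise_fit <- function(object, ...) object$removed

#' Denoised series with the voxel means restored
#'
#' The residual plus the intercept fit: the temporally filtered data as a
#' user would consume it (confound contributions removed, baseline signal
#' level kept, so TSNR remains interpretable).
#'
#' @param fit A [denoise_fit()].
#' @return A [bold_ts()].
#' @export
denoised_series <- function(fit) {
  stopifnot(inherits(fit, "denoise_fit"))
  Y <- bold_matrix(fit$residual, fit$mask) + fit$intercept_fit
  bold_unmatrix(fit$residual, Y, fit$mask)
}

#' Degrees-of-freedom report
#'
#' @param result A [denoise_fit()].
#' @return List with `dof_lost` (per voxel), `mean_dof_lost`, and
#'   `fraction_of_volumes` (mean DOFs lost over the number of volumes).
#' @export
dof_report <- function(result) {
  stopifnot(inherits(result, "denoise_fit"))
  list(dof_lost = result$dof_lost,
       mean_dof_lost = mean(result$dof_lost),
       fraction_of_volumes = mean(result$dof_lost) / result$n_volumes)
}
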