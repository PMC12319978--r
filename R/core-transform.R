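#' Spatial transform: per-excitation rigid motion, distortion and modulation
#'
#' Bundles the operators that map an image from the native acquisition space
#' into the anatomically consistent space: per-excitation rigid states
#' (3 rotations in degrees, 3 translations in mm), an optional voxel
#' displacement field along the phase-encode axis (mm), and a Jacobian
#' modulation map compensating the compression/spread of signal in the
#' phase-encode direction. Applying the identity transform returns the input
#' bit-for-bit.
#'
#' @param motion Optional [motion_trace()] (`n_volumes x n_excitations x 6`).
#'   `NULL` means no rigid motion.
#' @param displacement Optional 3D or 4D array of displacements (mm) along
#'   `pe_axis`. `NULL` means none.
#' @param jacobian Multiplicative modulation: scalar, 3D or 4D array; must be
#'   positive everywhere.
#' @param pe_axis Phase-encode axis for the displacement field (1, 2 or 3).
#' @param interpolation Only `"linear"` is supported.
#' @return Object of class `spatial_transform`.
#' @export
spatial_transform <- function(motion = NULL, displacement = NULL, jacobian = 1,
                              pe_axis = 2L, interpolation = "linear") {
  interpolation <- match.arg(interpolation, "linear")
  if (!all(jacobian > 0)) stop("jacobian modulation must be positive everywhere")
  structure(list(motion = motion, displacement = displacement,
                 jacobian = jacobian, pe_axis = as.integer(pe_axis),
                 interpolation = interpolation),
            class = "spatial_transform")
}

#' @export
print.spatial_transform <- function(x, ...) {
  cat("Spatial transform:",
      if (is.null(x$motion)) "no rigid motion" else "per-excitation rigid motion",
      "|", if (is.null(x$displacement)) "no displacement" else "PE displacement",
      "|", if (identical(x$jacobian, 1)) "unit modulation" else "Jacobian modulation",
      "\n")
  invisible(x)
}

is_identity_transform <- function(xform) {
  (is.null(xform$motion) || all(xform$motion == 0)) && is.null(xform$displacement)
}

rigid_matrix <- function(par, affine, centre_vox) {
  # par: rot (deg) then trans (mm); rotation about the image centre in world mm
  r <- par[1:3] * pi / 180
  Rx <- rbind(c(1, 0, 0), c(0, cos(r[1]), -sin(r[1])), c(0, sin(r[1]), cos(r[1])))
  Ry <- rbind(c(cos(r[2]), 0, sin(r[2])), c(0, 1, 0), c(-sin(r[2]), 0, cos(r[2])))
  Rz <- rbind(c(cos(r[3]), -sin(r[3]), 0), c(sin(r[3]), cos(r[3]), 0), c(0, 0, 1))
  R <- Rz %*% Ry %*% Rx
  cw <- (affine %*% c(centre_vox, 1))[1:3]
  M <- diag(4)
  M[1:3, 1:3] <- R
  M[1:3, 4] <- par[4:6] + cw - R %*% cw
  M
}

trilinear_sample <- function(vol, pts) {
  # vol: 3D array; pts: 3 x n 0-based voxel coordinates; outside -> 0
  d <- dim(vol)
  x <- pts[1, ]; y <- pts[2, ]; z <- pts[3, ]
  x0 <- floor(x); y0 <- floor(y); z0 <- floor(z)
  fx <- x - x0; fy <- y - y0; fz <- z - z0
  acc <- numeric(length(x))
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    w <- (if (dx) fx else 1 - fx) * (if (dy) fy else 1 - fy) * (if (dz) fz else 1 - fz)
    xi <- x0 + dx; yi <- y0 + dy; zi <- z0 + dz
    ok <- w > 0 & xi >= 0 & xi < d[1] & yi >= 0 & yi < d[2] & zi >= 0 & zi < d[3]
    if (any(ok))
      acc[ok] <- acc[ok] + w[ok] * vol[cbind(xi[ok] + 1, yi[ok] + 1, zi[ok] + 1)]
  }
  acc
}

jacobian_for <- function(xform, sp, t) {
  j <- xform$jacobian
  if (length(j) == 1L) return(array(j, sp))
  if (length(dim(j)) == 3L) return(j)
  j[, , , t]
}

#' Apply a spatial transform to a 4D image
#'
#' Pull-back resampling: each output voxel of an excitation's slices is
#' sampled (trilinear) from the input at the inverse rigid-mapped position,
#' after adding any phase-encode displacement, and the result is multiplied
#' by the Jacobian modulation. With an identity geometry the input is
#' returned unchanged up to modulation.
#'
#' @param data 4D array in acquisition space (x, y, slice, volume).
#' @param xform A [spatial_transform()].
#' @param scheme An [acq_scheme()] giving the slice-to-excitation map.
#' @param affine 4x4 voxel-to-world matrix (mm).
#' @return 4D array of the same shape, in the anatomically consistent space.
#' @export
apply_transform <- function(data, xform, scheme, affine = diag(c(2.2, 2.2, 2.2, 1))) {
  stopifnot(length(dim(data)) == 4L)
  if (!all(xform$jacobian > 0)) stop("jacobian modulation must be positive everywhere")
  sp <- dim(data)[1:3]
  nt <- dim(data)[4]
  out <- data
  if (!is_identity_transform(xform)) {
    if (sp[3] != scheme$n_slices)
      stop("slice dimension (", sp[3], ") does not match scheme (", scheme$n_slices, ")")
    ggrid <- as.matrix(expand.grid(x = seq_len(sp[1]) - 1, y = seq_len(sp[2]) - 1))
    centre <- (sp - 1) / 2
    Ainv <- solve(affine)
    for (t in seq_len(nt)) {
      vol <- data[, , , t]
      for (e in seq_len(scheme$n_excitations) - 1L) {
        par <- if (is.null(xform$motion)) numeric(6) else xform$motion[min(t, dim(xform$motion)[1]), e + 1, ]
        Minv <- Ainv %*% solve(rigid_matrix(par, affine, centre)) %*% affine
        for (s in scheme$order[[e + 1L]]) {
          vox <- cbind(ggrid, s)                     # 0-based output voxel coords
          if (!is.null(xform$displacement)) {
            disp <- if (length(dim(xform$displacement)) == 3L)
              xform$displacement[, , s + 1] else xform$displacement[, , s + 1, t]
            step <- sqrt(sum(affine[1:3, xform$pe_axis]^2))
            vox[, xform$pe_axis] <- vox[, xform$pe_axis] + as.vector(disp) / step
          }
          src <- Minv %*% rbind(t(vox), 1)
          out[, , s + 1, t] <- matrix(trilinear_sample(vol, src[1:3, , drop = FALSE]),
                                      sp[1], sp[2])
        }
      }
    }
  }
  if (!identical(xform$jacobian, 1))
    for (t in seq_len(nt)) out[, , , t] <- out[, , , t] * jacobian_for(xform, sp, t)
  out
}
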