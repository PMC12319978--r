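#' Separable 3D Gaussian smoothing
#'
#' Smooths a 3D array (or each volume of a 4D array) with a separable
#' Gaussian kernel of the given full width at half maximum, truncated at
#' 3 sigma and renormalised at the edges. `fwhm = 0` returns the input
#' unchanged.
#'
#' @param img 3D or 4D numeric array.
#' @param fwhm Full width at half maximum in mm.
#' @param voxdim Voxel dimensions in mm (length 3).
#' @return Array of the same shape.
#' @export
gaussian_smooth <- function(img, fwhm, voxdim = c(2.2, 2.2, 2.2)) {
  if (fwhm == 0) return(img)
  if (fwhm < 0) stop("fwhm must be non-negative")
  nd <- length(dim(img))
  if (nd == 4L) {
    for (t in seq_len(dim(img)[4]))
      img[, , , t] <- gaussian_smooth(img[, , , t], fwhm, voxdim)
    return(img)
  }
  stopifnot(nd == 3L)
  sigma <- fwhm / (2 * sqrt(2 * log(2))) / voxdim
  for (ax in 1:3) {
    s <- sigma[ax]
    r <- max(1L, ceiling(3 * s))
    k <- exp(-(seq(-r, r))^2 / (2 * s^2))
    img <- convolve_axis(img, k / sum(k), ax)
  }
  img
}

convolve_axis <- function(img, kernel, axis) {
  r <- (length(kernel) - 1L) %/% 2L
  out <- array(0, dim(img))
  wsum <- array(0, dim(img))
  n <- dim(img)[axis]
  for (j in seq_along(kernel)) {
    off <- j - r - 1L
    src <- seq_len(n) + off
    ok <- src >= 1L & src <= n
    if (!any(ok)) next
    idx_dst <- which(ok); idx_src <- src[ok]
    if (axis == 1L) {
      out[idx_dst, , ] <- out[idx_dst, , ] + kernel[j] * img[idx_src, , ]
      wsum[idx_dst, , ] <- wsum[idx_dst, , ] + kernel[j]
    } else if (axis == 2L) {
      out[, idx_dst, ] <- out[, idx_dst, ] + kernel[j] * img[, idx_src, ]
      wsum[, idx_dst, ] <- wsum[, idx_dst, ] + kernel[j]
    } else {
      out[, , idx_dst] <- out[, , idx_dst] + kernel[j] * img[, , idx_src]
      wsum[, , idx_dst] <- wsum[, , idx_dst] + kernel[j]
    }
  }
  out / wsum
}

#' Erode a 3D mask by one voxel (6-connectivity)
#'
#' A voxel survives if itself and all six face neighbours are inside the
#' mask; border voxels are removed.
#'
#' @param mask 3D logical array.
#' @param iterations Number of erosion passes.
#' @return Eroded 3D logical array.
#' @export
erode_mask <- function(mask, iterations = 1L) {
  stopifnot(length(dim(mask)) == 3L)
  m <- mask
  for (it in seq_len(iterations)) {
    d <- dim(m)
    out <- m
    pad <- function(a) { p <- array(FALSE, d + 2L); p[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- a; p }
    p <- pad(m)
    i <- 2:(d[1] + 1); j <- 2:(d[2] + 1); k <- 2:(d[3] + 1)
    out <- p[i, j, k] & p[i - 1, j, k] & p[i + 1, j, k] &
      p[i, j - 1, k] & p[i, j + 1, k] & p[i, j, k - 1] & p[i, j, k + 1]
    m <- out
  }
  m
}
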