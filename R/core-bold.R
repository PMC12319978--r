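#' 4D BOLD timeseries container
#'
#' Wraps a 4D intensity array indexed (x, y, slice, volume) together with the
#' repetition time, the voxel-to-world affine, a space tag distinguishing the
#' native acquisition space from the anatomically consistent (tissue) space,
#' and a brain mask.
#'
#' @param data 4D numeric array (x, y, slice, volume), finite values.
#' @param tr Repetition time in seconds.
#' @param affine 4x4 voxel-to-world matrix (mm). Defaults to a 2.2 mm
#'   isotropic diagonal affine.
#' @param space `"acquisition"` or `"anatomical"`.
#' @param brain_mask 3D logical array matching the spatial shape; defaults to
#'   all-`TRUE`.
#' @return Object of class `bold_ts`.
#' @export
bold_ts <- function(data, tr, affine = NULL, space = c("acquisition", "anatomical"),
                    brain_mask = NULL) {
  space <- match.arg(space)
  if (length(dim(data)) != 4L) stop("data must be a 4D array (x, y, slice, volume)")
  if (dim(data)[4] < 2L) stop("at least 2 volumes are required")
  if (!all(is.finite(data))) stop("intensities must be finite")
  if (!is.finite(tr) || tr <= 0) stop("tr must be positive (seconds)")
  if (is.null(affine)) affine <- diag(c(2.2, 2.2, 2.2, 1))
  if (!identical(dim(affine), c(4L, 4L))) stop("affine must be a 4x4 matrix")
  sp <- dim(data)[1:3]
  if (is.null(brain_mask)) brain_mask <- array(TRUE, sp)
  if (!identical(dim(brain_mask), sp)) stop("brain_mask shape must match the spatial shape")
  structure(list(data = data, tr = tr, affine = affine, space = space,
                 brain_mask = array(as.logical(brain_mask), sp)),
            class = "bold_ts")
}

#' @export
print.bold_ts <- function(x, ...) {
  d <- dim(x$data)
  cat("BOLD timeseries: ", paste(d[1:3], collapse = " x "), " voxels, ",
      d[4], " volumes, TR ", x$tr, " s, ", x$space, " space\n", sep = "")
  cat("  brain mask: ", sum(x$brain_mask), " voxels\n", sep = "")
  invisible(x)
}

n_volumes <- function(ts) dim(ts$data)[4]

#' Matrix view of a BOLD series
#'
#' @param ts A [bold_ts()].
#' @param mask Optional 3D logical array; defaults to the series' brain mask.
#' @return `n_volumes x n_voxels` matrix of masked time courses.
#' @export
bold_matrix <- function(ts, mask = NULL) {
  if (is.null(mask)) mask <- ts$brain_mask
  d <- dim(ts$data)
  t(matrix(ts$data, prod(d[1:3]), d[4])[as.vector(mask), , drop = FALSE])
}

#' Replace masked voxel time courses of a BOLD series
#'
#' Inverse of [bold_matrix()]: writes an `n_volumes x n_voxels` matrix back
#' into the 4D array at the masked locations.
#' @inheritParams bold_matrix
#' @param values `n_volumes x sum(mask)` matrix.
#' @export
bold_unmatrix <- function(ts, values, mask = NULL) {
  if (is.null(mask)) mask <- ts$brain_mask
  d <- dim(ts$data)
  flat <- matrix(ts$data, prod(d[1:3]), d[4])
  flat[as.vector(mask), ] <- t(values)
  ts$data <- array(flat, d)
  ts
}

#' Read / write BOLD NIfTI images
#'
#' Thin wrappers over RNifti. `read_bold()` requires a 4D image and returns a
#' [bold_ts()]; a round trip preserves voxel values to stored precision and
#' the affine exactly.
#'
#' @param path NIfTI-1/2 file path.
#' @param tr Repetition time; defaults to the pixdim time step when present.
#' @param space Space tag to attach (not stored in NIfTI).
#' @param brain_mask Optional 3D logical mask.
#' @return `read_bold()` a [bold_ts()]; `write_bold()` the path, invisibly.
#' @export
read_bold <- function(path, tr = NULL, space = c("acquisition", "anatomical"),
                      brain_mask = NULL) {
  space <- match.arg(space)
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 4L)
    stop("expected a 4D BOLD image, got ", length(dim(img)), "D: ", path)
  if (is.null(tr)) {
    tr <- RNifti::pixdim(img)[4]
    if (!is.finite(tr) || tr <= 0) stop("TR not stored in header; pass tr explicitly")
  }
  aff <- structure(RNifti::xform(img), class = NULL)
  bold_ts(array(as.numeric(img), dim(img)), tr = tr,
          affine = matrix(aff, 4, 4), space = space, brain_mask = brain_mask)
}

#' @rdname read_bold
#' @param ts A [bold_ts()] to write.
#' @export
write_bold <- function(ts, path) {
  img <- RNifti::asNifti(ts$data)
  img <- RNifti::`sform<-`(img, structure(ts$affine, code = 2L))
  pd <- RNifti::pixdim(img)
  pd[4] <- ts$tr
  RNifti::pixdim(img) <- pd
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read / write a 3D mask image
#'
#' @param path NIfTI path.
#' @return 3D logical array (values > 0).
#' @export
read_mask <- function(path) {
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L) stop("expected a 3D mask image: ", path)
  array(as.numeric(img) > 0, dim(img))
}

#' @rdname read_mask
#' @param mask 3D logical array.
#' @param affine Optional 4x4 affine.
#' @export
write_mask <- function(mask, path, affine = NULL) {
  img <- RNifti::asNifti(array(as.numeric(mask), dim(mask)))
  if (!is.null(affine)) img <- RNifti::`sform<-`(img, structure(affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Per-excitation rigid motion trace
#'
#' Slice-to-volume motion correction yields one set of 6 rigid parameters
#' (3 rotations in degrees, 3 translations in mm) per (volume, excitation).
#'
#' @param params Numeric array `n_volumes x n_excitations x 6`.
#' @param scheme Optional [acq_scheme()] checked against the excitation count.
#' @return Object of class `motion_trace` (the validated array).
#' @export
motion_trace <- function(params, scheme = NULL) {
  if (length(dim(params)) != 3L || dim(params)[3] != 6L)
    stop("params must be an n_volumes x n_excitations x 6 array")
  if (!all(is.finite(params))) stop("motion parameters must be finite")
  if (!is.null(scheme) && dim(params)[2] != scheme$n_excitations)
    stop("motion trace has ", dim(params)[2], " excitations; scheme declares ",
         scheme$n_excitations)
  structure(params, class = "motion_trace")
}

MOTION_COLS <- c("rot_x_deg", "rot_y_deg", "rot_z_deg",
                 "trans_x_mm", "trans_y_mm", "trans_z_mm")

#' Read / write motion parameters as TSV
#'
#' Layout: one row per (volume, excitation) in acquisition order, with header
#' `volume  excitation  rot_x_deg ... trans_z_mm`. Volume and excitation
#' indices are 0-based.
#'
#' @param path TSV file path.
#' @param scheme Optional [acq_scheme()] for shape validation.
#' @return A [motion_trace()].
#' @export
read_motion <- function(path, scheme = NULL) {
  tab <- utils::read.delim(path, check.names = FALSE)
  need <- c("volume", "excitation", MOTION_COLS)
  if (!all(need %in% names(tab)))
    stop("motion TSV must have columns: ", paste(need, collapse = ", "))
  nv <- max(tab$volume) + 1L
  ne <- max(tab$excitation) + 1L
  if (nrow(tab) != nv * ne) stop("motion TSV rows do not cover volumes x excitations")
  tab <- tab[order(tab$volume, tab$excitation), ]
  arr <- array(0, c(nv, ne, 6L))
  for (k in 1:6) arr[, , k] <- matrix(tab[[MOTION_COLS[k]]], nv, ne, byrow = TRUE)
  motion_trace(arr, scheme)
}

#' @rdname read_motion
#' @param motion A [motion_trace()].
#' @export
write_motion <- function(motion, path) {
  d <- dim(motion)
  grid <- expand.grid(excitation = seq_len(d[2]) - 1L, volume = seq_len(d[1]) - 1L)
  tab <- data.frame(volume = grid$volume, excitation = grid$excitation)
  flat <- matrix(aperm(unclass(motion), c(2, 1, 3)), d[1] * d[2], 6)
  for (k in 1:6) tab[[MOTION_COLS[k]]] <- flat[, k]
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
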