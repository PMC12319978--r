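#' Sequential multiband acquisition scheme
#'
#' Describes the slice-to-excitation geometry of a sequential multiband (MB)
#' EPI acquisition: `n_slices` slices are acquired in `n_excitations =
#' n_slices / mb_factor` RF excitations, each excitation collecting
#' `mb_factor` simultaneously excited slices. Under the sequential rule the
#' bands are contiguous stacks of `n_excitations` slices, so excitation `e`
#' (0-based) acquires slices `e, e + n_excitations, e + 2 n_excitations, ...`.
#' Within a band, adjacent slices are one excitation apart, except across a
#' band boundary where the temporal gap is `n_excitations - 1` excitations,
#' i.e. of the order of the repetition time.
#'
#' @param n_slices Number of slices per volume.
#' @param mb_factor Multiband factor (slices excited simultaneously). Must
#'   divide `n_slices`.
#' @param tr Repetition time in seconds.
#' @return An object of class `acq_scheme` with fields `n_slices`,
#'   `mb_factor`, `n_excitations`, `tr` and `order` (a list mapping 0-based
#'   excitation index to the 0-based slice indices it acquires).
#' @examples
#' sch <- acq_scheme(48, 3, 2.2)
#' sch$n_excitations       # 16
#' excitation_of(17, sch)  # 1
#' partners_of(0, sch)     # 16 32
#' @export
acq_scheme <- function(n_slices, mb_factor, tr = 2.2) {
  stopifnot(length(n_slices) == 1L, length(mb_factor) == 1L, length(tr) == 1L)
  n_slices <- as.integer(n_slices)
  mb_factor <- as.integer(mb_factor)
  if (n_slices < 1L || mb_factor < 1L)
    stop("n_slices and mb_factor must be positive integers")
  if (n_slices %% mb_factor != 0L)
    stop("n_slices (", n_slices, ") is not divisible by mb_factor (", mb_factor, ")")
  if (!is.finite(tr) || tr <= 0) stop("tr must be a positive number of seconds")
  n_exc <- n_slices %/% mb_factor
  order <- lapply(seq_len(n_exc) - 1L,
                  function(e) e + n_exc * (seq_len(mb_factor) - 1L))
  structure(list(n_slices = n_slices, mb_factor = mb_factor,
                 n_excitations = n_exc, tr = tr, order = order),
            class = "acq_scheme")
}

#' @export
print.acq_scheme <- function(x, ...) {
  cat("Sequential multiband acquisition scheme\n")
  cat("  slices:      ", x$n_slices, "\n")
  cat("  MB factor:   ", x$mb_factor, "\n")
  cat("  excitations: ", x$n_excitations, "\n")
  cat("  TR:          ", x$tr, "s\n")
  invisible(x)
}

check_slice <- function(slice, scheme) {
  if (!inherits(scheme, "acq_scheme")) stop("scheme must be an acq_scheme")
  slice <- as.integer(slice)
  if (any(slice < 0L | slice >= scheme$n_slices))
    stop("slice index out of range [0, ", scheme$n_slices - 1L, "]")
  slice
}

#' Excitation index of a slice
#'
#' @param slice 0-based slice index (vectorised).
#' @param scheme An [acq_scheme()].
#' @return 0-based excitation index acquiring the slice.
#' @export
excitation_of <- function(slice, scheme) {
  slice <- check_slice(slice, scheme)
  slice %% scheme$n_excitations
}

#' Simultaneously acquired partner slices
#'
#' Returns the other `mb_factor - 1` slices excited together with `slice`.
#' Symmetric: `b %in% partners_of(a)` iff `a %in% partners_of(b)`.
#'
#' @inheritParams excitation_of
#' @return Integer vector of 0-based slice indices (empty for MB = 1).
#' @export
partners_of <- function(slice, scheme) {
  slice <- check_slice(slice, scheme)
  stopifnot(length(slice) == 1L)
  set <- scheme$order[[excitation_of(slice, scheme) + 1L]]
  setdiff(set, slice)
}
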