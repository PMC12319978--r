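# Stationary ICA (symmetric FastICA, tanh contrast) and Minka's Laplace
# rank selection. These back the non-GM regressor, slab-component and
# group-decomposition stages; only the contract (deterministic given seed,
# sign fixed by positive skew) is pinned, not any particular tool's output.

#' Symmetric FastICA on whitened data
#'
#' @param Z `k x n` matrix with orthonormal-ish rows (whitened sources
#'   dimension x samples).
#' @param seed Integer seed for the random orthonormal start.
#' @param max_iter,tol Iteration controls.
#' @return List with `S` (`k x n` estimated sources, unit variance, sign
#'   fixed so each source has positive skew) and `W` (`k x k` unmixing).
#' @keywords internal
fast_ica_core <- function(Z, seed = 1L, max_iter = 500L, tol = 1e-7) {
  k <- nrow(Z); n <- ncol(Z)
  set.seed(seed)
  W <- qr.Q(qr(matrix(stats::rnorm(k * k), k, k)))
  sym_decorrelate <- function(W) {
    e <- eigen(W %*% t(W), symmetric = TRUE)
    e$vectors %*% diag(1 / sqrt(pmax(e$values, 1e-12)), k) %*% t(e$vectors) %*% W
  }
  W <- sym_decorrelate(W)
  for (it in seq_len(max_iter)) {
    WX <- W %*% Z
    G <- tanh(WX)
    gprime <- 1 - G^2
    W_new <- G %*% t(Z) / n - diag(rowMeans(gprime), k) %*% W
    W_new <- sym_decorrelate(W_new)
    delta <- max(abs(abs(diag(W_new %*% t(W))) - 1))
    W <- W_new
    if (delta < tol) break
  }
  S <- W %*% Z
  # unit variance across samples, sign by positive skew
  sdv <- sqrt(rowMeans(S^2) - rowMeans(S)^2)
  S <- sweep(S, 1, pmax(sdv, 1e-12), "/")
  sk <- rowMeans(sweep(S, 1, rowMeans(S))^3)
  flip <- ifelse(sk < 0, -1, 1)
  list(S = S * flip, W = W * flip)
}

#' Spatial ICA of a time x voxel matrix
#'
#' PCA-reduces the temporal dimension to `k`, whitens the spatial principal
#' components and runs symmetric FastICA so the spatial maps are maximally
#' independent (the convention of melodic-style decompositions). Time
#' courses are recovered by projecting the data onto the maps.
#'
#' @param X `n_volumes x n_voxels` matrix (columns demeaned internally).
#' @param k Number of components (must not exceed `min(dim(X)) - 1`).
#' @param seed Integer seed.
#' @param demean Subtract voxel means first (skip for inputs whose rows are
#'   already centred components, to avoid discarding a rank).
#' @return List with `maps` (`k x n_voxels`, unit L2 norm rows), `tcs`
#'   (`n_volumes x k`), and `var_spectrum` (PCA eigenvalues, for rank
#'   diagnostics).
#' @keywords internal
spatial_ica <- function(X, k, seed = 1L, demean = TRUE) {
  nt <- nrow(X); nv <- ncol(X)
  if (k > min(nt, nv)) stop("k = ", k, " components exceed the available rank")
  if (demean) X <- sweep(X, 2, colMeans(X))
  sv <- svd(X, nu = k, nv = k)
  d <- sv$d[seq_len(k)]
  if (any(d < 1e-10 * sv$d[1])) stop("data rank is below the requested dimensionality")
  Z <- t(sv$v) * sqrt(nv)              # k x nv whitened spatial components
  ic <- fast_ica_core(Z, seed = seed)
  maps <- ic$S                          # k x nv, unit variance rows
  norms <- sqrt(rowSums(maps^2))
  maps <- sweep(maps, 1, norms, "/")
  tcs <- X %*% t(maps)                  # nt x k (maps rows orthogonal)
  gram <- maps %*% t(maps)
  tcs <- tcs %*% solve(gram)
  list(maps = maps, tcs = tcs, var_spectrum = sv$d^2 / nt)
}

#' Minka's Laplace-evidence estimate of PCA dimensionality
#'
#' @param spectrum Decreasing eigenvalues of the sample covariance.
#' @param n_samples Number of observations the covariance was formed over.
#' @return The rank maximising the Laplace evidence approximation.
#' @keywords internal
minka_dimension <- function(spectrum, n_samples) {
  d <- length(spectrum)
  n <- n_samples
  spectrum <- pmax(spectrum, .Machine$double.eps)
  ll <- rep(-Inf, d - 1L)
  for (k in seq_len(d - 1L)) {
    v <- mean(spectrum[(k + 1):d])
    # stop before the numerically null tail (e.g. rank lost to residualisation)
    if (v <= 1e-10 * spectrum[1]) break
    pu <- -k * log(2)
    i <- seq_len(k)
    pu <- pu + sum(lgamma((d - i + 1) / 2) - ((d - i + 1) / 2) * log(pi))
    pl <- -n / 2 * sum(log(spectrum[seq_len(k)]))
    pv <- -n * (d - k) / 2 * log(v)
    m <- d * k - k * (k + 1) / 2
    pp <- log(2 * pi) * (m + k) / 2
    spectrum_ <- spectrum
    spectrum_[(k + 1):d] <- v
    pa <- 0
    for (i in seq_len(k)) {
      j <- (i + 1):d
      pa <- pa + sum(log((spectrum[i] - spectrum[j]) *
                           (1 / spectrum_[j] - 1 / spectrum_[i])) + log(n))
    }
    ll[k] <- pu + pl + pv + pp - pa / 2 - k / 2 * log(n)
  }
  which.max(ll)
}
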