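#' Age-balanced two-stage PCA + group ICA
#'
#' Fuses subjects across a wide maturational range with balanced per-age
#' contributions: (1) the time courses of age-matched individuals are
#' temporally concatenated and compressed to `n_pc` principal components per
#' age group; (2) within-component values are z-scored across voxels, so
#' every component contributes at unit scale irrespective of its absolute
#' amplitude; (3) the z-scored components of all age groups are concatenated
#' and compressed to a sample-average set of `n_pc` principal components;
#' (4) spatial ICA decomposes that set into `n_ic` modes. `n_pc` is capped
#' at the available rank with a warning.
#'
#' @param subjects List of subjects; each a list with `ts` (a [bold_ts()] or
#'   an `n_volumes x n_voxels` matrix) and `age` (weeks).
#' @param n_pc Number of principal components per stage.
#' @param n_ic Number of independent components (modes).
#' @param seed Integer seed.
#' @param mask Common 3D logical mask (required when `ts` are [bold_ts()];
#'   defaults to the first subject's brain mask).
#' @param age_group Optional explicit group labels; default `round(age)`.
#' @return Object of class `group_decomposition` with `modes`
#'   (`n_ic x n_voxels`, unit norm), `n_pc_used`, `mask`, `ages`, `groups`.
#' @export
age_balanced_pca_ica <- function(subjects, n_pc, n_ic, seed = 1L, mask = NULL,
                                 age_group = NULL) {
  stopifnot(length(subjects) >= 1L)
  ages <- vapply(subjects, function(s) as.numeric(s$age), numeric(1))
  groups <- if (is.null(age_group)) round(ages) else age_group
  mats <- lapply(subjects, function(s) {
    if (inherits(s$ts, "bold_ts")) {
      if (is.null(mask)) mask <<- s$ts$brain_mask
      bold_matrix(s$ts, mask)
    } else as.matrix(s$ts)
  })
  nvox <- unique(vapply(mats, ncol, integer(1)))
  if (length(nvox) != 1L) stop("subjects must share a common voxel grid")

  compress <- function(X, k, demean = TRUE) {
    if (demean) X <- sweep(X, 2, colMeans(X))
    sv <- svd(X, nu = 0, nv = 0)
    rank <- sum(sv$d > max(dim(X)) * .Machine$double.eps * sv$d[1])
    if (k > rank) {
      warning("n_pc = ", k, " exceeds available rank ", rank, "; reduced")
      k <- rank
    }
    sv <- svd(X, nu = 0, nv = k)
    comp <- t(sv$v) * sv$d[seq_len(k)]       # k x nvox principal components
    # deterministic sign: largest-magnitude loading positive, so the result
    # is invariant to row (timepoint/subject) ordering
    flip <- apply(comp, 1, function(r) sign(r[which.max(abs(r))]))
    comp * flip
  }

  per_age <- lapply(sort(unique(groups)), function(g) {
    X <- do.call(rbind, mats[groups == g])
    comp <- compress(X, n_pc)
    t(scale(t(comp)))                        # z-score within component across voxels
  })
  # z-scored component rows are already centred across voxels, so the
  # second compression and the ICA whitening skip demeaning (no rank loss)
  stacked <- do.call(rbind, per_age)
  final <- compress(stacked, n_pc, demean = FALSE)
  k_used <- nrow(final)
  if (n_ic > k_used) stop("n_ic exceeds the retained principal components")
  ic <- spatial_ica(final, n_ic, seed = seed, demean = FALSE)
  structure(list(modes = ic$maps, n_pc_used = k_used, mask = mask,
                 ages = ages, groups = groups, n_ic = n_ic),
            class = "group_decomposition")
}

#' @export
print.group_decomposition <- function(x, ...) {
  cat("Group decomposition: ", nrow(x$modes), " modes over ", ncol(x$modes),
      " voxels; ", length(x$ages), " subjects in ",
      length(unique(x$groups)), " age group(s)\n", sep = "")
  invisible(x)
}

#' Dual (spatial) regression of group modes on an individual series
#'
#' Per volume, least-squares fit of the group spatial modes (plus intercept)
#' to the image, yielding the subject's mode time courses.
#'
#' @param modes `K x n_voxels` matrix of spatial modes.
#' @param ts A [bold_ts()] or `n_volumes x n_voxels` matrix over the same
#'   voxels.
#' @param mask 3D logical mask (when `ts` is a [bold_ts()]).
#' @return `n_volumes x K` matrix of time courses.
#' @export
dual_regress <- function(modes, ts, mask = NULL) {
  Y <- if (inherits(ts, "bold_ts")) bold_matrix(ts, mask) else as.matrix(ts)
  if (ncol(Y) != ncol(modes)) stop("series and modes must share the voxel grid")
  X <- cbind(1, t(modes))
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) stop("collinear modes")
  t(qr.coef(qrx, t(Y))[-1, , drop = FALSE])
}

#' Per-edge mean and age-effect t-matrices
#'
#' For every pair of modes, fits each subject-level connectivity value
#' (Fisher z-transformed correlation by default) by OLS on an intercept and
#' demeaned age, and converts both coefficients to t-values. The diagonal is
#' set to zero. Designated components (e.g. a vascular mode) can be excluded.
#'
#' @param corrs List of per-subject `K x K` correlation matrices.
#' @param ages Numeric vector of subject ages.
#' @param fisher Apply `atanh` to the correlations first (default `TRUE`).
#' @param exclude Optional integer indices (1-based) of components to drop
#'   from the matrices before fitting.
#' @return List with `mean_t` and `age_t` (`K' x K'` symmetric matrices,
#'   zero diagonal), `mean_beta`, `age_beta`, `kept` (component indices).
#' @export
edge_age_fit <- function(corrs, ages, fisher = TRUE, exclude = NULL) {
  if (length(corrs) != length(ages)) stop("one correlation matrix per subject")
  if (length(ages) < 3L) stop("at least 3 subjects are required")
  K <- nrow(corrs[[1]])
  kept <- setdiff(seq_len(K), exclude)
  mats <- lapply(corrs, function(m) {
    m <- m[kept, kept, drop = FALSE]
    if (fisher) m <- atanh(pmin(pmax(m, -1 + 1e-12), 1 - 1e-12))
    m
  })
  k <- length(kept)
  X <- cbind(1, ages - mean(ages))
  mean_t <- age_t <- mean_b <- age_b <- matrix(0, k, k)
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    y <- vapply(mats, function(m) m[i, j], numeric(1))
    if (stats::sd(y) == 0 && any(X[, 2] != 0)) {
      # identical values across subjects: zero residual, slope exactly 0
      fitb <- c(mean(y), 0); fitt <- c(Inf, 0)
      if (y[1] == 0) fitt[1] <- 0
    } else {
      fit <- stats::lm.fit(X, y)
      s2 <- sum(fit$residuals^2) / (length(y) - 2)
      XtXinv <- chol2inv(chol(crossprod(X)))
      se <- sqrt(pmax(diag(XtXinv) * s2, 0))
      fitb <- fit$coefficients
      fitt <- ifelse(se > 0, fitb / se, ifelse(fitb == 0, 0, Inf * sign(fitb)))
    }
    mean_b[i, j] <- mean_b[j, i] <- fitb[1]
    age_b[i, j] <- age_b[j, i] <- fitb[2]
    mean_t[i, j] <- mean_t[j, i] <- fitt[1]
    age_t[i, j] <- age_t[j, i] <- fitt[2]
  }
  list(mean_t = mean_t, age_t = age_t, mean_beta = mean_b, age_beta = age_b,
       kept = kept)
}

#' Normalised Laplacian embedding and Ward clustering
#'
#' Thresholds the (t-)matrix at zero, builds the symmetric normalised
#' Laplacian of the resulting weighted graph, embeds nodes on the
#' eigenvectors of the `n_dims` smallest non-null eigenvalues, and cuts a
#' Ward-linkage hierarchy into `n_clusters`. A disconnected graph is
#' flagged; its components are embedded separately and kept apart in the
#' clustering.
#'
#' @param t_matrix Symmetric matrix (negative entries zeroed; diagonal
#'   ignored).
#' @param n_dims Embedding dimensions (default 3).
#' @param n_clusters Number of clusters to cut.
#' @return List with `coordinates` (`n x n_dims` per component),
#'   `labels` (integer cluster per node), `disconnected` (logical),
#'   `components` (node component index).
#' @export
embed_cluster <- function(t_matrix, n_dims = 3L, n_clusters) {
  if (!isSymmetric(unname(t_matrix), tol = 1e-8)) stop("matrix must be symmetric")
  W <- pmax(t_matrix, 0)
  diag(W) <- 0
  n <- nrow(W)
  comp <- graph_components(W > 0)
  disconnected <- max(comp) > 1L
  if (disconnected)
    warning("graph is disconnected: ", max(comp), " components embedded separately")
  coords <- matrix(0, n, n_dims)
  for (c_id in seq_len(max(comp))) {
    idx <- which(comp == c_id)
    if (length(idx) == 1L) next
    Wc <- W[idx, idx, drop = FALSE]
    d <- rowSums(Wc)
    d[d == 0] <- 1
    L <- diag(length(idx)) - diag(1 / sqrt(d)) %*% Wc %*% diag(1 / sqrt(d))
    e <- eigen((L + t(L)) / 2, symmetric = TRUE)
    ord <- order(e$values)              # ascending
    nonnull <- ord[e$values[ord] > 1e-8]
    take <- utils::head(nonnull, n_dims)
    if (length(take))
      coords[idx, seq_along(take)] <- e$vectors[, take, drop = FALSE]
  }
  feat <- if (disconnected) {
    ind <- matrix(0, n, max(comp))
    ind[cbind(seq_len(n), comp)] <- 10 * max(1, max(abs(coords)))
    cbind(ind, coords)
  } else coords
  hc <- stats::hclust(stats::dist(feat), method = "ward.D2")
  labels <- stats::cutree(hc, k = n_clusters)
  list(coordinates = coords, labels = labels,
       disconnected = disconnected, components = comp)
}

graph_components <- function(adj) {
  n <- nrow(adj)
  comp <- integer(n)
  c_id <- 0L
  for (start in seq_len(n)) {
    if (comp[start] > 0L) next
    c_id <- c_id + 1L
    queue <- start
    comp[start] <- c_id
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      nb <- which(adj[v, ] & comp == 0L)
      comp[nb] <- c_id
      queue <- c(queue, nb)
    }
  }
  comp
}

#' Seed-to-brain correlation map
#'
#' Pearson correlation of the mean seed-region time course with every voxel,
#' after optional Gaussian smoothing of the series.
#'
#' @param ts A [bold_ts()].
#' @param seed_mask 3D logical mask of the seed region.
#' @param fwhm Smoothing FWHM in mm (default 3).
#' @return 3D correlation map (NA outside the brain mask).
#' @export
seed_map <- function(ts, seed_mask, fwhm = 3) {
  if (!any(seed_mask)) stop("seed mask is empty")
  voxdim <- sqrt(colSums(ts$affine[1:3, 1:3]^2))
  sm <- ts
  if (fwhm > 0) sm$data <- gaussian_smooth(ts$data, fwhm, voxdim)
  seed_tc <- rowMeans(bold_matrix(sm, seed_mask))
  if (stats::sd(seed_tc) == 0) stop("zero-variance seed time course")
  Y <- bold_matrix(sm, sm$brain_mask)
  r <- suppressWarnings(as.vector(stats::cor(seed_tc, Y)))
  map <- array(NA_real_, dim(ts$data)[1:3])
  map[sm$brain_mask] <- r
  map
}

#' Group-level fit of seed correlation maps against age
#'
#' Voxel-wise OLS of the per-subject seed maps on an intercept and demeaned
#' age, converted to t-values.
#'
#' @param maps List of per-subject 3D correlation maps (same shape).
#' @param ages Numeric vector of ages.
#' @param fisher Apply `atanh` to correlations first (default `TRUE`).
#' @return List with `intercept_t` and `age_t` 3D maps.
#' @export
group_seed_fit <- function(maps, ages, fisher = TRUE) {
  if (length(maps) != length(ages)) stop("one map per subject")
  if (length(ages) < 3L) stop("at least 3 subjects are required")
  shape <- dim(maps[[1]])
  Y <- vapply(maps, as.vector, numeric(prod(shape)))   # nvox x S
  if (fisher) Y <- atanh(pmin(pmax(Y, -1 + 1e-12), 1 - 1e-12))
  X <- cbind(1, ages - mean(ages))
  ok <- stats::complete.cases(Y)
  it <- at <- rep(NA_real_, prod(shape))
  if (any(ok)) {
    fit <- stats::lm.fit(X, t(Y[ok, , drop = FALSE]))
    res <- as.matrix(fit$residuals)
    s2 <- colSums(res^2) / (length(ages) - 2)
    XtXinv <- chol2inv(chol(crossprod(X)))
    seb <- sqrt(outer(diag(XtXinv), s2))
    B <- as.matrix(fit$coefficients)
    tv <- ifelse(seb > 0, B / seb, ifelse(B == 0, 0, Inf * sign(B)))
    it[ok] <- tv[1, ]
    at[ok] <- tv[2, ]
  }
  list(intercept_t = array(it, shape), age_t = array(at, shape))
}
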