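test_that("MP maps broadcast per-excitation values and difference slice states", {
  sch <- small_scheme()
  nv <- 10L; ne <- sch$n_excitations
  # zero motion -> all 12 maps identically zero
  z <- mp_voxel_maps(motion_trace(array(0, c(nv, ne, 6)), sch), sch)
  expect_true(all(z$values == 0))
  # ramp in excitation index (same every volume): slice differential constant
  # within a volume, with the band-wrap step at the last excitation
  mot <- array(0, c(nv, ne, 6))
  for (e in seq_len(ne)) mot[, e, ] <- e - 1
  mpm <- mp_voxel_maps(motion_trace(mot, sch), sch)
  for (p in 1:6) {
    expect_equal(mpm$values[, , p], mot[, , p])
    ds <- mpm$values[, , 6 + p]
    expect_true(all(ds[, -ne] == 1))          # within-volume ramp step
    expect_true(all(ds[-nv, ne] == -(ne - 1)))  # wrap to next volume's first state
    expect_equal(ds[nv, ne], 0)               # final state zero-padded
  }
  # expanded maps with identity transform are constant within an excitation
  mpx <- mp_voxel_maps(motion_trace(mot, sch), sch, xform = spatial_transform(),
                       shape = c(4, 4, 12))
  arr <- mpx$maps[[1]]$data
  for (e in 0:(ne - 1)) {
    sl <- sch$order[[e + 1]] + 1
    vals <- arr[, , sl, 3]
    expect_equal(max(vals) - min(vals), 0)
    expect_equal(vals[1, 1, 1], mot[3, e + 1, 1])
  }
  expect_error(mp_voxel_maps(motion_trace(array(0, c(5, 3, 6))), sch), "match")
})

test_that("slice rearrangement is invertible with the documented state count", {
  sch <- small_scheme()
  arr <- array(rnorm(3 * 3 * 12 * 7), c(3, 3, 12, 7))
  st <- slice_rearrange(arr, sch)
  expect_equal(nrow(st), 7L * sch$n_excitations)
  expect_equal(ncol(st), 3L * 3L * sch$mb_factor)
  expect_equal(slice_restore(st, sch, c(3, 3, 12)), arr)
  # state k covers the slices of excitation (k-1) mod n_excitations at
  # volume (k-1) %/% n_excitations
  for (k in c(3L, 6L)) {
    e <- (k - 1L) %% sch$n_excitations
    t <- (k - 1L) %/% sch$n_excitations + 1L
    expect_equal(st[k, ], as.vector(arr[, , sch$order[[e + 1]] + 1, t]))
  }
  # the 350 x 16 acquisition yields 5600 states
  big <- acq_scheme(48, 3, 2.2)
  expect_equal(350L * big$n_excitations, 5600L)
})

test_that("the MP stack has 60 columns matching an independent oracle", {
  sch <- small_scheme()
  nv <- 6L; ne <- sch$n_excitations
  set.seed(8)
  mot <- array(rnorm(nv * ne * 6), c(nv, ne, 6))
  mpm <- mp_voxel_maps(motion_trace(mot, sch), sch)
  X <- mp_design(mpm, 2L)
  expect_equal(ncol(X), 60L)
  # oracle: per parameter, apply value/square/differential operators to the
  # scalar series of excitation 2 independently
  state_seq <- function(p) as.vector(t(mot[, , p]))
  for (p in 1:6) {
    s <- state_seq(p)
    ds_states <- c(diff(s), 0)
    ds <- matrix(ds_states, nv, ne, byrow = TRUE)[, 3]
    cols <- mp_oracle_columns(mot[, 3, p], ds)
    got <- X[, seq(p, 60, by = 6)]
    expect_equal(unname(got), unname(cols), tolerance = 1e-12)
  }
})

test_that("stack building is equivariant to reordering the 6 parameters", {
  sch <- small_scheme()
  set.seed(9)
  mot <- array(rnorm(5 * 4 * 6), c(5, 4, 6))
  perm <- c(3, 1, 6, 2, 5, 4)
  X1 <- mp_design(mp_voxel_maps(motion_trace(mot), sch), 1L)
  X2 <- mp_design(mp_voxel_maps(motion_trace(mot[, , perm]), sch), 1L)
  for (b in 0:9)
    expect_equal(unname(X2[, b * 6 + 1:6]), unname(X1[, b * 6 + perm]))
})

test_that("second volume differential equals twice-applied first differential", {
  sch <- small_scheme()
  set.seed(10)
  mot <- array(rnorm(8 * 4 * 6), c(8, 4, 6))
  X <- mp_design(mp_voxel_maps(motion_trace(mot), sch), 0L)
  dv <- X[, 13:18]    # third block
  d2v <- X[, 25:30]   # fifth block
  expect_equal(unname(d2v[-(1:2), ]), unname(apply(dv, 2, function(x) diff(x))[-1, ]))
})

test_that("z-scoring uses non-censored statistics and flags degenerate columns", {
  X <- cbind(a = c(1, 2, 3, 4, 100), b = rep(2, 5))
  cm <- censor_volumes(c(0, 0, 0, 0, 10))   # volume 4 censored
  Z <- mp_zscore(X, cm)
  expect_equal(attr(Z, "degenerate"), c(a = FALSE, b = TRUE))
  expect_equal(Z[, "b"], rep(0, 5))
  keep <- !cm$censored
  expect_equal(mean(Z[keep, "a"]), 0, tolerance = 1e-12)
  expect_equal(sd(Z[keep, "a"]), 1, tolerance = 1e-12)
})

test_that("per-voxel PCA retains components per the eigen-spectrum", {
  set.seed(12)
  # rank-1 stack: all columns proportional -> 1 component
  base <- rnorm(30)
  X1 <- outer(base, runif(60, 0.5, 2))
  r1 <- mp_pca(X1)
  expect_equal(r1$n_components, 1L)
  # var_kept = 1 keeps the numerical rank
  X3 <- matrix(rnorm(30 * 5), 30, 5) %*% matrix(rnorm(5 * 60), 5, 60)
  expect_equal(mp_pca(X3, var_kept = 1)$n_components, 5L)
  # constructed spectrum: orthonormal columns scaled to variances
  # (0.9, 0.09, 0.009, 0.001): cumulative (0.9, 0.99, 0.999) -> 2 at 0.99
  Q <- qr.Q(qr(matrix(rnorm(40 * 4), 40, 4)))
  X2 <- Q %*% diag(sqrt(c(0.9, 0.09, 0.009, 0.001) * 39))
  X2 <- sweep(X2, 2, colMeans(X2))  # make sample variances exact after centring
  sv <- svd(X2)$d^2
  k_expected <- which(cumsum(sv) / sum(sv) >= 0.99)[1]
  expect_equal(mp_pca(X2, var_kept = 0.99)$n_components, k_expected)
  # all-degenerate stack gets no regressors
  expect_equal(mp_pca(matrix(0, 10, 60))$n_components, 0L)
})

test_that("PCA scores cover all volumes while fitting non-censored ones", {
  sch <- small_scheme()
  set.seed(13)
  mot <- array(rnorm(20 * 4 * 6, 0, 0.5), c(20, 4, 6))
  cm <- censor_volumes(c(rep(0, 10), 0.2, rep(0, 9)))
  stk <- mp_stack(mp_voxel_maps(motion_trace(mot), sch), cm)
  expect_equal(length(stk$designs), 4L)
  expect_true(all(vapply(stk$designs, ncol, integer(1)) == 60L))
  red <- mp_pca(stk, cm)
  expect_true(all(red$n_components <= 60L))
  expect_true(all(vapply(red$designs, nrow, integer(1)) == 20L))
  expect_equal(red$mean_components, mean(red$n_components))
})

test_that("non-GM ICA recovers planted components and respects dim choices", {
  sch <- small_scheme()
  sc <- small_scene(seed = 17, K = 0, n_volumes = 80, drift_amplitude = 0,
                    wave_amplitude = 0, spike_amplitude = 0)
  sim <- simulate_scene(sc)
  wm_csf <- sc$masks$wm | sc$masks$csf
  core <- erode_mask(wm_csf)
  # plant 2 strong components inside the eroded mask
  set.seed(18)
  idx <- which(core)
  tcs_true <- scale(matrix(rnorm(80 * 2), 80, 2))
  # sparse positive (exponential-magnitude) maps with disjoint support and a
  # gap: strongly non-Gaussian, hence identifiable by spatial ICA
  n <- length(idx)
  m1 <- m2 <- numeric(n)
  m1[seq_len(floor(0.45 * n))] <- rexp(floor(0.45 * n))
  m2[(n - floor(0.45 * n) + 1):n] <- rexp(floor(0.45 * n))
  Y <- bold_matrix(sim$bold, core)
  Y <- Y + 30 * tcs_true %*% rbind(m1, m2)
  planted <- bold_unmatrix(sim$bold, Y, core)
  ng <- nongm_ica(planted, wm_csf, dim = 2, seed = 19)
  cc <- abs(cor(ng$tcs, tcs_true))
  expect_equal(ng$dim, 2L)
  best <- max(min(diag(cc)), min(cc[1, 2], cc[2, 1]))
  expect_gt(best, 0.95)
  # fixed dims are honoured
  expect_equal(ncol(nongm_ica(sim$bold, wm_csf, dim = 6, seed = 1)$tcs), 6L)
  # auto on near-white noise stays small and below the cap
  ngA <- nongm_ica(sim$bold, wm_csf, dim = "auto", seed = 1)
  expect_lte(ngA$dim, 90L)
  expect_error(nongm_ica(sim$bold, array(FALSE, c(12, 12, 12))), "empty")
})

test_that("unit-variance time courses come out of the ICA stage", {
  sc <- small_scene(seed = 23, n_volumes = 40)
  sim <- simulate_scene(sc)
  ng <- nongm_ica(sim$bold, sc$masks$wm | sc$masks$csf, dim = 3, seed = 5)
  expect_equal(apply(ng$tcs, 2, sd), rep(1, 3), tolerance = 1e-8,
               ignore_attr = TRUE)
})
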