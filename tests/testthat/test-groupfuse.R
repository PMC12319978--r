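# shared planted-mode cohort: K sparse positive maps, per-subject random
# time courses, group-specific amplitudes
make_cohort <- function(K = 3, nvox = 600, nt = 50, n_per_group = 2,
                        amps = c(1, 1.5, 2), ages = c(24, 28, 32),
                        noise_sd = 0.5, seed = 71) {
  set.seed(seed)
  maps <- matrix(0, K, nvox)
  span <- floor(nvox / K)
  for (k in seq_len(K))
    maps[k, (k - 1) * span + seq_len(span - 20)] <- rexp(span - 20)
  subjects <- list()
  for (g in seq_along(ages)) for (i in seq_len(n_per_group)) {
    tc <- matrix(rnorm(nt * K), nt, K)
    subjects[[length(subjects) + 1]] <-
      list(ts = amps[g] * tc %*% maps + matrix(rnorm(nt * nvox, 0, noise_sd), nt, nvox),
           age = ages[g], tcs = tc)
  }
  list(maps = maps, subjects = subjects)
}

test_that("age-balanced PCA+ICA recovers planted modes across amplitudes", {
  ch <- make_cohort()
  gd <- age_balanced_pca_ica(ch$subjects, n_pc = 20, n_ic = 3, seed = 5)
  expect_equal(nrow(gd$modes), 3L)
  m <- match_components(gd$modes, ch$maps)
  expect_gt(m$min_abs_r, 0.9)
  # permutation invariance to subject order under a fixed seed
  gd2 <- age_balanced_pca_ica(rev(ch$subjects), n_pc = 20, n_ic = 3, seed = 5)
  m12 <- match_components(gd2$modes, gd$modes)
  expect_gt(m12$min_abs_r, 0.999)
})

test_that("single age group equals plain PCA+ICA of the concatenation", {
  ch <- make_cohort(ages = 30, amps = 1, n_per_group = 4)
  # with a single group the cross-age replication that re-ranks z-scored
  # components is absent, so n_pc is set to the signal dimension; the
  # z-scoring is then absorbed and the result matches plain PCA+ICA
  gd <- age_balanced_pca_ica(ch$subjects, n_pc = 3, n_ic = 3, seed = 6)
  m <- match_components(gd$modes, ch$maps)
  expect_gt(m$min_abs_r, 0.9)
  expect_equal(length(unique(gd$groups)), 1L)
  plain <- fetalfilter:::spatial_ica(do.call(rbind, lapply(ch$subjects, `[[`, "ts")),
                                     3, seed = 6)
  expect_gt(match_components(gd$modes, plain$maps)$min_abs_r, 0.9)
})

test_that("n_pc above the available rank is reduced with a warning", {
  ch <- make_cohort(nt = 10, n_per_group = 1)
  w <- capture_warnings(
    gd <- age_balanced_pca_ica(ch$subjects, n_pc = 50, n_ic = 2, seed = 1))
  expect_true(length(w) >= 1 && all(grepl("rank", w)))
  expect_lt(gd$n_pc_used, 50L)
})

test_that("the z-scoring stage equalises per-age component norms", {
  # re-implement the first two stages to assert the invariant directly
  ch <- make_cohort()
  ages <- vapply(ch$subjects, `[[`, numeric(1), "age")
  for (g in unique(round(ages))) {
    X <- do.call(rbind, lapply(ch$subjects[round(ages) == g], `[[`, "ts"))
    X <- sweep(X, 2, colMeans(X))
    sv <- svd(X, nu = 0, nv = 8)
    comp <- t(scale(t(t(sv$v) * sv$d[1:8])))
    expect_equal(apply(comp, 1, sd), rep(1, 8), tolerance = 1e-10)
  }
})

test_that("dual regression recovers time courses", {
  ch <- make_cohort(noise_sd = 0)
  s <- ch$subjects[[1]]
  # noise-free: exact recovery
  tcs <- dual_regress(ch$maps, s$ts)
  expect_equal(tcs, s$tcs, tolerance = 1e-8)
  # orthonormal modes: time courses are inner products (after demeaning
  # absorbed by the intercept)
  Q <- qr.Q(qr(t(ch$maps)))
  Yq <- s$tcs %*% t(Q)
  expect_equal(dual_regress(t(Q), Yq), Yq %*% Q, tolerance = 1e-8)
  # noisy: correlation with truth stays high at SNR ~ 5
  chn <- make_cohort(noise_sd = 3, seed = 72)
  sn <- chn$subjects[[1]]
  tcn <- dual_regress(chn$maps, sn$ts)
  expect_true(all(diag(cor(tcn, sn$tcs)) > 0.9))
  expect_error(dual_regress(rbind(ch$maps, ch$maps[1, ]), s$ts), "collinear")
})

test_that("edge age fit recovers slopes and honours exclusions", {
  # identical matrices for all subjects: age t exactly 0
  m0 <- diag(4); m0[lower.tri(m0)] <- 0.3; m0[upper.tri(m0)] <- 0.3
  ef0 <- edge_age_fit(replicate(5, m0, simplify = FALSE), ages = 20:24)
  expect_true(all(ef0$age_t == 0))
  expect_true(isSymmetric(ef0$mean_t))
  # constructed edge 0.1 + 0.02 * (age - mean) + tiny noise (raw-r mode):
  # the slope estimate falls within its own 95% CI
  set.seed(73)
  ages <- seq(22, 38, length.out = 24)
  corrs <- lapply(ages, function(a) {
    m <- diag(3)
    m[1, 2] <- m[2, 1] <- 0.1 + 0.02 * (a - mean(ages)) + rnorm(1, 0, 0.005)
    m[1, 3] <- m[3, 1] <- 0.25
    m[2, 3] <- m[3, 2] <- 0.15
    m
  })
  ef <- edge_age_fit(corrs, ages, fisher = FALSE)
  se <- ef$age_beta[1, 2] / ef$age_t[1, 2]
  expect_lt(abs(ef$age_beta[1, 2] - 0.02), 1.96 * se)
  # excluding a designated component drops it from the matrices
  ef_ex <- edge_age_fit(corrs, ages, fisher = FALSE, exclude = 1L)
  expect_equal(dim(ef_ex$mean_t), c(2L, 2L))
  expect_equal(ef_ex$kept, c(2L, 3L))
  expect_equal(ef_ex$age_beta[1, 2], ef$age_beta[2, 3], tolerance = 1e-12)
  expect_error(edge_age_fit(corrs[1:2], ages[1:2]), "3 subjects")
})

test_that("embedding separates block structure and flags disconnection", {
  # two strong positive blocks, weakly connected: 2 clusters split them
  W <- matrix(0.01, 8, 8)
  W[1:4, 1:4] <- 1; W[5:8, 5:8] <- 1
  diag(W) <- 0
  ec <- embed_cluster(W, n_dims = 3, n_clusters = 2)
  expect_false(ec$disconnected)
  expect_equal(length(unique(ec$labels[1:4])), 1L)
  expect_equal(length(unique(ec$labels[5:8])), 1L)
  expect_true(ec$labels[1] != ec$labels[5])
  # fully disconnected blocks are flagged and separated exactly
  W2 <- W; W2[W2 == 0.01] <- 0
  expect_warning(ec2 <- embed_cluster(W2, n_dims = 2, n_clusters = 2),
                 "disconnected")
  expect_true(ec2$disconnected)
  expect_equal(ec2$components, rep(1:2, each = 4))
  expect_true(all(ec2$labels[1:4] != ec2$labels[5:8]))
  # negative entries are zeroed, not used as (invalid) weights
  W3 <- W; W3[1, 5] <- W3[5, 1] <- -5
  ec3 <- embed_cluster(W3, n_dims = 3, n_clusters = 2)
  ec3_ref <- embed_cluster(pmax(W3, 0), n_dims = 3, n_clusters = 2)
  expect_identical(ec3$labels, ec3_ref$labels)
  expect_identical(ec3$coordinates, ec3_ref$coordinates)
  # all-equal positive matrix collapses to one cluster when asked for one
  W4 <- matrix(1, 5, 5); diag(W4) <- 0
  ec4 <- embed_cluster(W4, n_dims = 3, n_clusters = 1)
  expect_equal(length(unique(ec4$labels)), 1L)
})

test_that("embedding labels are equivariant to node permutation", {
  set.seed(74)
  W <- matrix(0.05, 9, 9)
  W[1:3, 1:3] <- 0.9; W[4:6, 4:6] <- 0.8; W[7:9, 7:9] <- 1.1
  W <- W + matrix(runif(81, 0, 0.02), 9, 9)
  W <- (W + t(W)) / 2; diag(W) <- 0
  ec <- embed_cluster(W, n_dims = 3, n_clusters = 3)
  perm <- sample(9)
  ecp <- embed_cluster(W[perm, perm], n_dims = 3, n_clusters = 3)
  # same partition after permutation
  same <- outer(ec$labels[perm], ec$labels[perm], "==")
  same_p <- outer(ecp$labels, ecp$labels, "==")
  expect_equal(same_p, same)
})

test_that("seed maps peak on the seeded network and behave at the limits", {
  sc <- small_scene(seed = 75, n_volumes = 60, K = 2, noise_sd = 1,
                    drift_amplitude = 0, wave_amplitude = 0,
                    spike_amplitude = 0, leakage_fraction = 0)
  sim <- simulate_scene(sc)
  # seed: the top voxels of network 1
  m1 <- sc$maps[[1]]
  seed_mask <- m1 > quantile(m1[m1 > 0], 0.98)
  sm <- seed_map(sim$bold, seed_mask, fwhm = 0)
  # a single-voxel seed correlates perfectly with itself
  single <- array(FALSE, dim(m1))
  single[which.max(m1)] <- TRUE
  sm1 <- seed_map(sim$bold, single, fwhm = 0)
  expect_equal(sm1[which.max(m1)], 1, tolerance = 1e-12)
  # the map is higher on network-1 voxels than on network-2 voxels
  m2 <- sc$maps[[2]]
  on1 <- sm[m1 > quantile(m1[m1 > 0], 0.9) & !seed_mask]
  on2 <- sm[m2 > quantile(m2[m2 > 0], 0.9) & m1 < quantile(m1[m1 > 0], 0.5)]
  expect_gt(mean(on1, na.rm = TRUE), mean(on2, na.rm = TRUE))
  expect_error(seed_map(sim$bold, array(FALSE, c(12, 12, 12))), "empty")
})

test_that("group seed fit is centred on zero for an age-flat sample", {
  set.seed(76)
  shape <- c(6, 6, 6)
  maps <- lapply(1:8, function(i) array(tanh(rnorm(prod(shape), 0, 0.3)), shape))
  fit <- group_seed_fit(maps, ages = seq(24, 38, 2))
  expect_equal(mean(fit$age_t), 0, tolerance = 0.2)
  expect_equal(dim(fit$age_t), shape)
  # a planted age effect at one voxel is detected
  maps2 <- maps
  ages <- seq(24, 38, 2)
  for (i in seq_along(maps2)) maps2[[i]][2, 2, 2] <- 0.05 * (ages[i] - 31)
  fit2 <- group_seed_fit(maps2, ages)
  expect_gt(fit2$age_t[2, 2, 2], 10)
})
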