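#' Synthetic multiband acquisition scene
#'
#' Generates a reproducible scene describing a sequential multiband fMRI
#' acquisition with known ground truth: disjoint GM/WM/CSF tissue masks on an
#' ellipsoidal "brain", K spatial network maps (unit norm, pairwise spatial
#' correlation below 0.3, resampled if violated) with unit-variance time
#' courses, white Gaussian noise, a slow cosine drift, a travelling intensity
#' wave along the slice axis whose phase advances with excitation index and
#' motion magnitude (a spin-history surrogate, not a physics model),
#' inter-band leakage, motion spikes with matching intensity spikes, a
#' per-excitation rigid motion trace, and a Jacobian modulation field.
#'
#' Defaults emulate the release acquisition: 350 volumes of 48 slices at
#' MB factor 3 and TR 2.2 s, with noise scaled so the default temporal SNR is
#' about 20.
#'
#' @param grid Spatial shape `c(nx, ny, n_slices)`; the slice count must
#'   match the scheme.
#' @param scheme An [acq_scheme()].
#' @param K Number of planted network components (0 gives a pure-noise scene).
#' @param seed Integer seed; the same seed yields a bit-identical scene and
#'   simulation.
#' @param n_volumes Number of volumes.
#' @param baseline Mean tissue intensity (a.u.).
#' @param noise_sd White-noise standard deviation (a.u.).
#' @param signal_amplitude Amplitude multiplying each unit-norm network map
#'   (a.u.); the default gives peak network fluctuations of roughly 4% of
#'   baseline intensity.
#' @param drift_amplitude Amplitude of the low-frequency drift (a.u.).
#' @param wave_amplitude,wave_period Amplitude (a.u.) and temporal period
#'   (volumes) of the travelling wave.
#' @param leakage_fraction Fraction of mean partner-slice signal leaking into
#'   each voxel, in `[0, 1)`.
#' @param spike_volumes 0-based indices of motion-spike volumes; `NULL` draws
#'   2% of volumes at random.
#' @param spike_amplitude Intensity offset at spike volumes (a.u.); default
#'   ten times `noise_sd`.
#' @param motion_step Per-excitation random-walk step (deg / mm).
#' @param jacobian_range Half-range of the smooth modulation field around 1.
#' @return Object of class `synth_scene`.
#' @seealso [simulate_scene()]
#' @export
make_scene <- function(grid = c(24, 24, 48), scheme = acq_scheme(48, 3, 2.2),
                       K = 3, seed = 1L, n_volumes = 350,
                       baseline = 100, noise_sd = 5,
                       signal_amplitude = 20, drift_amplitude = 2,
                       wave_amplitude = 2, wave_period = 30,
                       leakage_fraction = 0.1,
                       spike_volumes = NULL, spike_amplitude = 10 * noise_sd,
                       motion_step = 0.02, jacobian_range = 0.05) {
  grid <- as.integer(grid)
  stopifnot(length(grid) == 3L, all(grid >= 2L))
  if (grid[3] != scheme$n_slices)
    stop("grid has ", grid[3], " slices but the scheme declares ", scheme$n_slices)
  if (K > prod(grid)) stop("K exceeds the number of voxels")
  if (leakage_fraction < 0 || leakage_fraction >= 1)
    stop("leakage_fraction must be in [0, 1)")
  set.seed(seed)

  masks <- make_tissue_masks(grid)
  brain <- masks$gm | masks$wm | masks$csf

  if (is.null(spike_volumes)) {
    n_spk <- max(1L, round(0.02 * n_volumes))
    spike_volumes <- sort(sample(seq_len(n_volumes - 1L), n_spk))  # keep vol 0 clean
  }
  spike_volumes <- as.integer(spike_volumes)
  stopifnot(all(spike_volumes >= 0L & spike_volumes < n_volumes))

  # network maps: Gaussian blobs centred in GM, supported inside the brain,
  # unit L2 norm; resample until pairwise |r| < 0.3
  maps <- list(); map_resamples <- 0L
  gm_idx <- which(masks$gm, arr.ind = TRUE)
  if (K > 0) {
    repeat {
      maps <- lapply(seq_len(K), function(k) {
        ctr <- gm_idx[sample(nrow(gm_idx), 1L), ]
        blob <- blob_map(grid, ctr, width = pmax(2, grid / 8)) * brain
        blob / sqrt(sum(blob^2))
      })
      if (K < 2 || max_abs_pairwise_cor(maps, brain) < 0.3) break
      map_resamples <- map_resamples + 1L
      if (map_resamples > 50L) stop("could not decorrelate the network maps")
    }
  }
  tcs <- if (K > 0) {
    raw <- apply(matrix(stats::rnorm(n_volumes * K), n_volumes, K), 2,
                 function(x) stats::filter(x, rep(1, 5) / 5, circular = TRUE))
    scale(raw)[, , drop = FALSE]
  } else matrix(0, n_volumes, 0)

  # per-excitation rigid motion: random walk over acquisition states plus
  # spikes; parameter order rot(deg) x3, trans(mm) x3
  ne <- scheme$n_excitations
  mot <- array(0, c(n_volumes, ne, 6))
  for (p in 1:6) {
    walk <- cumsum(stats::rnorm(n_volumes * ne, 0, motion_step))
    mot[, , p] <- matrix(walk, n_volumes, ne, byrow = TRUE)
  }
  for (v in spike_volumes)
    mot[v + 1L, , ] <- mot[v + 1L, , ] + matrix(stats::rnorm(ne * 6, 0, 2), ne, 6)

  jac <- 1 + jacobian_range * smooth_field(grid)

  structure(list(grid = grid, scheme = scheme, K = K, seed = seed,
                 n_volumes = as.integer(n_volumes),
                 masks = masks, brain_mask = brain,
                 maps = maps, tcs = tcs, map_resamples = map_resamples,
                 baseline = baseline, noise_sd = noise_sd,
                 signal_amplitude = signal_amplitude,
                 drift_amplitude = drift_amplitude,
                 wave_amplitude = wave_amplitude, wave_period = wave_period,
                 leakage_fraction = leakage_fraction,
                 spike_volumes = spike_volumes, spike_amplitude = spike_amplitude,
                 motion = motion_trace(mot, scheme),
                 jacobian = jac),
            class = "synth_scene")
}

make_tissue_masks <- function(grid) {
  ax <- lapply(grid, function(n) (seq_len(n) - (n + 1) / 2) / (n / 2))
  r2 <- outer(outer(ax[[1]]^2, ax[[2]]^2, "+"), ax[[3]]^2, "+")
  brain <- r2 <= 0.9
  csf_outer <- brain & r2 > 0.72
  vent <- r2 <= 0.04
  gm <- brain & !csf_outer & r2 > 0.35 & !vent
  wm <- brain & !csf_outer & !gm & !vent
  list(gm = gm, wm = wm, csf = csf_outer | vent)
}

blob_map <- function(grid, centre, width) {
  ax <- lapply(1:3, function(a) (seq_len(grid[a]) - centre[a]) / width[a])
  exp(-(outer(outer(ax[[1]]^2, ax[[2]]^2, "+"), ax[[3]]^2, "+")) / 2)
}

smooth_field <- function(grid) {
  ax <- lapply(grid, function(n) seq(0, 2 * pi, length.out = n))
  f <- outer(outer(sin(ax[[1]]), cos(ax[[2]]), "+"), sin(ax[[3]]), "+") / 3
  f + stats::rnorm(1, 0, 0.01)
}

max_abs_pairwise_cor <- function(maps, mask) {
  v <- vapply(maps, function(m) m[mask], numeric(sum(mask)))
  cm <- abs(stats::cor(v))
  max(cm[upper.tri(cm)])
}

#' @export
print.synth_scene <- function(x, ...) {
  cat("Synthetic multiband scene: ", paste(x$grid, collapse = " x "),
      " grid, ", x$n_volumes, " volumes, K = ", x$K, " networks\n", sep = "")
  cat("  MB ", x$scheme$mb_factor, ", TR ", x$scheme$tr,
      " s; leakage ", x$leakage_fraction, "; ",
      length(x$spike_volumes), " spike volumes\n", sep = "")
  invisible(x)
}

#' Simulate a BOLD acquisition from a scene
#'
#' Pure function of the scene: the composite signal is `baseline + sum of
#' network map x time-course products + drift + travelling wave`, to which
#' inter-band leakage adds `leakage_fraction` times the mean partner-slice
#' composite signal; intensity spikes are added at spike volumes, everything
#' is multiplied voxel-wise by the Jacobian modulation, and white Gaussian
#' noise is added last. Every additive component is returned separately in
#' the ground-truth bundle, so `bold - (baseline + network + drift + wave +
#' leakage + spike)` equals the noise draw exactly.
#'
#' @param scene A [make_scene()] scene.
#' @return List with `bold` (a [bold_ts()] in acquisition space) and `truth`
#'   (list of 4D component arrays `baseline`, `network`, `drift`, `wave`,
#'   `leakage`, `spike`, `noise`, all after modulation except `noise`, plus
#'   `tcs`, `maps` and the censoring-relevant `spike_volumes`).
#' @export
simulate_scene <- function(scene) {
  stopifnot(inherits(scene, "synth_scene"))
  g <- scene$grid; nt <- scene$n_volumes; sch <- scene$scheme
  brain <- scene$brain_mask
  nvox <- prod(g)

  base3 <- scene$baseline * brain
  net <- array(0, c(g, nt))
  if (scene$K > 0) {
    mapmat <- vapply(scene$maps, as.vector, numeric(nvox))   # nvox x K
    netflat <- mapmat %*% t(scene$tcs) * scene$signal_amplitude
    net <- array(netflat, c(g, nt))
  }

  tt <- seq_len(nt) - 1L
  drift_tc <- scene$drift_amplitude * cos(pi * tt / (nt - 1))
  drift <- outer(array(as.numeric(brain), g), drift_tc)

  # travelling wave: phase advances with excitation index and motion magnitude
  exc <- excitation_of(seq_len(g[3]) - 1L, sch)
  motion_mag <- apply(abs(unclass(scene$motion)), 1, mean)
  phase <- outer(2 * pi * exc / sch$n_excitations,
                 2 * pi * tt / scene$wave_period + motion_mag, "-")
  wave_st <- scene$wave_amplitude * sin(-phase)               # slice x time
  wave <- array(0, c(g, nt))
  for (s in seq_len(g[3]))
    wave[, , s, ] <- wave[, , s, ] + outer(brain[, , s] * 1, wave_st[s, ])

  composite <- sweep(net + drift + wave, 1:3, base3, "+")

  leak <- array(0, c(g, nt))
  if (scene$leakage_fraction > 0) {
    for (s in seq_len(g[3]) - 1L) {
      partners <- partners_of(s, sch)
      if (length(partners) == 0) next
      pm <- composite[, , partners + 1L, , drop = FALSE]
      leak[, , s + 1L, ] <- scene$leakage_fraction *
        apply(pm, c(1, 2, 4), mean) * as.numeric(brain[, , s + 1L])
    }
  }

  spike <- array(0, c(g, nt))
  for (v in scene$spike_volumes)
    spike[, , , v + 1L] <- scene$spike_amplitude * brain

  set.seed(scene$seed + 1L)
  noise <- array(stats::rnorm(nvox * nt, 0, scene$noise_sd), c(g, nt))

  modulate <- function(a) sweep(a, 1:3, scene$jacobian, "*")
  truth <- list(baseline = modulate(outer(base3, rep(1, nt))),
                network = modulate(net), drift = modulate(drift),
                wave = modulate(wave), leakage = modulate(leak),
                spike = modulate(spike), noise = noise,
                tcs = scene$tcs, maps = scene$maps,
                spike_volumes = scene$spike_volumes)
  data <- truth$baseline + truth$network + truth$drift + truth$wave +
    truth$leakage + truth$spike + noise

  list(bold = bold_ts(data, tr = sch$tr, space = "acquisition", brain_mask = brain),
       truth = truth)
}
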