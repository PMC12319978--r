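# Shared fixtures: a small 12-slice MB-3 scheme keeps unit tests fast while
# exercising the same combinatorics as the 48-slice acquisition.

small_scheme <- function() acq_scheme(12, 3, 2.2)

small_scene <- function(seed = 3, n_volumes = 60, K = 2, ...) {
  make_scene(grid = c(12, 12, 12), scheme = small_scheme(), K = K,
             seed = seed, n_volumes = n_volumes, ...)
}

# exhaustive best |r| assignment of recovered onto planted components
# (exact Hungarian solution for the small K used in tests)
match_components <- function(recovered, planted) {
  K <- nrow(planted)
  cc <- abs(stats::cor(t(recovered), t(planted)))
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      out <- c(out, lapply(perms(v[-i]), function(p) c(v[i], p)))
    out
  }
  best <- -Inf; best_p <- NULL
  for (p in perms(seq_len(K))) {
    s <- min(cc[cbind(p, seq_len(K))])
    if (s > best) { best <- s; best_p <- p }
  }
  list(min_abs_r = best, assignment = best_p)
}

# independent scalar oracle for the 60-column MP regressor set: applies each
# operator separately to a single parameter series
mp_oracle_columns <- function(m, ds) {
  dv <- function(x) c(0, diff(x))
  blocks <- list(m, m^2, dv(m), dv(m)^2, dv(dv(m)), dv(dv(m))^2,
                 ds, ds^2, dv(ds), dv(ds)^2)
  do.call(cbind, blocks)
}
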