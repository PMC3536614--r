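# Shared simulation runs, computed once per test session. The default
# network is 200E/40I; the heavier runs are memoized here because several
# tests interrogate different aspects of the same trajectory.
run_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(run_cache[[key]])) run_cache[[key]] <- force(expr)
  run_cache[[key]]
}

# default-parameter run of 10,000 steps (firing statistics, weight
# distribution at the standard observation point)
default_run_10k <- function(seed = 1L) {
  cached(paste0("run10k_", seed),
         sorn_run(sorn_params(seed = seed), 10000L, seed = seed))
}

# long run reaching past the connectivity dip (lifetime statistics, phases)
default_run_50k <- function(seed = 1L) {
  cached(paste0("run50k_", seed),
         sorn_run(sorn_params(seed = seed), 50000L, seed = seed,
                  record_raster = FALSE))
}

tiny_params <- function(ne = 10L, ni = 2L, ...) {
  sorn_params(n_exc = ne, n_inh = ni, ...)
}

# naive reference for one state update: triple-loop drive computation
brute_force_update <- function(state, params, noise_exc, noise_inh) {
  ne <- params$n_exc; ni <- params$n_inh
  x_new <- numeric(ne); y_new <- numeric(ni)
  for (i in seq_len(ne)) {
    drive <- 0
    for (j in seq_len(ne)) drive <- drive + state$w_ee[i, j] * state$x[j]
    for (k in seq_len(ni)) drive <- drive - state$w_ei[i, k] * state$y[k]
    x_new[i] <- as.numeric(drive - state$t_exc[i] + noise_exc[i] > 0)
  }
  for (k in seq_len(ni)) {
    drive <- 0
    for (j in seq_len(ne)) drive <- drive + state$w_ie[k, j] * state$x[j]
    y_new[k] <- as.numeric(drive - state$t_inh[k] + noise_inh[k] > 0)
  }
  list(x = x_new, y = y_new)
}
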