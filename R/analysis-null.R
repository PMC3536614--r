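#' Gibrat proportionate-growth null model
#'
#' Simulates an ensemble of synaptic weights that each grow multiplicatively,
#' `w <- w * exp(eps)` with `eps ~ N(0, growth_sd^2)` per step, optionally
#' rescaled to sum to one after every step (the analogue of synaptic
#' normalization). Without normalization the log-weight variance grows
#' linearly at rate `growth_sd^2` -- unbounded, at odds with biology; with
#' normalization the ensemble stays bounded while retaining a lognormal-like
#' shape. The null model reproduces the weight *distribution* but not the
#' weight-dependent fluctuation pattern of the full network, which is the
#' point of the comparison.
#'
#' @param n_synapses Ensemble size.
#' @param n_steps Number of growth steps.
#' @param growth_sd Standard deviation of the per-step log growth rate
#'   (may be 0: frozen ensemble).
#' @param normalize Rescale the ensemble to sum 1 each step.
#' @param w0 Initial weights; default equal at `1/n_synapses`.
#' @param keep_trajectories Also return the full `(n_steps + 1) x n_synapses`
#'   trajectory matrix.
#' @return A list: `weights` (final), `logvar` (variance of log-weights per
#'   step, length `n_steps + 1`), `trajectories` (matrix or `NULL`),
#'   `growth_sd`, `normalize`.
#' @export
gibrat_null <- function(n_synapses, n_steps, growth_sd, normalize = FALSE,
                        w0 = NULL, keep_trajectories = FALSE) {
  stopifnot(n_synapses >= 2, n_steps >= 1, growth_sd >= 0)
  w <- if (is.null(w0)) rep(1 / n_synapses, n_synapses) else {
    stopifnot(length(w0) == n_synapses, all(w0 > 0))
    w0
  }
  logvar <- numeric(n_steps + 1L)
  logvar[1L] <- stats::var(log(w))
  traj <- if (keep_trajectories) {
    m <- matrix(NA_real_, n_steps + 1L, n_synapses)
    m[1L, ] <- w
    m
  } else NULL
  for (t in seq_len(n_steps)) {
    w <- w * exp(rnorm(n_synapses, 0, growth_sd))
    if (normalize) w <- w / sum(w)
    logvar[t + 1L] <- stats::var(log(w))
    if (keep_trajectories) traj[t + 1L, ] <- w
  }
  list(weights = w, logvar = logvar, trajectories = traj,
       growth_sd = growth_sd, normalize = normalize)
}
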