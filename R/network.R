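#' Initialize a SORN network state
#'
#' Draws the initial synaptic matrices, thresholds and activity of a network.
#' Excitatory-to-excitatory (EE) connectivity is sparse: each ordered non-self
#' pair is connected independently with probability `p_ee_init`, and connected
#' weights are drawn from `init_dist` (default uniform on (0,1]) and then
#' row-normalized so the incoming weights of every excitatory unit sum to one.
#' Inhibitory-to-excitatory (EI) connections are sparse with probability
#' `p_ei_init`, uniform weights, row-normalized. Excitatory-to-inhibitory (IE)
#' connections are dense (all-to-all), uniform, row-normalized, and remain
#' fixed for the lifetime of the network. Thresholds are uniform on
#' `[0, t_exc_max]` / `[0, t_inh_max]`; initial activity is Bernoulli at the
#' target rate.
#'
#' @param params A [sorn_params()] object.
#' @param seed Integer RNG seed; defaults to `params$seed`.
#' @param init_dist Initial EE weight distribution on connected pairs, one of
#'   `"uniform"`, `"gaussian"` (|N(0.5, 0.25)|), `"exponential"` (rate 2) or
#'   `"constant"` (all equal before normalization). Distinctly different
#'   choices all converge to the same long-tailed stationary statistics.
#' @return A `sorn_state` list with elements `w_ee`, `w_ei`, `w_ie` (matrices,
#'   entry `[i, j]` = strength of the connection from unit `j` onto unit `i`),
#'   `t_exc`, `t_inh`, `x`, `y`, `x_prev`, `y_prev`, and `step = 0`.
#' @examples
#' st <- init_network(sorn_params(n_exc = 20, n_inh = 4), seed = 1)
#' range(rowSums(st$w_ie)) # each inhibitory unit's input sums to 1
#' @export
init_network <- function(params, seed = params$seed,
                         init_dist = c("uniform", "gaussian", "exponential", "constant")) {
  validate_params(params)
  init_dist <- match.arg(init_dist)
  set.seed(seed)
  ne <- params$n_exc
  ni <- params$n_inh

  # EE: sparse mask, weights from the chosen distribution, row-normalized
  mask <- matrix(runif(ne * ne) < params$p_ee_init, ne, ne)
  diag(mask) <- FALSE
  nconn <- sum(mask)
  w_ee <- matrix(0, ne, ne)
  if (nconn > 0) {
    w_ee[mask] <- switch(init_dist,
      uniform     = 1 - runif(nconn),          # uniform on (0, 1]
      gaussian    = abs(rnorm(nconn, 0.5, 0.25)) + 1e-12,
      exponential = rexp_pos(nconn, 2),
      constant    = rep(1, nconn)
    )
    w_ee <- normalize_rows(w_ee)
  }

  # EI: sparse, uniform, row-normalized so drive starts E/I balanced
  mask_ei <- matrix(runif(ne * ni) < params$p_ei_init, ne, ni)
  w_ei <- matrix(0, ne, ni)
  nei <- sum(mask_ei)
  if (nei > 0) {
    w_ei[mask_ei] <- 1 - runif(nei)
    w_ei <- normalize_rows(w_ei)
  }

  # IE: dense, fixed after initialization, rows sum to 1
  w_ie <- matrix(1 - runif(ni * ne), ni, ne)
  w_ie <- normalize_rows(w_ie)

  t_exc <- runif(ne, 0, params$t_exc_max)
  t_inh <- runif(ni, 0, params$t_inh_max)

  tr <- expand_target(params)
  x <- as.numeric(runif(ne) < tr)
  y <- as.numeric(runif(ni) < mean(tr))

  structure(list(
    w_ee = w_ee, w_ei = w_ei, w_ie = w_ie,
    t_exc = t_exc, t_inh = t_inh,
    x = x, y = y, x_prev = x, y_prev = y,
    step = 0L
  ), class = "sorn_state")
}

rexp_pos <- function(n, rate) -log(1 - runif(n)) / rate

# divide each nonzero row by its sum (rows index the receiving unit)
normalize_rows <- function(w) {
  rs <- .rowSums(w, nrow(w), ncol(w))
  rs[rs <= 0] <- 1
  w / rs
}

#' One synchronous state update of the network
#'
#' Computes the next binary activity vectors from the current ones. An
#' excitatory unit fires iff its recurrent excitatory drive minus inhibitory
#' drive minus threshold plus Gaussian noise is strictly positive; an
#' inhibitory unit fires iff its excitatory drive minus threshold plus noise
#' is strictly positive. Ties (drive exactly at threshold) stay silent.
#'
#' @param state A `sorn_state` (see [init_network()]).
#' @param params A [sorn_params()] object.
#' @param noise_exc,noise_inh Optional noise vectors; when `NULL` they are
#'   drawn as independent Gaussians with the configured standard deviations
#'   (excitatory noise first, then inhibitory, from the current RNG stream).
#' @return The state with `x`, `y` advanced one step and the previous activity
#'   preserved in `x_prev`, `y_prev`; `step` incremented.
#' @export
update_state <- function(state, params, noise_exc = NULL, noise_inh = NULL) {
  ne <- params$n_exc; ni <- params$n_inh
  stopifnot(length(state$x) == ne, length(state$y) == ni,
            all(dim(state$w_ee) == c(ne, ne)),
            all(dim(state$w_ei) == c(ne, ni)),
            all(dim(state$w_ie) == c(ni, ne)))
  if (is.null(noise_exc)) noise_exc <- rnorm(ne, 0, params$sigma_noise_exc)
  if (is.null(noise_inh)) noise_inh <- rnorm(ni, 0, params$sigma_noise_inh)
  drv <- drive_vectors(state$w_ee, state$w_ei, state$w_ie, state$x, state$y)
  x_new <- as.numeric(drv$exc - state$t_exc + noise_exc > 0)
  y_new <- as.numeric(drv$inh - state$t_inh + noise_inh > 0)
  state$x_prev <- state$x
  state$y_prev <- state$y
  state$x <- x_new
  state$y <- y_new
  state$step <- state$step + 1L
  state
}

# recurrent drives; exploits activity sparsity (column subsetting beats a
# dense matrix product at the typical ~10% firing rate)
drive_vectors <- function(w_ee, w_ei, w_ie, x, y) {
  ax <- which(x > 0)
  ay <- which(y > 0)
  ne <- nrow(w_ee)
  ni <- nrow(w_ie)
  exc_in <- if (length(ax)) .rowSums(w_ee[, ax, drop = FALSE], ne, length(ax)) else numeric(ne)
  inh_in <- if (length(ay)) .rowSums(w_ei[, ay, drop = FALSE], ne, length(ay)) else numeric(ne)
  ie_in  <- if (length(ax)) .rowSums(w_ie[, ax, drop = FALSE], ni, length(ax)) else numeric(ni)
  list(exc = exc_in - inh_in, inh = ie_in)
}
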