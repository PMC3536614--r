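#' Additive STDP on excitatory-to-excitatory weights
#'
#' Applies the causal spike-timing rule to every structurally existing EE
#' synapse: the weight from unit `j` onto unit `i` gains `eta` when `j` fired
#' at the previous step and `i` fires now (pre-before-post), and loses `eta`
#' in the reverse ordering. When both orderings hold the two terms cancel. A
#' weight driven to zero or below is set to exactly 0 and the synapse is
#' eliminated from the network.
#'
#' @param w_ee EE weight matrix, entry `[i, j]` = strength from `j` onto `i`;
#'   a strictly positive entry marks a structurally existing synapse.
#' @param x_now,x_prev Binary excitatory activity at steps `t+1` and `t`.
#' @param eta Nonnegative additive step size.
#' @return A list with `w_ee` (updated matrix) and `deltas`, a list of
#'   parallel vectors `post`, `pre`, `w_before`, `delta`, `eliminated` with
#'   one entry per synapse whose weight changed (unchanged synapses are
#'   omitted; coerce with `as.data.frame()` for a tabular view).
#' @export
stdp_update <- function(w_ee, x_now, x_prev, eta) {
  if (!is.numeric(eta) || length(eta) != 1L || eta < 0) {
    stop("invalid parameter 'eta_stdp': must be >= 0", call. = FALSE)
  }
  empty <- list(post = integer(), pre = integer(), w_before = numeric(),
                delta = numeric(), eliminated = logical())
  if (eta == 0) return(list(w_ee = w_ee, deltas = empty))
  up <- stdp_candidates(w_ee, x_now, x_prev)
  if (length(up$idx) == 0L) return(list(w_ee = w_ee, deltas = empty))
  delta <- eta * up$sign
  w0 <- w_ee[up$idx]
  w1 <- w0 + delta
  elim <- w1 <= 0
  w1[elim] <- 0
  w_ee[up$idx] <- w1
  ne <- nrow(w_ee)
  list(w_ee = w_ee,
       deltas = list(post = ((up$idx - 1L) %% ne) + 1L,
                     pre = ((up$idx - 1L) %/% ne) + 1L,
                     w_before = w0, delta = delta, eliminated = elim))
}

# linear indices of connected synapses with a nonzero STDP term and the sign
# (+1 pre-then-post, -1 post-then-pre); pairs where both terms fire cancel
stdp_candidates <- function(w_ee, x_now, x_prev) {
  a_now <- which(x_now > 0)
  a_prev <- which(x_prev > 0)
  if (length(a_now) == 0L || length(a_prev) == 0L) {
    return(list(idx = integer(), sign = numeric()))
  }
  ne <- nrow(w_ee)
  # potentiation candidates: post i active now, pre j active before
  i_pot <- rep(a_now, times = length(a_prev))
  j_pot <- rep(a_prev, each = length(a_now))
  # depression candidates: post i active before, pre j active now
  i_dep <- rep(a_prev, times = length(a_now))
  j_dep <- rep(a_now, each = length(a_prev))
  idx <- unique(c((j_pot - 1L) * ne + i_pot, (j_dep - 1L) * ne + i_dep))
  idx <- idx[w_ee[idx] > 0]
  if (length(idx) == 0L) return(list(idx = integer(), sign = numeric()))
  i <- ((idx - 1L) %% ne) + 1L
  j <- ((idx - 1L) %/% ne) + 1L
  sgn <- x_now[i] * x_prev[j] - x_prev[i] * x_now[j]
  keep <- sgn != 0
  list(idx = idx[keep], sign = sgn[keep])
}

#' Multiplicative synaptic normalization
#'
#' Rescales the incoming EE weights of every excitatory unit so they sum to
#' one. This models homeostatic synaptic scaling: it preserves the relative
#' strengths established by STDP while capping the total drive a unit
#' receives, which makes incoming synapses compete for a fixed resource. Rows
#' whose sum is zero (units with no incoming synapses) are left untouched.
#'
#' @param w_ee Nonnegative EE weight matrix (rows = receiving units).
#' @return The row-normalized matrix.
#' @export
synaptic_normalization <- function(w_ee) {
  stopifnot(all(w_ee >= 0))
  normalize_rows(w_ee)
}

#' Intrinsic plasticity of excitatory thresholds
#'
#' Moves each excitatory threshold toward the unit's target firing rate: a
#' unit that just fired raises its threshold by `eta_ip * (1 - target)`, a
#' silent unit lowers it by `eta_ip * target`. Thresholds are not clipped at
#' zero; under weak drive homeostasis may push them negative.
#'
#' @param t_exc Excitatory threshold vector.
#' @param x_now Binary excitatory activity.
#' @param eta_ip Nonnegative step size.
#' @param target_rate Target firing probability, scalar or per-unit.
#' @return Updated threshold vector.
#' @export
intrinsic_plasticity <- function(t_exc, x_now, eta_ip, target_rate) {
  stopifnot(eta_ip >= 0)
  t_exc + eta_ip * (x_now - target_rate)
}

#' Structural plasticity: probabilistic synapse creation
#'
#' With probability `p_struct`, draws one ordered non-self pair uniformly from
#' the currently unconnected EE pairs and creates it with weight `w_new`. If
#' every pair is already connected, or the attempt coin fails, nothing
#' changes. Creation is independent of network activity, mirroring the
#' activity-independent generation of new dendritic spines.
#'
#' @param w_ee EE weight matrix (zero entries off the diagonal = unconnected).
#' @param p_struct Attempt probability in `[0, 1]`.
#' @param w_new Strength of the created synapse.
#' @return A list with `w_ee` and `birth`: `c(post, pre)` of the created pair,
#'   or `NULL` when no synapse was created.
#' @export
structural_plasticity <- function(w_ee, p_struct, w_new) {
  if (runif(1) >= p_struct) return(list(w_ee = w_ee, birth = NULL))
  ne <- nrow(w_ee)
  cand <- which(w_ee <= 0)
  cand <- cand[((cand - 1L) %% ne) != ((cand - 1L) %/% ne)] # drop diagonal
  if (length(cand) == 0L) return(list(w_ee = w_ee, birth = NULL))
  pick <- cand[sample.int(length(cand), 1L)]
  w_ee[pick] <- w_new
  list(w_ee = w_ee,
       birth = c(post = ((pick - 1L) %% ne) + 1L, pre = ((pick - 1L) %/% ne) + 1L))
}

#' Inhibitory STDP on inhibitory-to-excitatory weights
#'
#' Balances excitation and inhibition: for every existing EI synapse whose
#' inhibitory unit fired at the previous step, the weight is reduced by
#' `eta_dep` when the excitatory target stayed silent (the inhibitory spike
#' "succeeded") and increased by the larger amount `eta_pot` when the target
#' fired anyway ("unsuccessful" inhibition). Depression clips at `w_floor`
#' rather than eliminating the synapse. Synapses whose inhibitory unit was
#' silent are unchanged.
#'
#' @param w_ei EI weight matrix, entry `[i, k]` = strength from inhibitory `k`
#'   onto excitatory `i`; zero entries are nonexistent synapses.
#' @param y_prev Binary inhibitory activity at step `t`.
#' @param x_now Binary excitatory activity at step `t+1`.
#' @param eta_pot,eta_dep Potentiation / depression steps, `eta_pot > eta_dep`.
#' @param w_floor Minimum retained weight.
#' @return Updated EI matrix.
#' @export
istdp_update <- function(w_ei, y_prev, x_now, eta_pot, eta_dep, w_floor) {
  if (eta_pot <= eta_dep) {
    stop("invalid parameter 'eta_istdp_pot': must exceed eta_istdp_dep", call. = FALSE)
  }
  k_act <- which(y_prev > 0)
  if (length(k_act) == 0L) return(w_ei)
  sub <- w_ei[, k_act, drop = FALSE]
  exists <- sub > 0
  pot <- exists & (x_now == 1)
  dep <- exists & (x_now == 0)
  sub[pot] <- sub[pot] + eta_pot
  sub[dep] <- pmax(sub[dep] - eta_dep, w_floor)
  w_ei[, k_act] <- sub
  w_ei
}
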