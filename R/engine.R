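#' One full simulation step (dynamics + all plasticity rules)
#'
#' Advances the network by one time step, applying in order: (1) the noisy
#' threshold dynamics, (2) STDP on EE weights using the (t, t+1) activity
#' pair, (3) iSTDP on EI weights, (4) synaptic normalization of EE rows,
#' (5) intrinsic plasticity of excitatory thresholds, (6) one structural
#' plasticity attempt. Normalization follows STDP so the incoming-sum-to-one
#' invariant holds at every step boundary; structural birth comes last so a
#' newborn synapse enters the next step at exactly `w_new`.
#'
#' Each mechanism can be ablated independently, which reproduces the
#' switch-off experiments (bursting without normalization, activity
#' extinction without intrinsic plasticity or iSTDP, connectivity collapse
#' without structural plasticity).
#'
#' @param state A `sorn_state` bundle (see [init_network()]).
#' @param params A [sorn_params()] object.
#' @param ablate Character vector of mechanisms to disable, a subset of
#'   `c("stdp", "normalization", "intrinsic", "istdp", "structural")`.
#' @return A list with `state` (advanced bundle), `deltas` (STDP changes this
#'   step, see [stdp_update()]) and `birth` (created pair or `NULL`).
#' @export
sorn_step <- function(state, params, ablate = character()) {
  ablate <- match_ablate(ablate)
  state <- update_state(state, params)
  deltas <- NULL
  if (!"stdp" %in% ablate) {
    up <- stdp_update(state$w_ee, state$x, state$x_prev, params$eta_stdp)
    state$w_ee <- up$w_ee
    deltas <- up$deltas
  }
  if (!"istdp" %in% ablate) {
    state$w_ei <- istdp_update(state$w_ei, state$y_prev, state$x,
                               params$eta_istdp_pot, params$eta_istdp_dep,
                               params$w_ei_floor)
  }
  if (!"normalization" %in% ablate) {
    # same arithmetic as synaptic_normalization(); skips its validation scan
    state$w_ee <- normalize_rows(state$w_ee)
  }
  if (!"intrinsic" %in% ablate) {
    state$t_exc <- intrinsic_plasticity(state$t_exc, state$x, params$eta_ip,
                                        expand_target(params))
  }
  birth <- NULL
  if (!"structural" %in% ablate) {
    sp <- structural_plasticity(state$w_ee, params$p_struct, params$w_new)
    state$w_ee <- sp$w_ee
    birth <- sp$birth
  }
  list(state = state, deltas = deltas, birth = birth)
}

match_ablate <- function(ablate) {
  ok <- c("stdp", "normalization", "intrinsic", "istdp", "structural")
  bad <- setdiff(ablate, ok)
  if (length(bad)) {
    stop("unknown ablation mechanism(s): ", paste(bad, collapse = ", "),
         " (choose from ", paste(ok, collapse = ", "), ")", call. = FALSE)
  }
  ablate
}

#' Run a SORN simulation
#'
#' Initializes a network (or resumes from a checkpoint) and iterates
#' [sorn_step()] for `n_steps`, recording the spike raster, the fraction of
#' existing EE connections, periodic sparse weight snapshots, the synapse
#' birth/death event log, and optionally the per-step STDP deltas needed for
#' the rich-get-richer analyses. All randomness flows through R's global RNG,
#' seeded once at the start (draw order per step: excitatory noise,
#' inhibitory noise, structural attempt), so a given seed reproduces a run
#' bit-exactly.
#'
#' The returned record carries a `checkpoint` (final state bundle plus RNG
#' state); passing it as `resume` continues the run exactly as if it had
#' never been interrupted.
#'
#' @param params A [sorn_params()] object.
#' @param n_steps Number of steps to simulate (>= 1).
#' @param seed RNG seed (ignored when resuming).
#' @param init_dist Initial EE weight distribution, see [init_network()].
#' @param snapshot_every Cadence (steps) of sparse EE weight snapshots; 0
#'   disables periodic snapshots. The initial and final states are always
#'   snapshotted.
#' @param record_raster Keep the full binary spike raster (matrices with
#'   `n_steps + 1` rows; row 1 is the initial state).
#' @param record_deltas Keep every STDP weight change (step, pair, weight
#'   before, signed delta). Needed by [stdp_conditional_curves()].
#' @param ablate Mechanisms to disable, see [sorn_step()].
#' @param resume A checkpoint from a previous record, or `NULL`.
#' @param memory_budget_mb Guard: error out if the raster plus projected
#'   snapshot storage would exceed this budget.
#' @return A `sorn_record` list: `params`, `seed`, `n_steps`, `ablate`,
#'   `raster_exc`, `raster_inh`, `connection_fraction`, `snapshots` (list of
#'   `list(step, pairs)` with `pairs` a data.frame `post, pre, w`), `events`
#'   (data.frame `post, pre, birth_step, death_step, cause`; `birth_step` NA
#'   for initial synapses, `death_step` NA while alive), `deltas`,
#'   `checkpoint`, `meta`.
#' @examples
#' rec <- sorn_run(sorn_params(n_exc = 20, n_inh = 4), n_steps = 50, seed = 1)
#' tail(rec$connection_fraction, 1)
#' @export
sorn_run <- function(params, n_steps, seed = params$seed,
                     init_dist = "uniform",
                     snapshot_every = 200L, record_raster = TRUE,
                     record_deltas = FALSE, ablate = character(),
                     resume = NULL, memory_budget_mb = 4096) {
  validate_params(params)
  ablate <- match_ablate(ablate)
  stopifnot(n_steps >= 1)
  n_steps <- as.integer(n_steps)
  ne <- params$n_exc; ni <- params$n_inh

  est_mb <- (as.numeric(n_steps) * (ne + ni) * 4 * record_raster +
             ifelse(snapshot_every > 0, n_steps / snapshot_every, 2) *
               (params$p_ee_init * ne * ne + n_steps * params$p_struct) * 24) / 2^20
  if (est_mb > memory_budget_mb) {
    stop(sprintf("recording would need ~%.0f MB, over the %.0f MB budget; ",
                 est_mb, memory_budget_mb),
         "raise memory_budget_mb, drop the raster, or coarsen snapshot_every",
         call. = FALSE)
  }

  if (is.null(resume)) {
    state <- init_network(params, seed = seed, init_dist = init_dist)
  } else {
    state <- resume$state
    assign(".Random.seed", resume$rng_state, envir = globalenv())
  }

  # --- event log: one row per synapse life, grown geometrically
  alive0 <- which(state$w_ee > 0)
  cap <- length(alive0) + as.integer(2 * n_steps * params$p_struct) + 64L
  ev_post <- integer(cap); ev_pre <- integer(cap)
  ev_birth <- rep(NA_integer_, cap); ev_death <- rep(NA_integer_, cap)
  n_ev <- length(alive0)
  ev_post[seq_len(n_ev)] <- ((alive0 - 1L) %% ne) + 1L
  ev_pre[seq_len(n_ev)] <- ((alive0 - 1L) %/% ne) + 1L
  birth_idx <- matrix(0L, ne, ne)   # alive pair -> row in event log
  birth_idx[alive0] <- seq_len(n_ev)

  grow <- function() {
    cap2 <- 2L * length(ev_post)
    length(ev_post) <<- cap2; length(ev_pre) <<- cap2
    ev_birth <<- c(ev_birth, rep(NA_integer_, cap2 - length(ev_birth)))
    ev_death <<- c(ev_death, rep(NA_integer_, cap2 - length(ev_death)))
  }

  if (record_raster) {
    raster_exc <- matrix(0L, n_steps + 1L, ne)
    raster_inh <- matrix(0L, n_steps + 1L, ni)
    raster_exc[1L, ] <- as.integer(state$x)
    raster_inh[1L, ] <- as.integer(state$y)
  }
  n_pairs <- ne * (ne - 1)
  n_conn <- length(alive0)
  conn_frac <- numeric(n_steps + 1L)
  conn_frac[1L] <- n_conn / n_pairs

  snaps <- list()
  take_snap <- function(step_now, w) {
    idx <- which(w > 0)
    snaps[[length(snaps) + 1L]] <<- list(
      step = step_now,
      pairs = data.frame(post = ((idx - 1L) %% ne) + 1L,
                         pre = ((idx - 1L) %/% ne) + 1L,
                         w = w[idx]))
  }
  take_snap(0L, state$w_ee)

  delta_chunks <- if (record_deltas) vector("list", n_steps) else NULL

  for (t in seq_len(n_steps)) {
    out <- sorn_step(state, params, ablate)
    state <- out$state

    d <- out$deltas
    if (!is.null(d) && length(d$post)) {
      if (record_deltas) {
        delta_chunks[[t]] <- c(d, list(step = rep.int(t, length(d$post))))
      }
      if (any(d$eliminated)) {
        sel <- d$eliminated
        key <- cbind(d$post[sel], d$pre[sel])
        ev_death[birth_idx[key]] <- t
        birth_idx[key] <- 0L
        n_conn <- n_conn - sum(sel)
      }
    }
    b <- out$birth
    if (!is.null(b)) {
      n_ev <- n_ev + 1L
      if (n_ev > length(ev_post)) grow()
      ev_post[n_ev] <- b[["post"]]; ev_pre[n_ev] <- b[["pre"]]
      ev_birth[n_ev] <- t
      birth_idx[b[["post"]], b[["pre"]]] <- n_ev
      n_conn <- n_conn + 1L
    }

    if (record_raster) {
      raster_exc[t + 1L, ] <- as.integer(state$x)
      raster_inh[t + 1L, ] <- as.integer(state$y)
    }
    conn_frac[t + 1L] <- n_conn / n_pairs
    if (snapshot_every > 0 && t %% snapshot_every == 0L && t < n_steps) {
      take_snap(t, state$w_ee)
    }
  }
  take_snap(n_steps, state$w_ee)

  keep <- seq_len(n_ev)
  events <- data.frame(post = ev_post[keep], pre = ev_pre[keep],
                       birth_step = ev_birth[keep], death_step = ev_death[keep],
                       cause = ifelse(is.na(ev_death[keep]), NA_character_,
                                      "stdp_elimination"))
  deltas <- if (record_deltas) {
    as.data.frame(data.table::rbindlist(delta_chunks[!vapply(delta_chunks, is.null, TRUE)]))
  } else NULL

  structure(list(
    params = params, seed = if (is.null(resume)) seed else NA_integer_,
    n_steps = n_steps, ablate = ablate, init_dist = init_dist,
    snapshot_every = as.integer(snapshot_every),
    raster_exc = if (record_raster) raster_exc else NULL,
    raster_inh = if (record_raster) raster_inh else NULL,
    connection_fraction = conn_frac,
    snapshots = snaps,
    events = events,
    deltas = deltas,
    checkpoint = list(state = state,
                      rng_state = get(".Random.seed", envir = globalenv())),
    meta = list(package_version = as.character(utils::packageVersion("sorn")))
  ), class = "sorn_record")
}

#' @export
print.sorn_record <- function(x, ...) {
  cat(sprintf("SORN record: %d steps, %dE/%dI, seed %s\n", x$n_steps,
              x$params$n_exc, x$params$n_inh, format(x$seed)))
  cat(sprintf("  final connection fraction %.4f; %d synapse lives logged; %d snapshots\n",
              tail(x$connection_fraction, 1), nrow(x$events), length(x$snapshots)))
  if (length(x$ablate)) cat("  ablated:", paste(x$ablate, collapse = ", "), "\n")
  invisible(x)
}

# snapshot lookup by step index
snapshot_at <- function(record, step) {
  steps <- vapply(record$snapshots, `[[`, integer(1), "step")
  hit <- which(steps == step)
  if (!length(hit)) {
    stop("no snapshot at step ", step, "; available: ",
         paste(steps, collapse = ", "), call. = FALSE)
  }
  record$snapshots[[hit[1]]]
}
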