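#' Network and plasticity parameters
#'
#' Constructs the full parameter set of a SORN: a recurrent network of binary
#' threshold neurons (default 200 excitatory, 40 inhibitory) shaped by five
#' plasticity mechanisms. All probabilities, learning rates and noise scales
#' are per discrete time step; one step corresponds roughly to a membrane time
#' constant / STDP window (10--20 ms), with the homeostatic mechanisms run
#' much faster than their biological counterparts (separation of time scales).
#'
#' @param n_exc Number of excitatory units.
#' @param n_inh Number of inhibitory units.
#' @param p_ee_init Probability that a given ordered non-self pair of
#'   excitatory units is structurally connected at initialization.
#' @param p_ei_init Probability that a given inhibitory unit connects onto a
#'   given excitatory unit at initialization.
#' @param eta_stdp Additive STDP step size for excitatory-to-excitatory
#'   weights.
#' @param eta_istdp_pot iSTDP potentiation step, applied to an
#'   inhibitory-to-excitatory weight when the inhibitory spike failed to
#'   silence the excitatory unit. Must exceed `eta_istdp_dep`.
#' @param eta_istdp_dep iSTDP depression step, applied when the inhibitory
#'   spike successfully silenced the excitatory unit.
#' @param eta_ip Intrinsic-plasticity threshold step size.
#' @param target_rate Target firing probability of excitatory units; scalar or
#'   a vector of length `n_exc`.
#' @param sigma_noise_exc,sigma_noise_inh Standard deviations of the white
#'   Gaussian membrane noise of excitatory / inhibitory units.
#' @param p_struct Per-step probability of one structural-plasticity attempt
#'   (creation of a new excitatory-to-excitatory synapse).
#' @param w_new Strength assigned to a newly created synapse.
#' @param w_ei_floor Smallest retained inhibitory-to-excitatory weight; iSTDP
#'   depression clips here instead of eliminating the synapse.
#' @param t_exc_max,t_inh_max Upper bounds of the uniform intervals from which
#'   excitatory / inhibitory thresholds are drawn at initialization.
#' @param hist_exclusion Weight below or at which synapses are excluded from
#'   weight histograms and distribution fits (mimics the detection limit of
#'   spine-imaging experiments).
#' @param seed Default RNG seed carried with the parameter set.
#'
#' @return An object of class `sorn_params` (a validated named list).
#' @examples
#' p <- sorn_params(n_exc = 20, n_inh = 4)
#' p$target_rate
#' @export
sorn_params <- function(n_exc = 200L,
                        n_inh = 40L,
                        p_ee_init = 0.1,
                        p_ei_init = 0.2,
                        eta_stdp = 0.004,
                        eta_istdp_pot = 0.01,
                        eta_istdp_dep = 0.001,
                        eta_ip = 0.01,
                        target_rate = 0.1,
                        sigma_noise_exc = sqrt(0.05),
                        sigma_noise_inh = sqrt(0.05),
                        p_struct = 0.1,
                        w_new = 0.001,
                        w_ei_floor = 0.001,
                        t_exc_max = 0.5,
                        t_inh_max = 1.0,
                        hist_exclusion = 1e-4,
                        seed = 1L) {
  p <- list(
    n_exc = as.integer(n_exc), n_inh = as.integer(n_inh),
    p_ee_init = p_ee_init, p_ei_init = p_ei_init,
    eta_stdp = eta_stdp,
    eta_istdp_pot = eta_istdp_pot, eta_istdp_dep = eta_istdp_dep,
    eta_ip = eta_ip, target_rate = target_rate,
    sigma_noise_exc = sigma_noise_exc, sigma_noise_inh = sigma_noise_inh,
    p_struct = p_struct, w_new = w_new, w_ei_floor = w_ei_floor,
    t_exc_max = t_exc_max, t_inh_max = t_inh_max,
    hist_exclusion = hist_exclusion, seed = as.integer(seed)
  )
  class(p) <- "sorn_params"
  validate_params(p)
  p
}

#' Validate a parameter set
#'
#' Checks every field of a [sorn_params()] object against its admissible
#' range and the cross-field constraints (e.g. the iSTDP potentiation step
#' must exceed the depression step). Errors name the offending field.
#'
#' @param p A `sorn_params` object (or a bare list with the same fields).
#' @return `p`, invisibly, if valid.
#' @export
validate_params <- function(p) {
  chk <- function(cond, field, msg) {
    if (!isTRUE(cond)) stop(sprintf("invalid parameter '%s': %s", field, msg), call. = FALSE)
  }
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  chk(num1(p$n_exc) && p$n_exc >= 1, "n_exc", "must be >= 1")
  chk(num1(p$n_inh) && p$n_inh >= 1, "n_inh", "must be >= 1")
  for (f in c("p_ee_init", "p_ei_init", "p_struct")) {
    chk(num1(p[[f]]) && p[[f]] >= 0 && p[[f]] <= 1, f, "must be a probability in [0,1]")
  }
  for (f in c("eta_stdp", "eta_istdp_pot", "eta_istdp_dep", "eta_ip",
              "sigma_noise_exc", "sigma_noise_inh")) {
    chk(num1(p[[f]]) && p[[f]] >= 0, f, "must be >= 0")
  }
  tr <- p$target_rate
  chk(is.numeric(tr) && (length(tr) == 1L || length(tr) == p$n_exc) &&
        all(tr > 0 & tr < 1), "target_rate",
      "must lie in (0,1), scalar or length n_exc")
  chk(num1(p$w_new) && p$w_new > 0, "w_new", "must be > 0")
  chk(num1(p$w_ei_floor) && p$w_ei_floor > 0, "w_ei_floor", "must be > 0")
  chk(num1(p$t_exc_max) && p$t_exc_max >= 0, "t_exc_max", "must be >= 0")
  chk(num1(p$t_inh_max) && p$t_inh_max >= 0, "t_inh_max", "must be >= 0")
  chk(num1(p$hist_exclusion) && p$hist_exclusion >= 0, "hist_exclusion", "must be >= 0")
  chk(p$eta_istdp_pot > p$eta_istdp_dep, "eta_istdp_pot",
      "iSTDP potentiation step must exceed the depression step")
  invisible(p)
}

#' @export
print.sorn_params <- function(x, ...) {
  cat("SORN parameters:", x$n_exc, "excitatory /", x$n_inh, "inhibitory units\n")
  flds <- setdiff(names(x), c("n_exc", "n_inh"))
  for (f in flds) cat(sprintf("  %-16s %s\n", f, paste(format(x[[f]]), collapse = " ")))
  invisible(x)
}

# target rate expanded to a per-unit vector
expand_target <- function(p) {
  if (length(p$target_rate) == 1L) rep(p$target_rate, p$n_exc) else p$target_rate
}
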