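#' Rich-get-richer curves: STDP outcome conditioned on synaptic weight
#'
#' Isolates the effect of STDP from synaptic normalization: for each weight
#' bin, the fraction of synapse-steps in which a synapse of that strength was
#' potentiated, the fraction in which it was depressed, and the net
#' normalized difference `(n_pot - n_dep) / n_total`. Event counts come from
#' the per-step STDP delta log (binned by the weight *before* the change);
#' the number of synapse-steps spent in each bin is estimated from the
#' periodic snapshots, each covering the steps up to the next snapshot.
#' A rising potentiation fraction with weight -- while depression stays
#' roughly flat -- is the rich-get-richer signature that turns additive STDP
#' into effectively multiplicative weight dynamics.
#'
#' @param record A `sorn_record` run with `record_deltas = TRUE`, or a list
#'   with elements `deltas` and `snapshots` in the record's format.
#' @param bins Weight-bin edges; default 20 bins uniform on the log scale
#'   over the observed snapshot weights.
#' @param exclusion Weights `<= exclusion` are ignored.
#' @return A data.frame: `bin_lo`, `bin_hi`, `mid`, `frac_pot`, `frac_dep`,
#'   `net`, `n_pot`, `n_dep`, `n_total` (estimated synapse-steps). Bins with
#'   no occupancy have `NA` fractions.
#' @export
stdp_conditional_curves <- function(record, bins = NULL, exclusion = 1e-4) {
  deltas <- record$deltas
  snaps <- record$snapshots
  if (is.null(deltas)) {
    stop("record has no STDP delta log; rerun with record_deltas = TRUE",
         call. = FALSE)
  }
  stopifnot(length(snaps) >= 1)
  snap_w <- unlist(lapply(snaps, function(s) s$pairs$w))
  snap_w <- snap_w[snap_w > exclusion]
  if (is.null(bins)) {
    bins <- 10^seq(log10(min(snap_w)), log10(max(snap_w)), length.out = 21L)
    bins[1] <- min(snap_w); bins[length(bins)] <- max(snap_w)
  }
  nb <- length(bins) - 1L

  # synapse-steps per bin: snapshot occupancy times steps covered
  steps <- vapply(snaps, `[[`, numeric(1), "step")
  coverage <- c(diff(steps), 0)
  n_total <- rep(0, nb)
  for (i in seq_along(snaps)) {
    if (coverage[i] <= 0) next
    w <- snaps[[i]]$pairs$w
    w <- w[w > exclusion]
    bi <- findInterval(w, bins, rightmost.closed = TRUE)
    ok <- bi >= 1 & bi <= nb
    n_total <- n_total + tabulate(bi[ok], nbins = nb) * coverage[i]
  }

  w0 <- deltas$w_before
  keep <- w0 > exclusion
  bi <- findInterval(w0[keep], bins, rightmost.closed = TRUE)
  ok <- bi >= 1 & bi <= nb
  bi <- bi[ok]
  dsign <- deltas$delta[keep][ok]
  n_pot <- tabulate(bi[dsign > 0], nbins = nb)
  n_dep <- tabulate(bi[dsign < 0], nbins = nb)

  frac <- function(num) ifelse(n_total > 0, num / n_total, NA_real_)
  data.frame(bin_lo = bins[-length(bins)], bin_hi = bins[-1L],
             mid = sqrt(bins[-length(bins)] * bins[-1L]),
             frac_pot = frac(n_pot), frac_dep = frac(n_dep),
             net = frac(n_pot - n_dep),
             n_pot = n_pot, n_dep = n_dep, n_total = n_total)
}
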