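#' Inter-spike-interval and coefficient-of-variation statistics
#'
#' Computes, for every unit of a binary spike raster, the inter-spike
#' intervals (gaps between consecutive spikes) after a washout period, the
#' maximum-likelihood exponential rate fitted to those ISIs, and the
#' coefficient of variation CV = sd(ISI)/mean(ISI). A CV near 1 with an
#' exponential ISI distribution is the signature of Poisson-like irregular
#' firing. Units with fewer than 3 ISIs are excluded from CV summaries and
#' flagged; units that never spike are flagged separately.
#'
#' @param raster Binary matrix, rows = time steps, columns = units.
#' @param washout Number of leading steps to discard (arbitrary initial
#'   transient).
#' @return A list: `isi` (per-unit integer vectors), `rate` (per-unit
#'   exponential MLE rate, `1/mean(ISI)`), `cv` (per-unit CV, `NA` where
#'   excluded), `mean_cv`, `excluded_units`, `silent_units`.
#' @export
isi_cv_stats <- function(raster, washout = 3000L) {
  stopifnot(nrow(raster) > washout + 1)
  sub <- raster[(washout + 1L):nrow(raster), , drop = FALSE]
  nu <- ncol(sub)
  isi <- vector("list", nu)
  rate <- rep(NA_real_, nu)
  cv <- rep(NA_real_, nu)
  silent <- logical(nu)
  for (u in seq_len(nu)) {
    sp <- which(sub[, u] > 0)
    if (length(sp) == 0L) {
      silent[u] <- TRUE
      isi[[u]] <- integer()
      next
    }
    gaps <- diff(sp)
    isi[[u]] <- gaps
    if (length(gaps) >= 1L) rate[u] <- 1 / mean(gaps)
    if (length(gaps) >= 3L) cv[u] <- sd(gaps) / mean(gaps)
  }
  list(isi = isi, rate = rate, cv = cv,
       mean_cv = mean(cv, na.rm = TRUE),
       excluded_units = which(is.na(cv)),
       silent_units = which(silent))
}

#' Pairwise Pearson correlations of spike trains
#'
#' Correlation matrix of the raw binary trains after washout. Constant trains
#' (always silent or always active) have undefined correlations; their
#' entries are `NA` and the units are listed in `constant_units`.
#'
#' @param raster Binary matrix, rows = steps, columns = units (excitatory and
#'   inhibitory trains may be column-bound to reproduce whole-network maps).
#' @param washout Leading steps to discard.
#' @return A list: `r` (correlation matrix), `constant_units`.
#' @export
pairwise_correlations <- function(raster, washout = 3000L) {
  stopifnot(nrow(raster) >= washout + 2)
  sub <- raster[(washout + 1L):nrow(raster), , drop = FALSE]
  v <- apply(sub, 2, stats::var)
  r <- suppressWarnings(cor(sub))
  list(r = r, constant_units = which(v == 0))
}

#' Return map of the excitatory population activity
#'
#' The fraction of active excitatory units `a(t)` plotted against `a(t+1)`
#' shows at a glance whether network activity is confined to a healthy band:
#' with all plasticity mechanisms active the cloud stays in a small region
#' away from 0 and 1, whereas removing intrinsic plasticity or iSTDP lets
#' activity die out or explode.
#'
#' @param raster Binary excitatory raster (steps x units).
#' @param washout Leading steps to discard.
#' @return A list: `a_t`, `a_next` (the point set), `min_activity`,
#'   `max_activity`, `n_silent` (number of post-washout steps with no active
#'   excitatory unit).
#' @export
activity_return_map <- function(raster, washout = 3000L) {
  stopifnot(nrow(raster) >= washout + 2)
  a <- rowMeans(raster[(washout + 1L):nrow(raster), , drop = FALSE])
  list(a_t = a[-length(a)], a_next = a[-1L],
       min_activity = min(a), max_activity = max(a),
       n_silent = sum(a == 0))
}
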