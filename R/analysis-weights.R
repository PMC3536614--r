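#' Log-binned weight histogram
#'
#' Bins weights into intervals of uniform width on the log scale and reports
#' the density as count divided by the *linear* bin width, the standard way
#' long-tailed synaptic strength distributions are displayed. Mimicking the
#' detection limit of spine imaging, weights at or below `exclusion` are
#' dropped before binning.
#'
#' @param weights Nonnegative weight vector.
#' @param exclusion Weights `<= exclusion` are excluded.
#' @param n_bins Number of bins.
#' @return A `sorn_loghist` list: `edges` (length `n_bins + 1`), `counts`,
#'   `density` (count / linear width), `mids` (geometric bin centers),
#'   `n_included`, `exclusion`. Conservation: `sum(density * diff(edges))`
#'   equals `n_included`.
#' @export
weight_histogram <- function(weights, exclusion = 1e-4, n_bins = 30L) {
  stopifnot(all(weights >= 0))
  w <- weights[weights > exclusion]
  if (length(w) == 0L) {
    stop("no weights above the exclusion threshold ", exclusion, call. = FALSE)
  }
  lo <- min(w); hi <- max(w)
  if (lo == hi) {
    edges <- c(lo / 1.01, hi * 1.01)   # degenerate support: one bin
    counts <- length(w)
  } else {
    edges <- 10^seq(log10(lo), log10(hi), length.out = n_bins + 1L)
    edges[1] <- lo; edges[length(edges)] <- hi   # guard rounding at extremes
    bin <- findInterval(w, edges, rightmost.closed = TRUE)
    counts <- tabulate(bin, nbins = length(edges) - 1L)
  }
  structure(list(edges = edges, counts = counts,
                 density = counts / diff(edges),
                 mids = sqrt(edges[-length(edges)] * edges[-1L]),
                 n_included = length(w), exclusion = exclusion),
            class = "sorn_loghist")
}

#' Maximum-likelihood lognormal fit
#'
#' Fits a lognormal distribution to the weights above the exclusion
#' threshold: `meanlog` and `sdlog` are the ML mean and standard deviation of
#' the log-weights (equivalently, a Gaussian fit on the log scale).
#' Goodness of fit is the one-sample Kolmogorov-Smirnov statistic against the
#' fitted distribution.
#'
#' @param weights Nonnegative weight vector.
#' @param exclusion Weights `<= exclusion` are excluded before fitting.
#' @return A `sorn_fit` list: `family = "lognormal"`, `meanlog`, `sdlog`,
#'   `gof_ks`, `n`.
#' @export
fit_lognormal <- function(weights, exclusion = 1e-4) {
  w <- weights[weights > exclusion]
  if (length(w) < 10L) {
    stop("insufficient data: need >= 10 weights above exclusion, got ",
         length(w), call. = FALSE)
  }
  lw <- log(w)
  mu <- mean(lw)
  sigma <- sqrt(mean((lw - mu)^2))   # ML estimate (divisor n)
  ks <- suppressWarnings(ks.test(w, plnorm, meanlog = mu, sdlog = sigma))
  structure(list(family = "lognormal", meanlog = mu, sdlog = sigma,
                 gof_ks = unname(ks$statistic), n = length(w)),
            class = "sorn_fit")
}

#' Maximum-likelihood exponential fit
#'
#' Companion to [fit_lognormal()] for model comparison (e.g. ISI
#' distributions, or screening whether weights are better described by a
#' lognormal than by an exponential): rate = 1/mean, KS statistic against the
#' fitted exponential.
#'
#' @param x Positive sample.
#' @return A `sorn_fit` list: `family = "exponential"`, `rate`, `gof_ks`, `n`.
#' @export
fit_exponential <- function(x) {
  x <- x[x > 0]
  stopifnot(length(x) >= 2)
  rate <- 1 / mean(x)
  ks <- suppressWarnings(ks.test(x, stats::pexp, rate = rate))
  structure(list(family = "exponential", rate = rate,
                 gof_ks = unname(ks$statistic), n = length(x)),
            class = "sorn_fit")
}

#' @export
print.sorn_fit <- function(x, ...) {
  pars <- setdiff(names(x), c("family", "gof_ks", "n"))
  cat(sprintf("%s fit (n = %d): %s; KS = %.4f\n", x$family, x$n,
              paste(sprintf("%s = %.4g", pars,
                            vapply(x[pars], as.numeric, 0)), collapse = ", "),
              x$gof_ks))
  invisible(x)
}

#' Minimal top fraction of weights holding a given share of total weight
#'
#' Sorts weights in decreasing order and accumulates until the running sum
#' reaches `share` of the total; returns the number of weights used as a
#' fraction of all positive weights. In cortex roughly the top 20% of
#' synapses carry 50% of the total synaptic weight; the self-organized
#' network reproduces this concentration.
#'
#' @param weights Nonnegative weight vector.
#' @param share Target share of the total weight, in (0, 1].
#' @return Fraction in (0, 1] of weights needed to reach `share`.
#' @export
top_share <- function(weights, share = 0.5) {
  stopifnot(share > 0, share <= 1)
  w <- weights[weights > 0]
  if (length(w) == 0L) stop("no positive weights", call. = FALSE)
  ws <- sort(w, decreasing = TRUE)
  k <- which(cumsum(ws) >= share * sum(ws))[1L]
  k / length(ws)
}

# accept either a record snapshot (list(step, pairs)) or a bare pairs table
snap_pairs <- function(s) {
  if (is.list(s) && !is.null(s$pairs)) s$pairs else s
}

pair_key <- function(post, pre) post * 1000000 + pre  # n_exc < 1e6 assumed

#' Weight changes between two snapshots
#'
#' Compares two sparse EE weight snapshots from the same run and splits all
#' pairs into three populations: `persisting` (present in both, with the
#' relative change B/A or absolute change B-A), `eliminated` (present only in
#' the earlier snapshot) and `newborn` (present only in the later one) --
#' the model analogue of spine-imaging change distributions, where strong
#' synapses show comparatively small relative fluctuations.
#'
#' @param snap_a,snap_b Snapshots (`list(step, pairs)` as stored in a
#'   `sorn_record`, or bare data.frames with columns `post`, `pre`, `w`).
#' @param mode `"relative"` (ratio B/A) or `"absolute"` (difference B-A).
#' @return A list: `mode`, `persisting` (data.frame `post, pre, w_a, w_b,
#'   change`), `eliminated` (`post, pre, w_a`), `newborn` (`post, pre, w_b`),
#'   and the three population counts.
#' @export
weight_change_stats <- function(snap_a, snap_b, mode = c("relative", "absolute")) {
  mode <- match.arg(mode)
  a <- snap_pairs(snap_a); b <- snap_pairs(snap_b)
  ka <- pair_key(a$post, a$pre); kb <- pair_key(b$post, b$pre)
  m <- match(ka, kb)
  pers <- !is.na(m)
  w_a <- a$w[pers]; w_b <- b$w[m[pers]]
  change <- if (mode == "relative") w_b / w_a else w_b - w_a
  list(mode = mode,
       persisting = data.frame(post = a$post[pers], pre = a$pre[pers],
                               w_a = w_a, w_b = w_b, change = change),
       eliminated = data.frame(post = a$post[!pers], pre = a$pre[!pers],
                               w_a = a$w[!pers]),
       newborn = {
         new <- is.na(match(kb, ka))
         data.frame(post = b$post[new], pre = b$pre[new], w_b = b$w[new])
       },
       n_persisting = sum(pers), n_eliminated = sum(!pers),
       n_newborn = sum(is.na(match(kb, ka))))
}

#' Mean absolute weight change as a function of starting weight
#'
#' Pairs consecutive snapshots (taken at the recording cadence) and averages
#' the absolute per-interval weight change |dw| within bins of the starting
#' weight. In the self-organized network the fluctuation amplitude grows
#' roughly linearly with weight -- multiplicative-looking dynamics despite
#' the additive STDP rule. A pair eliminated by the later snapshot
#' contributes |dw| = w.
#'
#' @param snapshots A `sorn_record`, or its `snapshots` list (>= 2 entries).
#' @param bins Bin edges for the starting weight; default 20 bins uniform on
#'   the log scale over the observed range.
#' @param exclusion Starting weights `<= exclusion` are ignored.
#' @return A data.frame: `bin_lo`, `bin_hi`, `mid`, `mean_abs_change`, `n`.
#' @export
fluctuation_vs_weight <- function(snapshots, bins = NULL, exclusion = 1e-4) {
  if (inherits(snapshots, "sorn_record")) snapshots <- snapshots$snapshots
  stopifnot(length(snapshots) >= 2)
  w0 <- numeric(0); dw <- numeric(0)
  for (i in seq_len(length(snapshots) - 1L)) {
    a <- snap_pairs(snapshots[[i]]); b <- snap_pairs(snapshots[[i + 1L]])
    m <- match(pair_key(a$post, a$pre), pair_key(b$post, b$pre))
    wb <- ifelse(is.na(m), 0, b$w[m])
    keep <- a$w > exclusion
    w0 <- c(w0, a$w[keep])
    dw <- c(dw, abs(wb - a$w)[keep])
  }
  if (is.null(bins)) {
    bins <- 10^seq(log10(min(w0)), log10(max(w0)), length.out = 21L)
    bins[1] <- min(w0); bins[length(bins)] <- max(w0)
  }
  bi <- findInterval(w0, bins, rightmost.closed = TRUE)
  ok <- bi >= 1 & bi <= length(bins) - 1L
  n <- tabulate(bi[ok], nbins = length(bins) - 1L)
  s <- rep(0, length(bins) - 1L)
  agg <- tapply(dw[ok], bi[ok], sum)
  s[as.integer(names(agg))] <- agg
  data.frame(bin_lo = bins[-length(bins)], bin_hi = bins[-1L],
             mid = sqrt(bins[-length(bins)] * bins[-1L]),
             mean_abs_change = ifelse(n > 0, s / n, NA_real_), n = n)
}
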