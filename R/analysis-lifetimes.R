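#' Lifetimes of structurally created synapses
#'
#' Extracts, from a run's event log, the lifetime (death step minus birth
#' step) of every synapse that was created by structural plasticity and
#' eliminated by STDP within the horizon. Synapses still alive at the horizon
#' are right-censored and excluded -- the long-lived stable backbone would
#' otherwise dominate the fit -- as are the synapses present at
#' initialization.
#'
#' For distribution fitting it can matter that every included synapse had the
#' same chance to reach a given lifetime: with `truncate_at = T`, only
#' synapses born no later than `horizon - T` are included and only lifetimes
#' `<= T` are kept, giving a uniformly right-truncated sample that pairs with
#' the `xmax` argument of [fit_power_law()].
#'
#' @param events Event log data.frame (`post, pre, birth_step, death_step,
#'   cause`) from a `sorn_record`, or the record itself.
#' @param horizon Last step covered by the log segment under analysis;
#'   defaults to the full run.
#' @param truncate_at Optional uniform observation window (steps); `NULL`
#'   keeps every death within the horizon.
#' @return Integer vector of lifetimes.
#' @export
synapse_lifetimes <- function(events, horizon = NULL, truncate_at = NULL) {
  if (inherits(events, "sorn_record")) {
    if (is.null(horizon)) horizon <- events$n_steps
    events <- events$events
  }
  stopifnot(!is.null(horizon))
  sel <- !is.na(events$birth_step) & !is.na(events$death_step) &
    events$death_step <= horizon
  if (!is.null(truncate_at)) {
    sel <- sel & events$birth_step <= horizon - truncate_at &
      (events$death_step - events$birth_step) <= truncate_at
  }
  as.integer(events$death_step[sel] - events$birth_step[sel])
}

#' Discrete power-law fit of synapse lifetimes
#'
#' Estimates the exponent `alpha` of `p(x) ~ x^-alpha` for `x >= xmin` in two
#' ways: (primary) discrete maximum likelihood, maximizing
#' `-n log zeta(alpha, xmin) - alpha * sum(log x)` with the Hurwitz zeta
#' function, and (secondary) a least-squares slope on the log-binned
#' log-density. Lifetimes of newly created synapses follow an exponent near
#' 3/2, the first-passage signature of random-walk weight dynamics.
#'
#' When the data are right-truncated by a finite observation window (every
#' lifetime from a finite run is), pass the window as `xmax`: the likelihood
#' then uses the truncated normalization over `[xmin, xmax]`. Ignoring the
#' truncation biases the exponent upward in the far tail.
#'
#' @param x Positive integer-valued sample (lifetimes).
#' @param xmin Smallest value included in the fit, or `"auto"` to select it by
#'   minimizing the KS distance between the empirical and fitted tails over
#'   candidate cutoffs (the Clauset-Shalizi-Newman procedure). Automatic
#'   selection matters for synapse lifetimes, whose short end is dominated by
#'   the geometric waiting times between plasticity events rather than by the
#'   first-passage power law.
#' @return A `sorn_fit` list: `family = "power_law"`, `alpha` (MLE magnitude),
#'   `slope` (`-alpha`, the plotted log-log slope), `ls_alpha` (least-squares
#'   magnitude), `xmin` (used), `gof_ks` (KS distance between the empirical
#'   and fitted discrete CDFs), `n`.
#' @param xmax Optional right-truncation bound (observation window).
#' @export
fit_power_law <- function(x, xmin = 2L, xmax = NULL) {
  if (!is.null(xmax)) stopifnot(all(x <= xmax))
  if (identical(xmin, "auto")) {
    xmin <- select_xmin(x, xmax = xmax)
  }
  x <- x[x >= xmin]
  n <- length(x)
  if (n < 100L) {
    stop("insufficient data: need >= 100 lifetimes >= xmin, got ", n,
         call. = FALSE)
  }
  alpha <- plaw_mle(x, xmin, xmax)

  # least-squares route on the log-binned density
  h <- weight_histogram(x, exclusion = xmin * (1 - 1e-9), n_bins = 15L)
  keep <- h$counts > 0
  fit <- lm(log10(h$density[keep]) ~ log10(h$mids[keep]))
  ls_alpha <- -unname(coef(fit)[2])

  structure(list(family = "power_law", alpha = alpha, slope = -alpha,
                 ls_alpha = ls_alpha, xmin = xmin,
                 gof_ks = plaw_ks(x, alpha, xmin, xmax), n = n),
            class = "sorn_fit")
}

# normalization sum_{k = xmin}^{xmax} k^-a (xmax = NULL: infinite tail)
plaw_norm <- function(a, xmin, xmax = NULL) {
  z <- hurwitz_zeta(a, xmin)
  if (!is.null(xmax)) z <- z - hurwitz_zeta(a, xmax + 1)
  z
}

# discrete MLE for p(x) ~ x^-a on [xmin, xmax]
plaw_mle <- function(x, xmin, xmax = NULL) {
  n <- length(x)
  slx <- sum(log(x))
  nll <- function(a) n * log(plaw_norm(a, xmin, xmax)) + a * slx
  optimize(nll, interval = c(1.01, 6))$minimum
}

# KS distance between the empirical CDF of x (>= xmin) and the fitted one
plaw_ks <- function(x, alpha, xmin, xmax = NULL) {
  top <- max(x)
  if (top > 1e6) return(NA_real_)
  supp <- xmin:top
  pmf <- supp^(-alpha) / plaw_norm(alpha, xmin, xmax)
  cdf_fit <- cumsum(pmf)
  ecdf_x <- cumsum(tabulate(x - xmin + 1L, nbins = length(supp))) / length(x)
  max(abs(ecdf_x - cdf_fit))
}

# KS-minimizing cutoff over candidate xmins that keep >= 100 tail points
select_xmin <- function(x, max_candidates = 40L, xmax = NULL) {
  cand <- sort(unique(x))
  cand <- cand[cand >= 2]
  cand <- cand[vapply(cand, function(m) sum(x >= m), 0L) >= 100L]
  if (!length(cand)) stop("insufficient data for xmin selection", call. = FALSE)
  if (length(cand) > max_candidates) {
    cand <- unique(round(exp(seq(log(min(cand)), log(max(cand)),
                                 length.out = max_candidates))))
    cand <- cand[vapply(cand, function(m) sum(x >= m), 0L) >= 100L]
  }
  ks <- vapply(cand, function(m) {
    tail_x <- x[x >= m]
    plaw_ks(tail_x, plaw_mle(tail_x, m, xmax), m, xmax)
  }, numeric(1))
  cand[which.min(ks)]
}

# Hurwitz zeta via direct sum plus Euler-Maclaurin tail
hurwitz_zeta <- function(a, q, n_terms = 10000L) {
  k <- q + seq_len(n_terms) - 1
  nn <- q + n_terms
  sum(k^(-a)) + nn^(1 - a) / (a - 1) - 0.5 * nn^(-a) + a * nn^(-a - 1) / 12
}

#' Classify connectivity phases from a connection-fraction series
#'
#' Splits the per-step fraction of existing EE connections into consecutive
#' windows, fits a linear slope to each, labels windows `decay`
#' (slope < -slope_tol), `growth` (> +slope_tol) or `stable`, and merges
#' contiguous windows with the same label. The self-organizing network passes
#' through exactly these phases: an initial decay in which STDP eliminates a
#' substantial fraction of the inherited synapses, a growth phase in which
#' structurally created synapses accumulate, and a stable regime with small
#' fluctuations.
#'
#' @param series Connection-fraction series (one value per step).
#' @param window Window length in steps.
#' @param slope_tol Absolute slope (per step) below which a window counts as
#'   stable. `NULL` (default) estimates it as twice the standard deviation of
#'   the window slopes in the last quarter of the series.
#' @return A list: `windows` (data.frame `start, end, slope, label`),
#'   `segments` (merged, same columns plus `n_windows`), `slope_tol`.
#' @export
phase_classify <- function(series, window = 1000L, slope_tol = NULL) {
  n <- length(series)
  stopifnot(n >= 2 * window)
  nw <- n %/% window
  tt <- seq_len(window)
  vt <- sum((tt - mean(tt))^2)
  slopes <- vapply(seq_len(nw), function(k) {
    y <- series[((k - 1L) * window + 1L):(k * window)]
    sum((tt - mean(tt)) * (y - mean(y))) / vt
  }, numeric(1))
  if (is.null(slope_tol)) {
    tail_sl <- slopes[ceiling(3 * nw / 4):nw]
    slope_tol <- 2 * sd(tail_sl)
    if (!is.finite(slope_tol) || slope_tol == 0) slope_tol <- 1e-12
  }
  label <- ifelse(slopes < -slope_tol, "decay",
                  ifelse(slopes > slope_tol, "growth", "stable"))
  windows <- data.frame(start = (seq_len(nw) - 1L) * window + 1L,
                        end = seq_len(nw) * window,
                        slope = slopes, label = label)
  runs <- rle(label)
  ends <- cumsum(runs$lengths)
  starts <- c(1L, head(ends, -1) + 1L)
  segments <- data.frame(start = windows$start[starts],
                         end = windows$end[ends],
                         label = runs$values, n_windows = runs$lengths)
  list(windows = windows, segments = segments, slope_tol = slope_tol)
}
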