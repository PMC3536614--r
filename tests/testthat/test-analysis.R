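test_that("a perfectly regular train has CV zero and the right rate", {
  raster <- matrix(0L, 1000, 1)
  raster[seq(10, 1000, by = 10), 1] <- 1L
  st <- isi_cv_stats(raster, washout = 100)
  expect_equal(st$cv[1], 0)
  expect_equal(st$rate[1], 1 / 10)
  expect_equal(st$mean_cv, 0)
})

test_that("geometric ISIs of a Bernoulli train give CV near sqrt(1-p)", {
  set.seed(17)
  p_fire <- 0.1
  raster <- matrix(as.integer(runif(1e5) < p_fire), ncol = 1)
  st <- isi_cv_stats(raster, washout = 0)
  expect_lt(abs(st$cv[1] - sqrt(1 - p_fire)), 0.02)
})

test_that("silent and sparse units are excluded and flagged", {
  raster <- cbind(rep(0L, 500), c(rep(0L, 498), 1L, 1L), rep(1L, 500))
  st <- isi_cv_stats(raster, washout = 0)
  expect_identical(st$silent_units, 1L)
  expect_true(all(c(1L, 2L) %in% st$excluded_units))
  expect_equal(st$cv[3], 0)   # tonic unit has zero-variance ISIs
})

test_that("correlation matrix has unit diagonal, NA rows for constants, and
           near-zero values for independent trains", {
  set.seed(23)
  raster <- cbind(as.integer(runif(1e5) < 0.1),
                  as.integer(runif(1e5) < 0.2),
                  rep(1L, 1e5))
  out <- pairwise_correlations(raster, washout = 0)
  expect_equal(out$r[1, 1], 1)
  expect_identical(out$constant_units, 3L)
  expect_true(is.na(out$r[1, 3]))
  expect_lt(abs(out$r[1, 2]), 0.02)
})

test_that("log-binned histogram conserves counts and applies the exclusion", {
  set.seed(4)
  w <- rlnorm(5000, -3, 1)
  h <- weight_histogram(w, exclusion = 1e-4, n_bins = 25)
  expect_equal(sum(h$density * diff(h$edges)), h$n_included, tolerance = 1e-9)
  expect_equal(h$n_included, sum(w > 1e-4))
  # degenerate support: all retained weights identical
  h1 <- weight_histogram(rep(0.1, 7), exclusion = 1e-4)
  expect_equal(sum(h1$counts), 7)
  expect_equal(sum(h1$counts > 0), 1)
  # boundary weights: at the threshold is excluded, above is kept
  expect_equal(weight_histogram(c(1e-6, 1e-4, 0.1), 1e-4)$n_included, 1)
  expect_error(weight_histogram(c(1e-6, 1e-5), 1e-4), "exclusion")
})

test_that("lognormal fit recovers known parameters and equals a Gaussian
           fit of the log-weights", {
  w <- make_fixture("lognormal-sample", seed = 5, meanlog = -3, sdlog = 1,
                    n = 1e4)
  f <- fit_lognormal(w, exclusion = 0)
  expect_lt(abs(f$meanlog - (-3)), 0.05)
  expect_lt(abs(f$sdlog - 1), 0.05)
  lw <- log(w)
  expect_equal(f$meanlog, mean(lw))
  expect_equal(f$sdlog, sqrt(mean((lw - mean(lw))^2)))
  expect_error(fit_lognormal(rep(1, 5), 0), "insufficient")
})

test_that("phase classification labels monotone and constant series", {
  dec <- seq(1, 0, length.out = 4000)
  out <- phase_classify(dec, window = 1000, slope_tol = 1e-6)
  expect_identical(unique(out$segments$label), "decay")
  expect_identical(nrow(out$segments), 1L)
  con <- rep(0.5, 4000)
  out2 <- phase_classify(con, window = 1000, slope_tol = 1e-6)
  expect_identical(out2$segments$label, "stable")
  gro <- c(seq(0.5, 0.2, length.out = 2000), seq(0.2, 0.6, length.out = 2000),
           rep(0.6, 2000))
  out3 <- phase_classify(gro, window = 1000, slope_tol = 1e-5)
  expect_identical(out3$segments$label, c("decay", "growth", "stable"))
})

test_that("lifetime extraction follows the censoring rules", {
  ev <- data.frame(post = c(1, 2, 3, 4), pre = c(2, 3, 4, 5),
                   birth_step = c(100L, 200L, NA, 300L),
                   death_step = c(103L, NA, 400L, 9000L),
                   cause = c("stdp_elimination", NA, "stdp_elimination",
                             "stdp_elimination"))
  lt <- synapse_lifetimes(ev, horizon = 5000)
  # born 100 died 103 -> 3; alive excluded; initial synapse excluded;
  # death beyond horizon excluded
  expect_identical(lt, 3L)
})

test_that("discrete power-law MLE recovers synthetic exponents", {
  x <- make_fixture("powerlaw-sample", seed = 7, alpha = 1.5, n = 1e4)
  f <- fit_power_law(x, xmin = 2)
  expect_lt(abs(f$alpha - 1.5), 0.1)
  expect_identical(f$slope, -f$alpha)
  x2 <- make_fixture("powerlaw-sample", seed = 8, alpha = 2.5, n = 1e4)
  expect_lt(abs(fit_power_law(x2)$alpha - 2.5), 0.1)
  expect_error(fit_power_law(1:50), "insufficient")
})

test_that("random-walk first-passage times show the 3/2 exponent", {
  lt <- make_fixture("random-walk-lifetimes", seed = 9, n = 1e5)
  f <- fit_power_law(lt, xmin = 2)
  expect_lt(abs(f$alpha - 1.5), 0.15)
})

test_that("weight change populations split into persisting/eliminated/newborn", {
  a <- data.frame(post = c(1, 2, 3), pre = c(2, 3, 1), w = c(0.5, 0.05, 0.2))
  b <- data.frame(post = c(1, 4), pre = c(2, 1), w = c(0.25, 0.001))
  out <- weight_change_stats(a, b, mode = "relative")
  expect_equal(out$persisting$change, 0.5)
  expect_identical(out$n_eliminated, 2L)
  expect_true(all(c(2, 3) %in% out$eliminated$post))
  expect_identical(out$newborn$post, 4)
  abs_out <- weight_change_stats(a, b, mode = "absolute")
  expect_equal(abs_out$persisting$change, -0.25)
  # identical snapshots: every relative change is exactly one
  same <- weight_change_stats(a, a)
  expect_true(all(same$persisting$change == 1))
  expect_identical(same$n_eliminated + same$n_newborn, 0L)
})

test_that("fluctuation curve is zero under frozen plasticity", {
  p <- tiny_params(15L, 3L)
  rec <- sorn_run(p, 400, seed = 3, snapshot_every = 100,
                  ablate = c("stdp", "normalization", "intrinsic", "istdp",
                             "structural"))
  fl <- fluctuation_vs_weight(rec, exclusion = 0)
  expect_true(all(fl$mean_abs_change[fl$n > 0] == 0))
})

test_that("Gibrat trajectories give |dw| growing linearly from the origin", {
  set.seed(41)
  g <- gibrat_null(500, 400, growth_sd = 0.05, normalize = TRUE,
                   keep_trajectories = TRUE)
  snaps <- lapply(seq(1, 401, by = 200), function(t) {
    list(step = t - 1,
         pairs = data.frame(post = seq_len(500), pre = 1L,
                            w = g$trajectories[t, ]))
  })
  fl <- fluctuation_vs_weight(snaps, exclusion = 0)
  ok <- fl$n > 5
  fit <- lm(fl$mean_abs_change[ok] ~ fl$mid[ok])
  slope <- unname(coef(fit)[2])
  intercept <- unname(coef(fit)[1])
  expect_gt(slope, 0)
  # intercept small relative to the largest fluctuation level
  expect_lt(abs(intercept), 0.2 * max(fl$mean_abs_change[ok]))
})

test_that("top-share accumulates the heaviest weights first", {
  expect_equal(top_share(rep(2, 10), 0.5), 0.5)
  expect_equal(top_share(c(6, 1, 1, 1, 1), 0.5), 0.2)
  expect_equal(top_share(c(1, 9), 0.5), 0.5)
  expect_error(top_share(c(0, 0)), "positive")
})

test_that("return map summarizes degenerate rasters exactly", {
  silent <- matrix(0L, 200, 10)
  out <- activity_return_map(silent, washout = 50)
  expect_true(all(out$a_t == 0) && all(out$a_next == 0))
  expect_identical(out$n_silent, 150L)
  active <- matrix(1L, 200, 10)
  out2 <- activity_return_map(active, washout = 50)
  expect_identical(c(out2$min_activity, out2$max_activity), c(1, 1))
  expect_identical(out2$n_silent, 0L)
})

test_that("Gibrat null: frozen at sd 0; unnormalized log-variance grows at
           sd^2 per step; normalized ensemble stays lognormal-like", {
  set.seed(19)
  g0 <- gibrat_null(100, 50, growth_sd = 0)
  expect_true(all(g0$weights == g0$weights[1]))

  g1 <- gibrat_null(1000, 10000, growth_sd = 0.05, normalize = FALSE)
  t_idx <- seq_along(g1$logvar) - 1
  slope <- unname(coef(lm(g1$logvar ~ t_idx))[2])
  expect_lt(abs(slope - 0.05^2), 0.1 * 0.05^2)

  g2 <- gibrat_null(1000, 10000, growth_sd = 0.05, normalize = TRUE)
  ln <- fit_lognormal(g2$weights, exclusion = 0)
  ex <- fit_exponential(g2$weights)
  expect_lt(ln$gof_ks, ex$gof_ks)
  expect_lt(ln$gof_ks, 0.05)
})

test_that("rich-get-richer curves respect counting identities on a small run", {
  p <- tiny_params(20L, 4L)
  rec <- sorn_run(p, 1500, seed = 15, snapshot_every = 100,
                  record_deltas = TRUE)
  cc <- stdp_conditional_curves(rec, exclusion = 1e-4)
  occ <- cc$n_total > 0
  expect_true(all(cc$frac_pot[occ] >= 0 & cc$frac_pot[occ] <= 1))
  expect_true(all(cc$frac_dep[occ] >= 0 & cc$frac_dep[occ] <= 1))
  expect_true(all(is.na(cc$frac_pot[!occ])))
  expect_equal(cc$net[occ], (cc$n_pot[occ] - cc$n_dep[occ]) / cc$n_total[occ])
})
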