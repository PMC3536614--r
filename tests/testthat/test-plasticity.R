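make_w <- function(ne, pairs, vals) {
  w <- matrix(0, ne, ne)
  w[pairs] <- vals
  w
}

test_that("causal pre-before-post firing potentiates by exactly eta", {
  w <- make_w(3, cbind(2, 1), 0.5)          # synapse 1 -> 2
  up <- stdp_update(w, x_now = c(0, 1, 0), x_prev = c(1, 0, 0), eta = 0.004)
  expect_equal(up$w_ee[2, 1], 0.504)
  expect_equal(up$deltas$delta, 0.004)
  expect_false(up$deltas$eliminated)
})

test_that("silent network leaves every weight unchanged", {
  w <- make_w(4, cbind(c(2, 3), c(1, 4)), c(0.2, 0.7))
  up <- stdp_update(w, rep(0, 4), rep(0, 4), eta = 0.004)
  expect_identical(up$w_ee, w)
  expect_length(up$deltas$post, 0)
})

test_that("post-then-pre ordering depresses and eliminates small weights", {
  w <- make_w(3, cbind(2, 1), 0.002)
  # post (2) fired at t, pre (1) fires at t+1 -> depression below zero
  up <- stdp_update(w, x_now = c(1, 0, 0), x_prev = c(0, 1, 0), eta = 0.004)
  expect_identical(up$w_ee[2, 1], 0)
  expect_true(up$deltas$eliminated)
  expect_equal(up$deltas$w_before, 0.002)
})

test_that("coincident firing at both steps cancels to no change", {
  w <- make_w(2, rbind(c(1, 2), c(2, 1)), c(0.4, 0.6))
  up <- stdp_update(w, x_now = c(1, 1), x_prev = c(1, 1), eta = 0.01)
  expect_identical(up$w_ee, w)
  expect_length(up$deltas$post, 0)
})

test_that("STDP only touches structurally existing synapses", {
  w <- make_w(3, cbind(2, 1), 0.5)
  up <- stdp_update(w, x_now = c(0, 0, 1), x_prev = c(1, 1, 0), eta = 0.004)
  expect_identical(up$w_ee, w)   # 1->3 and 2->3 do not exist
})

test_that("swapping activity order negates every delta (antisymmetry)", {
  set.seed(5)
  for (rep in 1:20) {
    ne <- 8L
    w <- matrix(runif(ne * ne) * (runif(ne * ne) < 0.4), ne, ne)
    diag(w) <- 0
    # large weights so no delta reaches the elimination floor
    w[w > 0] <- w[w > 0] + 1
    x1 <- as.numeric(runif(ne) < 0.4)
    x0 <- as.numeric(runif(ne) < 0.4)
    a <- stdp_update(w, x1, x0, 0.004)$deltas
    b <- stdp_update(w, x0, x1, 0.004)$deltas
    key_a <- paste(a$post, a$pre)
    key_b <- paste(b$post, b$pre)
    expect_setequal(key_a, key_b)
    if (length(key_a)) expect_equal(a$delta, -b$delta[match(key_a, key_b)])
  }
})

test_that("normalization rescales rows to sum one and fixes hand example", {
  w <- rbind(c(0, 1, 1, 2), c(0.2, 0, 0.3, 0.5), rep(0, 4), c(0, 0, 4, 0))
  out <- synaptic_normalization(w)
  expect_equal(out[1, ], c(0, 0.25, 0.25, 0.5))
  expect_equal(out[2, ], c(0.2, 0, 0.3, 0.5))    # already normalized
  expect_identical(out[3, ], rep(0, 4))           # zero row untouched
  rs <- rowSums(out)
  expect_true(all(abs(rs[rs > 0] - 1) < 1e-9))
})

test_that("normalization is idempotent and scale-invariant", {
  set.seed(8)
  w <- matrix(runif(100) * (runif(100) < 0.5), 10, 10)
  n1 <- synaptic_normalization(w)
  expect_equal(synaptic_normalization(n1), n1, tolerance = 1e-12)
  expect_equal(synaptic_normalization(3.7 * w), n1, tolerance = 1e-12)
})

test_that("intrinsic plasticity moves thresholds as documented", {
  expect_equal(intrinsic_plasticity(0.5, 1, 0.01, 0.1), 0.509)
  expect_equal(intrinsic_plasticity(0.5, 0, 0.01, 0.1), 0.499)
  expect_identical(intrinsic_plasticity(c(0.2, 0.4), c(1, 0), 0, 0.1),
                   c(0.2, 0.4))
})

test_that("an isolated noise-driven unit converges to its target rate", {
  # single unit, no synapses: rate is controlled by threshold vs noise alone
  p <- sorn_params(n_exc = 1L, n_inh = 1L, p_ee_init = 0, p_ei_init = 0,
                   target_rate = 0.1)
  st <- init_network(p, seed = 2)
  set.seed(2)
  n <- 1e5L
  fired <- logical(n)
  for (t in seq_len(n)) {
    st <- update_state(st, p)
    st$t_exc <- intrinsic_plasticity(st$t_exc, st$x, p$eta_ip, 0.1)
    fired[t] <- st$x > 0
  }
  expect_lt(abs(mean(fired[-(1:1000)]) - 0.1), 0.02)
})

test_that("structural plasticity is a no-op on a full graph", {
  w <- matrix(1, 5, 5); diag(w) <- 0
  set.seed(1)
  out <- structural_plasticity(w, p_struct = 1, w_new = 0.001)
  expect_identical(out$w_ee, w)
  expect_null(out$birth)
})

test_that("a forced birth fills the single empty pair at exactly 0.001", {
  w <- matrix(1, 4, 4); diag(w) <- 0
  w[2, 3] <- 0
  set.seed(1)
  out <- structural_plasticity(w, p_struct = 1, w_new = 0.001)
  expect_identical(out$w_ee[2, 3], 0.001)
  expect_identical(unname(out$birth), c(2L, 3L))
})

test_that("birth candidates are drawn uniformly over unconnected pairs", {
  # 4 units, 4 existing synapses -> 8 unconnected ordered pairs
  w <- make_w(4, rbind(c(1, 2), c(2, 1), c(3, 4), c(4, 3)), 1)
  set.seed(42)
  n <- 20000L
  picks <- character(n)
  for (k in seq_len(n)) {
    out <- structural_plasticity(w, 1, 0.001)
    picks[k] <- paste(out$birth, collapse = ",")
  }
  counts <- table(picks)
  expect_length(counts, 8L)
  pval <- stats::chisq.test(counts)$p.value
  expect_gt(pval, 1e-4)
})

test_that("iSTDP follows the success/failure rule with flooring", {
  w <- matrix(c(0.5, 0.0015), 2, 1)   # two excitatory, one inhibitory
  # inhibitory fired; unit 1 fires anyway (+pot), unit 2 silenced (-dep)
  out <- istdp_update(w, y_prev = 1, x_now = c(1, 0),
                      eta_pot = 0.004, eta_dep = 0.001, w_floor = 0.001)
  expect_equal(out[1, 1], 0.504)
  expect_equal(out[2, 1], 0.001)   # 0.0015 - 0.001 floored at 0.001
  # second successful inhibition: stays exactly at the floor
  out2 <- istdp_update(out, 1, c(1, 0), 0.004, 0.001, 0.001)
  expect_identical(out2[2, 1], 0.001)
  # silent inhibitory unit changes nothing
  expect_identical(istdp_update(w, 0, c(1, 0), 0.004, 0.001, 0.001), w)
  # nonexistent synapses (zero entries) stay zero
  w0 <- matrix(c(0, 0.5), 2, 1)
  expect_identical(istdp_update(w0, 1, c(0, 0), 0.004, 0.001, 0.001)[1, 1], 0)
  expect_error(istdp_update(w, 1, c(1, 0), 0.001, 0.002, 0.001), "eta_istdp_pot")
})

test_that("weights stay nonnegative under random plasticity sequences", {
  set.seed(31)
  p <- tiny_params(12L, 3L)
  st <- init_network(p, seed = 31)
  for (t in 1:300) {
    out <- sorn_step(st, p)
    st <- out$state
    expect_true(all(st$w_ee >= 0))
    expect_true(all(st$w_ei >= 0))
    wei <- st$w_ei[st$w_ei > 0]
    expect_true(all(wei >= p$w_ei_floor - 1e-12))
  }
})
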