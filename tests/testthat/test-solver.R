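test_that("the integer-order limit reproduces classical solutions", {
  tr <- abm_solve(function(t, x) -x, orders = 1, x0 = 1, h = 1e-3, t_end = 1)
  expect_equal(tail(tr, 1)$x1, exp(-1), tolerance = 5e-3)
  expect_equal(tr$time, seq(0, 1, by = 1e-3))
})

test_that("a half-order relaxation matches the Mittag-Leffler oracle", {
  tr <- abm_solve(function(t, x) -x, orders = 0.5, x0 = 1, h = 2^-9, t_end = 1)
  ts <- c(0.25, 0.5, 1)
  for (t0 in ts) {
    oracle <- mittag_leffler(0.5, -sqrt(t0))
    got <- tr$x1[abs(tr$time - t0) < 1e-12]
    expect_equal(got, oracle, tolerance = 1e-3)
  }
})

test_that("empirical convergence order is at least one on a smooth test", {
  ref <- abm_solve(function(t, x) -x, 0.97, 1, h = 2^-10, t_end = 1)
  err <- vapply(c(2^-6, 2^-7, 2^-8), function(h) {
    tr <- abm_solve(function(t, x) -x, 0.97, 1, h = h, t_end = 1)
    abs(tail(tr, 1)$x1 - tail(ref, 1)$x1)
  }, 0)
  expect_gt(err[1] / err[2], 2)   # halving h at least halves the error
  expect_gt(err[2] / err[3], 2)
})

test_that("the compiled chain kernel agrees with the generic callback solver", {
  m <- chain_model("I", 0.97, 4.5, 5)
  tr_fast <- simulate_chain(m, x0 = 1, h = 2^-5, t_end = 4)
  tr_gen <- abm_solve(function(t, s) chain_rhs(m, s), c(0.97, 1),
                      c(x = 1, y = 0), h = 2^-5, t_end = 4)
  expect_equal(tr_fast$x, tr_gen$x, tolerance = 1e-12)
  expect_equal(tr_fast$y, tr_gen$y, tolerance = 1e-12)

  m2 <- chain_model("II", 0.9, 2, 3)
  tr_fast2 <- simulate_chain(m2, x0 = 0.5, h = 2^-5, t_end = 4)
  tr_gen2 <- abm_solve(function(t, s) chain_rhs(m2, s), c(0.9, 1),
                       c(x = 0.5, y = 0), h = 2^-5, t_end = 4)
  expect_equal(tr_fast2$x, tr_gen2$x, tolerance = 1e-12)
})

test_that("the positive equilibrium is a fixed point of the scheme", {
  for (v in c("I", "II")) {
    m <- chain_model(v, 0.97, 4.5, 5)
    eq <- equilibria(m)
    tr <- simulate_chain(m, x0 = eq$x[2], y0 = eq$y[2], h = 2^-5, t_end = 20)
    expect_lt(max(abs(tr$x - eq$x[2])), 1e-6)
    expect_lt(max(abs(tr$y - eq$y[2])), 1e-6)
  }
})

test_that("divergence is flagged with the step index, never NaN rows", {
  # cold start near the equilibrium abscissa lies outside the basin
  m <- chain_model("I", 0.97, 4.5, 5)
  tr <- simulate_chain(m, x0 = 22.5, y0 = 0, h = 2^-6, t_end = 50)
  expect_false(is.na(attr(tr, "diverged_at")))
  expect_true(all(is.finite(tr$x)))
  expect_true(all(is.finite(tr$y)))
  expect_lt(max(tr$time), 50)
})

test_that("the delayed logistic solver respects theory on both sides of r1(0)", {
  # r = 0: classical logistic-type approach to the carrying state
  m0 <- logistic_delay_model(1, 1, 0)
  tr0 <- simulate_logistic_dde(m0, h = 2^-5, t_end = 30)
  expect_equal(tail(tr0, 1)$y, 1, tolerance = 1e-3)

  # below the critical delay (r1(0) = 0.6046): convergence to 1
  m1 <- logistic_delay_model(1, 1, 0.3125)
  tr1 <- simulate_logistic_dde(m1, h = 2^-5, t_end = 60)
  expect_identical(classify_regime(tr1)$label, "converged")
  expect_equal(unname(classify_regime(tr1)$limit), 1, tolerance = 1e-2)

  # above it: sustained oscillation, no convergence
  m2 <- logistic_delay_model(1, 1, 0.6875)
  tr2 <- simulate_logistic_dde(m2, h = 2^-5, t_end = 60)
  expect_false(classify_regime(tr2)$label == "converged")
  tail_y <- tr2$y[tr2$time > 45]
  expect_gt(diff(range(tail_y)), 0.1)
})

test_that("delays are snapped to the grid with a warning", {
  m <- logistic_delay_model(1, 1, 0.33)
  expect_warning(simulate_logistic_dde(m, h = 2^-4, t_end = 2), "snapped")
  m2 <- logistic_delay_model(1, 1, 0.25)
  expect_silent(tr <- simulate_logistic_dde(m2, h = 2^-4, t_end = 2))
  expect_equal(tr$y[1], 0.5)   # y(0) = phi(0)
})

test_that("solver input validation", {
  expect_error(abm_solve(function(t, x) -x, 1.2, 1, h = 0.1, t_end = 1),
               "orders")
  expect_error(abm_solve(function(t, x) -x, c(1, 1), 1, h = 0.1, t_end = 1),
               "lengths")
  expect_error(simulate_chain(chain_model("I", 0.9, 1, 1), x0 = -1), "x0")
})
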