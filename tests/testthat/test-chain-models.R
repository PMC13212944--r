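test_that("equilibria match the closed forms and satisfy the dynamics", {
  eqI <- equilibria(chain_model("I", 0.97, 2, 5))
  expect_equal(eqI$x, c(0, 25))
  expect_equal(eqI$y, c(0, 5))

  eqII <- equilibria(chain_model("II", 0.97, 2, 25))
  expect_equal(eqII$x, c(0, 25))
  expect_equal(eqII$y, c(0, 25))

  # both variants coincide at a = 1
  expect_equal(equilibria(chain_model("I", 0.9, 1, 1))$x[2], 1)
  expect_equal(equilibria(chain_model("II", 0.9, 1, 1))$x[2], 1)

  # right-hand sides vanish at every returned equilibrium
  fx <- sample_fixtures(303, 20)
  for (i in seq_len(nrow(fx))) {
    for (v in c("I", "II")) {
      m <- chain_model(v, fx$alpha1[i], fx$rho[i], fx$a[i])
      eq <- equilibria(m)
      for (j in 1:2) {
        expect_lt(max(abs(chain_rhs(m, c(eq$x[j], eq$y[j])))),
                  1e-12 * (1 + max(abs(c(eq$x[j], eq$y[j]))))^2)
      }
    }
  }
})

test_that("Jacobians match hand differentiation of the chain systems", {
  m <- chain_model("I", 0.97, 4.5, 5)
  expect_equal(chain_jacobian(m, "positive"),
               rbind(c(4.5, -2 * 4.5 * 5), c(1, -5)))
  expect_equal(chain_jacobian(m, "trivial"), rbind(c(4.5, 0), c(1, -5)))

  m2 <- chain_model("II", 0.97, 4.5, 5)
  expect_equal(chain_jacobian(m2, "positive"),
               rbind(c(4.5, -4.5), c(10, -5)))
  expect_equal(chain_jacobian(m2, "trivial"), rbind(c(4.5, -4.5), c(0, -5)))

  expect_error(chain_jacobian(m, c(3, 3)), "not an equilibrium")
})

test_that("both variants share the positive-equilibrium polynomial", {
  # spot value from a published reference parameter set
  p <- char_poly_at(chain_model("I", 0.97, 4.5, 4.6), "positive")
  expect_identical(p$exponents, c(197L, 100L, 97L, 0L))
  expect_equal(p$coefficients, c(1, -4.5, 4.6, 4.5 * 4.6))

  fx <- sample_fixtures(808, 25)
  for (i in seq_len(nrow(fx))) {
    pI <- char_poly_at(chain_model("I", fx$alpha1[i], fx$rho[i], fx$a[i]),
                       "positive")
    pII <- char_poly_at(chain_model("II", fx$alpha1[i], fx$rho[i], fx$a[i]),
                        "positive")
    expect_identical(pI$exponents, pII$exponents)
    expect_equal(pI$coefficients, pII$coefficients)
  }
})

test_that("the trivial equilibrium is unstable for sampled parameters", {
  fx <- sample_fixtures(505, 25)
  for (i in seq_len(nrow(fx))) {
    v <- if (i %% 2 == 0) "I" else "II"
    rep <- stability_report(
      chain_model(v, fx$alpha1[i], fx$rho[i], fx$a[i]), which = "trivial"
    )
    expect_lt(rep$min_arg, 1e-8)
    expect_identical(rep$verdict, "unstable")
  }
})

test_that("region scan maps the stability boundary", {
  # low growth: the whole band with kernel rate above the growth rate is
  # stable (for a < rho the Jacobian trace rho - a is positive and no order
  # can stabilize the equilibrium)
  g <- region_scan(chain_model("I", 0.97, 0.9, 1), c("alpha1", "a"),
                   axis1 = c(0.5, 0.75, 0.97), axis2 = c(2, 5, 20, 45))
  expect_true(all(g$verdict == "stable"))

  # the boundary in a at (alpha1, rho) = (0.97, 4.5) lies in (4.5, 4.6)
  g2 <- region_scan(chain_model("I", 0.97, 4.5, 1), c("alpha1", "a"),
                    axis1 = 0.97, axis2 = c(4, 4.5, 4.6, 6),
                    refine_boundary = TRUE)
  b <- attr(g2, "boundary")
  expect_identical(nrow(b), 1L)
  expect_gt(b$axis2_lo, 4.4)
  expect_lt(b$axis2_hi, 4.6)
  expect_lt(b$axis2_hi - b$axis2_lo, 1e-4 * 4.6 * 1.01)

  # verdicts flip at most once along each column of an (alpha1, a) grid
  g3 <- region_scan(chain_model("I", 0.97, 4.5, 1), c("alpha1", "a"),
                    axis1 = c(0.9, 0.95, 0.99),
                    axis2 = c(1, 2.5, 4, 5.5, 7, 10))
  for (a1 in unique(g3$alpha1)) {
    col <- g3$verdict[g3$alpha1 == a1 & g3$verdict != "marginal"]
    expect_lte(sum(col[-1] != col[-length(col)]), 1L)
  }
})

test_that("growing rho never stabilizes an unstable node along a ray", {
  rhos <- seq(0.5, 25, length.out = 50)
  reps <- vapply(rhos, function(r) {
    stability_report(chain_model("I", 0.97, r, 4.5))$verdict
  }, character(1))
  seen_unstable <- FALSE
  for (v in reps) {
    if (v == "unstable") seen_unstable <- TRUE
    if (seen_unstable) expect_false(v == "stable")
  }
  expect_true(seen_unstable)   # the ray does cross the boundary
})

test_that("invalid grids and parameters are rejected", {
  m <- chain_model("I", 0.97, 1, 1)
  expect_error(region_scan(m, c("a", "alpha1"), 1, 1), "axis2")
  expect_error(region_scan(m, c("alpha1", "a"), c(0.5, 0.4), c(1, 2)),
               "increasing")
  expect_error(region_scan(m, c("alpha1", "a"), 0.5, c(0, 1)), "positive")
  expect_error(chain_model("I", 1.0, 1, 1), "less than 1")
  expect_error(chain_model("I", 0.97, -1, 1), "rho")
})
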