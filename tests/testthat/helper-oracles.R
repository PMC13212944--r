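# Independent oracles used across tests.

# Mittag-Leffler E_alpha(z) by truncated power series. The factorial growth of
# Gamma(alpha k + 1) makes the tail negligible long before k_max for |z| <= 2.
mittag_leffler <- function(alpha, z, k_max = 150L) {
  k <- 0:k_max
  sum(z^k / gamma(alpha * k + 1))
}

# min |Arg| of a polynomial's roots via base polyroot (Jenkins-Traub), an
# algorithm independent of the companion-matrix + Newton path under test.
min_arg_polyroot <- function(p) {
  cf <- numeric(poly_degree(p) + 1L)
  cf[p$exponents + 1L] <- p$coefficients
  min(abs(Arg(polyroot(cf))))
}

# Cofactor expansion for a small complex matrix (base det() is real-only).
det_complex <- function(A) {
  n <- nrow(A)
  if (n == 1L) return(A[1, 1])
  s <- 0 + 0i
  for (j in seq_len(n)) {
    s <- s + (-1)^(1 + j) * A[1, j] * det_complex(A[-1, -j, drop = FALSE])
  }
  s
}

# Published reference parameter sets: the reported minimum root arguments for
# the chain models at M = 100 (denominator-100 convention).
published_cases <- function() {
  tibble::tibble(
    variant = c("I", "I", "I", "I", "I", "II", "II", "II", "II", "II"),
    alpha1 = c(0.97, 0.97, 0.97, 0.98, 0.98, 0.99, 0.99, 0.99, 0.95, 0.95),
    rho = c(4.5, 4.5, 4.5, 14, 14.651, 6, 6, 6, 22, 22.91),
    a = c(4.5, 4.6, 5, 15, 15, 6.015, 6.05, 6.1, 25, 25),
    min_arg = c(0.0157111, 0.0158209, 0.0162375, 0.0159407, 0.0157088,
                0.0157085, 0.0157375, 0.0157787, 0.0159264, 0.0157135),
    verdict = c("marginal", "stable", "stable", "stable", "marginal",
                "marginal", "stable", "stable", "stable", "marginal")
  )
}
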