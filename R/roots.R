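#' All roots of a sparse polynomial
#'
#' Roots are computed as eigenvalues of the (balanced, via LAPACK) companion
#' matrix of the dense monic expansion, then optionally polished by Newton
#' iteration on the sparse form until the Newton step satisfies
#' \eqn{|p(\lambda)/p'(\lambda)| < 10^{-13}(1 + |\lambda|)}. Polishing on the
#' sparse form avoids the \eqn{O(\mathrm{deg})} rounding noise of dense Horner
#' evaluation for the chain-model polynomials, whose degree is about 200 but
#' which have only four terms.
#'
#' @param p A [sparse_poly()] of degree at least 1.
#' @param refine Apply Newton polishing (default `TRUE`).
#' @param max_iter Maximum Newton iterations per root.
#' @return Complex vector of `poly_degree(p)` roots (with multiplicity), in
#'   decreasing order of `|Arg|` ties broken arbitrarily; carries an attribute
#'   `"residuals"` with \eqn{|p(\lambda_i)|}.
#' @examples
#' poly_roots(sparse_poly(c(2, 0), c(1, 1)))   # +i, -i
#' @export
poly_roots <- function(p, refine = TRUE, max_iter = 60L) {
  d <- poly_degree(p)
  if (!is.finite(d) || d < 1L) abort("polynomial degree must be >= 1.")
  cf <- poly_dense(p)          # ascending c0..cd, cd != 0
  cf <- cf / cf[length(cf)]    # monic

  n_zero <- 0L
  while (cf[1L] == 0 && length(cf) > 1L) {  # exact structural zeros only
    cf <- cf[-1L]
    n_zero <- n_zero + 1L
  }
  n <- length(cf) - 1L
  roots <- complex(0)
  if (n == 1L) {
    roots <- as.complex(-cf[1L])
  } else if (n >= 2L) {
    C <- matrix(0, n, n)
    C[cbind(2:n, 1:(n - 1L))] <- 1
    C[, n] <- -cf[1:n]
    roots <- eigen(C, only.values = TRUE)$values
  }
  if (refine && length(roots)) roots <- newton_polish(p, roots, max_iter)
  roots <- c(roots, rep(0 + 0i, n_zero))
  res <- Mod(poly_eval(p, roots))
  attr(roots, "residuals") <- res
  roots
}

newton_polish <- function(p, z, max_iter = 60L) {
  dp <- poly_deriv(p)
  for (k in seq_along(z)) {
    zi <- z[k]
    for (it in seq_len(max_iter)) {
      der <- poly_eval(dp, zi)
      if (Mod(der) == 0) break
      step <- poly_eval(p, zi) / der
      zi <- zi - step
      if (Mod(step) < 1e-13 * (1 + Mod(zi))) break
    }
    # keep the polish only if it did not jump to a different basin
    if (Mod(zi - z[k]) < 0.1 * (1 + Mod(z[k]))) z[k] <- zi
  }
  z
}

#' Minimum absolute argument over a set of characteristic roots
#'
#' The stability wedge for an order-\eqn{1/M} polynomial system is
#' \eqn{|\arg(\lambda)| > \pi/(2M)}; this helper extracts the binding
#' quantity \eqn{\min_i |\arg(\lambda_i)|} with the principal branch
#' \eqn{\arg \in (-\pi, \pi]}. A positive real root gives 0; a negative real
#' root gives \eqn{\pi}. A root at the origin means the constant term of the
#' characteristic polynomial vanishes and the test degenerates, which is
#' signalled as an error (condition class `"fracstab_degenerate"`) rather than
#' silently dropped.
#'
#' @param roots Nonempty complex vector.
#' @param zero_tol Roots with modulus below `zero_tol` are treated as zero.
#' @return Minimal \eqn{|\arg(\lambda)|} in radians (\eqn{\ge 0}).
#' @examples
#' min_arg(c(1i, -1i))   # pi/2
#' @export
min_arg <- function(roots, zero_tol = 1e-12) {
  if (length(roots) == 0L) abort("`roots` must be nonempty.")
  m <- Mod(roots)
  if (any(m < zero_tol)) {
    abort("degenerate: zero root (vanishing constant term).",
          class = "fracstab_degenerate")
  }
  min(abs(Arg(roots)))
}
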