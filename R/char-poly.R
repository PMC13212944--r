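#' Characteristic polynomial of an incommensurate fractional linearization
#'
#' For a Caputo system \eqn{D^{\alpha_i} x_i = f_i(x)} linearized at an
#' equilibrium with Jacobian \eqn{A = (a_{ij})}, and rational orders
#' \eqn{\alpha_i = v_i/u_i} with common denominator multiple \eqn{M}, local
#' asymptotic stability is governed by the roots of
#' \deqn{\det\!\big(\mathrm{diag}(\lambda^{M\alpha_1},\dots,\lambda^{M\alpha_n}) - A\big) = 0,}
#' a polynomial in \eqn{\lambda} because every \eqn{M\alpha_i} is an integer.
#' The determinant is expanded exactly by the Leibniz formula over
#' permutations, with sparse-polynomial arithmetic for the diagonal monomials;
#' no numerical elimination is involved, so coefficients are exact up to
#' floating-point addition of products of Jacobian entries.
#'
#' @param jacobian Square numeric matrix of partial derivatives at the
#'   equilibrium.
#' @param orders List of [rational_order()] objects, one per state component.
#' @param M Common multiple of the denominators. Defaults to
#'   [common_multiple()] of `orders`; must be divisible by every denominator.
#'
#' @return A [sparse_poly()] of degree \eqn{\sum_i M\alpha_i}.
#' @examples
#' # 2x2 chain-model linearization at the positive equilibrium:
#' J <- rbind(c(4.5, -2 * 4.5 * 4.5), c(1, -4.5))
#' p <- char_poly(J, list(rational_order(0.97), rational_order(1)))
#' p  # lambda^197 + 4.5 lambda^97 - 4.5 lambda^100 + 20.25
#' @export
char_poly <- function(jacobian, orders, M = NULL) {
  jacobian <- as.matrix(jacobian)
  n <- nrow(jacobian)
  if (ncol(jacobian) != n) abort("`jacobian` must be square.")
  if (inherits(orders, "rational_order")) orders <- list(orders)
  if (length(orders) != n) {
    abort(sprintf("length(orders) is %d but the Jacobian is %dx%d.",
                  length(orders), n, n))
  }
  if (is.null(M)) M <- common_multiple(orders)
  M <- as.integer(M)
  for (o in orders) {
    if (M %% o$u != 0L) {
      abort(sprintf("M = %d is not divisible by denominator %d.", M, o$u))
    }
  }
  if (n > 8L) abort("Leibniz expansion is limited to n <= 8 states.")

  mexp <- vapply(orders, function(o) {
    e <- M * o$alpha
    if (abs(e - round(e)) > 1e-9) {
      abort(sprintf("M * alpha = %g is not an integer for order %s.", e, format(o)))
    }
    as.integer(round(e))
  }, integer(1))

  entry <- function(i, j) {
    if (i == j) sparse_poly(c(mexp[i], 0L), c(1, -jacobian[i, i]))
    else sparse_poly(0L, -jacobian[i, j])
  }

  acc <- sparse_poly(integer(), numeric())
  for (perm in permutations_of(n)) {
    prod_p <- sparse_poly(0L, perm_sign(perm))
    nonzero <- TRUE
    for (i in seq_len(n)) {
      e <- entry(i, perm[i])
      if (length(e$exponents) == 0L) { nonzero <- FALSE; break }
      prod_p <- poly_mul(prod_p, e)
    }
    if (nonzero) acc <- poly_add(acc, prod_p)
  }
  acc
}

# All permutations of 1..n (n small).
permutations_of <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (sub in permutations_of(n - 1L)) {
    for (pos in 0:(n - 1L)) {
      out[[length(out) + 1L]] <- append(sub, n, after = pos)
    }
  }
  out
}

perm_sign <- function(perm) {
  inv <- 0L
  n <- length(perm)
  for (i in seq_len(n - 1L)) {
    inv <- inv + sum(perm[(i + 1L):n] < perm[i])
  }
  if (inv %% 2L == 0L) 1 else -1
}
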