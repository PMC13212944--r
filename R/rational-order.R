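#' Represent a fractional order as an exact rational
#'
#' The minimum-argument stability test for incommensurate Caputo systems
#' requires every order \eqn{\alpha_i} to be written as a rational
#' \eqn{v_i/u_i}. Two conventions are supported: `"denominator"` keeps a fixed
#' denominator (default 100, matching two-decimal orders such as 0.97 or 0.95
#' and the threshold \eqn{\pi/200}), and `"reduced"` enforces
#' \eqn{\gcd(v, u) = 1}. The stability verdict is invariant under the choice
#' (see [stability_report()]): inflating the denominator by \eqn{k} maps every
#' characteristic root to its \eqn{k}-th roots and scales both the minimal
#' argument and the threshold \eqn{\pi/(2M)} by \eqn{1/k}.
#'
#' @param alpha Real order in \eqn{(0, 1]}.
#' @param convention `"denominator"` (fixed denominator, the default) or
#'   `"reduced"` (coprime numerator/denominator).
#' @param denominator Positive integer denominator for the `"denominator"`
#'   convention. `alpha * denominator` must be within `1e-9` of an integer.
#'
#' @return An object of class `"rational_order"`: a list with fields `alpha`,
#'   `v` (numerator), `u` (denominator) and `reduced` (logical; whether
#'   \eqn{\gcd(v,u)=1} was enforced). Always `v/u == alpha` to within `1e-12`
#'   and \eqn{0 < v \le u}.
#'
#' @examples
#' rational_order(0.97)                          # 97/100
#' rational_order(0.98, "reduced")               # 49/50
#' rational_order(1)                             # 1/1 (integer order)
#' @export
rational_order <- function(alpha,
                           convention = c("denominator", "reduced"),
                           denominator = 100L) {
  convention <- match.arg(convention)
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha)) {
    abort("`alpha` must be a single finite number.")
  }
  if (alpha <= 0 || alpha > 1) {
    abort(sprintf("`alpha` must lie in (0, 1], got %g.", alpha))
  }
  if (convention == "denominator") {
    d <- as.integer(denominator)
    if (is.na(d) || d < 1L) abort("`denominator` must be a positive integer.")
    v_real <- alpha * d
    v <- round(v_real)
    if (abs(v_real - v) > 1e-9) {
      abort(sprintf(
        "alpha = %.12g is not representable with denominator %d (alpha * d is %.3g away from an integer).",
        alpha, d, abs(v_real - v)
      ))
    }
    out <- list(alpha = alpha, v = as.integer(v), u = d,
                reduced = gcd_int(as.integer(v), d) == 1L)
  } else {
    vu <- rationalize_cf(alpha, tol = 1e-12, max_denom = 1e7)
    out <- list(alpha = alpha, v = vu[[1L]], u = vu[[2L]], reduced = TRUE)
  }
  stopifnot(abs(out$v / out$u - alpha) <= 1e-12, out$v >= 1L, out$v <= out$u)
  structure(out, class = "rational_order")
}

#' @export
print.rational_order <- function(x, ...) {
  cat(sprintf("<rational_order> %g = %d/%d%s\n", x$alpha, x$v, x$u,
              if (x$reduced) " (reduced)" else ""))
  invisible(x)
}

#' @export
format.rational_order <- function(x, ...) sprintf("%d/%d", x$v, x$u)

# Euclid on non-negative integers.
gcd_int <- function(a, b) {
  a <- abs(as.integer(a)); b <- abs(as.integer(b))
  while (b != 0L) { t <- b; b <- a %% b; a <- t }
  a
}

lcm_int <- function(a, b) {
  as.integer(a / gcd_int(a, b)) * as.integer(b)
}

# Best rational approximation by continued fractions.
rationalize_cf <- function(x, tol = 1e-12, max_denom = 1e7) {
  p0 <- 0L; q0 <- 1L; p1 <- 1L; q1 <- 0L
  r <- x
  for (i in 1:64) {
    a <- floor(r)
    p2 <- a * p1 + p0; q2 <- a * q1 + q0
    if (q2 > max_denom) break
    p0 <- p1; q0 <- q1; p1 <- p2; q1 <- q2
    if (abs(p1 / q1 - x) <= tol) break
    frac <- r - a
    if (frac < 1e-15) break
    r <- 1 / frac
  }
  if (abs(p1 / q1 - x) > tol) {
    abort(sprintf("cannot rationalize %.15g to tolerance %g with denominator <= %g.",
                  x, tol, max_denom))
  }
  list(as.integer(p1), as.integer(q1))
}

#' Least common multiple of the denominators of a set of orders
#'
#' Computes \eqn{M}, the common multiple used to turn the incommensurate
#' characteristic determinant into a polynomial in \eqn{\lambda}: substituting
#' \eqn{s = \lambda^{1/M}} makes every exponent \eqn{M\alpha_i} an integer.
#'
#' @param orders A list of [rational_order()] objects (a single object is
#'   promoted to a list).
#' @return Integer \eqn{M}, the LCM of all denominators.
#' @examples
#' common_multiple(list(rational_order(0.97), rational_order(1)))  # 100
#' common_multiple(list(rational_order(0.5, "reduced"),
#'                      rational_order(1/3, "reduced")))           # 6
#' @export
common_multiple <- function(orders) {
  if (inherits(orders, "rational_order")) orders <- list(orders)
  if (length(orders) == 0L) abort("`orders` must be a nonempty list.")
  dens <- vapply(orders, function(o) {
    if (!inherits(o, "rational_order")) abort("every element must be a rational_order.")
    o$u
  }, integer(1))
  Reduce(lcm_int, dens)
}
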