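#' Distributed-delay logistic models reduced by the linear chain trick
#'
#' Two fractional logistic models with an exponentially distributed delay
#' (weak kernel \eqn{e^{-a(t-s)}}, chain length 1):
#'
#' * **Variant I** delays the crowding term through the kernel of the state:
#'   \eqn{D^{\alpha_1} x = \rho x - \rho\,(\int_0^t e^{-a(t-s)} x(s)\,ds)^2}.
#'   With \eqn{y(t) = \int_0^t e^{-a(t-s)} x(s)\,ds} this becomes the
#'   incommensurate system
#'   \eqn{D^{\alpha_1} x = \rho x - \rho y^2,\; D^{1} y = x - a y}, `y(0) = 0`.
#' * **Variant II** distributes the squared state:
#'   \eqn{D^{\alpha_1} x = \rho x - \rho \int_0^t e^{-a(t-s)} x^2(s)\,ds},
#'   reducing to \eqn{D^{\alpha_1} x = \rho x - \rho y,\; D^{1} y = x^2 - a y}.
#'
#' Both have a trivial equilibrium at the origin (always unstable: the
#' characteristic polynomial has a positive real root) and one positive
#' equilibrium — \eqn{(a^2, a)} for variant I, \eqn{(a, a)} for variant II —
#' whose characteristic polynomials coincide term by term:
#' \deqn{\lambda^{M(\alpha_1+1)} + a\lambda^{M\alpha_1} - \rho\lambda^{M} + a\rho = 0.}
#'
#' @param variant `"I"` or `"II"`.
#' @param alpha1 Fractional order of the state equation, in \eqn{(0, 1)}.
#'   May be a number (rationalized with `denominator`) or a
#'   [rational_order()]. The chain variable always has order
#'   \eqn{\alpha_2 = 1}.
#' @param rho Growth coefficient, \eqn{> 0}.
#' @param a Kernel decay rate (1/time), \eqn{> 0}.
#' @param denominator Denominator convention for rationalizing `alpha1`
#'   (default 100, i.e. two-decimal orders and threshold \eqn{\pi/200}).
#'
#' @return Object of class `"chain_model"`.
#' @examples
#' m <- chain_model("I", alpha1 = 0.97, rho = 4.5, a = 4.6)
#' equilibria(m)
#' stability_report(m)$verdict    # "stable"
#' @export
chain_model <- function(variant = c("I", "II"), alpha1, rho, a,
                        denominator = 100L) {
  variant <- match.arg(variant)
  if (!is.numeric(rho) || length(rho) != 1L || rho <= 0) abort("`rho` must be > 0.")
  if (!is.numeric(a) || length(a) != 1L || a <= 0) abort("`a` must be > 0.")
  if (!inherits(alpha1, "rational_order")) {
    alpha1 <- rational_order(alpha1, "denominator", denominator)
  }
  if (alpha1$alpha >= 1) abort("`alpha1` must be strictly less than 1.")
  structure(
    list(variant = variant, alpha1 = alpha1,
         alpha2 = rational_order(1, "denominator", 1L),
         rho = rho, a = a),
    class = "chain_model"
  )
}

#' @export
print.chain_model <- function(x, ...) {
  cat(sprintf(
    "<chain_model %s> alpha1 = %s, rho = %g, a = %g  (positive equilibrium (%g, %g))\n",
    x$variant, format(x$alpha1), x$rho, x$a,
    equilibria(x)$x[2], equilibria(x)$y[2]
  ))
  invisible(x)
}

#' Right-hand side of a chain-reduced system
#'
#' @param model A [chain_model()].
#' @param state Numeric vector `c(x, y)`.
#' @return Numeric vector `c(dx, dy)` of Caputo-derivative values.
#' @export
chain_rhs <- function(model, state) {
  x <- state[1L]; y <- state[2L]
  if (model$variant == "I") {
    c(model$rho * x - model$rho * y^2, x - model$a * y)
  } else {
    c(model$rho * x - model$rho * y, x^2 - model$a * y)
  }
}

#' Equilibria of a chain-reduced model
#'
#' @param model A [chain_model()].
#' @return Tibble with columns `equilibrium` (`"trivial"`, `"positive"`),
#'   `x`, `y`. Variant I: \eqn{(0,0)} and \eqn{(a^2, a)}; variant II:
#'   \eqn{(0,0)} and \eqn{(a, a)}.
#' @export
equilibria <- function(model) {
  stopifnot(inherits(model, "chain_model"))
  a <- model$a
  pos <- if (model$variant == "I") c(a^2, a) else c(a, a)
  tibble::tibble(
    equilibrium = c("trivial", "positive"),
    x = c(0, pos[1L]),
    y = c(0, pos[2L])
  )
}

#' Jacobian of a chain-reduced model at an equilibrium
#'
#' @param model A [chain_model()].
#' @param point Either an equilibrium label (`"positive"`, `"trivial"`) or a
#'   numeric `c(x, y)` point; a numeric point must be an equilibrium (the
#'   right-hand side must vanish to `1e-9`).
#' @return 2x2 numeric matrix of partial derivatives.
#' @examples
#' m <- chain_model("I", 0.97, rho = 4.5, a = 4.5)
#' chain_jacobian(m, "positive")   # rbind(c(rho, -2*rho*a), c(1, -a))
#' @export
chain_jacobian <- function(model, point = "positive") {
  stopifnot(inherits(model, "chain_model"))
  if (is.character(point)) {
    eq <- equilibria(model)
    row <- eq[eq$equilibrium == match.arg(point, eq$equilibrium), ]
    point <- c(row$x, row$y)
  } else {
    res <- chain_rhs(model, point)
    if (max(abs(res)) > 1e-9) {
      abort(sprintf("point (%g, %g) is not an equilibrium (residual %.3g).",
                    point[1L], point[2L], max(abs(res))))
    }
  }
  x <- point[1L]; y <- point[2L]
  if (model$variant == "I") {
    rbind(c(model$rho, -2 * model$rho * y), c(1, -model$a))
  } else {
    rbind(c(model$rho, -model$rho), c(2 * x, -model$a))
  }
}

#' Characteristic polynomial of a chain model at an equilibrium
#'
#' Composes [chain_jacobian()] with [char_poly()]. At the positive
#' equilibrium both variants give the identical sparse polynomial
#' \eqn{\{M(\alpha_1+1)\!: 1,\; M\alpha_1\!: a,\; M\!: -\rho,\; 0\!: a\rho\}};
#' at the trivial equilibrium the constant term flips sign to \eqn{-a\rho},
#' which forces a positive real root (sign change of the polynomial on the
#' positive axis) and hence instability for any \eqn{\rho, a > 0}.
#'
#' @param model A [chain_model()].
#' @param which `"positive"` or `"trivial"`.
#' @param M Common multiple of the order denominators (default from the
#'   model's orders).
#' @return A [sparse_poly()].
#' @export
char_poly_at <- function(model, which = c("positive", "trivial"), M = NULL) {
  which <- match.arg(which)
  if (is.null(M)) M <- common_multiple(list(model$alpha1, model$alpha2))
  char_poly(chain_jacobian(model, which),
            list(model$alpha1, model$alpha2), M = M)
}
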