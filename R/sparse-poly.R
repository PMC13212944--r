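#' Sparse polynomials with integer exponents
#'
#' The characteristic equations of the chain-reduced models are sparse: a
#' handful of terms with exponents up to \eqn{M(\alpha_1 + 1) \approx 200}.
#' Storing (exponent, coefficient) pairs keeps evaluation, differentiation and
#' Newton refinement cheap and exact.
#'
#' @param exponents Non-negative integer exponents.
#' @param coefficients Real coefficients, same length as `exponents`.
#'   Duplicate exponents are combined; zero coefficients are dropped.
#' @return An object of class `"sparse_poly"`: a list with integer vector
#'   `exponents` (strictly decreasing) and numeric `coefficients` (leading
#'   coefficient nonzero). The zero polynomial has empty vectors.
#' @examples
#' p <- sparse_poly(c(197, 100, 97, 0), c(1, -4.5, 4.5, 20.25))
#' poly_degree(p)
#' poly_eval(p, 1 + 0i)
#' @export
sparse_poly <- function(exponents, coefficients) {
  if (length(exponents) != length(coefficients)) {
    abort("`exponents` and `coefficients` must have the same length.")
  }
  e <- as.integer(round(exponents))
  if (any(abs(exponents - e) > 1e-9) || any(e < 0L)) {
    abort("exponents must be non-negative integers.")
  }
  cf <- tapply(as.numeric(coefficients), e, sum)
  e <- as.integer(names(cf))
  cf <- as.numeric(cf)
  keep <- cf != 0
  e <- e[keep]; cf <- cf[keep]
  o <- order(e, decreasing = TRUE)
  structure(list(exponents = e[o], coefficients = cf[o]), class = "sparse_poly")
}

#' @export
print.sparse_poly <- function(x, ...) {
  if (length(x$exponents) == 0L) {
    cat("<sparse_poly> 0\n")
    return(invisible(x))
  }
  terms <- sprintf("%+g*lambda^%d", x$coefficients, x$exponents)
  cat("<sparse_poly>", paste(terms, collapse = " "), "\n")
  invisible(x)
}

#' @rdname sparse_poly
#' @param p,q Sparse polynomials.
#' @export
poly_degree <- function(p) {
  if (length(p$exponents) == 0L) -Inf else p$exponents[1L]
}

#' @rdname sparse_poly
#' @param z Complex (or numeric) vector of evaluation points.
#' @export
poly_eval <- function(p, z) {
  z <- as.complex(z)
  out <- rep(0 + 0i, length(z))
  for (k in seq_along(p$exponents)) {
    out <- out + p$coefficients[k] * z^p$exponents[k]
  }
  out
}

#' @rdname sparse_poly
#' @export
poly_deriv <- function(p) {
  keep <- p$exponents > 0L
  sparse_poly(p$exponents[keep] - 1L, p$coefficients[keep] * p$exponents[keep])
}

#' @rdname sparse_poly
#' @export
poly_add <- function(p, q) {
  sparse_poly(c(p$exponents, q$exponents), c(p$coefficients, q$coefficients))
}

#' @rdname sparse_poly
#' @export
poly_mul <- function(p, q) {
  if (length(p$exponents) == 0L || length(q$exponents) == 0L) {
    return(sparse_poly(integer(), numeric()))
  }
  e <- outer(p$exponents, q$exponents, `+`)
  cf <- outer(p$coefficients, q$coefficients)
  sparse_poly(as.vector(e), as.vector(cf))
}

#' @rdname sparse_poly
#' @param s Scalar multiplier.
#' @export
poly_scale <- function(p, s) sparse_poly(p$exponents, p$coefficients * s)

# Dense coefficient vector c0, c1, ..., cd (ascending powers).
poly_dense <- function(p) {
  d <- poly_degree(p)
  if (!is.finite(d)) return(numeric())
  out <- numeric(d + 1L)
  out[p$exponents + 1L] <- p$coefficients
  out
}

#' @export
as.data.frame.sparse_poly <- function(x, ...) {
  data.frame(exponent = x$exponents, coefficient = x$coefficients)
}

#' @export
tidy.sparse_poly <- function(x, ...) {
  tibble::tibble(exponent = x$exponents, coefficient = x$coefficients)
}
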