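#' Fractional logistic equation with a discrete delay
#'
#' The Caputo equation
#' \deqn{D^{\alpha} y(t) = \rho y(t) - \rho y^2(t - r), \qquad y(t) = \phi(t) \; (t \le 0),}
#' with order \eqn{\alpha \in (0, 1]}, growth coefficient \eqn{\rho > 0} and
#' discrete delay \eqn{r \ge 0}. Its equilibria are \eqn{y^* = 0} (unstable
#' for every delay) and \eqn{y^* = 1}, which is stable exactly for delays
#' below the first critical curve \eqn{r_1(0)} and loses stability there
#' through a Hopf bifurcation.
#'
#' @param alpha Order in \eqn{(0, 1]}.
#' @param rho Growth coefficient, \eqn{> 0}.
#' @param r Delay, \eqn{\ge 0} (time units).
#' @param history Function \eqn{\phi(t)} on \eqn{[-r, 0]} (default the
#'   constant 0.5; only used by [simulate_logistic_dde()]).
#' @return Object of class `"logistic_delay_model"`.
#' @examples
#' m <- logistic_delay_model(alpha = 1, rho = 1, r = 0.3)
#' is_stable(m)$verdict   # "stable": 0.3 < r1(0) = pi/(3*sqrt(3))
#' @export
logistic_delay_model <- function(alpha, rho, r, history = function(t) rep(0.5, length(t))) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha > 1) abort("`alpha` must be in (0, 1].")
  if (!is.numeric(rho) || rho <= 0) abort("`rho` must be > 0.")
  if (!is.numeric(r) || r < 0) abort("`r` must be >= 0.")
  if (!is.function(history)) abort("`history` must be a function of t.")
  structure(list(alpha = alpha, rho = rho, r = r, history = history),
            class = "logistic_delay_model")
}

#' @export
print.logistic_delay_model <- function(x, ...) {
  cat(sprintf("<logistic_delay_model> alpha = %g, rho = %g, r = %g\n",
              x$alpha, x$rho, x$r))
  invisible(x)
}

#' Equilibria of the delayed logistic equation
#'
#' Solutions of \eqn{\rho y^*(1 - y^*) = 0}: always \eqn{\{0, 1\}},
#' independent of \eqn{\rho}.
#'
#' @param rho Growth coefficient, \eqn{> 0}.
#' @return Numeric vector `c(0, 1)`.
#' @export
logistic_equilibria <- function(rho) {
  if (rho <= 0) abort("`rho` must be > 0.")
  c(0, 1)
}

#' Characteristic residual of the delayed logistic linearization
#'
#' Evaluates \eqn{\lambda^{\alpha} + \rho(2 y^* e^{-\lambda r} - 1)} with the
#' principal branch of \eqn{\lambda^{\alpha}}. A value of zero means
#' \eqn{\lambda} is a characteristic root at the equilibrium \eqn{y^*}; every
#' other operation in this module is validated against this residual.
#'
#' @param lambda Complex evaluation point (nonzero when `alpha` is not an
#'   integer).
#' @param model A [logistic_delay_model()].
#' @param y_star Equilibrium value, 0 or 1.
#' @return Complex residual.
#' @export
char_residual <- function(lambda, model, y_star) {
  lambda <- as.complex(lambda)
  lambda^model$alpha + model$rho * (2 * y_star * exp(-lambda * model$r) - 1)
}

#' Imaginary-axis crossing frequencies
#'
#' Frequencies \eqn{u > 0} at which a characteristic root can sit on the
#' imaginary axis, obtained from the squared-modulus equation
#' \eqn{u^{2\alpha} - 2\rho u^{\alpha}\cos(\alpha\pi/2) + \rho^2(1 - 4y^{*2}) = 0}:
#' \deqn{u^{\alpha} = \rho\cos(\alpha\pi/2) \pm \rho\sqrt{4 y^{*2} - \sin^2(\alpha\pi/2)}.}
#' Branches whose right-hand side is not strictly positive carry no real
#' frequency and are discarded (for \eqn{y^* = 1} the minus branch is always
#' inadmissible since \eqn{\sqrt{4 - \sin^2} > \cos}).
#'
#' @param alpha Order in \eqn{(0, 1]}.
#' @param rho Growth coefficient, \eqn{> 0}.
#' @param y_star Equilibrium, 0 or 1.
#' @return Tibble with columns `sign_u` (`"+"`/`"-"`) and `u`; zero rows when
#'   no branch is admissible (no imaginary-axis crossing).
#' @examples
#' crossing_frequencies(1, 1, 1)$u   # sqrt(3)
#' @export
crossing_frequencies <- function(alpha, rho, y_star) {
  if (!y_star %in% c(0, 1)) abort("`y_star` must be 0 or 1.")
  disc <- 4 * y_star^2 - sin(alpha * pi / 2)^2
  if (disc < 0) return(tibble::tibble(sign_u = character(), u = numeric()))
  rhs <- rho * cos(alpha * pi / 2) + c(`+` = 1, `-` = -1) * rho * sqrt(disc)
  keep <- rhs > 0
  tibble::tibble(sign_u = names(rhs)[keep],
                 u = unname(rhs[keep])^(1 / alpha))
}

#' Critical delay curves
#'
#' Delays at which the linearization at \eqn{y^* = 1} has a root on the
#' imaginary axis. From the real part of the characteristic equation,
#' \eqn{\cos(ur) = (u^{\alpha}\cos(\alpha\pi/2) - \rho)/(-2\rho y^*)}, giving
#' the two curve families
#' \deqn{r_1(n) = \frac{2n\pi + \arccos(\cdot)}{u}, \qquad
#'       r_2(n) = \frac{2n\pi - \arccos(\cdot)}{u} \;(n \ge 1).}
#' Only the `r1` family also satisfies the imaginary-part equation
#' \eqn{u^{\alpha}\sin(\alpha\pi/2) = 2\rho y^* \sin(ur)}, i.e. makes
#' \eqn{\lambda = iu} an actual root: the `r2` family is a spurious branch of
#' the squared-modulus equation, retained for completeness and always lying
#' above \eqn{r_1(0)}. The returned `genuine` flag records a run-time residual
#' test of [char_residual()] at \eqn{\lambda = iu}, not an assumption.
#'
#' @inheritParams crossing_frequencies
#' @param n Branch index (non-negative integer; `r2` requires `n >= 1`).
#' @param family `"r1"` or `"r2"`.
#' @return One-row tibble (class `"critical_curve_point"`) with `n`, `family`,
#'   `sign_u`, `u`, `r`, `residual` (\eqn{|}characteristic residual at
#'   \eqn{iu}|) and `genuine` (`residual < 1e-9`).
#' @examples
#' critical_delay(1, 1)$r           # pi/(3*sqrt(3)) ~ 0.60460
#' @export
critical_delay <- function(alpha, rho, y_star = 1, n = 0L,
                           family = c("r1", "r2")) {
  family <- match.arg(family)
  n <- as.integer(n)
  if (n < 0L) abort("`n` must be a non-negative integer.")
  if (family == "r2" && n < 1L) abort("family r2 starts at n = 1.")
  if (y_star == 0) abort("y* = 0 has no imaginary-axis crossing (real positive root for every delay).")
  freq <- crossing_frequencies(alpha, rho, y_star)
  if (nrow(freq) == 0L) abort("no admissible crossing frequency.")
  # smallest critical delay comes from the largest admissible u
  freq <- freq[which.max(freq$u), ]
  u <- freq$u
  arg <- (u^alpha * cos(alpha * pi / 2) - rho) / (-2 * rho * y_star)
  if (arg < -1 - 1e-12 || arg > 1 + 1e-12) {
    abort("no crossing on this branch (arccos argument out of [-1, 1]).")
  }
  theta <- acos(min(1, max(-1, arg)))
  r <- if (family == "r1") (2 * n * pi + theta) / u else (2 * n * pi - theta) / u
  res <- Mod(char_residual(1i * u,
                           logistic_delay_model(alpha, rho, r), y_star))
  out <- tibble::tibble(n = n, family = family, sign_u = freq$sign_u,
                        u = u, r = r, residual = res, genuine = res < 1e-9)
  class(out) <- c("critical_curve_point", class(out))
  out
}

#' Transversality of the root crossing
#'
#' The real part of \eqn{d\lambda/dr} at a crossing \eqn{\lambda = iu} on a
#' critical curve, computed two independent ways and cross-checked to
#' \eqn{10^{-9}}: (i) from the four auxiliary quantities
#' \eqn{z_1, \dots, z_4} of the quotient formula
#' \eqn{\mathrm{Re}(d\lambda/dr) = (z_1 z_3 + z_2 z_4)/(z_3^2 + z_4^2)}, and
#' (ii) from the compact identity
#' \eqn{z_1 z_3 + z_2 z_4 = r\rho u^{\alpha+1}(1 - \sin(\alpha\pi/2))
#' + \alpha u^{2\alpha} - r u \rho^2 \cos(\alpha\pi/2)}.
#' A positive value means the root pair moves rightward as the delay grows,
#' so no root re-enters the left half-plane across the curve and the region
#' below \eqn{r_1(0)} is the only stable one.
#'
#' @param alpha Order in \eqn{(0, 1]}.
#' @param rho Growth coefficient, \eqn{> 0}.
#' @param r Delay at the crossing, \eqn{> 0}.
#' @param u Crossing frequency, \eqn{> 0}.
#' @return Signed real \eqn{\mathrm{Re}(d\lambda/dr)}, with attribute
#'   `"numerator"` carrying both evaluations of \eqn{z_1 z_3 + z_2 z_4}.
#' @export
transversality <- function(alpha, rho, r, u) {
  if (u <= 0 || r <= 0) abort("`u` and `r` must be positive.")
  c2 <- cos(alpha * pi / 2); s2 <- sin(alpha * pi / 2)
  z1 <- u * rho * c2 - u^(alpha + 1) * cos((alpha + 1) * pi / 2)
  z2 <- u * rho * s2 - u^(alpha + 1) * sin((alpha + 1) * pi / 2)
  z3 <- alpha * u^(alpha - 1) * cos((alpha - 1) * pi / 2) + r * u^alpha * c2 - rho * r
  z4 <- alpha * u^(alpha - 1) * sin((alpha - 1) * pi / 2) + r * u^alpha * s2
  denom <- z3^2 + z4^2
  if (denom == 0) abort("degenerate denominator (z3^2 + z4^2 = 0).")
  num_z <- z1 * z3 + z2 * z4
  num_id <- r * rho * u^(alpha + 1) * (1 - s2) + alpha * u^(2 * alpha) -
    r * u * rho^2 * c2
  if (abs(num_z - num_id) > 1e-9 * (1 + abs(num_z))) {
    abort(sprintf("transversality numerator mismatch: %.12g vs %.12g.",
                  num_z, num_id))
  }
  structure(num_z / denom, numerator = c(z_form = num_z, identity = num_id))
}

#' Delay-stability verdict for the delayed logistic equation
#'
#' For \eqn{y^* = 1}: stable iff the delay is below the first critical curve
#' \eqn{r_1(0)}, marginal (Hopf boundary) within
#' `tol = 1e-6 * (1 + r1(0))` of it, unstable beyond. For \eqn{y^* = 0}:
#' unstable for every delay (the characteristic function
#' \eqn{\lambda^\alpha - \rho} has the positive real root \eqn{\rho^{1/\alpha}}).
#'
#' @param model A [logistic_delay_model()].
#' @param y_star Equilibrium to assess (default 1).
#' @return A list with `verdict` (`"stable"`, `"unstable"`, `"marginal"`),
#'   `r_crit` (\eqn{r_1(0)}; `NA` for \eqn{y^* = 0}) and `hopf` (`TRUE` when
#'   marginal at the boundary).
#' @export
is_stable <- function(model, y_star = 1) {
  stopifnot(inherits(model, "logistic_delay_model"))
  if (y_star == 0) {
    return(list(verdict = "unstable", r_crit = NA_real_, hopf = FALSE))
  }
  r10 <- critical_delay(model$alpha, model$rho, y_star = 1, n = 0L, "r1")$r
  tol <- 1e-6 * (1 + r10)
  verdict <- if (model$r < r10 - tol) "stable"
             else if (model$r > r10 + tol) "unstable"
             else "marginal"
  list(verdict = verdict, r_crit = r10, hopf = verdict == "marginal")
}

#' Parameter-plane stability map for the delayed logistic equation
#'
#' Evaluates [is_stable()] at \eqn{y^* = 1} over a grid in the `(alpha, r)`
#' or `(rho, r)` plane; the stable/unstable boundary is the closed-form curve
#' \eqn{r_1(0)} as a function of the first axis.
#'
#' @param axes `c("alpha", "r")` or `c("rho", "r")`.
#' @param axis1,axis2 Ordered coordinate vectors (`alpha` in \eqn{(0,1]},
#'   `rho` positive, delay non-negative).
#' @param fixed Value of the parameter not on an axis (`rho` for the
#'   `(alpha, r)` plane, `alpha` for `(rho, r)`).
#' @return Tibble of class `"region_grid"` with the axis columns, `verdict`
#'   and `r_crit` (the boundary value at that column).
#' @examples
#' g <- region_scan_logistic(c("alpha", "r"), axis1 = c(0.8, 0.9, 1),
#'                           axis2 = c(0.2, 0.6, 1.2), fixed = 1)
#' @export
region_scan_logistic <- function(axes = c("alpha", "r"), axis1, axis2, fixed) {
  axes <- as.character(axes)
  if (!identical(axes[2L], "r") || !axes[1L] %in% c("alpha", "rho")) {
    abort("`axes` must be c(\"alpha\", \"r\") or c(\"rho\", \"r\").")
  }
  grid <- tidyr::expand_grid(!!axes[1L] := axis1, r = axis2)
  verdicts <- purrr::map2(grid[[1L]], grid$r, function(v1, r) {
    alpha <- if (axes[1L] == "alpha") v1 else fixed
    rho <- if (axes[1L] == "rho") v1 else fixed
    m <- logistic_delay_model(alpha, rho, r)
    s <- is_stable(m)
    tibble::tibble(verdict = s$verdict, r_crit = s$r_crit)
  })
  grid <- dplyr::bind_cols(grid, dplyr::bind_rows(verdicts))
  structure(grid, class = c("region_grid", class(grid)),
            axes = axes, fixed = setNames(list(fixed),
                                          setdiff(c("alpha", "rho"), axes[1L])),
            variant = "logistic", boundary = NULL)
}
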