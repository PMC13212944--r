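#' Fractional Adams predictor-corrector solver
#'
#' Integrates the incommensurate Caputo system
#' \eqn{D^{\alpha_i} x_i = f_i(t, x)} on a uniform grid with the fractional
#' Adams-Bashforth-Moulton scheme: a fractional rectangle-rule predictor
#' followed by `n_corrector` trapezoid-rule corrections (default 1, the PECE
#' scheme). The memory term is the full-history sum — no short-memory
#' truncation — so the cost is \eqn{O(N^2)}; the inner loop is compiled.
#' At \eqn{\alpha = 1} the scheme reduces to the classical one-step
#' Adams-Bashforth-Moulton pair.
#'
#' If the state norm exceeds `overflow_guard`, the trajectory is truncated at
#' the offending step and flagged as divergent (inspect
#' `attr(traj, "diverged_at")`); states in the returned object are always
#' finite.
#'
#' @param f Vector field `f(t, x)` returning a numeric vector, one entry per
#'   state component.
#' @param orders Numeric vector of Caputo orders in \eqn{(0, 1]}, one per
#'   component.
#' @param x0 Initial state at \eqn{t = 0}.
#' @param h Step size (time units), default \eqn{2^{-7}}.
#' @param t_end Final time, \eqn{\ge h}.
#' @param n_corrector Number of corrector applications (default 1).
#' @param overflow_guard Divergence threshold on `max(abs(state))`.
#'
#' @return A tibble of class `"fracstab_trajectory"` with column `time` and
#'   one column per state component; attributes `orders`, `h` and
#'   `diverged_at` (`NA` or the first bad step index).
#' @examples
#' tr <- abm_solve(function(t, x) -x, orders = 1, x0 = 1, h = 1e-2, t_end = 1)
#' tail(tr, 1)$x1 - exp(-1)   # ~1e-6
#' @export
abm_solve <- function(f, orders, x0, h = 2^-7, t_end,
                      n_corrector = 1L, overflow_guard = 1e8) {
  orders <- as.numeric(orders)
  if (any(orders <= 0 | orders > 1)) abort("all orders must lie in (0, 1].")
  if (length(orders) != length(x0)) abort("`orders` and `x0` lengths differ.")
  if (h <= 0 || t_end < h) abort("need h > 0 and t_end >= h.")
  N <- as.integer(round(t_end / h))
  wrapped <- function(t, x) as.numeric(f(t, x))
  res <- abm_pece_cpp(wrapped, orders, as.numeric(x0), h, N,
                      as.integer(n_corrector), overflow_guard)
  nm <- names(x0)
  if (is.null(nm)) nm <- paste0("x", seq_along(x0))
  build_trajectory(res, h, nm, orders)
}

build_trajectory <- function(res, h, comp_names, orders) {
  n_done <- res$n_done
  states <- res$states
  if (is.null(dim(states))) states <- matrix(states, ncol = 1L)
  keep <- seq_len(n_done + 1L)
  df <- tibble::as_tibble(setNames(
    as.data.frame(states[keep, , drop = FALSE]), comp_names
  ))
  df <- dplyr::bind_cols(tibble::tibble(time = (keep - 1L) * h), df)
  diverged <- if (res$diverged_at >= 0L) res$diverged_at else NA_integer_
  structure(df, class = c("fracstab_trajectory", class(df)),
            orders = orders, h = h, diverged_at = diverged)
}

#' Simulate a chain-reduced distributed-delay model
#'
#' Runs the fractional Adams scheme (compiled, with the model's right-hand
#' side) on the two-component chain system with orders
#' \eqn{(\alpha_1, 1)}. The chain variable starts at \eqn{y(0) = 0} by the
#' defining integral. The default initial population is `x0 = 1`: a small
#' positive state well inside the basin of attraction of the positive
#' equilibrium. (Starting near the equilibrium with `y(0) = 0` is *not*
#' equivalent — that point lies outside the basin for the weakly damped
#' parameter sets and the true solution escapes in finite time.)
#'
#' With `t_end = NULL` the horizon is chosen adaptively: the run is extended
#' through 100, 200 and 400 time units until [classify_regime()] reaches a
#' verdict; the result of the classification is stored in
#' `attr(traj, "regime")`.
#'
#' To probe the *local* regime at the positive equilibrium (convergent spiral
#' vs sustained oscillation at the stability boundary), start from a small
#' perturbation instead of a cold start: near the boundary the basin of
#' attraction shrinks to a neighbourhood of the equilibrium and every
#' trajectory with \eqn{y(0) = 0} escapes, whatever `x0`. [near_equilibrium()]
#' builds such a perturbed initial state.
#'
#' @param model A [chain_model()].
#' @param x0 Initial population, \eqn{> 0} (default 1).
#' @param y0 Initial chain state (default 0, the value fixed by the defining
#'   integral).
#' @param h Step size (default \eqn{2^{-7}}).
#' @param t_end Final time, or `NULL` for the adaptive schedule.
#' @param n_corrector,overflow_guard See [abm_solve()].
#' @param ... Passed to [classify_regime()] in adaptive mode.
#'
#' @return A `"fracstab_trajectory"` tibble with columns `time`, `x`, `y`.
#' @examples
#' m <- chain_model("I", 0.97, rho = 4.5, a = 5)
#' tr <- simulate_chain(m, h = 2^-5, t_end = 60)
#' tail(tr, 1)   # near the equilibrium (25, 5)
#' @export
simulate_chain <- function(model, x0 = 1, y0 = 0, h = 2^-7, t_end = NULL,
                           n_corrector = 1L, overflow_guard = 1e8, ...) {
  stopifnot(inherits(model, "chain_model"))
  if (x0 <= 0) abort("`x0` must be > 0.")
  run <- function(T) {
    N <- as.integer(round(T / h))
    res <- abm_chain_cpp(if (model$variant == "I") 1L else 2L,
                         model$alpha1$alpha, model$rho, model$a,
                         x0, y0, h, N, as.integer(n_corrector), overflow_guard)
    build_trajectory(res, h, c("x", "y"), c(model$alpha1$alpha, 1))
  }
  if (!is.null(t_end)) return(run(t_end))
  for (T in c(100, 200, 400)) {
    tr <- run(T)
    reg <- classify_regime(tr, ...)
    if (reg$label != "undecided" || T == 400) {
      attr(tr, "regime") <- reg
      return(tr)
    }
  }
}

#' Perturbed initial state near the positive equilibrium
#'
#' Returns `c(x0, y0)` a relative distance `eps` from the positive
#' equilibrium of a chain model (both components scaled by `1 + eps`).
#' Useful as a local-stability probe for [simulate_chain()].
#'
#' @param model A [chain_model()].
#' @param eps Relative perturbation (default 0.02).
#' @return Named numeric vector `c(x0 = , y0 = )`.
#' @export
near_equilibrium <- function(model, eps = 0.02) {
  eq <- equilibria(model)
  pos <- eq[eq$equilibrium == "positive", ]
  c(x0 = pos$x * (1 + eps), y0 = pos$y * (1 + eps))
}

#' Simulate the fractional logistic equation with a discrete delay
#'
#' Fractional Adams scheme for
#' \eqn{D^{\alpha} y = \rho y(t) - \rho y^2(t - r)} with history
#' \eqn{y(t) = \phi(t)} for \eqn{t \le 0}. The delayed state is read from the
#' stored solution grid by an exact index shift \eqn{r/h} (no interpolation);
#' `r` is snapped to the nearest multiple of `h` with a warning if needed.
#' The initial value is \eqn{y(0) = \phi(0)}.
#'
#' @param model A [logistic_delay_model()] (its `history` supplies \eqn{\phi}).
#' @param h Step size (default \eqn{2^{-7}}).
#' @param t_end Final time.
#' @param n_corrector,overflow_guard See [abm_solve()].
#' @return A `"fracstab_trajectory"` tibble with columns `time`, `y`.
#' @examples
#' m <- logistic_delay_model(1, 1, r = 0.25)
#' tr <- simulate_logistic_dde(m, h = 2^-5, t_end = 40)
#' tail(tr, 1)$y    # ~1
#' @export
simulate_logistic_dde <- function(model, h = 2^-7, t_end = 100,
                                  n_corrector = 1L, overflow_guard = 1e8) {
  stopifnot(inherits(model, "logistic_delay_model"))
  L_real <- model$r / h
  L <- as.integer(round(L_real))
  if (abs(L_real - L) > 1e-9) {
    warn(sprintf("delay r = %g snapped to %g (nearest multiple of h = %g).",
                 model$r, L * h, h))
  }
  phi <- as.numeric(model$history(((0:L) - L) * h))
  if (length(phi) != L + 1L || any(!is.finite(phi))) {
    abort("`history` must return finite values on [-r, 0].")
  }
  N <- as.integer(round(t_end / h))
  res <- abm_logistic_dde_cpp(model$alpha, model$rho, L, phi, h, N,
                              as.integer(n_corrector), overflow_guard)
  build_trajectory(res, h, "y", model$alpha)
}

#' @export
autoplot.fracstab_trajectory <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object), -"time",
                              names_to = "component", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$value,
                                     colour = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "t", y = "state")
}
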