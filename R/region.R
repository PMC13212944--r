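#' Parameter-plane stability map for a chain model
#'
#' Evaluates [stability_report()] at the positive equilibrium over a grid in
#' one of the planes `(alpha1, a)`, `(rho, a)` or `(alpha1, rho)`, holding the
#' third parameter at the template model's value. Optionally refines the
#' stable/unstable boundary along each grid column by bisection in the second
#' axis (which is always a continuous parameter, `a` or `rho`).
#'
#' @param model A [chain_model()] template supplying the variant, the fixed
#'   parameter and the rationalization denominator.
#' @param axes Character vector of length 2 naming the plane, e.g.
#'   `c("alpha1", "a")`. Axis names must be distinct members of
#'   `{"alpha1", "rho", "a"}` and the second axis must be `"a"` or `"rho"`.
#' @param axis1,axis2 Ordered coordinate vectors. `alpha1` values must be
#'   representable under the model's denominator convention and lie in
#'   \eqn{(0,1)}; `rho` and `a` values must be positive.
#' @param tol Marginality tolerance passed to [stability_report()].
#' @param refine_boundary If `TRUE`, bisect each stable/unstable sign change
#'   of the IMFOS along axis2 to the given relative width.
#' @param bisect_rel Relative width target for boundary bisection.
#'
#' @return A tibble of class `"region_grid"` with the two axis columns plus
#'   `min_arg`, `imfos`, `verdict`. Attributes: `axes`, `fixed` (named list of
#'   held parameters), and — when refined — `boundary`, a tibble of
#'   `(axis1, axis2_lo, axis2_hi)` brackets per sign change.
#' @examples
#' m <- chain_model("I", 0.97, rho = 4.5, a = 4.5)
#' g <- region_scan(m, c("alpha1", "a"),
#'                  axis1 = c(0.95, 0.97, 0.99), axis2 = c(4, 4.5, 5, 6))
#' dplyr::count(g, verdict)
#' @export
region_scan <- function(model, axes = c("alpha1", "a"),
                        axis1, axis2, tol = 1e-5,
                        refine_boundary = FALSE, bisect_rel = 1e-4) {
  stopifnot(inherits(model, "chain_model"))
  axes <- as.character(axes)
  ok <- length(axes) == 2L && all(axes %in% c("alpha1", "rho", "a")) &&
    axes[1L] != axes[2L] && axes[2L] %in% c("a", "rho")
  if (!ok) abort("`axes` must be two distinct names from {alpha1, rho, a}, with axis2 in {a, rho}.")
  check_axis(axes[1L], axis1)
  check_axis(axes[2L], axis2)
  denom <- model$alpha1$u

  at <- function(v1, v2) {
    par <- list(alpha1 = model$alpha1$alpha, rho = model$rho, a = model$a)
    par[[axes[1L]]] <- v1
    par[[axes[2L]]] <- v2
    m <- chain_model(model$variant, par$alpha1, par$rho, par$a,
                     denominator = denom)
    stability_report(m, which = "positive", tol = tol)
  }

  grid <- tidyr::expand_grid(!!axes[1L] := axis1, !!axes[2L] := axis2)
  reports <- purrr::map2(grid[[1L]], grid[[2L]], at)
  grid$min_arg <- purrr::map_dbl(reports, "min_arg")
  grid$imfos <- purrr::map_dbl(reports, "imfos")
  grid$verdict <- purrr::map_chr(reports, "verdict")

  boundary <- NULL
  if (refine_boundary) {
    boundary <- purrr::map_dfr(unique(grid[[1L]]), function(v1) {
      col <- grid[grid[[1L]] == v1, ]
      s <- sign(col$imfos)
      flips <- which(s[-1L] * s[-length(s)] < 0)
      purrr::map_dfr(flips, function(i) {
        lo <- col[[2L]][i]; hi <- col[[2L]][i + 1L]
        f_lo <- col$imfos[i]
        while ((hi - lo) > bisect_rel * max(abs(hi), 1)) {
          mid <- (lo + hi) / 2
          f_mid <- at(v1, mid)$imfos
          if (sign(f_mid) == sign(f_lo)) { lo <- mid; f_lo <- f_mid } else hi <- mid
        }
        tibble::tibble(!!axes[1L] := v1, axis2_lo = lo, axis2_hi = hi)
      })
    })
  }

  fixed_name <- setdiff(c("alpha1", "rho", "a"), axes)
  fixed <- setNames(
    list(switch(fixed_name, alpha1 = model$alpha1$alpha, rho = model$rho, a = model$a)),
    fixed_name
  )
  structure(grid,
            class = c("region_grid", class(grid)),
            axes = axes, fixed = fixed, variant = model$variant,
            boundary = boundary)
}

check_axis <- function(name, values) {
  if (length(values) < 1L || is.unsorted(values, strictly = TRUE)) {
    abort(sprintf("axis `%s` must be a strictly increasing vector.", name))
  }
  if (name == "alpha1") {
    if (any(values <= 0 | values >= 1)) abort("`alpha1` axis must lie in (0, 1).")
  } else if (any(values <= 0)) {
    abort(sprintf("axis `%s` must be positive (the kernel rate and growth coefficient are > 0).", name))
  }
  invisible(values)
}

#' @export
autoplot.region_grid <- function(object, ...) {
  axes <- attr(object, "axes")
  ggplot2::ggplot(object, ggplot2::aes(
    x = .data[[axes[1L]]], y = .data[[axes[2L]]], fill = .data$verdict
  )) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_manual(values = c(
      stable = "#2166ac", unstable = "#b2182b", marginal = "#fddbc7"
    )) +
    ggplot2::labs(
      title = sprintf("Stability region, model %s", attr(object, "variant")),
      subtitle = paste(names(attr(object, "fixed")), "=",
                       unlist(attr(object, "fixed")), collapse = ", ")
    )
}
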