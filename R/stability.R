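#' Minimum-argument stability test for incommensurate fractional systems
#'
#' Applies the root-argument criterion: an equilibrium of an incommensurate
#' Caputo system whose orders share the common denominator multiple \eqn{M} is
#' asymptotically stable iff every root \eqn{\lambda} of the characteristic
#' polynomial satisfies \eqn{|\arg(\lambda)| > \pi/(2M)}. The report carries
#' the instability measure (IMFOS)
#' \deqn{\mathrm{imfos} = \pi/(2M) - \min_i |\arg(\lambda_i)|,}
#' negative for stable equilibria. Verdicts within `tol` radians of the
#' threshold are reported `"marginal"`: at the boundary a conjugate root pair
#' sits on the wedge and the nonlinear system exhibits a periodic (Hopf-type)
#' solution rather than decay.
#'
#' `stability_report()` is generic: apply it to a [sparse_poly()] (with `M`
#' supplied) or directly to a [chain_model()] (the characteristic polynomial
#' at the requested equilibrium is built internally).
#'
#' @param x A [sparse_poly()] or a [chain_model()].
#' @param M Positive integer; the common multiple of the order denominators
#'   (defines the wedge half-angle \eqn{\pi/(2M)}).
#' @param tol Marginality tolerance in radians (default `1e-5`). Reported
#'   Hopf-boundary parameter sets for these models sit within a few `1e-6`
#'   of the threshold while decisive cases differ by at least `3e-5`, so
#'   `1e-5` separates the two cleanly.
#' @param refine Newton-polish the companion-matrix roots (default `TRUE`).
#' @param ... Passed between methods.
#'
#' @return An object of class `"stability_report"`: a list with `min_arg`,
#'   `threshold` (\eqn{= \pi/(2M)}), `imfos` (`threshold - min_arg`),
#'   `verdict` (`"stable"`, `"unstable"` or `"marginal"`), `n_roots`,
#'   `worst_root` (a root attaining `min_arg`), `roots`, `M` and `tol`.
#'   [tidy()] returns the per-root table, [glance()] the one-row summary.
#'
#' @examples
#' p <- sparse_poly(c(197, 100, 97, 0), c(1, -4.5, 5, 22.5))
#' rep <- stability_report(p, M = 100)
#' rep$verdict          # "stable"
#' glance(rep)
#' @export
stability_report <- function(x, ...) UseMethod("stability_report")

#' @rdname stability_report
#' @export
stability_report.sparse_poly <- function(x, M, tol = 1e-5, refine = TRUE, ...) {
  M <- as.integer(M)
  if (is.na(M) || M < 1L) abort("`M` must be a positive integer.")
  if (tol <= 0) abort("`tol` must be positive.")
  roots <- poly_roots(x, refine = refine)
  ma <- min_arg(roots)
  threshold <- pi / (2 * M)
  imfos <- threshold - ma
  verdict <- if (imfos < -tol) "stable" else if (imfos > tol) "unstable" else "marginal"
  worst <- roots[which.min(abs(Arg(roots)))]
  structure(
    list(min_arg = ma, threshold = threshold, imfos = imfos, verdict = verdict,
         n_roots = length(roots), worst_root = worst, roots = roots,
         M = M, tol = tol),
    class = "stability_report"
  )
}

#' @rdname stability_report
#' @param which Which equilibrium of a chain model: `"positive"` or
#'   `"trivial"`.
#' @export
stability_report.chain_model <- function(x, which = c("positive", "trivial"),
                                         M = NULL, tol = 1e-5, refine = TRUE, ...) {
  which <- match.arg(which)
  if (is.null(M)) M <- common_multiple(list(x$alpha1, x$alpha2))
  p <- char_poly_at(x, which = which, M = M)
  stability_report(p, M = M, tol = tol, refine = refine)
}

#' @export
print.stability_report <- function(x, ...) {
  cat("<stability_report>\n")
  cat(sprintf("  verdict    : %s\n", x$verdict))
  cat(sprintf("  min|arg|   : %.7f rad\n", x$min_arg))
  cat(sprintf("  threshold  : %.7f rad (pi/(2*%d))\n", x$threshold, x$M))
  cat(sprintf("  IMFOS      : %+.3e rad (negative => stable)\n", x$imfos))
  cat(sprintf("  roots      : %d (worst at %.6f%+.6fi)\n",
              x$n_roots, Re(x$worst_root), Im(x$worst_root)))
  invisible(x)
}

#' @export
tidy.stability_report <- function(x, ...) {
  tibble::tibble(
    root = x$roots,
    modulus = Mod(x$roots),
    arg = Arg(x$roots),
    inside_wedge = abs(Arg(x$roots)) <= x$threshold
  )
}

#' @export
glance.stability_report <- function(x, ...) {
  tibble::tibble(
    min_arg = x$min_arg, threshold = x$threshold, imfos = x$imfos,
    verdict = x$verdict, n_roots = x$n_roots, M = x$M, tol = x$tol
  )
}

#' @export
autoplot.stability_report <- function(object, ...) {
  df <- tidy(object)
  wedge <- tibble::tibble(
    arg = c(object$threshold, -object$threshold),
    slope = tan(c(object$threshold, -object$threshold))
  )
  rmax <- max(df$modulus) * 1.05
  ggplot2::ggplot(df, ggplot2::aes(x = Re(.data$root), y = Im(.data$root))) +
    ggplot2::geom_segment(
      data = wedge,
      ggplot2::aes(x = 0, y = 0, xend = rmax * cos(.data$arg),
                   yend = rmax * sin(.data$arg)),
      inherit.aes = FALSE, linetype = "dashed", colour = "grey40"
    ) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$inside_wedge), size = 0.8) +
    ggplot2::scale_colour_manual(
      values = c(`TRUE` = "red", `FALSE` = "black"),
      name = "inside wedge"
    ) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "Re(lambda)", y = "Im(lambda)",
      title = sprintf("Characteristic roots (verdict: %s)", object$verdict),
      subtitle = sprintf("min|arg| = %.6f, threshold pi/(2M) = %.6f",
                         object$min_arg, object$threshold)
    )
}
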