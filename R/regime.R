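#' Classify the long-run regime of a trajectory
#'
#' Operationalizes the qualitative labels of the simulation figures
#' ("asymptotically stable" vs "periodic solution") from the tail of a
#' computed trajectory:
#'
#' * `"divergent"` — the solver's overflow guard fired;
#' * `"converged"` — the peak-to-peak amplitude of every component over the
#'   tail window is below `conv_tol * (1 + |tail mean|)`; the reported
#'   `limit` is the tail mean;
#' * `"periodic"` — the tail oscillation has stabilized: the peak-to-peak
#'   amplitudes of the two halves of the tail window agree within 20% and
#'   exceed the convergence tolerance;
#' * `"undecided"` — otherwise (e.g. a transient still decaying or growing).
#'
#' @param traj A `"fracstab_trajectory"` (from [abm_solve()],
#'   [simulate_chain()] or [simulate_logistic_dde()]).
#' @param tail_fraction Fraction of the trajectory used as the tail window
#'   (default 0.25). The window must contain at least 100 steps.
#' @param conv_tol Relative convergence tolerance (default `5e-3`).
#'
#' @return An object of class `"regime_label"`: a list with `label`, `limit`
#'   (tail-mean state vector when converged, otherwise `NA`) and
#'   `tail_amplitude` (largest component peak-to-peak over the tail).
#' @examples
#' tr <- abm_solve(function(t, x) -x, 1, x0 = 1, h = 0.01, t_end = 20)
#' classify_regime(tr)$label   # "converged"
#' @export
classify_regime <- function(traj, tail_fraction = 0.25, conv_tol = 5e-3) {
  stopifnot(inherits(traj, "fracstab_trajectory"))
  if (!is.na(attr(traj, "diverged_at"))) {
    return(structure(list(label = "divergent", limit = NA_real_,
                          tail_amplitude = Inf),
                     class = "regime_label"))
  }
  vals <- as.matrix(traj[, setdiff(names(traj), "time"), drop = FALSE])
  n <- nrow(vals)
  n_tail <- floor(n * tail_fraction)
  if (n_tail < 100L) {
    abort("trajectory too short: the tail window must hold at least 100 steps.")
  }
  tail_vals <- vals[(n - n_tail + 1L):n, , drop = FALSE]
  means <- colMeans(tail_vals)
  ptp <- apply(tail_vals, 2L, function(v) diff(range(v)))
  scale <- conv_tol * (1 + abs(means))
  amp <- max(ptp)
  if (all(ptp < scale)) {
    return(structure(list(label = "converged", limit = means,
                          tail_amplitude = amp),
                     class = "regime_label"))
  }
  half <- floor(n_tail / 2)
  w1 <- tail_vals[seq_len(half), , drop = FALSE]
  w2 <- tail_vals[(n_tail - half + 1L):n_tail, , drop = FALSE]
  ptp1 <- apply(w1, 2L, function(v) diff(range(v)))
  ptp2 <- apply(w2, 2L, function(v) diff(range(v)))
  k <- which.max(ptp)
  stabilized <- abs(ptp1[k] - ptp2[k]) <= 0.2 * max(ptp1[k], ptp2[k]) &&
    min(ptp1[k], ptp2[k]) > scale[k]
  label <- if (stabilized) "periodic" else "undecided"
  structure(list(label = label, limit = NA_real_, tail_amplitude = amp),
            class = "regime_label")
}

#' @export
print.regime_label <- function(x, ...) {
  cat(sprintf("<regime_label> %s (tail amplitude %.3g)\n",
              x$label, x$tail_amplitude))
  if (x$label == "converged") {
    cat("  limit:", paste(sprintf("%.6g", x$limit), collapse = ", "), "\n")
  }
  invisible(x)
}
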