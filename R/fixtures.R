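#' Sample random parameter triples for property testing
#'
#' Draws deterministic (given `seed`) parameter triples
#' \eqn{(\alpha_1, \rho, a)}: the order on the two-decimal grid
#' \eqn{\{0.05, 0.06, \dots, 0.99\}} (so every draw is representable under
#' the denominator-100 convention), and \eqn{\rho}, \eqn{a} log-uniform on
#' \eqn{[0.1, 100]}. The caller's RNG state is left untouched.
#'
#' @param seed Integer seed.
#' @param n Number of triples, \eqn{\ge 1}.
#' @return Tibble with columns `alpha1`, `rho`, `a`.
#' @examples
#' sample_fixtures(1, 3)
#' @export
sample_fixtures <- function(seed, n) {
  if (n < 1L) abort("`n` must be >= 1.")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  tibble::tibble(
    alpha1 = sample(seq(0.05, 0.99, by = 0.01), n, replace = TRUE),
    rho = 10^stats::runif(n, -1, 2),
    a = 10^stats::runif(n, -1, 2)
  )
}
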