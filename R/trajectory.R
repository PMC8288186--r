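#' Deterministic allele-frequency trajectory under selection
#'
#' Propagates the frequency of a (dominant) beneficial allele forward in
#' time. Two models are available:
#'
#' * `"linearized"`: the first-order approximation in which the frequency
#'   changes by `p * s` per generation. Within a generation the update is
#'   interpolated linearly per year, so the trajectory is piecewise linear
#'   with knots at generation boundaries.
#' * `"exact_dominant"`: the standard one-locus recurrence for a completely
#'   dominant allele with genotype fitnesses 1 + s (AA, Aa) and 1 (aa):
#'   `delta_p = p * s * q^2 / (1 + s - s * q^2)` per generation, again
#'   interpolated linearly per year inside generations.
#'
#' The output is clipped to `[1e-6, 1 - 1e-6]` so downstream ratios stay
#' finite even under long strong selection.
#'
#' @param p0 Starting frequency, strictly inside (0, 1).
#' @param s Selection coefficient per generation (may be 0 or negative).
#' @param years Number of years to propagate (non-negative).
#' @param model `"linearized"` or `"exact_dominant"`.
#' @param generation_years Length of one generation in years (default 25).
#'
#' @return Numeric vector of length `years + 1`: frequency at year offsets
#'   `0, 1, ..., years`.
#' @examples
#' simulate_allele_trajectory(0.4, 0.02, 25)[26]  # 0.408
#' @export
simulate_allele_trajectory <- function(p0, s, years,
                                       model = c("linearized", "exact_dominant"),
                                       generation_years = 25) {
  model <- match.arg(model)
  if (!is.numeric(p0) || length(p0) != 1L || is.na(p0) || p0 <= 0 || p0 >= 1) {
    stop("`p0` must be a single frequency strictly inside (0, 1)", call. = FALSE)
  }
  stopifnot(is.numeric(s), length(s) == 1L, is.finite(s),
            is.numeric(years), length(years) == 1L, years >= 0,
            generation_years > 0)
  years <- as.integer(years)

  eps <- 1e-6
  n_gen <- ceiling(years / generation_years)
  # frequency at each generation boundary 0..n_gen, clipped as it goes
  pg <- numeric(n_gen + 1L)
  pg[1L] <- p0
  if (n_gen > 0) {
    for (k in seq_len(n_gen)) {
      p <- pg[k]
      q <- 1 - p
      dp <- switch(model,
        linearized = p * s,
        exact_dominant = p * s * q^2 / (1 + s - s * q^2)
      )
      pg[k + 1L] <- min(max(p + dp, eps), 1 - eps)
    }
  }

  yr <- 0:years
  gen <- pmin(floor(yr / generation_years), n_gen - 1L)
  if (n_gen == 0L) return(rep(p0, years + 1L))
  frac <- (yr - gen * generation_years) / generation_years
  out <- pg[gen + 1L] + frac * (pg[gen + 2L] - pg[gen + 1L])
  pmin(pmax(out, eps), 1 - eps)
}
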