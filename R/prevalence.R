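#' Standardized genotype weight
#'
#' `w = (x - 2p) / sqrt(2p(1-p))`: mean 0 and variance 1 under
#' Hardy-Weinberg at frequency `p`.
#'
#' @param x Dosage (0/1/2; vectorized).
#' @param p Reference allele frequency, strictly inside (0, 1).
#' @return Standardized genotype.
#' @export
standardized_weight <- function(x, p) {
  if (any(p <= 0 | p >= 1)) {
    stop("`p` must be strictly inside (0, 1)", call. = FALSE)
  }
  (x - 2 * p) / sqrt(2 * p * (1 - p))
}

#' Residual (environmental) liability variance
#'
#' `var_genetic * (1/h2 - 1)`, so the total liability variance is
#' `var_genetic / h2`.
#'
#' @param var_genetic Empirical variance of the genetic score (>= 0).
#' @param h2 Heritability in (0, 1].
#' @return Residual variance.
#' @export
residual_variance <- function(var_genetic, h2) {
  stopifnot(var_genetic >= 0)
  if (!(h2 > 0 && h2 <= 1)) {
    stop("`h2` must be in (0, 1]", call. = FALSE)
  }
  var_genetic * (1 / h2 - 1)
}

#' Calibrate the liability threshold to a target prevalence
#'
#' Chooses `y0` as the empirical `(1 - target)`-quantile (inverse-ECDF
#' type) of the reference cohort's liability scores, so the proportion of
#' scores strictly above `y0` equals the target within `1/n`. The same
#' threshold is reused for every cohort.
#'
#' @param scores Liability scores of the reference cohort (non-empty).
#' @param target_prevalence Target in (0, 1); a target of 0 is allowed
#'   and puts the threshold at the maximum (prevalence 0).
#' @return Threshold `y0`.
#' @export
calibrate_threshold <- function(scores, target_prevalence) {
  stopifnot(length(scores) >= 1)
  if (target_prevalence < 0 || target_prevalence >= 1) {
    stop("`target_prevalence` must be in [0, 1)", call. = FALSE)
  }
  stats::quantile(scores, 1 - target_prevalence, names = FALSE, type = 1)
}

#' Liability-threshold model specification
#'
#' @param u Per-SNP allelic effects on the standardized genotype scale
#'   (positive = more liability). [liability_effects_from_assoc()]
#'   converts per-allele refractive-error betas to this scale.
#' @param p Per-SNP reference allele frequencies in (0, 1) (one value per
#'   SNP for all cohorts, so cohort differences enter only through
#'   genotypes).
#' @param h2 Liability heritability in (0, 1], default 0.35.
#' @param target_prevalence Reference-cohort prevalence used to calibrate
#'   the threshold, default 0.303.
#' @param n_replicates Residual redraws averaged over, default 100.
#' @param seed Optional integer seed for the residual draws.
#' @return Object of class `liability_model`.
#' @export
liability_model <- function(u, p, h2 = 0.35, target_prevalence = 0.303,
                            n_replicates = 100L, seed = NULL) {
  stopifnot(length(u) == length(p), n_replicates >= 1)
  if (any(p <= 0 | p >= 1)) stop("`p` must be inside (0, 1)", call. = FALSE)
  if (!(h2 > 0 && h2 <= 1)) stop("`h2` must be in (0, 1]", call. = FALSE)
  structure(list(u = u, p = p, h2 = h2,
                 target_prevalence = target_prevalence,
                 n_replicates = as.integer(n_replicates), seed = seed),
            class = "liability_model")
}

#' Convert per-allele effect sizes to standardized liability effects
#'
#' A per-risk-allele effect `beta` on spherical equivalent (negative =
#' more myopic) maps to a standardized liability effect
#' `u = -beta * sqrt(2p(1-p))`: the sqrt factor undoes the genotype
#' standardization and the sign flip orients liability so that larger
#' values mean more myopia risk.
#'
#' @param beta Per-risk-allele effects on spherical equivalent (diopters).
#' @param p Risk-allele frequencies.
#' @return Standardized liability effects `u`.
#' @export
liability_effects_from_assoc <- function(beta, p) {
  -beta * sqrt(2 * p * (1 - p))
}

#' Predict per-cohort prevalence from genotypes under the liability model
#'
#' Computes the standardized genetic score `sum_i w_ij u_i` per
#' individual (missing genotypes imputed to `2p`, i.e. `w = 0`), then for
#' each replicate draws fresh Gaussian residuals with variance
#' `var(score) * (1/h2 - 1)`, calibrates the threshold on the reference
#' cohort to the target prevalence (a null model with all `u = 0` falls
#' back to a unit-variance pure environmental liability so calibration
#' stays well defined), and records each cohort's proportion
#' above threshold. Reports the mean and standard error over replicates.
#'
#' @param model [liability_model()].
#' @param G Dosage matrix (individuals x SNPs, columns matching
#'   `model$u`).
#' @param cohort Cohort labels per individual; the first sorted level (or
#'   factor level) is the calibration reference.
#' @return Data frame: cohort, n, mean_prevalence, se; attribute
#'   `delta_points` holds the last-minus-first cohort difference in
#'   percentage points.
#' @export
predict_prevalence <- function(model, G, cohort) {
  stopifnot(inherits(model, "liability_model"), ncol(G) == length(model$u))
  f <- if (is.factor(cohort)) cohort else factor(cohort)
  n_by <- table(f)
  if (any(n_by == 0)) {
    warning("dropping empty cohort level(s): ",
            paste(names(n_by)[n_by == 0], collapse = ", "))
    f <- droplevels(f)
  }
  if (!is.null(model$seed)) set.seed(model$seed)
  W <- sweep(sweep(G, 2L, 2 * model$p, "-"), 2L,
             sqrt(2 * model$p * (1 - model$p)), "/")
  W[is.na(W)] <- 0  # missing dosage imputed to 2p
  g <- drop(W %*% model$u)
  var_g <- stats::var(g)
  # a null model (all u = 0) degenerates to a pure environmental
  # liability; use unit residual variance as the generator does
  res_sd <- if (var_g > 0) sqrt(residual_variance(var_g, model$h2)) else 1

  ref <- levels(f)[1L]
  n <- length(g)
  prev <- matrix(NA_real_, model$n_replicates, nlevels(f),
                 dimnames = list(NULL, levels(f)))
  for (r in seq_len(model$n_replicates)) {
    y <- g + stats::rnorm(n, 0, res_sd)
    y0 <- calibrate_threshold(y[f == ref], model$target_prevalence)
    prev[r, ] <- tapply(y > y0, f, mean)
  }
  out <- data.frame(
    cohort = levels(f), n = as.vector(table(f)),
    mean_prevalence = colMeans(prev),
    se = apply(prev, 2L, stats::sd) / sqrt(model$n_replicates),
    stringsAsFactors = FALSE, row.names = NULL
  )
  attr(out, "delta_points") <-
    100 * (out$mean_prevalence[nrow(out)] - out$mean_prevalence[1L])
  out
}

#' Excess disease cases implied by a prevalence increment
#'
#' @param delta_prevalence_points Prevalence change in percentage points.
#' @param population Population size (>= 0).
#' @return Number of cases, rounded to the nearest integer.
#' @examples
#' excess_cases(0.211, 55429643)  # 116957
#' @export
excess_cases <- function(delta_prevalence_points, population) {
  stopifnot(population >= 0)
  round(population * delta_prevalence_points / 100)
}

#' Genetic share of a prevalence increase
#'
#' @param genetic_delta Genetically driven prevalence change (points).
#' @param total_delta Total observed change (points, non-zero).
#' @return Percentage `100 * genetic_delta / total_delta`.
#' @examples
#' fraction_of_increase(0.211, 43.5 - 30.3)  # ~1.6
#' @export
fraction_of_increase <- function(genetic_delta, total_delta) {
  if (total_delta == 0) stop("total change is zero: share undefined", call. = FALSE)
  100 * genetic_delta / total_delta
}
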