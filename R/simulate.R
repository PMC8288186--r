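#' Simulate a biobank-style birth-cohort dataset
#'
#' Generates individuals in the configured birth cohorts with genotypes,
#' a heritable liability phenotype expressed as refractive error, and
#' reproductive/lifespan traits, all with planted ground truth taken from
#' the panel:
#'
#' * Birth years are uniform within each cohort span; each SNP's
#'   risk-allele frequency follows its deterministic selection trajectory
#'   evaluated at the individual's birth year, and genotypes are drawn
#'   `Binomial(2, p_birthyear)` (Hardy-Weinberg within birth year).
#' * Liability is the standardized genetic score `sum_i w_ij u_i` plus a
#'   Gaussian residual with variance `var(score) * (1/h2 - 1)`, so the
#'   genetic score explains a fraction `h2` of liability variance. When
#'   all `u_true` are zero the liability is a pure standard-normal
#'   environmental score.
#' * Age-40 spherical equivalent (SpE) is an affine map of liability with
#'   negative slope, shifted so that the first cohort's myopia prevalence
#'   (SpE < -0.5 D) equals `cohort1_prevalence`, plus the configured
#'   environmental trend in birth year.
#' * Observed SpE adds the cumulative hyperopic aging shift from age 40 to
#'   the exam age (exam years 2006-2010, ages clamped to the schedule
#'   range) and is split into per-eye sphere/cylinder readings whose
#'   spherical equivalent averages back exactly to the per-person value.
#' * Age at first birth (AFB), number of children ever born (NEB) and
#'   parental lifespans are baseline + genotype x planted effect +
#'   Gaussian noise; NEB is rounded and floored at 0, and AFB is defined
#'   only for individuals with NEB >= 1.
#' * Ten principal-component columns are standard Gaussian noise and sex
#'   is Bernoulli(0.5); genotypes are masked missing at `missing_rate`.
#'
#' @param panel [snp_panel()] with planted truth.
#' @param config [sim_config()].
#' @return Object of class `cohort_dataset`: list with `genotypes`
#'   (individuals x SNPs integer matrix of risk-allele dosages, `NA` =
#'   missing), `phenotypes` (data frame; see package README for columns),
#'   `panel`, `config`, and `truth` (per-individual liability and true
#'   age-40 SpE, for validation).
#' @export
simulate_individuals <- function(panel, config) {
  stopifnot(inherits(panel, "snp_panel"), inherits(config, "sim_config"))
  set.seed(config$seed)
  cs <- config$cohort_spec
  n_cohort <- nrow(cs)
  n <- config$n_per_cohort * n_cohort
  m <- nrow(panel)

  cohort_idx <- rep(seq_len(n_cohort), each = config$n_per_cohort)
  span <- cs$end_year - cs$start_year + 1L
  birth_year <- cs$start_year[cohort_idx] +
    floor(stats::runif(n) * span[cohort_idx])
  year0 <- cs$start_year[1L]
  horizon <- max(cs$end_year) - year0

  # genotypes: per-SNP frequency at each birth year, HW draws
  G <- matrix(NA_integer_, n, m, dimnames = list(NULL, panel$id))
  yr_off <- birth_year - year0
  for (i in seq_len(m)) {
    traj <- simulate_allele_trajectory(
      panel$baseline_freq[i], panel$s_true[i], horizon,
      model = config$trajectory_model,
      generation_years = config$generation_years
    )
    G[, i] <- stats::rbinom(n, 2L, traj[yr_off + 1L])
  }

  # liability and refractive error
  p <- panel$baseline_freq
  W <- sweep(sweep(G, 2L, 2 * p, "-"), 2L, sqrt(2 * p * (1 - p)), "/")
  gscore <- drop(W %*% panel$u_true)
  var_g <- stats::var(gscore)
  if (var_g > 0) {
    liability <- gscore + stats::rnorm(n, 0, sqrt(var_g * (1 / config$h2 - 1)))
  } else {
    liability <- stats::rnorm(n)  # pure environmental liability
  }
  spe_scale <- config$spe_sd / stats::sd(liability)
  spe_pre <- -spe_scale * liability +
    config$env_trend_per_year * (birth_year - year0)
  in_c1 <- cohort_idx == 1L
  shift <- -0.5 - stats::quantile(spe_pre[in_c1], config$cohort1_prevalence,
                                  names = FALSE, type = 7)
  spe40 <- spe_pre + shift

  exam_year <- sample(2006:2010, n, replace = TRUE)
  exam_age <- pmin(max(config$aging_schedule$age_end),
                   pmax(40L, exam_year - birth_year))
  spe_obs <- spe40 + aging_shift(exam_age, config$aging_schedule)

  eye_dev <- stats::rnorm(n, 0, config$eye_sd)
  cyl_R <- -abs(stats::rnorm(n, 0.3, 0.2))
  cyl_L <- -abs(stats::rnorm(n, 0.3, 0.2))
  sphere_R <- (spe_obs + eye_dev) - cyl_R / 2
  sphere_L <- (spe_obs - eye_dev) - cyl_L / 2

  neb_raw <- config$neb_mean + drop(G %*% panel$beta_neb) +
    stats::rnorm(n, 0, config$neb_sd)
  neb <- pmax(0, round(neb_raw))
  afb <- config$afb_mean + drop(G %*% panel$beta_afb) +
    stats::rnorm(n, 0, config$afb_sd)
  afb <- pmax(12, afb)
  afb[neb < 1] <- NA_real_

  mother_lifespan <- config$mother_lifespan_mean +
    drop(G %*% panel$beta_lifespan) + stats::rnorm(n, 0, config$lifespan_sd)
  father_lifespan <- config$father_lifespan_mean +
    drop(G %*% panel$beta_lifespan) + stats::rnorm(n, 0, config$lifespan_sd)

  pcs <- matrix(stats::rnorm(n * 10L), n, 10L,
                dimnames = list(NULL, paste0("pc", 1:10)))

  if (config$missing_rate > 0 && m > 0) {
    G[stats::runif(n * m) < config$missing_rate] <- NA_integer_
  }

  iid <- sprintf("id%06d", seq_len(n))
  rownames(G) <- iid
  phenotypes <- data.frame(
    iid = iid, birth_year = birth_year,
    sex = stats::rbinom(n, 1L, 0.5), exam_age = exam_age,
    sphere_R = sphere_R, cyl_R = cyl_R, sphere_L = sphere_L, cyl_L = cyl_L,
    afb = afb, neb = neb,
    mother_lifespan = mother_lifespan, father_lifespan = father_lifespan,
    stringsAsFactors = FALSE
  )
  phenotypes <- cbind(phenotypes, as.data.frame(pcs))

  structure(list(
    genotypes = G, phenotypes = phenotypes, panel = panel, config = config,
    truth = data.frame(iid = iid, liability = liability, spe40 = spe40,
                       cohort = cohort_idx, stringsAsFactors = FALSE)
  ), class = "cohort_dataset")
}

#' @export
print.cohort_dataset <- function(x, ...) {
  cat(sprintf("<cohort_dataset> %d individuals x %d SNPs, %d cohorts\n",
              nrow(x$genotypes), ncol(x$genotypes), nrow(x$config$cohort_spec)))
  invisible(x)
}

#' Generate a genome-wide control-SNP pool for matched resampling
#'
#' Builds a pool of neutral SNPs (`s_true = 0`, no planted effects) whose
#' allele frequencies and recombination rates jitter around values drawn
#' from the focal panel, so that every panel SNP has admissible matches
#' within the matching tolerances used by [sample_matched_controls()].
#'
#' @param panel Focal [snp_panel()] whose frequency/recombination ranges
#'   the pool must span.
#' @param pool_size Number of control SNPs (>= 10x the panel size is
#'   recommended so matching without replacement is comfortable).
#' @param freq_jitter Half-width of the uniform frequency jitter around
#'   the sampled panel frequency; keep below the matching tolerance.
#' @param rr_jitter Half-width of the recombination-rate jitter (cM/Mb).
#' @param seed Optional integer seed.
#' @return A neutral [snp_panel()] with ids prefixed `ctrl`.
#' @export
simulate_control_pool <- function(panel, pool_size,
                                  freq_jitter = 0.008, rr_jitter = 0.04,
                                  seed = NULL) {
  stopifnot(inherits(panel, "snp_panel"), pool_size >= 1)
  if (!is.null(seed)) set.seed(seed)
  src <- sample.int(nrow(panel), pool_size, replace = TRUE)
  freq <- panel$baseline_freq[src] +
    stats::runif(pool_size, -freq_jitter, freq_jitter)
  freq <- pmin(pmax(freq, 1e-3), 1 - 1e-3)
  rr <- pmax(0, panel$recomb_rate[src] +
               stats::runif(pool_size, -rr_jitter, rr_jitter))
  snp_panel(
    id = sprintf("ctrl%06d", seq_len(pool_size)),
    baseline_freq = freq,
    chrom = "20", pos = seq_len(pool_size) * 1000L + 10L,
    recomb_rate = rr
  )
}
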