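#' Default 5-year birth-cohort specification, 1940-1969
#'
#' @return Data frame with `start_year` and `end_year` for six 5-year
#'   cohorts: 1940-1944, ..., 1965-1969.
#' @export
default_cohort_spec <- function() {
  starts <- seq(1940L, 1965L, by = 5L)
  data.frame(start_year = starts, end_year = starts + 4L)
}

#' Default age-correction schedule for the hyperopic shift of aging
#'
#' Adult refractive error drifts in the hyperopic (positive) direction
#' with age; longitudinal eye studies of European-ancestry populations
#' report the shift as a change in spherical equivalent per 5-year age
#' band. The published band values are not reproduced here, so the
#' schedule is an explicit input everywhere in the package; this default
#' is a plausible synthetic stand-in covering ages 40-70, with the shift
#' accelerating in late middle age.
#'
#' @return Data frame with columns `age_start`, `age_end`,
#'   `delta_spe_per_5y` (diopters per 5 years, positive = hyperopic).
#' @export
default_aging_schedule <- function() {
  data.frame(
    age_start = c(40, 45, 50, 55, 60, 65),
    age_end   = c(45, 50, 55, 60, 65, 70),
    delta_spe_per_5y = c(0.05, 0.10, 0.15, 0.20, 0.25, 0.25)
  )
}

#' Simulation configuration for synthetic birth-cohort data
#'
#' Bundles the scalar knobs of the cohort generator. Per-SNP truth
#' (baseline frequency, selection coefficient, liability and
#' reproductive/lifespan effects) lives in the [snp_panel()].
#'
#' @param n_per_cohort Individuals per birth cohort.
#' @param cohort_spec Data frame of `start_year`/`end_year`, ordered and
#'   non-overlapping; default [default_cohort_spec()].
#' @param h2 Liability heritability in (0, 1]; default 0.35.
#' @param cohort1_prevalence Target disease prevalence (at age 40) in the
#'   first cohort, used to calibrate the liability-to-diopter map;
#'   default 0.303.
#' @param spe_sd Marginal standard deviation of spherical equivalent at
#'   age 40, in diopters; default 2.5.
#' @param env_trend_per_year Environmental drift of age-40 spherical
#'   equivalent in diopters per birth year (negative = later cohorts more
#'   myopic for non-genetic reasons); default 0.
#' @param aging_schedule Age-correction schedule table; default
#'   [default_aging_schedule()].
#' @param generation_years Generation time in years; default 25.
#' @param trajectory_model Allele-trajectory model passed to
#'   [simulate_allele_trajectory()].
#' @param missing_rate Fraction of genotypes masked as missing, in `[0, 1)`.
#' @param afb_mean,afb_sd Baseline mean/SD of age at first live birth (years).
#' @param neb_mean,neb_sd Baseline mean/SD of number of children ever born.
#' @param mother_lifespan_mean,father_lifespan_mean,lifespan_sd Parental
#'   lifespan baselines (years).
#' @param eye_sd SD of the per-eye deviation around the per-person
#'   spherical equivalent (diopters).
#' @param seed Integer seed; a fixed seed makes the generated dataset
#'   byte-identical across runs.
#'
#' @return Object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_per_cohort = 2000L,
                       cohort_spec = default_cohort_spec(),
                       h2 = 0.35,
                       cohort1_prevalence = 0.303,
                       spe_sd = 2.5,
                       env_trend_per_year = 0,
                       aging_schedule = default_aging_schedule(),
                       generation_years = 25,
                       trajectory_model = c("linearized", "exact_dominant"),
                       missing_rate = 0,
                       afb_mean = 25, afb_sd = 4,
                       neb_mean = 2.0, neb_sd = 1.3,
                       mother_lifespan_mean = 78,
                       father_lifespan_mean = 74,
                       lifespan_sd = 10,
                       eye_sd = 0.15,
                       seed = 1L) {
  trajectory_model <- match.arg(trajectory_model)
  stopifnot(n_per_cohort >= 1, is.data.frame(cohort_spec),
            all(c("start_year", "end_year") %in% names(cohort_spec)))
  if (!(h2 > 0 && h2 <= 1)) {
    stop("`h2` must be in (0, 1]; a heritability of 0 leaves the residual variance undefined",
         call. = FALSE)
  }
  stopifnot(cohort1_prevalence > 0, cohort1_prevalence < 1,
            spe_sd > 0, missing_rate >= 0, missing_rate < 1,
            generation_years > 0)
  cs <- cohort_spec[order(cohort_spec$start_year), , drop = FALSE]
  if (any(cs$end_year < cs$start_year)) {
    stop("cohort spans must have end_year >= start_year", call. = FALSE)
  }
  if (nrow(cs) > 1 && any(cs$start_year[-1] <= cs$end_year[-nrow(cs)])) {
    stop("cohort spans must be non-overlapping and ordered", call. = FALSE)
  }
  structure(list(
    n_per_cohort = as.integer(n_per_cohort), cohort_spec = cs,
    h2 = h2, cohort1_prevalence = cohort1_prevalence, spe_sd = spe_sd,
    env_trend_per_year = env_trend_per_year, aging_schedule = aging_schedule,
    generation_years = generation_years, trajectory_model = trajectory_model,
    missing_rate = missing_rate,
    afb_mean = afb_mean, afb_sd = afb_sd, neb_mean = neb_mean, neb_sd = neb_sd,
    mother_lifespan_mean = mother_lifespan_mean,
    father_lifespan_mean = father_lifespan_mean, lifespan_sd = lifespan_sd,
    eye_sd = eye_sd, seed = as.integer(seed)
  ), class = "sim_config")
}

#' SNP panel with planted ground truth
#'
#' The panel records everything the generator needs per SNP and everything
#' the evaluation needs to score recovery: baseline risk-allele frequency,
#' local recombination rate (used by matched-control sampling), the planted
#' per-generation selection coefficient `s_true`, the liability effect
#' `u_true` per standardized risk allele (positive = more disease
#' liability = more negative spherical equivalent), and planted effects on
#' age at first birth, number of children ever born, and parental lifespan
#' (per risk allele, in trait units).
#'
#' @param id Unique SNP identifiers.
#' @param baseline_freq Risk-allele frequency in (0, 1) at the first birth
#'   year of the simulation.
#' @param chrom,pos Chromosome label and 1-based position.
#' @param risk_allele,other_allele Allele codes (must differ per SNP).
#' @param recomb_rate Local recombination rate, cM/Mb.
#' @param s_true,u_true,beta_afb,beta_neb,beta_lifespan Planted truth;
#'   recycled scalars allowed.
#' @return Data frame of class `snp_panel`.
#' @export
snp_panel <- function(id, baseline_freq,
                      chrom = "1", pos = seq_along(id) * 1000L,
                      risk_allele = "A", other_allele = "G",
                      recomb_rate = 1,
                      s_true = 0, u_true = 0,
                      beta_afb = 0, beta_neb = 0, beta_lifespan = 0) {
  n <- length(id)
  if (anyDuplicated(id)) stop("SNP ids must be unique", call. = FALSE)
  panel <- data.frame(
    id = as.character(id), chrom = as.character(rep_len(chrom, n)),
    pos = as.integer(rep_len(pos, n)),
    risk_allele = as.character(rep_len(risk_allele, n)),
    other_allele = as.character(rep_len(other_allele, n)),
    baseline_freq = rep_len(baseline_freq, n),
    recomb_rate = rep_len(recomb_rate, n),
    s_true = rep_len(s_true, n), u_true = rep_len(u_true, n),
    beta_afb = rep_len(beta_afb, n), beta_neb = rep_len(beta_neb, n),
    beta_lifespan = rep_len(beta_lifespan, n),
    stringsAsFactors = FALSE
  )
  if (any(panel$pos <= 0)) stop("positions must be positive", call. = FALSE)
  if (any(panel$risk_allele == panel$other_allele)) {
    stop("risk_allele must differ from other_allele", call. = FALSE)
  }
  if (any(panel$baseline_freq <= 0 | panel$baseline_freq >= 1)) {
    stop("baseline frequencies must be strictly inside (0, 1)", call. = FALSE)
  }
  class(panel) <- c("snp_panel", "data.frame")
  panel
}
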