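#' Spherical equivalent from per-eye sphere and cylinder
#'
#' SpE per eye is sphere power plus half the cylinder power; the
#' per-person value is the mean over the two eyes. A minus-cylinder
#' convention is assumed; set `plus_cylinder = TRUE` to negate
#' plus-cylinder input before combining.
#'
#' @param sphere_R,cyl_R,sphere_L,cyl_L Per-eye readings in diopters
#'   (vectorized). Any missing component yields `NA` for that person, to
#'   be excluded downstream.
#' @param plus_cylinder Logical; input uses the plus-cylinder convention.
#' @return Numeric vector of spherical equivalents (diopters).
#' @examples
#' spherical_equivalent(-2, -1, -2, -1)  # -2.5
#' @export
spherical_equivalent <- function(sphere_R, cyl_R, sphere_L, cyl_L,
                                 plus_cylinder = FALSE) {
  if (plus_cylinder) {
    cyl_R <- -cyl_R
    cyl_L <- -cyl_L
  }
  ((sphere_R + cyl_R / 2) + (sphere_L + cyl_L / 2)) / 2
}

#' Cumulative hyperopic aging shift between age 40 and an exam age
#'
#' Accumulates the scheduled change in spherical equivalent across the
#' 5-year age bands spanned by `[40, exam_age]`, prorating linearly inside
#' partially covered bands.
#'
#' @param exam_age Ages in years (vectorized).
#' @param schedule Data frame with `age_start`, `age_end`,
#'   `delta_spe_per_5y` covering the required age range contiguously.
#' @return Shift in diopters (0 at exam_age = 40).
#' @export
aging_shift <- function(exam_age, schedule) {
  stopifnot(all(c("age_start", "age_end", "delta_spe_per_5y") %in% names(schedule)))
  sch <- schedule[order(schedule$age_start), , drop = FALSE]
  out <- numeric(length(exam_age))
  for (b in seq_len(nrow(sch))) {
    lo <- pmax(40, sch$age_start[b])
    years_in <- pmax(0, pmin(exam_age, sch$age_end[b]) - lo)
    out <- out + years_in * sch$delta_spe_per_5y[b] / 5
  }
  out
}

#' Correct observed spherical equivalent to age 40
#'
#' Subtracts the accumulated hyperopic aging shift between age 40 and the
#' exam age, inverting the scheduled drift exactly.
#'
#' @param spe Observed spherical equivalent (diopters, vectorized).
#' @param exam_age Age at examination; must lie in `[40, max schedule age]`.
#' @param schedule Aging schedule table (see [aging_shift()]).
#' @return Predicted spherical equivalent at age 40.
#' @export
correct_to_age40 <- function(spe, exam_age, schedule) {
  max_age <- max(schedule$age_end)
  bad <- !is.na(exam_age) & (exam_age < 40 | exam_age > max_age)
  if (any(bad)) {
    stop(sprintf("exam ages outside the correctable range [40, %d]: e.g. %s",
                 max_age, exam_age[bad][1L]), call. = FALSE)
  }
  spe - aging_shift(exam_age, schedule)
}

#' Call myopia from age-40 spherical equivalent
#'
#' @param spe40 Spherical equivalent at age 40 (diopters).
#' @param cutoff Threshold; myopia is `spe40 < cutoff` (strict), default
#'   -0.5 D.
#' @return Logical vector (`NA` where `spe40` is missing).
#' @export
call_myopia <- function(spe40, cutoff = -0.5) {
  spe40 < cutoff
}

#' Assign individuals to birth cohorts with small-year exclusion
#'
#' Individuals outside every cohort span, or born in a year with fewer
#' than `min_n` individuals, are excluded (label `NA`). Exclusion counts
#' are attached as the `"exclusions"` attribute.
#'
#' @param birth_years Integer vector.
#' @param cohort_spec Data frame of ordered, non-overlapping
#'   `start_year`/`end_year` spans.
#' @param min_n Minimum per-birth-year sample size (default 100).
#' @return Character vector of cohort labels (`"start-end"`), `NA` for
#'   excluded individuals; attribute `exclusions` holds a named count per
#'   reason (`outside_span`, `small_year`).
#' @export
assign_cohorts <- function(birth_years, cohort_spec, min_n = 100L) {
  cs <- cohort_spec[order(cohort_spec$start_year), , drop = FALSE]
  labels <- sprintf("%d-%d", cs$start_year, cs$end_year)
  idx <- rep(NA_integer_, length(birth_years))
  for (k in seq_len(nrow(cs))) {
    idx[birth_years >= cs$start_year[k] & birth_years <= cs$end_year[k]] <- k
  }
  outside <- sum(is.na(idx) & !is.na(birth_years))
  tab <- table(birth_years[!is.na(idx)])
  small_years <- as.integer(names(tab)[tab < min_n])
  small <- !is.na(idx) & birth_years %in% small_years
  idx[small] <- NA_integer_
  out <- labels[idx]
  if (!any(!is.na(out))) {
    stop("no individuals remain after cohort assignment", call. = FALSE)
  }
  attr(out, "exclusions") <- c(outside_span = outside, small_year = sum(small))
  attr(out, "levels") <- labels
  out
}

#' Per-cohort prevalence with Wilson 95% confidence intervals
#'
#' @param myopic Logical vector of disease calls (`NA` allowed, dropped).
#' @param cohort Cohort labels parallel to `myopic`.
#' @param conf Confidence level, default 0.95.
#' @return Data frame: cohort, n, n_cases, prevalence, ci_lo, ci_hi.
#' @export
cohort_prevalence <- function(myopic, cohort, conf = 0.95) {
  keep <- !is.na(myopic) & !is.na(cohort)
  myopic <- myopic[keep]
  cohort <- cohort[keep]
  levs <- attr(cohort, "levels")
  if (is.null(levs)) levs <- sort(unique(cohort))
  f <- factor(cohort, levels = levs)
  n <- as.vector(table(f))
  if (any(n == 0)) stop("empty cohort in prevalence computation", call. = FALSE)
  k <- as.vector(tapply(myopic, f, sum))
  phat <- k / n
  z <- stats::qnorm(1 - (1 - conf) / 2)
  denom <- 1 + z^2 / n
  center <- (phat + z^2 / (2 * n)) / denom
  half <- z * sqrt(phat * (1 - phat) / n + z^2 / (4 * n^2)) / denom
  data.frame(cohort = levs, n = n, n_cases = k, prevalence = phat,
             ci_lo = pmax(0, center - half), ci_hi = pmin(1, center + half),
             stringsAsFactors = FALSE)
}

#' Full phenotype preparation stage
#'
#' Computes spherical equivalent, corrects it to age 40, calls myopia,
#' assigns cohorts and applies exclusion filters, keeping an exclusion
#' account such that input n = retained n + sum of per-reason exclusions.
#'
#' @param phenotypes Phenotype table with the columns written by
#'   [write_dataset()] (per-eye sphere/cylinder, `exam_age`,
#'   `birth_year`; an optional logical `exclude` column marks records the
#'   caller removed for external reasons such as surgery or ancestry).
#' @param schedule Aging schedule table.
#' @param cohort_spec Cohort spans; default [default_cohort_spec()].
#' @param myopia_cutoff Diopter threshold for myopia, default -0.5.
#' @param min_cohort_n Minimum per-birth-year n, default 100.
#' @param plus_cylinder Cylinder sign convention switch.
#' @return List with `data` (retained rows plus `spe`, `spe40`, `myopia`,
#'   `cohort` columns), `prevalence` (per-cohort table) and `exclusions`
#'   (named counts).
#' @export
prepare_phenotypes <- function(phenotypes, schedule,
                               cohort_spec = default_cohort_spec(),
                               myopia_cutoff = -0.5, min_cohort_n = 100L,
                               plus_cylinder = FALSE) {
  ph <- phenotypes
  n_input <- nrow(ph)
  excl <- c(caller_flagged = 0L, missing_refraction = 0L,
            outside_span = 0L, small_year = 0L)

  if (!is.null(ph$exclude)) {
    excl["caller_flagged"] <- sum(ph$exclude, na.rm = TRUE)
    ph <- ph[!ph$exclude %in% TRUE, , drop = FALSE]
  }
  spe <- spherical_equivalent(ph$sphere_R, ph$cyl_R, ph$sphere_L, ph$cyl_L,
                              plus_cylinder = plus_cylinder)
  ok <- !is.na(spe) & !is.na(ph$exam_age)
  excl["missing_refraction"] <- sum(!ok)
  ph <- ph[ok, , drop = FALSE]
  spe <- spe[ok]

  ph$spe <- spe
  ph$spe40 <- correct_to_age40(spe, ph$exam_age, schedule)
  ph$myopia <- call_myopia(ph$spe40, cutoff = myopia_cutoff)
  cohort <- assign_cohorts(ph$birth_year, cohort_spec, min_n = min_cohort_n)
  excl["outside_span"] <- attr(cohort, "exclusions")[["outside_span"]]
  excl["small_year"] <- attr(cohort, "exclusions")[["small_year"]]
  keep <- !is.na(cohort)
  levs <- attr(cohort, "levels")
  ph$cohort <- unclass(cohort)
  ph <- ph[keep, , drop = FALSE]

  stopifnot(n_input == nrow(ph) + sum(excl))
  cohort_kept <- structure(ph$cohort, levels = levs)
  list(data = ph,
       prevalence = cohort_prevalence(ph$myopia, cohort_kept),
       exclusions = excl)
}
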