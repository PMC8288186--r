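#' Risk-allele frequency within a cohort
#'
#' @param dosage Risk-allele dosages (0/1/2, `NA` missing).
#' @param cohort Cohort labels parallel to `dosage` (factor or character);
#'   `NULL` computes a single overall frequency.
#' @return Named vector of frequencies `sum(dosage) / (2 * n_nonmissing)`;
#'   `NA` for cohorts with no called genotypes.
#' @export
cohort_allele_freq <- function(dosage, cohort = NULL) {
  if (is.null(cohort)) {
    nn <- sum(!is.na(dosage))
    return(if (nn == 0) NA_real_ else sum(dosage, na.rm = TRUE) / (2 * nn))
  }
  f <- factor(cohort)
  num <- tapply(dosage, f, sum, na.rm = TRUE)
  den <- 2 * tapply(!is.na(dosage), f, sum)
  out <- as.vector(num / ifelse(den == 0, NA, den))
  names(out) <- levels(f)
  out
}

#' Linear trend of allele frequency in birth year
#'
#' Regresses per-individual dosage/2 on birth year; the slope estimates
#' the risk-allele frequency change per year, with a two-tailed t-test of
#' zero slope. Uses the closed-form simple regression so genome-scale
#' scans stay fast. Constant dosage (or fewer than 2 distinct birth
#' years after removing missing genotypes) yields a flagged, undefined
#' test rather than a fabricated p-value.
#'
#' @param dosage Risk-allele dosages (0/1/2, `NA` missing).
#' @param birth_year Birth years parallel to `dosage`.
#' @return One-row data frame: slope_per_year, se, p, n_used, intercept,
#'   degenerate.
#' @export
trend_test <- function(dosage, birth_year) {
  cc <- !is.na(dosage) & !is.na(birth_year)
  x <- birth_year[cc]
  y <- dosage[cc] / 2
  n <- length(x)
  if (n < 3L || length(unique(x)) < 2L) {
    stop("trend test needs >= 3 individuals with >= 2 distinct birth years",
         call. = FALSE)
  }
  if (length(unique(y)) < 2L) {
    return(data.frame(slope_per_year = 0, se = NA_real_, p = NA_real_,
                      n_used = n, intercept = y[1L], degenerate = TRUE))
  }
  xbar <- mean(x); ybar <- mean(y)
  sxx <- sum((x - xbar)^2)
  sxy <- sum((x - xbar) * (y - ybar))
  syy <- sum((y - ybar)^2)
  b <- sxy / sxx
  rss <- syy - b * sxy
  s2 <- rss / (n - 2L)
  se <- sqrt(s2 / sxx)
  p <- 2 * stats::pt(-abs(b / se), n - 2L)
  data.frame(slope_per_year = b, se = se, p = p, n_used = n,
             intercept = ybar - b * xbar, degenerate = FALSE)
}

#' Selection coefficient from a per-year frequency slope
#'
#' Under a completely dominant beneficial allele the frequency changes by
#' approximately `p * s` per generation, so
#' `s = slope_per_year * generation_years / p0`.
#'
#' @param slope_per_year Frequency change per year.
#' @param p0 Baseline frequency, strictly inside (0, 1).
#' @param generation_years Generation time, default 25.
#' @return Selection coefficient per generation (same sign as the slope).
#' @export
selection_coefficient <- function(slope_per_year, p0, generation_years = 25) {
  if (any(p0 <= 0 | p0 >= 1)) {
    stop("`p0` must be strictly inside (0, 1)", call. = FALSE)
  }
  slope_per_year * generation_years / p0
}

#' Two-tailed exact binomial sign test
#'
#' Tests whether the split of rising vs declining alleles departs from
#' the symmetric null (proportion 0.5): `p = min(1, 2 * smaller tail)`,
#' which at a symmetric null coincides with the equally-extreme-outcomes
#' rule.
#'
#' @param n_up,n_down Counts (sum must be >= 1).
#' @return Two-tailed p-value.
#' @examples
#' binomial_sign_test(26, 6)  # 0.00054
#' @export
binomial_sign_test <- function(n_up, n_down) {
  n <- n_up + n_down
  stopifnot(n >= 1, n_up >= 0, n_down >= 0)
  min(1, 2 * stats::pbinom(min(n_up, n_down), n, 0.5))
}

#' Sample matched control-SNP sets
#'
#' For each control set, every panel SNP is matched by one pool SNP drawn
#' uniformly from those within `freq_tol` in allele frequency and
#' `rr_tol` in recombination rate, without replacement within a set
#' (replacement is allowed across sets). A panel SNP with no admissible
#' pool match raises an error naming the SNP.
#'
#' @param panel Focal [snp_panel()].
#' @param pool Control pool [snp_panel()] (disjoint from the panel).
#' @param n_sets Number of control sets (the negative-control analyses
#'   use 100).
#' @param freq_tol Frequency tolerance, default 0.01.
#' @param rr_tol Recombination-rate tolerance in cM/Mb, default 0.05.
#' @param seed Optional integer seed.
#' @return List of character vectors of pool SNP ids, one per set, each
#'   parallel to `panel$id`.
#' @export
sample_matched_controls <- function(panel, pool, n_sets, freq_tol = 0.01,
                                    rr_tol = 0.05, seed = NULL) {
  stopifnot(inherits(panel, "snp_panel"), inherits(pool, "snp_panel"),
            n_sets >= 1)
  if (any(panel$id %in% pool$id)) {
    stop("control pool must be disjoint from the panel", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  admissible <- lapply(seq_len(nrow(panel)), function(i) {
    which(abs(pool$baseline_freq - panel$baseline_freq[i]) <= freq_tol &
          abs(pool$recomb_rate - panel$recomb_rate[i]) <= rr_tol)
  })
  none <- lengths(admissible) == 0L
  if (any(none)) {
    stop("no admissible control match for panel SNP(s): ",
         paste(utils::head(panel$id[none], 5), collapse = ", "), call. = FALSE)
  }
  lapply(seq_len(n_sets), function(set) {
    used <- logical(nrow(pool))
    picks <- integer(nrow(panel))
    for (i in sample.int(nrow(panel))) {
      avail <- admissible[[i]][!used[admissible[[i]]]]
      if (length(avail) == 0L) {
        stop("control pool exhausted for panel SNP ", panel$id[i],
             " (set ", set, "); enlarge the pool", call. = FALSE)
      }
      pick <- if (length(avail) == 1L) avail else sample(avail, 1L)
      picks[i] <- pick
      used[pick] <- TRUE
    }
    pool$id[picks]
  })
}

#' Selection scan over a SNP panel
#'
#' Runs the birth-year trend test at every panel SNP, applies
#' Benjamini-Hochberg FDR within the panel, estimates the per-generation
#' selection coefficient under the dominant model, and summarizes the
#' rise/decline split among FDR-significant SNPs with the exact binomial
#' sign test. The baseline frequency `p0` entering `s = delta_p / p0` is
#' the fitted frequency at the first cohort's midpoint year (switch
#' `p0_method = "raw"` to use the raw first-cohort frequency instead).
#'
#' @param panel [snp_panel()] restricted to verified SNPs.
#' @param dataset `cohort_dataset` (or any list with `genotypes` and
#'   `phenotypes$birth_year`).
#' @param cohort_spec Cohort spans used for per-cohort frequencies and
#'   the first-cohort midpoint; default [default_cohort_spec()].
#' @param fdr_level FDR threshold for calling a trend significant.
#' @param generation_years Generation time, default 25.
#' @param p0_method `"fitted"` (default) or `"raw"`.
#' @return Object of class `selection_scan`: list with `estimates` (per
#'   SNP: per-cohort frequencies, slope_per_year, trend p and q, p0, s,
#'   direction among significant SNPs) and `summary` (n_tested, n_sig,
#'   n_up, n_down, sign_test_p).
#' @export
scan_panel <- function(panel, dataset, cohort_spec = default_cohort_spec(),
                       fdr_level = 0.05, generation_years = 25,
                       p0_method = c("fitted", "raw")) {
  p0_method <- match.arg(p0_method)
  G <- dataset$genotypes[, panel$id, drop = FALSE]
  by <- dataset$phenotypes$birth_year
  cohort <- assign_cohorts(by, cohort_spec, min_n = 0L)
  levs <- attr(cohort, "levels")
  if (nrow(panel) == 0L) {
    return(structure(list(
      estimates = data.frame(), summary = list(n_tested = 0L, n_sig = 0L,
                                               n_up = 0L, n_down = 0L,
                                               sign_test_p = NA_real_)
    ), class = "selection_scan"))
  }
  tt <- do.call(rbind, lapply(seq_len(ncol(G)), function(i) {
    trend_test(G[, i], by)
  }))
  freqs <- t(vapply(seq_len(ncol(G)), function(i) {
    cohort_allele_freq(G[, i], factor(cohort, levels = levs))
  }, numeric(length(levs))))
  colnames(freqs) <- paste0("freq_", seq_along(levs))

  mid1 <- mean(c(cohort_spec$start_year[1L], cohort_spec$end_year[1L]))
  p0 <- switch(p0_method,
    fitted = tt$intercept + tt$slope_per_year * mid1,
    raw = freqs[, 1L]
  )
  p0 <- pmin(pmax(p0, 1e-6), 1 - 1e-6)
  q <- rep(NA_real_, nrow(tt))
  ok <- !tt$degenerate
  q[ok] <- bh_fdr(tt$p[ok])
  sig <- !is.na(q) & q < fdr_level
  s <- selection_coefficient(tt$slope_per_year, p0, generation_years)
  direction <- ifelse(!sig, "0", ifelse(tt$slope_per_year > 0, "+", "-"))

  est <- data.frame(snp_id = panel$id, freqs,
                    slope_per_year = tt$slope_per_year, se = tt$se,
                    trend_p = tt$p, trend_q = q, p0 = p0, s = s,
                    direction = direction, degenerate = tt$degenerate,
                    stringsAsFactors = FALSE)
  n_up <- sum(direction == "+")
  n_down <- sum(direction == "-")
  summary <- list(
    n_tested = sum(ok), n_sig = n_up + n_down, n_up = n_up, n_down = n_down,
    sign_test_p = if (n_up + n_down >= 1) binomial_sign_test(n_up, n_down)
                  else NA_real_
  )
  structure(list(estimates = est, summary = summary), class = "selection_scan")
}

#' @export
print.selection_scan <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "<selection_scan> %d SNPs tested: %d significant trends (%d up / %d down), sign-test p = %s\n",
    s$n_tested, s$n_sig, s$n_up, s$n_down, format(s$sign_test_p, digits = 3)))
  invisible(x)
}

#' Trend scan of matched control sets
#'
#' Scores each matched control set by the number of SNPs with a
#' significant frequency trend and the direction split. Significance per
#' SNP is the raw trend p-value at `alpha` by default (each set is
#' scored marginally, as in a permutation null); `fdr = TRUE` applies
#' Benjamini-Hochberg within each set instead.
#'
#' @param control_sets List of SNP-id vectors from
#'   [sample_matched_controls()].
#' @param dataset `cohort_dataset` containing genotypes for the pool SNPs.
#' @param alpha Per-SNP significance level, default 0.05.
#' @param fdr Apply within-set FDR correction instead of the raw level.
#' @return Data frame: set, n_significant, n_sig_increase, n_sig_decrease.
#' @export
scan_control_sets <- function(control_sets, dataset, alpha = 0.05,
                              fdr = FALSE) {
  by <- dataset$phenotypes$birth_year
  all_ids <- unique(unlist(control_sets))
  tt <- lapply(all_ids, function(id) trend_test(dataset$genotypes[, id], by))
  names(tt) <- all_ids
  do.call(rbind, lapply(seq_along(control_sets), function(k) {
    ids <- control_sets[[k]]
    p <- vapply(tt[ids], `[[`, numeric(1), "p")
    slope <- vapply(tt[ids], `[[`, numeric(1), "slope_per_year")
    crit <- if (fdr) bh_fdr(p) else p
    sig <- !is.na(crit) & crit < alpha
    data.frame(set = k, n_significant = sum(sig),
               n_sig_increase = sum(sig & slope > 0),
               n_sig_decrease = sum(sig & slope < 0))
  }))
}
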