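#' Screen the panel for parental-lifespan associations
#'
#' Associates each SNP with the lifespan of the participants' mothers and
#' fathers separately (covariate-adjusted, FDR within each parent trait)
#' and flags SNPs significant for either parent. Flagged SNPs should be
#' removed from the selection panel before sign tests and prevalence
#' modeling, because a lifespan effect can mimic a birth-cohort frequency
#' trend through differential survival to assessment. If one parent's
#' lifespans are entirely missing the screen degrades to the other parent
#' with a warning; if both are missing it is skipped with a warning.
#'
#' @param panel [snp_panel()] of SNPs to screen.
#' @param dataset `cohort_dataset` with `mother_lifespan` and
#'   `father_lifespan` phenotype columns.
#' @param covariates Optional covariate matrix (defaults to exam age, sex
#'   and the 10 PC columns when present).
#' @param fdr_level FDR threshold, default 0.05.
#' @return List with `flagged` (SNP ids), `results` (both per-parent
#'   association tables) and `skipped` (logical).
#' @export
lifespan_screen <- function(panel, dataset, covariates = NULL,
                            fdr_level = 0.05) {
  ph <- dataset$phenotypes
  G <- dataset$genotypes[, panel$id, drop = FALSE]
  if (is.null(covariates)) covariates <- default_covariates(ph)
  traits <- list(mother_lifespan = ph$mother_lifespan,
                 father_lifespan = ph$father_lifespan)
  traits <- Filter(function(v) !is.null(v) && any(!is.na(v)), traits)
  if (length(traits) == 0L) {
    warning("no parental lifespans available; lifespan screen skipped")
    return(list(flagged = character(0), results = NULL, skipped = TRUE))
  }
  if (length(traits) == 1L) {
    warning("only ", names(traits), " available; screening a single parent")
  }
  results <- do.call(rbind, lapply(names(traits), function(tr) {
    assoc_scan(G, traits[[tr]], covariates, trait = tr)
  }))
  flagged <- unique(results$snp_id[!is.na(results$q) &
                                   results$q < fdr_level])
  list(flagged = flagged, results = results, skipped = FALSE)
}

default_covariates <- function(ph) {
  cols <- intersect(c("exam_age", "sex", paste0("pc", 1:10)), names(ph))
  if (length(cols) == 0L) return(NULL)
  as.matrix(ph[, cols, drop = FALSE])
}

#' Direction consistency of selection with reproductive effects
#'
#' A positively selected risk allele is "consistent" with selection via
#' reproduction if it lowers age at first birth (earlier reproduction)
#' or raises the number of children ever born; a negatively selected
#' allele is consistent if it raises AFB or lowers NEB. Consistency is
#' judged only on FDR-significant trait associations; a SNP is consistent
#' when all of its significant reproductive associations point the
#' consistent way. The overall departure from coin-flip consistency is
#' an exact binomial test at null 0.5.
#'
#' @param selection `selection_scan` estimates (or data frame with
#'   `snp_id`, `direction` in `{"+","-","0"}`).
#' @param afb_assoc,neb_assoc Association tables from [assoc_scan()] for
#'   AFB and NEB, oriented to the risk allele.
#' @param fdr_level Significance threshold on `q`, default 0.05.
#' @return List with `records` (per SNP with >= 1 significant trait:
#'   consistency per trait and overall verdict) and `binomial_p`.
#' @export
direction_consistency <- function(selection, afb_assoc, neb_assoc,
                                  fdr_level = 0.05) {
  est <- if (inherits(selection, "selection_scan")) selection$estimates
         else selection
  est <- est[est$direction %in% c("+", "-"), , drop = FALSE]
  consist <- function(dir, beta, good_sign) {
    # good_sign: sign of beta consistent with positive selection
    ifelse(dir == "+", sign(beta) == good_sign, sign(beta) == -good_sign)
  }
  rows <- lapply(seq_len(nrow(est)), function(i) {
    id <- est$snp_id[i]
    dir <- est$direction[i]
    a <- afb_assoc[afb_assoc$snp_id == id, , drop = FALSE]
    n <- neb_assoc[neb_assoc$snp_id == id, , drop = FALSE]
    afb_sig <- nrow(a) == 1 && !is.na(a$q) && a$q < fdr_level
    neb_sig <- nrow(n) == 1 && !is.na(n$q) && n$q < fdr_level
    if (!afb_sig && !neb_sig) return(NULL)
    afb_cons <- if (afb_sig) consist(dir, a$beta, -1) else NA
    neb_cons <- if (neb_sig) consist(dir, n$beta, +1) else NA
    data.frame(snp_id = id, direction = dir,
               afb_significant = afb_sig, afb_consistent = afb_cons,
               neb_significant = neb_sig, neb_consistent = neb_cons,
               consistent = all(c(afb_cons, neb_cons), na.rm = TRUE),
               stringsAsFactors = FALSE)
  })
  records <- do.call(rbind, rows)
  if (is.null(records) || nrow(records) == 0L) {
    return(list(records = records, binomial_p = NA_real_))
  }
  k_cons <- sum(records$consistent)
  list(records = records,
       binomial_p = binomial_sign_test(k_cons, nrow(records) - k_cons))
}

#' Correlation of selection coefficients with trait effect sizes
#'
#' Pearson correlation with the t-transform two-tailed p-value
#' `t = r * sqrt((n - 2) / (1 - r^2))` on n - 2 degrees of freedom.
#'
#' @param s Selection coefficients.
#' @param beta Paired effect sizes.
#' @return List: r, n, p.
#' @export
s_effect_correlation <- function(s, beta) {
  cc <- !is.na(s) & !is.na(beta)
  s <- s[cc]; beta <- beta[cc]
  n <- length(s)
  if (n < 3L) stop("need >= 3 paired values", call. = FALSE)
  if (stats::sd(s) == 0 || stats::sd(beta) == 0) {
    stop("zero variance: correlation undefined", call. = FALSE)
  }
  r <- stats::cor(s, beta)
  list(r = r, n = n, p = cor_p_from_r(r, n))
}

#' Two-tailed p-value for a Pearson correlation via the t-transform
#'
#' @param r Correlation coefficient.
#' @param n Number of pairs (>= 3).
#' @return Two-tailed p-value from `t = r * sqrt((n-2)/(1-r^2))` on
#'   `n - 2` degrees of freedom (1 exactly at r = 0).
#' @examples
#' cor_p_from_r(-0.67, 9)  # ~0.048
#' @export
cor_p_from_r <- function(r, n) {
  stopifnot(n >= 3, abs(r) <= 1)
  if (abs(r) == 1) return(0)
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  2 * stats::pt(-abs(tstat), n - 2)
}

#' Two-sample comparison of a trait between phenotype groups
#'
#' Welch two-sample t-test by default (pooled-variance with
#' `var_equal = TRUE`), reporting group means and standard errors.
#'
#' @param x,y Trait values in the two groups (e.g. myopic vs non-myopic);
#'   each needs >= 2 non-missing values.
#' @param var_equal Use the pooled-variance t-test.
#' @return List: p, t, mean_x, mean_y, se_x, se_y, diff (mean_x - mean_y).
#' @export
group_t_test <- function(x, y, var_equal = FALSE) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2L || length(y) < 2L) {
    stop("both groups need >= 2 values", call. = FALSE)
  }
  ht <- stats::t.test(x, y, var.equal = var_equal)
  list(p = ht$p.value, t = unname(ht$statistic),
       mean_x = mean(x), mean_y = mean(y),
       se_x = stats::sd(x) / sqrt(length(x)),
       se_y = stats::sd(y) / sqrt(length(y)),
       diff = mean(x) - mean(y))
}

#' Pearson chi-square contrast of two association proportions
#'
#' 2x2 Pearson chi-square (1 df, no continuity correction — the
#' uncorrected statistic is the one used for the matched-control
#' contrast) comparing `k1/n1` significant SNPs against `k2/n2`.
#'
#' @param k1,n1 Significant count and total in the first group.
#' @param k2,n2 Same for the second group.
#' @return List: statistic, p, proportions.
#' @examples
#' association_proportion_chisq(15, 30, 3, 30)  # X^2 = 11.4, p = 0.0007
#' @export
association_proportion_chisq <- function(k1, n1, k2, n2) {
  stopifnot(n1 >= 1, n2 >= 1, k1 <= n1, k2 <= n2, k1 >= 0, k2 >= 0)
  tab <- matrix(c(k1, n1 - k1, k2, n2 - k2), nrow = 2, byrow = TRUE)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected == 0)) {
    stop("zero expected cell count: chi-square undefined", call. = FALSE)
  }
  ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(ht$statistic), p = ht$p.value,
       proportions = c(k1 / n1, k2 / n2))
}
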