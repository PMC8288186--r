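#' Genotype quality control
#'
#' Flags SNPs in the fixed order minor-allele count, missingness,
#' imputation information score; each removed SNP carries exactly one
#' removal reason (the first failed check). Thresholds are strict
#' inequalities: removed when MAC < `mac_min`, missing rate > `miss_max`,
#' or info score < `info_min`.
#'
#' @param G Dosage matrix (individuals x SNPs, 0/1/2 with `NA` missing).
#' @param info Optional named vector of per-SNP imputation info scores;
#'   the info check is skipped when absent.
#' @param mac_min,miss_max,info_min Thresholds (defaults 5, 0.05, 0.3).
#' @return List with `report` (per-SNP data frame: id, n_nonmiss, mac,
#'   missing_rate, info, reason — `NA` reason = retained) and `keep`
#'   (character vector of retained SNP ids).
#' @export
qc_filter <- function(G, info = NULL, mac_min = 5, miss_max = 0.05,
                      info_min = 0.3) {
  n <- nrow(G)
  nonmiss <- colSums(!is.na(G))
  ac <- colSums(G, na.rm = TRUE)
  mac <- pmin(ac, 2 * nonmiss - ac)
  miss_rate <- 1 - nonmiss / n
  info_v <- if (is.null(info)) rep(NA_real_, ncol(G)) else info[colnames(G)]

  reason <- rep(NA_character_, ncol(G))
  reason[mac < mac_min] <- "mac_fail"
  reason[is.na(reason) & miss_rate > miss_max] <- "missing_fail"
  if (!is.null(info)) {
    reason[is.na(reason) & info_v < info_min] <- "info_fail"
  }
  report <- data.frame(
    id = colnames(G), n_nonmiss = nonmiss, mac = mac,
    missing_rate = miss_rate, info = info_v, reason = reason,
    stringsAsFactors = FALSE, row.names = NULL
  )
  list(report = report, keep = colnames(G)[is.na(reason)])
}

#' Covariate-adjusted single-SNP linear association
#'
#' Ordinary least squares of the phenotype on allele dosage plus an
#' intercept and covariates, with complete-case handling and a two-tailed
#' t-test on the dosage coefficient. Degenerate fits (dosage constant
#' after filtering, or collinear with the covariates) are flagged, not
#' fabricated: estimates come back `NA` with `degenerate = TRUE`.
#'
#' @param dosage Numeric vector of risk-allele dosages (0/1/2, `NA` ok).
#' @param phenotype Numeric response.
#' @param covariates Optional numeric matrix/data frame of covariates.
#' @return One-row data frame: beta, se, p, n_used, degenerate.
#' @export
linear_assoc <- function(dosage, phenotype, covariates = NULL) {
  x <- as.numeric(dosage)
  y <- as.numeric(phenotype)
  C <- if (is.null(covariates)) NULL else as.matrix(covariates)
  cc <- !is.na(x) & !is.na(y)
  if (!is.null(C)) cc <- cc & stats::complete.cases(C)
  x <- x[cc]; y <- y[cc]
  n <- length(x)
  k <- if (is.null(C)) 0L else ncol(C)
  degen <- data.frame(beta = NA_real_, se = NA_real_, p = NA_real_,
                      n_used = n, degenerate = TRUE)
  if (n < k + 3L || length(unique(x)) < 2L) return(degen)
  X <- cbind(`(Intercept)` = 1, dosage = x, if (!is.null(C)) C[cc, , drop = FALSE])
  fit <- stats::lm.fit(X, y)
  if (fit$rank < ncol(X) || is.na(fit$coefficients["dosage"])) return(degen)
  df <- n - fit$rank
  if (df < 1L) return(degen)
  sigma2 <- sum(fit$residuals^2) / df
  XtXinv <- chol2inv(fit$qr$qr[seq_len(fit$rank), seq_len(fit$rank), drop = FALSE])
  # column order after pivoting
  coef_idx <- match("dosage", colnames(X)[fit$qr$pivot[seq_len(fit$rank)]])
  if (is.na(coef_idx)) return(degen)
  se <- sqrt(sigma2 * XtXinv[coef_idx, coef_idx])
  beta <- fit$coefficients["dosage"]
  tstat <- beta / se
  data.frame(beta = unname(beta), se = se,
             p = 2 * stats::pt(-abs(tstat), df), n_used = n,
             degenerate = FALSE)
}

#' Association scan of one trait over a SNP panel
#'
#' Runs [linear_assoc()] for every SNP column and applies
#' Benjamini-Hochberg FDR within the scan (degenerate SNPs excluded from
#' the correction).
#'
#' @param G Dosage matrix (individuals x SNPs).
#' @param phenotype Numeric response vector.
#' @param covariates Optional covariate matrix/data frame.
#' @param trait Trait name recorded in the result.
#' @return Data frame: snp_id, trait, beta, se, p, q, n_used, degenerate.
#' @export
assoc_scan <- function(G, phenotype, covariates = NULL, trait = "trait") {
  res <- do.call(rbind, lapply(seq_len(ncol(G)), function(i) {
    linear_assoc(G[, i], phenotype, covariates)
  }))
  res <- cbind(snp_id = colnames(G), trait = trait, res,
               stringsAsFactors = FALSE)
  res$q <- NA_real_
  ok <- !res$degenerate
  res$q[ok] <- bh_fdr(res$p[ok])
  rownames(res) <- NULL
  res[, c("snp_id", "trait", "beta", "se", "p", "q", "n_used", "degenerate")]
}

#' Greedy LD pruning on sample-dosage correlation
#'
#' Pairwise linkage disequilibrium is the squared Pearson correlation of
#' dosages over complete pairs. SNPs are visited in order of association
#' strength (smallest p first; ties broken by smaller genomic
#' coordinate) and a SNP is kept only if its R-squared with every
#' already-kept SNP is at or below the threshold — so of any high-LD
#' pair the member with the weaker association is discarded, and of a
#' mutually correlated clique only the strongest member survives.
#' `method = "random"` visits SNPs in random order instead (robustness
#' variant).
#'
#' @param G Dosage matrix.
#' @param pvals Named or positional vector of association p-values, one
#'   per SNP column.
#' @param r2_threshold Pruning threshold, default 0.8 (prune when R^2 is
#'   strictly greater).
#' @param pos Optional genomic coordinates for tie-breaking.
#' @param method `"pvalue"` (default) or `"random"`.
#' @return List with `keep` (retained SNP ids) and `removed` (ids pruned).
#' @export
ld_prune <- function(G, pvals, r2_threshold = 0.8, pos = NULL,
                     method = c("pvalue", "random")) {
  method <- match.arg(method)
  m <- ncol(G)
  if (m == 0L) return(list(keep = character(0), removed = character(0)))
  if (is.null(pos)) pos <- seq_len(m)
  r2 <- suppressWarnings(stats::cor(G, use = "pairwise.complete.obs"))^2
  r2[is.na(r2)] <- 0
  ord <- if (method == "pvalue") order(pvals, pos) else sample.int(m)
  kept <- integer(0)
  for (i in ord) {
    if (length(kept) == 0L || all(r2[i, kept] <= r2_threshold)) {
      kept <- c(kept, i)
    }
  }
  kept <- sort(kept)
  list(keep = colnames(G)[kept], removed = colnames(G)[-kept])
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted q-values (monotone in sorted order, capped at 1),
#' via [stats::p.adjust()].
#'
#' @param pvals Numeric p-values in `[0, 1]`.
#' @return q-values of the same length.
#' @export
bh_fdr <- function(pvals) {
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(pvals, method = "BH")
}

#' Orient association results to the declared risk allele
#'
#' Re-signs effect estimates so the counted allele is the declared risk
#' allele, and flags SNPs whose risk allele associates with a *more
#' positive* refractive error (direction-discordant with the declared
#' risk direction, since risk should push spherical equivalent negative).
#'
#' @param assoc Data frame from [assoc_scan()] on the refractive-error
#'   trait, with a `beta` column per counted allele.
#' @param counted_allele,risk_allele Character vectors (parallel to
#'   `assoc` rows): the allele whose dosage was counted and the declared
#'   risk allele.
#' @return `assoc` with `beta` oriented to the risk allele and a logical
#'   `discordant` column (`TRUE` when the oriented beta is positive).
#' @export
orient_risk_allele <- function(assoc, counted_allele, risk_allele) {
  flip <- counted_allele != risk_allele
  assoc$beta <- ifelse(flip, -assoc$beta, assoc$beta)
  assoc$discordant <- !is.na(assoc$beta) & assoc$beta > 0
  assoc
}
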