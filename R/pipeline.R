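#' Pipeline run configuration
#'
#' Collects every threshold and constant used by [run_pipeline()], with
#' the defaults used throughout the package: FDR 0.05, LD R^2 0.8, MAC 5,
#' missingness 0.05, info 0.3, myopia cutoff -0.5 D, minimum cohort birth
#' year n 100, generation time 25 y, heritability 0.35, 100 control sets,
#' 100 liability replicates, and the 1969 UK population 55,429,643 for
#' the excess-case extrapolation.
#'
#' @param dataset_dir Directory holding a dataset written by
#'   [write_dataset()] (ignored when a `cohort_dataset` is passed to
#'   [run_pipeline()] directly).
#' @param output_dir Directory for stage TSVs and the JSON report;
#'   `NULL` = do not write files.
#' @param fdr,r2,mac,missing,info,myopia_cutoff,min_cohort_n Thresholds.
#' @param generation_years,h2,n_control_sets,n_replicates,population
#'   Constants.
#' @param target_prevalence Reference-cohort prevalence for liability
#'   calibration; `NULL` (default) uses the observed first-cohort
#'   prevalence.
#' @param cohort_spec Cohort spans, default [default_cohort_spec()].
#' @param seed Master seed; per-stage streams are derived from it so
#'   stages are individually reproducible.
#' @return List of class `run_config`.
#' @export
run_config <- function(dataset_dir = NULL, output_dir = NULL,
                       fdr = 0.05, r2 = 0.8, mac = 5, missing = 0.05,
                       info = 0.3, myopia_cutoff = -0.5, min_cohort_n = 100L,
                       generation_years = 25, h2 = 0.35,
                       n_control_sets = 100L, n_replicates = 100L,
                       population = 55429643,
                       target_prevalence = NULL,
                       cohort_spec = default_cohort_spec(),
                       seed = 1L) {
  stopifnot(fdr > 0, fdr < 1, r2 > 0, r2 <= 1, mac >= 0,
            missing >= 0, missing <= 1, info >= 0,
            n_control_sets >= 1, n_replicates >= 1, population >= 0)
  structure(as.list(environment()), class = "run_config")
}

stage_seed <- function(seed, stage) {
  # distinct reproducible stream per stage, kept within 32-bit range
  (as.integer(seed) * 97L + stage * 1009L) %% .Machine$integer.max
}

#' Run the full selection-attribution pipeline
#'
#' Executes the stages in order: phenotype preparation (spherical
#' equivalent, age-40 correction, myopia calls, cohort assignment) ->
#' association verification of the panel against refractive error (QC,
#' LD pruning, FDR, risk-direction orientation) -> birth-cohort selection
#' scan with matched-control sets -> parental-lifespan screen and
#' exclusion -> rise/decline sign tests -> reproductive pleiotropy tests
#' (AFB/NEB associations, direction consistency, s-vs-effect
#' correlations, myopic vs non-myopic group contrasts, control
#' chi-square) -> liability-threshold prevalence prediction -> excess
#' cases. Identical config + seed gives an identical report.
#'
#' @param config [run_config()].
#' @param dataset Optional in-memory `cohort_dataset`; when `NULL` the
#'   dataset is read from `config$dataset_dir`.
#' @param control_pool Optional control [snp_panel()]; control SNPs must
#'   have genotype columns in the dataset.
#' @return List of class `pipeline_report` with per-stage results, the
#'   SNP accounting (`snp_categories`: every input SNP in exactly one of
#'   qc_removed / ld_removed / not_verified / lifespan_excluded /
#'   scanned), and the resolved config echo. Written as `report.json`
#'   plus per-stage TSVs when `config$output_dir` is set.
#' @export
run_pipeline <- function(config, dataset = NULL, control_pool = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(dataset)) {
    if (is.null(config$dataset_dir)) {
      stop("no dataset or dataset_dir given", call. = FALSE)
    }
    dataset <- read_dataset(config$dataset_dir)
  }
  if (is.null(control_pool)) control_pool <- dataset$pool
  panel <- dataset$panel
  schedule <- if (!is.null(dataset$config$aging_schedule))
    dataset$config$aging_schedule else default_aging_schedule()

  ## stage 1: phenotype preparation ----------------------------------
  prep <- prepare_phenotypes(dataset$phenotypes, schedule,
                             cohort_spec = config$cohort_spec,
                             myopia_cutoff = config$myopia_cutoff,
                             min_cohort_n = config$min_cohort_n)
  ph <- prep$data
  keep_row <- match(ph$iid, dataset$phenotypes$iid)
  G_all <- dataset$genotypes[keep_row, , drop = FALSE]
  G <- G_all[, panel$id, drop = FALSE]
  covars <- default_covariates(ph)

  ## stage 2: association verification -------------------------------
  qc <- qc_filter(G, mac_min = config$mac, miss_max = config$missing,
                  info_min = config$info)
  Gq <- G[, qc$keep, drop = FALSE]
  spe_assoc <- assoc_scan(Gq, ph$spe, covars, trait = "spe")
  set.seed(stage_seed(config$seed, 2L))
  pruned <- ld_prune(Gq, spe_assoc$p,
                     r2_threshold = config$r2,
                     pos = panel$pos[match(qc$keep, panel$id)])
  spe_assoc <- spe_assoc[spe_assoc$snp_id %in% pruned$keep, , drop = FALSE]
  spe_assoc$q <- NA_real_
  ok <- !spe_assoc$degenerate
  spe_assoc$q[ok] <- bh_fdr(spe_assoc$p[ok])
  # dosages count the risk allele by construction; orientation flags
  # SNPs whose declared risk allele pushes refraction the wrong way
  spe_assoc <- orient_risk_allele(
    spe_assoc,
    counted_allele = panel$risk_allele[match(spe_assoc$snp_id, panel$id)],
    risk_allele = panel$risk_allele[match(spe_assoc$snp_id, panel$id)]
  )
  verified <- spe_assoc$snp_id[!is.na(spe_assoc$q) &
                               spe_assoc$q < config$fdr &
                               !spe_assoc$discordant]
  vpanel <- panel[panel$id %in% verified, , drop = FALSE]

  dataset_prep <- list(genotypes = G_all, phenotypes = ph)

  ## stage 3: selection scan + matched controls ----------------------
  scan <- scan_panel(vpanel, dataset_prep, cohort_spec = config$cohort_spec,
                     fdr_level = config$fdr,
                     generation_years = config$generation_years)
  control_summary <- NULL
  if (!is.null(control_pool)) {
    sets <- sample_matched_controls(vpanel, control_pool,
                                    n_sets = config$n_control_sets,
                                    seed = stage_seed(config$seed, 3L))
    control_summary <- scan_control_sets(sets, dataset_prep,
                                         alpha = config$fdr)
  }

  ## stage 4: lifespan screen and exclusion --------------------------
  screen <- lifespan_screen(vpanel, dataset_prep, covariates = covars,
                            fdr_level = config$fdr)
  kept_panel <- vpanel[!vpanel$id %in% screen$flagged, , drop = FALSE]
  scan_kept <- scan_panel(kept_panel, dataset_prep,
                          cohort_spec = config$cohort_spec,
                          fdr_level = config$fdr,
                          generation_years = config$generation_years)

  ## stage 5: reproductive pleiotropy --------------------------------
  afb_assoc <- assoc_scan(G_all[, kept_panel$id, drop = FALSE], ph$afb,
                          covars, trait = "afb")
  neb_assoc <- assoc_scan(G_all[, kept_panel$id, drop = FALSE], ph$neb,
                          covars, trait = "neb")
  consistency <- direction_consistency(scan_kept, afb_assoc, neb_assoc,
                                       fdr_level = config$fdr)
  sig_scan <- scan_kept$estimates[scan_kept$estimates$direction != "0", ,
                                  drop = FALSE]
  cor_res <- list(afb = NULL, neb = NULL)
  for (tr in c("afb", "neb")) {
    at <- get(paste0(tr, "_assoc"))
    at <- at[!is.na(at$q) & at$q < config$fdr, , drop = FALSE]
    shared <- intersect(sig_scan$snp_id, at$snp_id)
    if (length(shared) >= 3L) {
      s_v <- sig_scan$s[match(shared, sig_scan$snp_id)]
      b_v <- at$beta[match(shared, at$snp_id)]
      cor_res[[tr]] <- tryCatch(s_effect_correlation(s_v, b_v),
                                error = function(e) NULL)
    }
  }
  groups <- list(
    afb = group_t_test(ph$afb[ph$myopia %in% TRUE], ph$afb[ph$myopia %in% FALSE]),
    neb = group_t_test(ph$neb[ph$myopia %in% TRUE], ph$neb[ph$myopia %in% FALSE])
  )

  ## stage 6: prevalence prediction + excess cases -------------------
  cohort_f <- factor(ph$cohort,
                     levels = sprintf("%d-%d", config$cohort_spec$start_year,
                                      config$cohort_spec$end_year))
  target <- if (is.null(config$target_prevalence))
    prep$prevalence$prevalence[1L] else config$target_prevalence
  model_panel <- kept_panel
  prevalence_pred <- NULL
  delta_points <- NA_real_
  if (nrow(model_panel) > 0L) {
    mb <- spe_assoc$beta[match(model_panel$id, spe_assoc$snp_id)]
    p_ref <- vapply(model_panel$id, function(id)
      cohort_allele_freq(G_all[, id]), numeric(1))
    p_ref <- pmin(pmax(p_ref, 1e-4), 1 - 1e-4)
    model <- liability_model(
      u = liability_effects_from_assoc(mb, p_ref), p = p_ref,
      h2 = config$h2, target_prevalence = target,
      n_replicates = config$n_replicates,
      seed = stage_seed(config$seed, 6L)
    )
    prevalence_pred <- predict_prevalence(
      model, G_all[, model_panel$id, drop = FALSE], cohort_f)
    delta_points <- attr(prevalence_pred, "delta_points")
  }
  observed_delta_points <- 100 * (prep$prevalence$prevalence[nrow(prep$prevalence)] -
                                  prep$prevalence$prevalence[1L])
  excess <- if (is.na(delta_points)) NA_real_
            else excess_cases(delta_points, config$population)

  ## SNP accounting --------------------------------------------------
  category <- rep("scanned", nrow(panel))
  names(category) <- panel$id
  category[!panel$id %in% qc$keep] <- "qc_removed"
  category[panel$id %in% pruned$removed] <- "ld_removed"
  category[panel$id %in% qc$keep & !panel$id %in% pruned$removed &
           !panel$id %in% verified] <- "not_verified"
  category[panel$id %in% screen$flagged] <- "lifespan_excluded"

  report <- structure(list(
    config = unclass(config),
    seed = config$seed,
    exclusions = as.list(prep$exclusions),
    prevalence_observed = prep$prevalence,
    funnel = list(n_input_snps = nrow(panel), n_qc_pass = length(qc$keep),
                  n_ld_pruned = length(pruned$keep),
                  n_verified = length(verified),
                  n_lifespan_flagged = length(screen$flagged),
                  n_scanned = nrow(kept_panel)),
    snp_categories = as.list(category),
    association = spe_assoc,
    selection = scan$summary,
    selection_after_lifespan_exclusion = scan_kept$summary,
    selection_estimates = scan_kept$estimates,
    control_summary = control_summary,
    pleiotropy = list(
      consistency_p = consistency$binomial_p,
      n_consistency_records = if (is.null(consistency$records)) 0L
                              else nrow(consistency$records),
      afb_correlation = cor_res$afb, neb_correlation = cor_res$neb,
      group_tests = groups
    ),
    prevalence_predicted = prevalence_pred,
    genetic_delta_points = delta_points,
    observed_delta_points = observed_delta_points,
    excess_cases = excess,
    fraction_of_increase = if (!is.na(delta_points) &&
                               observed_delta_points != 0)
      fraction_of_increase(delta_points, observed_delta_points) else NA_real_
  ), class = "pipeline_report")

  if (!is.null(config$output_dir)) write_report(report, config$output_dir)
  report
}

write_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tsv_write(report$association, file.path(dir, "association.tsv"))
  tsv_write(report$selection_estimates, file.path(dir, "selection.tsv"))
  if (!is.null(report$control_summary)) {
    tsv_write(report$control_summary, file.path(dir, "control_summary.tsv"))
  }
  tsv_write(report$prevalence_observed, file.path(dir, "prevalence_observed.tsv"))
  if (!is.null(report$prevalence_predicted)) {
    tsv_write(report$prevalence_predicted,
              file.path(dir, "prevalence_predicted.tsv"))
  }
  jsonlite::write_json(unclass(report), file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null", force = TRUE)
  invisible(dir)
}

#' @export
print.pipeline_report <- function(x, ...) {
  f <- x$funnel
  cat(sprintf(
    paste0("<pipeline_report> %d SNPs -> %d QC -> %d LD-pruned -> %d verified",
           " -> %d after lifespan exclusion\n"),
    f$n_input_snps, f$n_qc_pass, f$n_ld_pruned, f$n_verified, f$n_scanned))
  s <- x$selection_after_lifespan_exclusion
  cat(sprintf("  trends: %d up / %d down (sign-test p = %s)\n",
              s$n_up, s$n_down, format(s$sign_test_p, digits = 3)))
  cat(sprintf("  genetic prevalence change: %+.3f points; excess cases: %s\n",
              x$genetic_delta_points, format(x$excess_cases, big.mark = ",")))
  invisible(x)
}

#' Generate a named synthetic study scenario
#'
#' Three scenarios cover the causal structures the pipeline must
#' distinguish:
#'
#' * `paper_like`: 213 liability SNPs, 26 planted with positive and 6
#'   with negative selection; among the positively selected, 8 lower age
#'   at first birth and 5 raise number of children (one overlap); among
#'   the negatively selected, 1 raises AFB and 2 lower NEB. Reproduction
#'   explains the selection signal.
#' * `lifespan_confounded`: 20 SNPs carry both a frequency trend and a
#'   planted parental-lifespan effect — the trend is the survival
#'   artifact the lifespan screen must catch and exclude.
#' * `all_null`: liability effects only; no selection, no reproductive or
#'   lifespan effects.
#'
#' Planted selection coefficients are scaled to the scenario sample size
#' so the planted structure is statistically recoverable (see the methods
#' vignette for the power reasoning).
#'
#' @param name Scenario name.
#' @param seed Integer seed.
#' @param n_per_cohort Individuals per cohort, default 2000.
#' @param n_snps Panel size, default 213.
#' @param pool_size Control-pool size (0 = no pool), default 10 x panel.
#' @param dir Optional directory: when given the dataset is written with
#'   [write_dataset()].
#' @return List: `dataset`, `panel`, `pool` (or `NULL`), `config`.
#' @export
generate_scenario <- function(name = c("paper_like", "all_null",
                                       "lifespan_confounded"),
                              seed = 1L, n_per_cohort = 2000L,
                              n_snps = 213L, pool_size = 10L * n_snps,
                              dir = NULL) {
  name <- tryCatch(match.arg(name), error = function(e)
    stop("unknown scenario; available: paper_like, all_null, lifespan_confounded",
         call. = FALSE))
  set.seed(stage_seed(seed, 0L))
  freq <- stats::runif(n_snps, 0.1, 0.9)
  u <- abs(stats::rnorm(n_snps, 0.06, 0.02)) + 0.02
  s <- numeric(n_snps)
  beta_afb <- beta_neb <- beta_lifespan <- numeric(n_snps)
  # selection magnitude scaled so planted trends are detectable at the
  # scenario's n (slope ~ p*s/25 against se ~ sqrt(pq/2)/(sqrt(n)*sd(year)))
  s_mag <- 0.12 * sqrt(50000 / (6 * n_per_cohort))

  if (name == "paper_like") {
    up <- 1:26
    down <- 27:32
    s[up] <- s_mag * stats::runif(26, 0.8, 1.6)
    s[down] <- -s_mag * stats::runif(6, 0.8, 1.6)
    afb_snps <- up[1:8]; neb_snps <- up[8:12]  # one overlap at up[8]
    beta_afb[afb_snps] <- -stats::runif(8, 0.25, 0.45)
    beta_neb[neb_snps] <- stats::runif(5, 0.08, 0.15)
    beta_afb[down[1]] <- 0.35
    beta_neb[down[2:3]] <- -stats::runif(2, 0.08, 0.15)
  } else if (name == "lifespan_confounded") {
    conf <- 1:20
    s[conf] <- s_mag * sample(c(-1, 1), 20, replace = TRUE) *
      stats::runif(20, 0.9, 1.5)
    beta_lifespan[conf] <- -0.5
  }

  panel <- snp_panel(
    id = sprintf("rs%06d", seq_len(n_snps)),
    baseline_freq = freq,
    chrom = as.character(rep_len(1:22, n_snps)),
    pos = seq_len(n_snps) * 5000L,
    recomb_rate = stats::runif(n_snps, 0.2, 3),
    s_true = s, u_true = u, beta_afb = beta_afb, beta_neb = beta_neb,
    beta_lifespan = beta_lifespan
  )
  pool <- if (pool_size > 0) {
    simulate_control_pool(panel, pool_size, seed = stage_seed(seed, 1L))
  } else NULL

  config <- sim_config(n_per_cohort = n_per_cohort,
                       env_trend_per_year = -0.03,
                       seed = stage_seed(seed, 2L))
  sim_panel <- if (is.null(pool)) panel else rbind_panel(panel, pool)
  dataset <- simulate_individuals(sim_panel, config)
  dataset$panel <- panel   # focal panel; pool genotypes stay in the matrix
  dataset$pool <- pool
  if (!is.null(dir)) write_dataset(dataset, dir)
  list(dataset = dataset, panel = panel, pool = pool, config = config)
}

rbind_panel <- function(a, b) {
  out <- rbind(as.data.frame(a), as.data.frame(b))
  class(out) <- c("snp_panel", "data.frame")
  out
}
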