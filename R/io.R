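#' Write a cohort dataset to disk as VCF + TSV files
#'
#' Emits the standard file set consumed by [read_dataset()] and
#' [run_pipeline()]:
#' `genotypes.vcf` (VCF 4.2, GT-only biallelic records, REF = other
#' allele, ALT = risk allele, missing as `./.`), `phenotypes.tsv`,
#' `snp_meta.tsv` (id, chrom, pos, risk/other allele, baseline frequency,
#' recombination rate), `truth.tsv` (the panel's planted truth), and
#' `aging_schedule.tsv`. A read-back round trip reproduces the in-memory
#' genotype matrix and phenotype table exactly.
#'
#' @param data `cohort_dataset` from [simulate_individuals()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of file paths.
#' @export
write_dataset <- function(data, dir) {
  stopifnot(inherits(data, "cohort_dataset"))
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE)) {
    stop("cannot create output directory: ", dir, call. = FALSE)
  }
  paths <- c(
    vcf = file.path(dir, "genotypes.vcf"),
    phenotypes = file.path(dir, "phenotypes.tsv"),
    snp_meta = file.path(dir, "snp_meta.tsv"),
    truth = file.path(dir, "truth.tsv"),
    aging_schedule = file.path(dir, "aging_schedule.tsv")
  )
  meta <- as.data.frame(data$panel)
  meta$role <- "panel"
  if (!is.null(data$pool)) {
    pm <- as.data.frame(data$pool)
    pm$role <- "control"
    meta <- rbind(meta, pm)
  }
  # keep only SNPs with genotype columns, in matrix column order
  meta <- meta[match(colnames(data$genotypes), meta$id), , drop = FALSE]
  write_genotype_vcf(data$genotypes, meta, paths["vcf"])
  tsv_write(data$phenotypes, paths["phenotypes"])
  meta_cols <- c("id", "chrom", "pos", "risk_allele", "other_allele",
                 "baseline_freq", "recomb_rate", "role")
  tsv_write(meta[meta_cols], paths["snp_meta"])
  truth_cols <- c("id", "s_true", "u_true", "beta_afb", "beta_neb",
                  "beta_lifespan")
  tsv_write(meta[truth_cols], paths["truth"])
  tsv_write(data$config$aging_schedule, paths["aging_schedule"])
  invisible(paths)
}

tsv_write <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
}

tsv_read <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    na.strings = "NA", check.names = FALSE)
}

# VCF 4.2 writer, GT field only. Dosage counts the ALT (risk) allele.
write_genotype_vcf <- function(G, panel, path) {
  n <- nrow(G)
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=cohortsel",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(G)), collapse = "\t")
  )
  body <- vapply(seq_len(nrow(panel)), function(i) {
    g <- G[, panel$id[i]]
    gt <- ifelse(is.na(g), "./.", gt_code[as.character(g)])
    paste(c(panel$chrom[i], panel$pos[i], panel$id[i], panel$other_allele[i],
            panel$risk_allele[i], ".", "PASS", ".", "GT", gt),
          collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
}

#' Read a cohort dataset back from a directory
#'
#' Inverse of [write_dataset()]. Genotypes are parsed from the VCF with
#' `vcfR` and converted to risk-allele (ALT) dosages; planted truth is
#' reattached to the panel when `truth.tsv` is present.
#'
#' @param dir Directory written by [write_dataset()].
#' @return A `cohort_dataset` (its `config` holds only the aging schedule
#'   and cohort spec inferred from the phenotype birth years).
#' @export
read_dataset <- function(dir) {
  vcf_path <- file.path(dir, "genotypes.vcf")
  meta <- tsv_read(file.path(dir, "snp_meta.tsv"))
  phenotypes <- tsv_read(file.path(dir, "phenotypes.tsv"))
  schedule <- tsv_read(file.path(dir, "aging_schedule.tsv"))
  truth_path <- file.path(dir, "truth.tsv")
  truth <- if (file.exists(truth_path)) tsv_read(truth_path) else NULL

  G <- read_genotype_vcf(vcf_path)
  # align to metadata order
  G <- G[, meta$id, drop = FALSE]

  build_panel <- function(m) {
    p <- snp_panel(
      id = m$id, baseline_freq = m$baseline_freq, chrom = m$chrom,
      pos = m$pos, risk_allele = m$risk_allele,
      other_allele = m$other_allele, recomb_rate = m$recomb_rate
    )
    if (!is.null(truth)) {
      tr <- truth[match(p$id, truth$id), , drop = FALSE]
      for (col in c("s_true", "u_true", "beta_afb", "beta_neb",
                    "beta_lifespan")) {
        p[[col]] <- tr[[col]]
      }
    }
    p
  }
  if (is.null(meta$role)) meta$role <- "panel"
  panel <- build_panel(meta[meta$role == "panel", , drop = FALSE])
  pool <- if (any(meta$role == "control")) {
    build_panel(meta[meta$role == "control", , drop = FALSE])
  } else NULL

  structure(list(
    genotypes = G, phenotypes = phenotypes, panel = panel, pool = pool,
    config = list(aging_schedule = schedule), truth = NULL
  ), class = "cohort_dataset")
}

#' Read ALT-allele dosages from a GT-only VCF
#'
#' @param path VCF file (plain text or bgzipped).
#' @return Integer matrix, individuals x SNPs, `NA` for missing genotypes.
#' @export
read_genotype_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  if (nrow(v@fix) == 0) {
    ids <- character(0)
    samples <- colnames(v@gt)[-1]
    return(matrix(NA_integer_, length(samples), 0,
                  dimnames = list(samples, ids)))
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  dos <- matrix(NA_integer_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  dos[gt %in% c("0/0", "0|0")] <- 0L
  dos[gt %in% c("0/1", "1/0", "0|1", "1|0")] <- 1L
  dos[gt %in% c("1/1", "1|1")] <- 2L
  t(dos)
}
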