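stage2_free <- function(fd, init) {
  unique(c(
    intersect(free_measurement(fd),
              c(paste0("mu.", init$schema$indicators$label),
                "beta.age", "beta.sex")),
    free_correlations(fd)))
}

snp_dosages_in_sample <- function(ped, geno, snp) {
  m <- match(ped$iid, rownames(geno))
  g <- ifelse(is.na(m), NA_real_, geno[m, snp])
  g[!is.na(g)]
}

#' Per-SNP latent-factor association test
#'
#' Runs the stage-2 model on the genotyped subsample with the measurement
#' parameters fixed at the stage-1 (total sample) estimates: sex-specific
#' additive SNP effects on the latent factor are estimated freely together
#' with the means, covariate effects and familial correlations, and tested
#' by likelihood ratio (default) or Wald tests against zero, per sex (1 df
#' each) and jointly (2 df).
#'
#' @param ped Pedigree of the genotyped subsample.
#' @param phen Wide phenotype table (normalized on the total sample).
#' @param geno Dosage matrix.
#' @param snp SNP label (column of `geno`).
#' @param stage1 `model_params` carrying the stage-1 estimates (e.g.
#'   `two_stage_protocol(...)$stage1$params`).
#' @param cohort `"adult"` or `"child"`.
#' @param test `"lrt"` or `"wald"` for the per-sex p-values.
#' @return An object of class `assoc_result` with the estimates, standard
#'   errors, p-values and QC flags for the SNP.
#' @export
test_snp <- function(ped, phen, geno, snp, stage1,
                     cohort = stage1$cohort, test = c("lrt", "wald")) {
  test <- match.arg(test)
  if (inherits(stage1, "fit_result")) stage1 <- stage1$params
  stopifnot(inherits(stage1, "model_params"))
  g <- snp_dosages_in_sample(ped, geno, snp)
  if (length(unique(g)) < 2)
    stop("SNP ", snp, " is monomorphic in the analysis sample")
  fd <- build_family_data(ped, phen, cohort, geno, snp,
                          center_dosage = TRUE)
  base <- stage2_free(fd, stage1)
  full <- fit_model(fd, stage1, c(base, "beta.snp.m", "beta.snp.f"),
                    se = TRUE)
  if (test == "lrt") {
    red_m <- fit_model(fd, stage1, c(base, "beta.snp.f"))
    red_f <- fit_model(fd, stage1, c(base, "beta.snp.m"))
    p_m <- lrt(full, red_m)$p
    p_f <- lrt(full, red_f)$p
  } else {
    z <- full$estimates[c("beta.snp.m", "beta.snp.f")] /
      full$se[c("beta.snp.m", "beta.snp.f")]
    p_m <- 2 * stats::pnorm(-abs(z[1]))
    p_f <- 2 * stats::pnorm(-abs(z[2]))
  }
  red_j <- fit_model(fd, stage1, base)
  hw <- hwe_test(geno, snp, ped)
  structure(list(
    snp = snp,
    beta_m = unname(full$estimates["beta.snp.m"]),
    beta_f = unname(full$estimates["beta.snp.f"]),
    se_m = unname(full$se["beta.snp.m"]),
    se_f = unname(full$se["beta.snp.f"]),
    p_m = unname(p_m), p_f = unname(p_f),
    p_joint = lrt(full, red_j)$p,
    maf = maf(geno, snp, ped),
    hwe_fail = hw$p < 0.01,
    high_missingness = mean(is.na(geno[, snp])) > 0.05,
    test = test, fit = full), class = "assoc_result")
}

#' @export
print.assoc_result <- function(x, ...) {
  cat(sprintf(
    "<assoc_result> %s  beta_m=%.3f (p=%.4g)  beta_f=%.3f (p=%.4g)  joint p=%.4g\n",
    x$snp, x$beta_m, x$p_m, x$beta_f, x$p_f, x$p_joint))
  if (x$hwe_fail) cat("  flag: HWE p < 0.01\n")
  if (x$high_missingness) cat("  flag: missingness > 5%\n")
  invisible(x)
}

#' Between/within-family decomposition of a SNP effect
#'
#' Splits the dosage effect on the latent factor into a between-family
#' component (the family mean dosage among genotyped offspring, confoundable
#' by population stratification) and a within-family deviation component
#' (stratification-free, since co-twins and siblings come from the same
#' population). Genotyped parents enter through their own dosage in the
#' between channel. Sex differences are not included: one coefficient per
#' component. The 1-df likelihood-ratio test of equal components is a test
#' for population stratification.
#'
#' @inheritParams test_snp
#' @return List with `beta_between`, `beta_within`, their standard errors,
#'   `p_equality`, and `defined` (FALSE, with everything NA, when no family
#'   carries within-family dosage variance).
#' @export
between_within_test <- function(ped, phen, geno, snp, stage1,
                                cohort = stage1$cohort) {
  if (inherits(stage1, "fit_result")) stage1 <- stage1$params
  fd <- build_family_data(ped, phen, cohort, geno, snp, decompose = "bw",
                          center_dosage = TRUE)
  wvar <- sum(vapply(fd$groups, function(g) sum(g$GW^2), 0))
  if (wvar == 0)
    return(list(beta_between = NA_real_, beta_within = NA_real_,
                se_between = NA_real_, se_within = NA_real_,
                p_equality = NA_real_, defined = FALSE,
                note = "no within-family dosage variance"))
  base <- stage2_free(fd, stage1)
  full <- fit_model(fd, stage1, c(base, "beta.snp.b", "beta.snp.w"),
                    se = TRUE)
  fd_eq <- build_family_data(ped, phen, cohort, geno, snp,
                             decompose = "combined", center_dosage = TRUE)
  red <- fit_model(fd_eq, stage1, c(base, "beta.snp.b"))
  list(beta_between = unname(full$estimates["beta.snp.b"]),
       beta_within = unname(full$estimates["beta.snp.w"]),
       se_between = unname(full$se["beta.snp.b"]),
       se_within = unname(full$se["beta.snp.w"]),
       p_equality = lrt(full, red)$p, defined = TRUE)
}

#' Recessive re-analysis of a SNP
#'
#' Re-runs [test_snp()] with the dosage recoded by [code_recessive()]:
#' minor-allele homozygotes versus carriers of the major allele. SNPs with
#' no homozygous minor-allele carriers in the sample return `NA` results
#' with a diagnostic note instead of an error.
#'
#' @inheritParams test_snp
#' @return An `assoc_result`, or a list with `note` when undefined.
#' @export
recessive_test <- function(ped, phen, geno, snp, stage1,
                           cohort = stage1$cohort, test = "lrt") {
  rec <- code_recessive(geno, snp)
  out <- tryCatch(test_snp(ped, phen, rec, snp, stage1, cohort, test),
                  error = function(e) NULL)
  if (is.null(out))
    return(structure(list(snp = snp, beta_m = NA_real_, beta_f = NA_real_,
                          se_m = NA_real_, se_f = NA_real_, p_m = NA_real_,
                          p_f = NA_real_, p_joint = NA_real_,
                          note = "no minor-allele homozygotes in sample"),
                     class = "assoc_result"))
  out$model <- "recessive"
  out
}

#' Association scan across SNPs
#'
#' @inheritParams test_snp
#' @param snps SNP labels (default: all columns of `geno`).
#' @param model `"additive"` or `"recessive"`.
#' @return Data frame with one row per SNP in the published results-table
#'   layout (SNP, MAF, HWE flag, per-sex betas, SEs and p-values, joint p).
#' @export
assoc_scan <- function(ped, phen, geno, stage1, snps = colnames(geno),
                       cohort = stage1$cohort, model = "additive",
                       test = "lrt") {
  rows <- lapply(snps, function(s) {
    r <- if (model == "recessive")
      recessive_test(ped, phen, geno, s, stage1, cohort, test)
    else test_snp(ped, phen, geno, s, stage1, cohort, test)
    data.frame(snp = s,
               maf = if (is.null(r$maf)) NA_real_ else r$maf,
               beta_m = r$beta_m, se_m = r$se_m, p_m = r$p_m,
               beta_f = r$beta_f, se_f = r$se_f, p_f = r$p_f,
               p_joint = r$p_joint,
               hwe_fail = isTRUE(r$hwe_fail),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write / read an association results table
#'
#' Plain TSV round-tripping losslessly (`NA` for missing entries, full
#' double precision).
#'
#' @param tab Data frame from [assoc_scan()].
#' @param path File path.
#' @export
write_assoc_results <- function(tab, path) {
  num <- vapply(tab, is.numeric, TRUE)
  out <- tab
  for (j in which(num)) out[[j]] <- sprintf("%.17g", tab[[j]])
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_assoc_results
#' @export
read_assoc_results <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  for (cc in intersect(c("hwe_fail", "significant", "defined"), names(tab)))
    tab[[cc]] <- as.logical(tab[[cc]])
  tab
}
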