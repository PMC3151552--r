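#' Run the full association pipeline
#'
#' Chains the analysis stages: (optional) cohort simulation or file input,
#' normal-scores transformation on the total sample, genotype QC, the
#' stage-1 measurement-model fit on the total sample, per-SNP stage-2
#' association tests (with optional stratification and recessive
#' re-analyses), and delimited result tables plus a log. All randomness is
#' seeded; two runs with the same configuration and seed produce
#' byte-identical result tables.
#'
#' @param config A configuration list, or the path of a JSON file holding
#'   one. Fields: `cohort` (`"adult"`/`"child"`); either `paths` (named list
#'   with `pedigree`, `phenotypes`, `genotypes`) or `simulate` (named list
#'   with `families` — a data frame-like list with `type`, `parents`,
#'   `brothers`, `sisters`, `n` — plus optional `maf`, `participation`,
#'   `truth` parameter overrides); `outdir`; `alpha` (default 0.01);
#'   `normalize` (default TRUE); `tests` (subset of `"additive"`,
#'   `"recessive"`, `"stratification"`); `seed`.
#' @return Invisibly, a list with the QC summary, stage-1 fit, and the
#'   association table(s); result files are written under `outdir`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- jsonlite::fromJSON(config, simplifyVector = TRUE)
  }
  cohort <- if (is.null(config$cohort)) "adult" else config$cohort
  alpha <- if (is.null(config$alpha)) 0.01 else config$alpha
  tests <- if (is.null(config$tests)) "additive" else config$tests
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  outdir <- config$outdir
  if (is.null(outdir)) stop("config must name an output directory 'outdir'")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  logl <- c(paste("twinfactor", as.character(utils::packageVersion(
    "twinfactor"))), paste("seed", seed), paste("cohort", cohort))

  if (!is.null(config$simulate)) {
    sim <- config$simulate
    fam <- as.data.frame(sim$families, stringsAsFactors = FALSE)
    cc <- cohort_config(
      fam, cohort,
      participation = if (is.null(sim$participation)) 1
                      else unlist(sim$participation),
      maf = if (is.null(sim$maf)) 0.3 else unlist(sim$maf),
      seed = seed)
    truth <- do.call(if (cohort == "adult") adult_model_params
                     else child_model_params,
                     as.list(unlist(sim$truth)))
    dat <- simulate_cohort(cc, truth)
    ped <- dat$ped; phen <- dat$phen; geno <- dat$geno
    write_pedigree(ped, file.path(outdir, "pedigree.tsv"))
    write_phenotypes(phen, file.path(outdir, "phenotypes.tsv"))
    write_dosage(geno, file.path(outdir, "genotypes.tsv"))
    logl <- c(logl, "input: simulated cohort")
  } else {
    p <- config$paths
    ped <- read_pedigree(p$pedigree)
    phen <- read_phenotypes(p$phenotypes)
    geno <- read_dosage(p$genotypes)
    logl <- c(logl, paste("input:", p$pedigree))
  }

  if (is.null(config$normalize) || isTRUE(config$normalize)) {
    phen <- normalize_phenotypes(phen, cohort)
    logl <- c(logl, "normal-scores transform applied on the total sample")
  }

  qc <- qc_summary(ped, geno)
  utils::write.table(format(qc$snps, digits = 10), file.path(outdir,
                     "qc.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  geno <- orient_minor(geno, ped)

  init <- if (cohort == "adult") adult_model_params()
          else child_model_params()
  total_fd <- build_family_data(ped, phen, cohort)
  stage1 <- fit_model(total_fd, init,
                      c(free_measurement(total_fd),
                        free_correlations(total_fd)))
  write_params(stage1$params, file.path(outdir, "stage1_params.tsv"))
  logl <- c(logl,
            paste("stage1 -2lnL", format(stage1$minus2LL, digits = 12),
                  "converged", stage1$convergence))

  out <- list(qc = qc, stage1 = stage1)
  if ("additive" %in% tests) {
    tab <- assoc_scan(ped, phen, geno, stage1$params, cohort = cohort)
    tab$significant <- !is.na(tab$p_joint) & tab$p_joint < alpha
    write_assoc_results(tab, file.path(outdir, "assoc.tsv"))
    out$assoc <- tab
  }
  if ("recessive" %in% tests) {
    tabr <- assoc_scan(ped, phen, geno, stage1$params, cohort = cohort,
                       model = "recessive")
    write_assoc_results(tabr, file.path(outdir, "assoc_recessive.tsv"))
    out$assoc_recessive <- tabr
  }
  if ("stratification" %in% tests) {
    rows <- lapply(colnames(geno), function(s) {
      bw <- between_within_test(ped, phen, geno, s, stage1$params, cohort)
      data.frame(snp = s, beta_between = bw$beta_between,
                 beta_within = bw$beta_within,
                 p_equality = bw$p_equality, defined = bw$defined,
                 stringsAsFactors = FALSE)
    })
    tabs <- do.call(rbind, rows)
    write_assoc_results(tabs, file.path(outdir, "stratification.tsv"))
    out$stratification <- tabs
  }
  writeLines(logl, file.path(outdir, "log.txt"))
  invisible(out)
}
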