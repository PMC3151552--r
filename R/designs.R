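## census of the genotyped samples: unique genotypes, complete MZ pairs and
## per-occasion participation counts in the published study
genotyped_census <- list(
  adult = list(
    m = list(n_geno = 562L, mz_pairs = 42L,
             occ_n = c(ad1991 = 63, ad1995 = 151, ad1997 = 298,
                       ad2000 = 311, ad2002 = 425)),
    f = list(n_geno = 942L, mz_pairs = 89L,
             occ_n = c(ad1991 = 114, ad1995 = 246, ad1997 = 519,
                       ad2000 = 603, ad2002 = 751))),
  child = list(
    m = list(n_geno = 526L, mz_pairs = 144L,
             occ_n = c(mot7 = 479, fat7 = 414, mot10 = 468, fat10 = 399,
                       mot12 = 438, fat12 = 367, self = 364)),
    f = list(n_geno = 552L, mz_pairs = 160L,
             occ_n = c(mot7 = 509, fat7 = 446, mot10 = 480, fat10 = 389,
                       mot12 = 471, fat12 = 396, self = 454))))

reconstructed_units <- function(census, sex, participation) {
  n_unique <- census$n_geno - census$mz_pairs
  singles <- n_unique - census$mz_pairs
  part <- NULL
  if (identical(participation, "occasion"))
    part <- census$occ_n / census$n_geno
  list(
    list(count = census$mz_pairs, roles = c("twin1", "twin2"),
         sexes = c(sex, sex), zygosity = "MZ", participation = part),
    list(count = singles, roles = "twin1", sexes = sex, zygosity = "DZ",
         participation = part))
}

#' Power designs reconstructed from the published genotyped-sample counts
#'
#' The genotyped samples are reconstructed from the printed information:
#' unique genotype counts (520 male / 853 female adults; 382 male / 392
#' female children), complete MZ pair counts (42/89 adults, 144/160
#' children), factor loadings set to the square roots of the printed
#' per-occasion variance-explained fractions, and the printed latent twin
#' correlations. Each MZ pair enters as a genuine pair sharing one genotype;
#' the remaining unique genotypes enter as singletons.
#'
#' By default every reconstructed person is completely observed, following
#' the study's statement that only the number of unique genotypes entered
#' its power calculations. `participation = "occasion"` instead thins each
#' indicator to the genotyped-sample occasion counts.
#'
#' The child designs zero the (unpublished) residual correlation structure:
#' the printed information set contains loadings and latent twin
#' correlations only.
#'
#' @param sex `"m"` or `"f"`: the per-sex 1-df test design.
#' @param participation `"complete"` or `"occasion"`.
#' @param alpha,target Test size and target power.
#' @return A `power_design`.
#' @export
adult_power_design <- function(sex = c("f", "m"),
                               participation = c("complete", "occasion"),
                               alpha = 0.01, target = 0.8) {
  sex <- match.arg(sex)
  participation <- match.arg(participation)
  params <- adult_model_params(beta.age = 0, beta.sex = 0)
  census <- genotyped_census$adult[[sex]]
  power_design(params, reconstructed_units(census, sex, participation),
               maf = 0.5, alpha = alpha, df = 1, target = target,
               effect_sex = sex)
}

#' @rdname adult_power_design
#' @export
child_power_design <- function(sex = c("m", "f"),
                               participation = c("complete", "occasion"),
                               alpha = 0.01, target = 0.8) {
  sex <- match.arg(sex)
  participation <- match.arg(participation)
  params <- child_model_params(
    beta.age = 0, beta.sex = 0,
    rho.raters.a7 = 0, rho.raters.a10 = 0, rho.raters.a12 = 0,
    rho.twin.mz.a7 = 0, rho.twin.mz.a10 = 0, rho.twin.mz.a12 = 0,
    rho.twin.mz.self = 0, rho.twin.dz.a7 = 0, rho.twin.dz.a10 = 0,
    rho.twin.dz.a12 = 0, rho.twin.dz.self = 0)
  census <- genotyped_census$child[[sex]]
  power_design(params, reconstructed_units(census, sex, participation),
               maf = 0.5, alpha = alpha, df = 1, target = target,
               effect_sex = sex)
}

## materialize a power design as a pedigree (for Monte-Carlo validation)
design_pedigree <- function(design) {
  rows <- list()
  fi <- 0L
  for (u in design$units) {
    sp <- u$spec
    for (r in seq_len(u$count)) {
      fi <- fi + 1L
      fid <- sprintf("P%05d", fi)
      rows[[fi]] <- data.frame(
        fid = fid, iid = paste0(fid, "_", seq_along(sp$roles)),
        pat = "0", mat = "0", sex = sp$sexes, role = sp$roles,
        zygosity = ifelse(is_twin(sp$roles), sp$zygosity, NA_character_),
        stringsAsFactors = FALSE)
    }
  }
  ped <- do.call(rbind, rows)
  class(ped) <- c("pedigree", "data.frame")
  ped
}

#' Monte-Carlo power of a design by simulate-and-refit
#'
#' Independent cross-validation of [ncp_power()]: data are simulated from
#' the design's family configurations (Mendelian genotypes at the design
#' MAF, phenotypes from the latent-factor model with the SNP effect set
#' from `ve`), and each replicate is analysed by the same FIML
#' likelihood-ratio test the noncentrality calculation describes (means and
#' latent correlations free, measurement fixed, 1-df test of the SNP
#' effect).
#'
#' @param design A `power_design` with a single `effect_sex`.
#' @param ve Variance-explained proportion under the alternative.
#' @param nrep Number of replicates.
#' @param seed Integer RNG seed.
#' @return A `power_result` with `power`, its binomial `se`, and `nrep`.
#' @export
mc_power <- function(design, ve, nrep = 200, seed = 1L) {
  stopifnot(!is.null(design$effect_sex))
  beta <- ve_to_beta(ve, design$maf)
  truth <- design$params
  truth$values[[paste0("beta.snp.", design$effect_sex)]] <- beta
  ped <- design_pedigree(design)
  labs_keep <- unique(unlist(lapply(design$units, function(u)
    if (is.null(u$spec$indicators)) design$params$schema$indicators$label
    else u$spec$indicators)))
  bsnp <- paste0("beta.snp.", design$effect_sex)
  rej <- logical(nrep)
  for (r in seq_len(nrep)) {
    geno <- simulate_genotypes(ped, c(snp1 = design$maf),
                               seed = seed + 7L * r)
    phen <- simulate_phenotypes(ped, truth, geno, seed = seed + 7L * r + 3L)
    drop <- setdiff(design$params$schema$indicators$label, labs_keep)
    for (d in drop) phen[[d]] <- NA_real_
    ## participation thinning
    set.seed(seed + 7L * r + 5L)
    for (u in design$units) {
      part <- u$spec$participation
      if (is.null(part)) next
      for (labx in names(part)) if (part[[labx]] < 1 &&
                                    labx %in% names(phen)) {
        thin <- stats::runif(nrow(phen)) > part[[labx]]
        phen[[labx]][thin] <- NA_real_
      }
    }
    fd <- build_family_data(ped, phen, design$params$schema, geno, "snp1")
    base <- unique(c(
      intersect(free_measurement(fd),
                c(paste0("mu.", labs_keep), "beta.sex")),
      free_correlations(fd)))
    full <- fit_model(fd, design$params, c(base, bsnp))
    red <- fit_model(fd, design$params, base)
    rej[r] <- lrt(full, red)$p < design$alpha
  }
  structure(list(power = mean(rej),
                 se = stats::sd(rej) / sqrt(nrep), nrep = nrep, ve = ve,
                 alpha = design$alpha, df = design$df,
                 method = "monte-carlo"), class = "power_result")
}
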