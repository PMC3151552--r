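#' Configuration for the synthetic twin-family cohort generator
#'
#' @param families Data frame with columns `type` (one of `MZM`, `DZM`,
#'   `MZF`, `DZF`, `DOS`), `parents` (logical), `brothers`, `sisters`
#'   (0-2 each) and `n` (number of families of that configuration). The
#'   child cohort allows twins only.
#' @param cohort `"adult"` or `"child"`.
#' @param participation Per-indicator inclusion probability: a single number,
#'   a vector named by indicator label, or a matrix (indicator labels x
#'   roles). Defaults to full participation.
#' @param maf Minor allele frequency per simulated SNP (named vector; names
#'   default to `snp1`, `snp2`, ...).
#' @param seed Integer RNG seed.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(families, cohort = c("adult", "child"),
                          participation = 1, maf = 0.3, seed = 1L) {
  cohort <- match.arg(cohort)
  schema <- cohort_schema(cohort)
  stopifnot(is.data.frame(families),
            all(c("type", "n") %in% names(families)))
  if (is.null(families$parents)) families$parents <- FALSE
  if (is.null(families$brothers)) families$brothers <- 0L
  if (is.null(families$sisters)) families$sisters <- 0L
  if (!all(families$type %in% c("MZM", "DZM", "MZF", "DZF", "DOS")))
    stop("unknown family type")
  if (any(families$n < 0)) stop("family counts must be nonnegative")
  if (cohort == "child" &&
      any(families$parents | families$brothers > 0 | families$sisters > 0))
    stop("child cohort pedigrees contain twin pairs only")
  roles <- names(schema$role_indicators)
  lab <- schema$indicators$label
  P <- matrix(1, nrow(schema$indicators), length(roles),
              dimnames = list(lab, roles))
  if (is.matrix(participation)) {
    P[rownames(participation), colnames(participation)] <- participation
  } else if (!is.null(names(participation))) {
    P[names(participation), ] <- participation
  } else {
    P[, ] <- participation
  }
  if (any(P < 0 | P > 1)) stop("participation probabilities must be in [0,1]")
  if (any(maf <= 0 | maf > 0.5)) stop("maf must lie in (0, 0.5]")
  if (is.null(names(maf))) names(maf) <- paste0("snp", seq_along(maf))
  structure(list(families = families, cohort = cohort, schema = schema,
                 participation = P, maf = maf, seed = as.integer(seed)),
            class = "cohort_config")
}

#' Build the pedigree implied by a cohort configuration
#'
#' Deterministic: the pedigree structure (family memberships, roles, sexes,
#' zygosities, parental links) is fully fixed by the configuration. MZ and
#' same-sex DZ pairs get the type's sex; opposite-sex (DOS) pairs are one
#' male (`twin1`) and one female (`twin2`). Co-twins and siblings share both
#' parent IDs; when parents are not part of the pedigree the parent IDs are
#' absent (`"0"`).
#'
#' @param config A `cohort_config`.
#' @return A data frame of class `pedigree` with columns `fid`, `iid`,
#'   `pat`, `mat`, `sex` (`"m"`/`"f"`), `role`, `zygosity`.
#' @export
build_families <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  blocks <- list()
  fi <- 0L
  for (k in seq_len(nrow(config$families))) {
    cf <- config$families[k, ]
    if (cf$n == 0) next
    tw_sex <- switch(cf$type, MZM = c("m", "m"), DZM = c("m", "m"),
                     MZF = c("f", "f"), DZF = c("f", "f"), DOS = c("m", "f"))
    zyg <- if (cf$type %in% c("MZM", "MZF")) "MZ" else "DZ"
    role <- c("twin1", "twin2",
              if (cf$parents) c("father", "mother"),
              rep("brother", cf$brothers), rep("sister", cf$sisters))
    sex <- c(tw_sex, if (cf$parents) c("m", "f"),
             rep("m", cf$brothers), rep("f", cf$sisters))
    fid <- sprintf("F%06d", fi + seq_len(cf$n))
    fi <- fi + cf$n
    pat <- if (cf$parents) paste0(fid, "_fa") else "0"
    mat <- if (cf$parents) paste0(fid, "_mo") else "0"
    for (j in seq_along(role)) {
      isp <- role[j] %in% c("father", "mother")
      blocks[[length(blocks) + 1L]] <- data.frame(
        fid = fid,
        iid = if (role[j] == "father") pat else if (role[j] == "mother")
          mat else paste0(fid, "_", j),
        pat = if (isp) "0" else pat,
        mat = if (isp) "0" else mat,
        sex = sex[j], role = role[j],
        zygosity = if (role[j] %in% c("twin1", "twin2")) zyg
                   else NA_character_,
        slot = j, stringsAsFactors = FALSE)
    }
  }
  ped <- do.call(rbind, blocks)
  ped <- ped[order(ped$fid, ped$slot), ]
  ped$slot <- NULL
  rownames(ped) <- NULL
  class(ped) <- c("pedigree", "data.frame")
  ped
}

#' Simulate biallelic genotypes down a pedigree
#'
#' Founders (parents) are drawn from Hardy-Weinberg proportions at the given
#' minor allele frequency; offspring receive one allele from each parent by
#' Mendelian transmission; MZ co-twins get identical genotypes. For
#' parent-less pedigrees (the child cohort) latent founder genotypes are
#' synthesized internally so that DZ/sibling dosage correlations remain 0.5.
#'
#' @param ped A `pedigree`.
#' @param maf Minor allele frequency per SNP (named vector) in (0, 0.5].
#' @param seed Integer RNG seed.
#' @return Numeric matrix of minor-allele dosages, rows named by individual
#'   ID, one column per SNP.
#' @export
simulate_genotypes <- function(ped, maf, seed = 1L) {
  stopifnot(all(maf > 0 & maf <= 0.5))
  if (is.null(names(maf))) names(maf) <- paste0("snp", seq_along(maf))
  set.seed(as.integer(seed))
  fids <- unique(ped$fid)
  nf <- length(fids)
  G <- matrix(NA_real_, nrow(ped), length(maf),
              dimnames = list(ped$iid, names(maf)))
  fam_of <- match(ped$fid, fids)
  for (s in seq_along(maf)) {
    p <- maf[s]
    gf <- stats::rbinom(nf, 2, p)   # fathers (observed or latent)
    gm <- stats::rbinom(nf, 2, p)
    transmit <- function(g) stats::rbinom(length(g), 1, g / 2)
    kid_dose <- function(rows) {
      f <- fam_of[rows]
      transmit(gf[f]) + transmit(gm[f])
    }
    rows_fa <- which(ped$role == "father")
    rows_mo <- which(ped$role == "mother")
    G[rows_fa, s] <- gf[fam_of[rows_fa]]
    G[rows_mo, s] <- gm[fam_of[rows_mo]]
    r1 <- which(ped$role == "twin1")
    G[r1, s] <- kid_dose(r1)
    r2 <- which(ped$role == "twin2")
    mz <- !is.na(ped$zygosity[r2]) & ped$zygosity[r2] == "MZ"
    ## MZ co-twin copies twin1 (same family); DZ draws independently
    co <- match(ped$fid[r2], ped$fid[r1])
    G[r2[mz], s] <- G[r1[co[mz]], s]
    G[r2[!mz], s] <- kid_dose(r2[!mz])
    rs <- which(ped$role %in% c("brother", "sister"))
    G[rs, s] <- kid_dose(rs)
  }
  G
}

## per-occasion mean twin age at the adult survey years, used to draw a
## family's base birth-cohort age; later occasions follow the calendar gaps
adult_age_offsets <- c(0, 4, 6, 9, 11)

#' Simulate longitudinal phenotypes under the latent-factor model
#'
#' Per family the latent factors are drawn from a multivariate normal with
#' unit variances and the familial correlation matrix of `truth`; the value
#' of member i at indicator t is
#' mu_t + beta_age age + beta_sex sex + lambda_t,s (F_i + beta_snp_s g_i) +
#' residual, with the adult residuals independent and the child residuals
#' carrying the rater-shared, zygosity-dependent cross-twin structure of
#' [implied_cov()]. Ages: adult families draw a base twin age at the first
#' occasion (normal, mean 20, sd 3) and follow the survey-year gaps, with
#' siblings offset +3 and parents +28 years; child self-report ages are
#' uniform on 14-18. Ages are stored centered at the sample mean.
#'
#' @param ped A `pedigree`.
#' @param truth A `model_params` object (the simulation ground truth).
#' @param geno Dosage matrix from [simulate_genotypes()], or `NULL` when
#'   both SNP effects are zero.
#' @param seed Integer RNG seed.
#' @param snp Column of `geno` carrying the causal SNP (default first).
#' @return Wide data frame: `iid`, one column per indicator label, and
#'   `age.<label>` columns for age-adjusted indicators.
#' @export
simulate_phenotypes <- function(ped, truth, geno = NULL, seed = 1L,
                                snp = NULL) {
  stopifnot(inherits(truth, "model_params"))
  v <- truth$values
  schema <- truth$schema
  if (is.null(geno) && (v[["beta.snp.m"]] != 0 || v[["beta.snp.f"]] != 0))
    stop("nonzero SNP effect requires genotypes")
  set.seed(as.integer(seed))
  K <- nrow(schema$indicators)
  lab <- schema$indicators$label
  n <- nrow(ped)
  Y <- matrix(NA_real_, n, K, dimnames = list(ped$iid, lab))
  AGE <- matrix(NA_real_, n, K)
  g <- rep(0, n)
  if (!is.null(geno)) {
    if (is.null(snp)) snp <- colnames(geno)[1]
    gg <- geno[ped$iid, snp]
    g <- ifelse(is.na(gg), 0, gg)  # missing genotype: no SNP mean term
  }
  sexnum <- as.numeric(ped$sex == "f")
  bsnp <- ifelse(ped$sex == "m", v[["beta.snp.m"]], v[["beta.snp.f"]])

  ## ages (uncentered for now)
  fids <- unique(ped$fid)
  fam_of <- match(ped$fid, fids)
  if (schema$cohort == "adult") {
    base <- stats::rnorm(length(fids), 20, 3)[fam_of]
    base <- base + ifelse(ped$role %in% c("brother", "sister"), 3,
                   ifelse(ped$role %in% c("father", "mother"), 28, 0))
    AGE <- outer(base, adult_age_offsets, `+`)
  } else {
    AGE[, 1:6] <- matrix(rep(c(7, 7, 10, 10, 12, 12), each = n), n)
    AGE[, 7] <- stats::runif(n, 14, 18)
  }

  sig <- vapply(split(seq_len(n), ped$fid), function(rows)
    paste(ped$role[rows], ped$sex[rows], ped$zygosity[rows], collapse = "|"),
    "")
  sig_per_fam <- sig[match(fids, names(sig))]
  for (sg in unique(sig_per_fam)) {
    fset <- fids[sig_per_fam == sg]
    rows1 <- which(ped$fid == fset[1])
    nm <- length(rows1)
    nfam <- length(fset)
    rowmat <- matrix(which(ped$fid %in% fset), nrow = nfam, ncol = nm,
                     byrow = TRUE)
    members <- data.frame(role = ped$role[rows1], sex = ped$sex[rows1],
                          zygosity = ped$zygosity[rows1],
                          stringsAsFactors = FALSE)
    R <- latent_corr_matrix(members, v)
    U <- tryCatch(chol(R), error = function(e)
      stop("latent correlation matrix not positive definite for family ",
           "configuration ", sg))
    Fm <- matrix(stats::rnorm(nfam * nm), nfam) %*% U  # rows ~ MVN(0, R)
    ## child cross-twin residual age factors
    res_fac <- NULL
    if (schema$cohort == "child") {
      zk <- if (identical(members$zygosity[1], "MZ")) "mz" else "dz"
      res_fac <- lapply(stats::setNames(nm = c("a7", "a10", "a12", "self")),
        function(a) {
          rho <- v[[paste0("rho.twin.", zk, ".", a)]]
          Z <- matrix(stats::rnorm(nfam * 2), nfam)
          Z %*% chol(matrix(c(1, rho, rho, 1), 2))
        })
    }
    for (m in seq_len(nm)) {
      rows <- rowmat[, m]
      s <- members$sex[m]
      for (t in schema$role_indicators[[members$role[m]]]) {
        lam <- v[[paste0("lambda.", s, ".", lab[t])]]
        s2 <- v[[paste0("sigma2.", s, ".", lab[t])]]
        mval <- v[[paste0("mu.", lab[t])]] + v[["beta.sex"]] * sexnum[rows]
        if (schema$indicators$use_age[t])
          mval <- mval + v[["beta.age"]] * AGE[rows, t]
        if (schema$cohort == "child") {
          a <- schema$indicators$agegrp[t]
          share <- if (a == "self") 1 else v[[paste0("rho.raters.", a)]]
          eps <- sqrt(share * s2) * res_fac[[a]][, m] +
                 sqrt((1 - share) * s2) * stats::rnorm(nfam)
        } else {
          eps <- sqrt(s2) * stats::rnorm(nfam)
        }
        Y[rows, t] <- mval +
          lam * (Fm[, m] + bsnp[rows] * g[rows]) + eps
      }
    }
  }
  ## center ages at the observed sample mean (the model convention)
  use <- schema$indicators$use_age
  AGE[, use] <- AGE[, use] - mean(AGE[, use], na.rm = TRUE)
  phen <- data.frame(iid = ped$iid, Y, stringsAsFactors = FALSE)
  for (t in which(use)) phen[[paste0("age.", lab[t])]] <- AGE[, t]
  rownames(phen) <- NULL
  phen
}

#' Apply occasion-specific participation (missingness) to a phenotype table
#'
#' Entries are set missing independently per indicator, per individual, with
#' probability one minus the role-specific participation probability
#' (missing completely at random). Individuals losing all their entries stay
#' in the pedigree; they simply contribute nothing to the likelihood.
#'
#' @param phen Wide phenotype table from [simulate_phenotypes()].
#' @param ped The matching `pedigree` (for roles).
#' @param config A `cohort_config` carrying the participation matrix.
#' @param seed Integer RNG seed.
#' @return The phenotype table with entries blanked to `NA`.
#' @export
apply_missingness <- function(phen, ped, config, seed = 1L) {
  P <- config$participation
  set.seed(as.integer(seed))
  role <- ped$role[match(phen$iid, ped$iid)]
  for (labx in rownames(P)) {
    pr <- P[labx, role]
    drop <- stats::runif(nrow(phen)) > pr
    phen[[labx]][drop] <- NA_real_
  }
  phen
}

#' Simulate a complete cohort (pedigree, genotypes, phenotypes)
#'
#' Convenience wrapper chaining [build_families()], [simulate_genotypes()],
#' [simulate_phenotypes()] and [apply_missingness()]. Bit-reproducible given
#' `(config, truth)`: all randomness derives from `config$seed`.
#'
#' @param config A `cohort_config`.
#' @param truth A `model_params` object used as ground truth.
#' @return List with elements `ped`, `geno`, `phen`.
#' @export
simulate_cohort <- function(config, truth) {
  ped <- build_families(config)
  geno <- simulate_genotypes(ped, config$maf, seed = config$seed)
  phen <- simulate_phenotypes(ped, truth, geno, seed = config$seed + 1L)
  phen <- apply_missingness(phen, ped, config, seed = config$seed + 2L)
  list(ped = ped, geno = geno, phen = phen)
}
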