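#' Describe one family's design
#'
#' A family design lists the family members (role, sex, zygosity), which
#' indicators each member was observed on, ages at the age-adjusted
#' indicators, and each member's SNP dosage. Together with a `model_params`
#' object it determines the implied mean vector and covariance matrix of the
#' observed measures.
#'
#' @param roles Character vector of roles (`twin1`, `twin2`, `father`,
#'   `mother`, `brother`, `sister`).
#' @param sexes Character vector, `"m"` or `"f"`.
#' @param zygosity `"MZ"`, `"DZ"` or `NA` per member (set on twins).
#' @param cohort `"adult"` or `"child"`.
#' @param obs Logical matrix (members x indicators) of observed entries;
#'   defaults to every indicator valid for the member's role. Entries outside
#'   the role's valid set are forced to `FALSE`.
#' @param ages Numeric matrix (members x indicators) of ages at measurement;
#'   only needed where the schema applies the age covariate and `beta.age`
#'   is nonzero. Ages should be centered before analysis.
#' @param dosage Numeric vector of minor-allele dosages (0/1/2, `NA` =
#'   genotype missing: the member's SNP mean term is omitted).
#' @return An object of class `family_design`.
#' @export
family_design <- function(roles, sexes, zygosity = NA, cohort = "adult",
                          obs = NULL, ages = NULL, dosage = NULL) {
  schema <- if (inherits(cohort, "cohort_schema")) cohort else
    cohort_schema(cohort)
  n <- length(roles)
  stopifnot(length(sexes) == n)
  valid_roles <- names(schema$role_indicators)
  if (!all(roles %in% valid_roles))
    stop("invalid role(s) for cohort '", schema$cohort, "': ",
         paste(setdiff(roles, valid_roles), collapse = ", "))
  if (!all(sexes %in% c("m", "f"))) stop("sexes must be 'm' or 'f'")
  zygosity <- rep_len(as.character(zygosity), n)
  K <- nrow(schema$indicators)
  valid <- matrix(FALSE, n, K)
  for (i in seq_len(n)) valid[i, schema$role_indicators[[roles[i]]]] <- TRUE
  if (is.null(obs)) obs <- valid else obs <- obs & valid
  if (is.null(ages)) ages <- matrix(NA_real_, n, K)
  if (is.null(dosage)) dosage <- rep(NA_real_, n)
  structure(list(schema = schema,
                 members = data.frame(role = roles, sex = sexes,
                                      zygosity = zygosity,
                                      stringsAsFactors = FALSE),
                 obs = obs, ages = ages, dosage = as.numeric(dosage)),
            class = "family_design")
}

is_twin <- function(role) role %in% c("twin1", "twin2")
is_offspring <- function(role) role %in% c("twin1", "twin2", "brother",
                                           "sister")

## latent-factor correlation between two distinct family members
relative_corr <- function(ri, si, zi, rj, sj, v) {
  if (is_twin(ri) && is_twin(rj)) {
    if (identical(zi, "MZ"))
      return(if (si == "m") v[["r.mzm"]] else v[["r.mzf"]])
    if (si != sj) return(v[["r.dos"]])
    return(if (si == "m") v[["r.dzm"]] else v[["r.dzf"]])
  }
  parent_i <- ri %in% c("father", "mother")
  parent_j <- rj %in% c("father", "mother")
  if (parent_i && parent_j) return(v[["r.sp"]])
  if (parent_i || parent_j) {
    prole <- if (parent_i) ri else rj
    csex <- if (parent_i) sj else si
    key <- paste0("r.", if (prole == "father") "f" else "m",
                  if (csex == "m") "s" else "d")
    return(v[[key]])
  }
  ## twin-sibling or sibling-sibling: DZ-level correlation of the matching
  ## sex pairing
  if (si != sj) return(v[["r.dos"]])
  if (si == "m") v[["r.dzm"]] else v[["r.dzf"]]
}

latent_corr_matrix <- function(members, v) {
  n <- nrow(members)
  R <- diag(1, n)
  if (n > 1) {
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      R[i, j] <- R[j, i] <- relative_corr(
        members$role[i], members$sex[i], members$zygosity[i],
        members$role[j], members$sex[j], v)
    }
  }
  R
}

## index table of observed (member, indicator) entries, member-major
design_index <- function(fam) {
  w <- which(t(fam$obs), arr.ind = TRUE)  # indicator-major transpose trick
  data.frame(member = w[, 2], ind = w[, 1])
}

entry_values <- function(fam, params) {
  v <- params$values
  idx <- design_index(fam)
  lab <- fam$schema$indicators$label[idx$ind]
  sex <- fam$members$sex[idx$member]
  list(idx = idx, lab = lab, sex = sex,
       lambda = unname(v[paste0("lambda.", sex, ".", lab)]),
       sigma2 = unname(v[paste0("sigma2.", sex, ".", lab)]))
}

#' Model-implied covariance matrix of one family's observed measures
#'
#' Cov(y_it, y_ju) = lambda_t,s(i) lambda_u,s(j) R_ij + residual term, where
#' R is the latent-factor correlation matrix over family members (unit
#' diagonal: the factor variance is fixed to 1). Adult residuals are
#' independent across persons and occasions. Child residuals add, per age, a
#' rater-shared residual factor (mother and father rating of the same child)
#' whose cross-twin correlation depends on zygosity.
#'
#' @param fam A `family_design`.
#' @param params A `model_params` of the matching cohort.
#' @param check If `TRUE`, error when the assembled matrix is not positive
#'   semi-definite.
#' @return Covariance matrix over the observed entries (member-major order),
#'   with attribute `"index"` mapping rows to (member, indicator).
#' @export
implied_cov <- function(fam, params, check = TRUE) {
  stopifnot(fam$schema$cohort == params$cohort)
  v <- params$values
  ev <- entry_values(fam, params)
  idx <- ev$idx
  E <- nrow(idx)
  R <- latent_corr_matrix(fam$members, v)
  S <- outer(ev$lambda, ev$lambda) * R[idx$member, idx$member, drop = FALSE]
  ## residual block
  Vres <- matrix(0, E, E)
  diag(Vres) <- ev$sigma2
  if (params$cohort == "child" && E > 1) {
    ag <- fam$schema$indicators$agegrp[idx$ind]
    sdres <- sqrt(ev$sigma2)
    for (a in unique(ag)) {
      share <- if (a == "self") 1 else v[[paste0("rho.raters.", a)]]
      ee <- which(ag == a)
      for (p1 in ee) for (p2 in ee) {
        if (p1 == p2) next
        i <- idx$member[p1]; j <- idx$member[p2]
        if (i == j) {
          Vres[p1, p2] <- share * sdres[p1] * sdres[p2]
        } else if (is_twin(fam$members$role[i]) &&
                   is_twin(fam$members$role[j])) {
          zk <- if (identical(fam$members$zygosity[i], "MZ")) "mz" else "dz"
          rho <- v[[paste0("rho.twin.", zk, ".", a)]]
          Vres[p1, p2] <- rho * share * sdres[p1] * sdres[p2]
        }
      }
    }
  }
  S <- S + Vres
  attr(S, "index") <- idx
  if (check && E > 0) {
    e <- min(eigen(S, symmetric = TRUE, only.values = TRUE)$values)
    if (e < -1e-8 * max(1, max(abs(diag(S)))))
      stop("implied covariance matrix is not positive semi-definite")
  }
  S
}

#' Model-implied mean vector of one family's observed measures
#'
#' Entry for member i at indicator t:
#' mu_t + beta_age * age_it + beta_sex * sex_i + beta_snp_s(i) *
#' lambda_t,s(i) * g_i, with sex coded 0 = male, 1 = female and g the
#' minor-allele dosage. The age term applies only to age-adjusted indicators
#' (all adult occasions; the adolescent self-report in children). Members
#' with missing dosage simply have no SNP term.
#'
#' @inheritParams implied_cov
#' @return Numeric vector over the observed entries (member-major order).
#' @export
implied_mean <- function(fam, params) {
  stopifnot(fam$schema$cohort == params$cohort)
  v <- params$values
  ev <- entry_values(fam, params)
  idx <- ev$idx
  mu <- v[paste0("mu.", ev$lab)]
  sexnum <- as.numeric(ev$sex == "f")
  m <- mu + v[["beta.sex"]] * sexnum
  use_age <- fam$schema$indicators$use_age[idx$ind]
  if (v[["beta.age"]] != 0 && any(use_age)) {
    age <- fam$ages[cbind(idx$member, idx$ind)]
    if (anyNA(age[use_age]))
      stop("missing age at an age-adjusted indicator while beta.age != 0")
    m[use_age] <- m[use_age] + v[["beta.age"]] * age[use_age]
  }
  g <- fam$dosage[idx$member]
  bsnp <- ifelse(ev$sex == "m", v[["beta.snp.m"]], v[["beta.snp.f"]])
  term <- bsnp * ev$lambda * g
  term[is.na(term)] <- 0
  unname(m + term)
}

#' Proportion of latent-trait variance explained by a SNP
#'
#' Under Hardy-Weinberg proportions an additive effect beta on the
#' unit-variance latent factor contributes variance beta^2 * 2 maf (1 - maf),
#' so the SNP's share of the total latent-trait variance is
#' VE = beta^2 2pq / (1 + beta^2 2pq).
#'
#' @param beta Additive SNP effect on the latent factor.
#' @param maf Minor allele frequency in (0, 0.5].
#' @return Proportion in [0, 1).
#' @export
snp_variance_explained <- function(beta, maf) {
  stopifnot(maf > 0, maf <= 0.5)
  s <- beta^2 * 2 * maf * (1 - maf)
  s / (1 + s)
}

## inverse of snp_variance_explained: the beta giving a target VE
ve_to_beta <- function(ve, maf) {
  stopifnot(ve > 0, ve < 1)
  sqrt((ve / (1 - ve)) / (2 * maf * (1 - maf)))
}
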