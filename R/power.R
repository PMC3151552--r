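## dosage correlation between family members under additive coding:
## MZ co-twins share the genotype; DZ twins, siblings and parent-offspring
## pairs correlate 0.5; spouses are unrelated
genotype_corr_matrix <- function(members) {
  n <- nrow(members)
  K <- diag(1, n)
  if (n > 1) for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    pi_ <- members$role[i] %in% c("father", "mother")
    pj_ <- members$role[j] %in% c("father", "mother")
    K[i, j] <- K[j, i] <-
      if (pi_ && pj_) 0
      else if (pi_ || pj_) 0.5
      else if (is_twin(members$role[i]) && is_twin(members$role[j]) &&
               identical(members$zygosity[i], "MZ")) 1
      else 0.5
  }
  K
}

## one power-design unit: a family configuration with its complete-data
## structural matrices and per-entry observation probabilities
build_power_unit <- function(params, roles, sexes, zygosity, count,
                             participation = NULL, indicators = NULL,
                             effect_sex = NULL) {
  fam <- family_design(roles, sexes, zygosity, params$schema)
  if (!is.null(indicators)) {
    keep <- params$schema$indicators$label %in% indicators
    fam$obs <- fam$obs & matrix(keep, nrow(fam$obs), length(keep),
                                byrow = TRUE)
  }
  ev <- entry_values(fam, params)
  idx <- ev$idx
  E <- nrow(idx)
  n <- nrow(fam$members)
  ## residual part: implied covariance minus the factor part
  v <- params$values
  R <- latent_corr_matrix(fam$members, v)
  S <- implied_cov(fam, params, check = TRUE)
  Vres <- S - outer(ev$lambda, ev$lambda) * R[idx$member, idx$member]
  Lam_cols <- matrix(0, E, n)
  Lam_cols[cbind(seq_len(E), idx$member)] <- ev$lambda
  ## name the latent correlation parameter governing each member pair
  rnames <- param_block(params, "correlations")
  probe <- stats::setNames(seq_along(rnames) + 100, rnames)
  cname <- matrix(NA_character_, n, n)
  if (n > 1) for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    val <- relative_corr(fam$members$role[i], fam$members$sex[i],
                         fam$members$zygosity[i], fam$members$role[j],
                         fam$members$sex[j], probe)
    cname[i, j] <- cname[j, i] <- names(probe)[probe == val]
  }
  probs <- rep(1, E)
  if (!is.null(participation)) {
    lab <- params$schema$indicators$label[idx$ind]
    probs <- unname(participation[lab])
  }
  mask <- if (is.null(effect_sex)) rep(1, n) else
    as.numeric(fam$members$sex == effect_sex)
  list(count = count, members = fam$members, idx = idx,
       lambda = ev$lambda, Lam_cols = Lam_cols, Vres = Vres,
       corr_names = cname, K = genotype_corr_matrix(fam$members),
       probs = probs, effect_mask = mask,
       spec = list(roles = roles, sexes = sexes, zygosity = zygosity,
                   indicators = indicators, participation = participation))
}

#' Construct a power design
#'
#' A roster of family configurations (with counts), a no-SNP parameter set,
#' and the test settings. Each configuration may carry per-indicator
#' participation probabilities (entries observed independently); by default
#' every member is completely observed.
#'
#' @param params `model_params` describing the measurement model and latent
#'   correlations under which power is evaluated (SNP effects zero).
#' @param units List of configuration descriptions, each a list with
#'   `count`, `roles`, `sexes`, `zygosity` and optionally `participation`
#'   (named probability vector by indicator label) and `indicators` (labels
#'   to restrict the measurement model to, e.g. for univariate designs).
#' @param maf Minor allele frequency of the hypothetical SNP (0.5 by
#'   default: in the variance-explained parameterization results are
#'   invariant to this choice).
#' @param alpha Test size (0.01).
#' @param df Test degrees of freedom (1: a per-sex test).
#' @param target Target power (0.80).
#' @param effect_sex Sex whose latent factor carries the hypothesized SNP
#'   effect, or `NULL` for all members.
#' @return An object of class `power_design`.
#' @export
power_design <- function(params, units, maf = 0.5, alpha = 0.01, df = 1,
                         target = 0.8, effect_sex = NULL) {
  stopifnot(alpha > 0, alpha < 1)
  built <- lapply(units, function(u)
    build_power_unit(params, u$roles, u$sexes, u$zygosity, u$count,
                     u$participation, u$indicators, effect_sex))
  structure(list(params = params, units = built, maf = maf, alpha = alpha,
                 df = df, target = target, effect_sex = effect_sex),
            class = "power_design")
}

#' @export
print.power_design <- function(x, ...) {
  cat("<power_design>", length(x$units), "configuration(s),",
      sum(vapply(x$units, `[[`, 0, "count")), "families; alpha =",
      x$alpha, ", df =", x$df, "\n")
  invisible(x)
}

## enumerate observation patterns of a unit: entries with probability 1 are
## always present, probability 0 always absent, the rest enumerate
unit_patterns <- function(u) {
  E <- length(u$probs)
  stoch <- which(u$probs > 0 & u$probs < 1)
  if (length(stoch) > 14)
    stop("too many partially observed entries to enumerate (",
         length(stoch), "); reduce the participation structure")
  fixed <- u$probs == 1
  if (!length(stoch))
    return(list(list(entries = which(fixed), w = 1)))
  pats <- vector("list", 2^length(stoch))
  for (b in seq_len(2^length(stoch)) - 1L) {
    inc <- as.logical(bitwAnd(b, 2^(seq_along(stoch) - 1L)))
    sel <- sort(c(which(fixed), stoch[inc]))
    w <- prod(u$probs[stoch[inc]]) * prod(1 - u$probs[stoch[!inc]])
    pats[[b + 1L]] <- list(entries = sel, w = w)
  }
  pats[vapply(pats, function(p) length(p$entries) > 0 && p$w > 0, TRUE)]
}

## latent correlation matrix of a unit at the null parameter vector theta
unit_R <- function(u, theta) {
  n <- nrow(u$members)
  R <- diag(1, n)
  if (n > 1) for (i in seq_len(n - 1)) for (j in (i + 1):n)
    R[i, j] <- R[j, i] <- theta[[u$corr_names[i, j]]]
  R
}

## Satorra-Saris discrepancy of the alternative's implied moments from the
## null model (beta = 0, latent correlations theta), summed over units,
## patterns and the genotype mixture. The genotype mixture enters the mean
## term exactly through the dosage covariance matrix 2pq K; the occasion
## intercepts profile to zero by symmetry (missingness and genotype are
## independent, so the pattern-wise genotype-averaged mean shift vanishes).
ncp_discrepancy <- function(design, beta, theta) {
  s2g <- 2 * design$maf * (1 - design$maf) * beta^2
  total <- 0
  for (u in design$units) {
    R0 <- unit_R(u, theta)
    Ra <- unit_R(u, design$params$values)  # alternative: true correlations
    mem <- u$idx$member
    S0_full <- outer(u$lambda, u$lambda) * R0[mem, mem, drop = FALSE] +
      u$Vres
    Sa_full <- outer(u$lambda, u$lambda) * Ra[mem, mem, drop = FALSE] +
      u$Vres
    eff <- u$effect_mask
    Ke <- u$K * outer(eff, eff)
    B_full <- u$Lam_cols %*% Ke %*% t(u$Lam_cols)
    for (p in u$patterns) {
      e <- p$entries
      S0 <- S0_full[e, e, drop = FALSE]
      Sa <- Sa_full[e, e, drop = FALSE]
      U <- tryCatch(chol(S0), error = function(err) NULL)
      if (is.null(U)) return(Inf)
      S0inv <- chol2inv(U)
      ld0 <- 2 * sum(log(diag(U)))
      lda <- determinant(Sa, logarithm = TRUE)$modulus[1]
      meanterm <- s2g * sum(S0inv * B_full[e, e])
      covterm <- sum(S0inv * Sa) + ld0 - lda - length(e)
      total <- total + u$count * p$w * (meanterm + covterm)
    }
  }
  total
}

prep_patterns <- function(design) {
  design$units <- lapply(design$units, function(u) {
    u$patterns <- unit_patterns(u)
    u
  })
  design
}

#' Noncentrality-based power for a latent-factor SNP test
#'
#' Satorra-Saris procedure: the SNP effect implied by the target
#' variance-explained proportion is translated into a shift of the implied
#' family moments; the null model (no SNP effect, latent correlations free)
#' is fitted to those moments by the FIML discrepancy, and the minimized
#' discrepancy, weighted by configuration counts, is the noncentrality
#' parameter of the test's chi-square distribution under the alternative.
#'
#' @param design A `power_design`.
#' @param ve Proportion of total latent-trait variance explained by the SNP
#'   (0 < ve < 1), on the proportion scale.
#' @return List of class `power_result`: `power`, `ncp`, `ve`, `method`.
#' @export
ncp_power <- function(design, ve) {
  stopifnot(inherits(design, "power_design"), ve > 0, ve < 1)
  beta <- ve_to_beta(ve, design$maf)
  design <- prep_patterns(design)
  free <- unique(stats::na.omit(unlist(lapply(design$units,
                                              function(u) u$corr_names))))
  if (length(free)) {
    start <- atanh(design$params$values[free])
    obj <- function(tr) {
      theta <- design$params$values
      theta[free] <- tanh(tr)
      ncp_discrepancy(design, beta, theta)
    }
    opt <- stats::nlminb(start, obj, control = list(rel.tol = 1e-12))
    ncp <- opt$objective
  } else {
    ncp <- ncp_discrepancy(design, beta, design$params$values)
  }
  crit <- stats::qchisq(1 - design$alpha, design$df)
  pow <- stats::pchisq(crit, design$df, ncp = ncp, lower.tail = FALSE)
  structure(list(power = pow, ncp = ncp, ve = ve, alpha = design$alpha,
                 df = design$df, method = "ncp"), class = "power_result")
}

#' @export
print.power_result <- function(x, ...) {
  cat(sprintf("<power_result> power = %.4f (NCP = %.3f) at VE = %.3g%% [%s]\n",
              x$power, x$ncp, 100 * x$ve, x$method))
  invisible(x)
}

#' Minimum detectable variance explained at target power
#'
#' Bisection on the variance-explained proportion until the NCP-based power
#' matches the design's target power to 1e-4.
#'
#' @param design A `power_design`.
#' @return Minimum detectable VE, as a percentage of latent-trait variance.
#' @export
min_detectable_ve <- function(design) {
  target <- design$target
  stopifnot(target > design$alpha)
  lo <- 1e-6; hi <- 0.6
  if (ncp_power(design, hi)$power < target)
    stop("design cannot reach target power even at 60% variance explained")
  repeat {
    mid <- (lo + hi) / 2
    pw <- ncp_power(design, mid)$power
    if (abs(pw - target) < 1e-4 || (hi - lo) < 1e-9) break
    if (pw < target) lo <- mid else hi <- mid
  }
  100 * mid
}

#' Restrict a power design to a single indicator (univariate version)
#'
#' The univariate comparison design keeps the same families, genotype
#' sharing and counts but measures each person once; the loading and
#' residual variance of the chosen indicator define the single-phenotype
#' measurement model.
#'
#' @param design A `power_design` built by [power_design()] or the
#'   reconstruction helpers.
#' @param indicator Indicator label to keep.
#' @return A `power_design`.
#' @export
univariate_design <- function(design, indicator) {
  specs <- lapply(design$units, function(u) {
    sp <- u$spec
    sp$indicators <- indicator
    sp$count <- u$count
    sp
  })
  power_design(design$params, specs, maf = design$maf,
               alpha = design$alpha, df = design$df,
               target = design$target, effect_sex = design$effect_sex)
}

#' @rdname ncp_power
#' @param indicator Indicator label for the univariate variant.
#' @export
univariate_power <- function(design, ve, indicator) {
  ncp_power(univariate_design(design, indicator), ve)
}

#' Falconer-style heritability from latent-factor twin correlations
#'
#' Pools the MZ and DZ correlations by averaging, then applies the classic
#' decomposition a2 = 2(rMZ - rDZ), c2 = 2 rDZ - rMZ, e2 = 1 - rMZ. When
#' the implied shared-environment component is negative the AE fallback
#' sets c2 = 0 and a2 = rMZ.
#'
#' @param r_mz Numeric vector of MZ latent-factor correlations.
#' @param r_dz Numeric vector of DZ/sibling latent-factor correlations.
#' @return Named vector `c(a2, c2, e2)`.
#' @export
falconer_h2 <- function(r_mz, r_dz) {
  stopifnot(all(abs(c(r_mz, r_dz)) <= 1))
  rmz <- mean(r_mz); rdz <- mean(r_dz)
  a2 <- 2 * (rmz - rdz)
  c2 <- 2 * rdz - rmz
  e2 <- 1 - rmz
  if (c2 < 0) {
    c2 <- 0
    a2 <- rmz
  }
  c(a2 = a2, c2 = c2, e2 = e2)
}
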