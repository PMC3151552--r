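#' Assemble raw family data for FIML estimation
#'
#' Groups families by configuration signature (roles, sexes, zygosity and
#' missingness pattern) so that the likelihood can be evaluated vectorized
#' per group: all families in a group share one implied covariance matrix,
#' while means vary with age, sex and dosage. Members with no observed
#' phenotype entries are marginalized out (dropped); families with no
#' observed entries contribute nothing and are dropped.
#'
#' @param ped A `pedigree`.
#' @param phen Wide phenotype table (indicator columns plus `age.*` columns).
#' @param cohort `"adult"`, `"child"`, or a `cohort_schema`.
#' @param geno Optional dosage matrix; with `snp`, attaches one SNP's
#'   dosages to the members (missing dosage = member's SNP mean term is
#'   omitted for that SNP only).
#' @param snp SNP column of `geno` to attach.
#' @param center_dosage Center the attached dosage at the analysis-sample
#'   mean (the association-protocol convention; makes the orientation flip
#'   0<->2 an exact sign change of beta).
#' @param decompose `"none"` attaches the raw dosage (sex-specific additive
#'   model); `"bw"` splits each offspring's dosage into the family mean
#'   among genotyped offspring (between channel) and the deviation from it
#'   (within channel), with genotyped parents entering through the between
#'   channel; `"combined"` routes the raw dosage through the between channel
#'   only, giving the single sex-free dosage coefficient that is the
#'   equality restriction of the between/within split.
#' @return An object of class `family_data`.
#' @export
build_family_data <- function(ped, phen, cohort = "adult", geno = NULL,
                              snp = NULL,
                              decompose = c("none", "bw", "combined"),
                              center_dosage = FALSE) {
  decompose <- match.arg(decompose)
  schema <- if (inherits(cohort, "cohort_schema")) cohort else
    cohort_schema(cohort)
  lab <- schema$indicators$label
  K <- length(lab)
  prow <- match(ped$iid, phen$iid)
  Yall <- matrix(NA_real_, nrow(ped), K)
  Aall <- matrix(NA_real_, nrow(ped), K)
  for (t in seq_len(K)) {
    if (lab[t] %in% names(phen)) Yall[, t] <- phen[[lab[t]]][prow]
    ac <- paste0("age.", lab[t])
    if (ac %in% names(phen)) Aall[, t] <- phen[[ac]][prow]
  }
  gall <- rep(NA_real_, nrow(ped))
  if (!is.null(geno)) {
    if (is.null(snp)) snp <- colnames(geno)[1]
    m <- match(ped$iid, rownames(geno))
    gall <- ifelse(is.na(m), NA_real_, geno[m, snp])
    ## optional: center dosage at the analysis-sample mean (as ages are
    ## centered): beta is unchanged, members without a genotype sit at the
    ## average, and flipping the dosage orientation becomes an exact sign
    ## change under the shared-intercept mean model
    if (center_dosage && any(!is.na(gall)))
      gall <- gall - mean(gall, na.rm = TRUE)
  }
  ## restrict observations to the member's valid indicator set
  valid <- matrix(FALSE, nrow(ped), K)
  for (r in names(schema$role_indicators))
    valid[ped$role == r, schema$role_indicators[[r]]] <- TRUE
  obs_all <- !is.na(Yall) & valid

  keep <- rowSums(obs_all) > 0
  sig_member <- paste(ped$role, ped$sex, ped$zygosity,
                      apply(obs_all, 1, function(z) paste(as.integer(z),
                                                          collapse = "")))
  fam_rows <- split(which(keep), ped$fid[keep])
  fam_rows <- fam_rows[lengths(fam_rows) > 0]
  sig_fam <- vapply(fam_rows, function(rows)
    paste(sig_member[rows], collapse = " | "), "")
  groups <- lapply(split(seq_along(fam_rows), sig_fam), function(fidx) {
    rows1 <- fam_rows[[fidx[1]]]
    nmem <- length(rows1)
    design <- family_design(ped$role[rows1], ped$sex[rows1],
                            ped$zygosity[rows1], schema,
                            obs = obs_all[rows1, , drop = FALSE])
    idx <- design_index(design)
    E <- nrow(idx)
    nfam <- length(fidx)
    Y <- matrix(NA_real_, nfam, E)
    AGE <- matrix(NA_real_, nfam, E)
    G <- matrix(NA_real_, nfam, nmem)
    GB <- GW <- NULL
    for (i in seq_along(fidx)) {
      rows <- fam_rows[[fidx[i]]]
      Y[i, ] <- Yall[cbind(rows[idx$member], idx$ind)]
      AGE[i, ] <- Aall[cbind(rows[idx$member], idx$ind)]
      G[i, ] <- gall[rows]
    }
    if (decompose != "none") {
      GB <- GW <- matrix(0, nfam, nmem)
      offspring <- is_offspring(design$members$role)
      for (i in seq_len(nfam)) {
        g <- G[i, ]
        if (decompose == "combined") {
          GB[i, ] <- ifelse(is.na(g), 0, g)
        } else {
          go <- g[offspring]
          gbar <- if (any(!is.na(go))) mean(go, na.rm = TRUE) else NA_real_
          gb <- ifelse(offspring, gbar, g)        # parents: own dosage
          gw <- ifelse(offspring, g - gbar, 0)
          gb[is.na(g) | is.na(gb)] <- 0
          gw[is.na(g) | is.na(gw)] <- 0
          GB[i, ] <- gb; GW[i, ] <- gw
        }
      }
    }
    g <- list(design = design, idx = idx,
              lab = lab[idx$ind],
              sex = ped$sex[rows1][idx$member],
              use_age = schema$indicators$use_age[idx$ind],
              member = idx$member,
              fids = names(fam_rows)[fidx],
              Y = Y, AGE = AGE, G = G, GB = GB, GW = GW, n = nfam)
    cache_group_positions(g, schema)
  })
  structure(list(schema = schema, groups = groups,
                 n_families = length(fam_rows)),
            class = "family_data")
}

## precompute integer positions into the parameter vector so the likelihood
## can assemble each group's implied moments without name lookups
cache_group_positions <- function(g, schema) {
  nm <- par_names(schema)
  mem <- g$design$members
  E <- nrow(g$idx)
  g$lam_pos <- match(paste0("lambda.", g$sex, ".", g$lab), nm)
  g$sig_pos <- match(paste0("sigma2.", g$sex, ".", g$lab), nm)
  g$mu_pos <- match(paste0("mu.", g$lab), nm)
  g$bage_pos <- match("beta.age", nm)
  g$bsex_pos <- match("beta.sex", nm)
  g$bsnp_pos <- ifelse(g$sex == "m", match("beta.snp.m", nm),
                       match("beta.snp.f", nm))
  g$sexnum <- as.numeric(g$sex == "f")
  ## E x E positions of the latent correlation governing each entry pair
  ## (NA on same-member blocks, where the factor correlation is 1)
  n <- nrow(mem)
  rnames <- nm[grepl("^r\\.", nm)]
  probe <- stats::setNames(seq_along(rnames) + 100, rnames)
  cp <- matrix(NA_integer_, n, n)
  if (n > 1) for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    val <- relative_corr(mem$role[i], mem$sex[i], mem$zygosity[i],
                         mem$role[j], mem$sex[j], probe)
    cp[i, j] <- cp[j, i] <- match(names(probe)[probe == val], nm)
  }
  g$corr_pos_ent <- cp[g$member, g$member, drop = FALSE]
  ## child residual structure: list of symmetric entry pairs with the
  ## positions of the parameters whose product scales sd_e1 * sd_e2
  res <- NULL
  if (schema$cohort == "child" && E > 1) {
    ag <- schema$indicators$agegrp[g$idx$ind]
    e1 <- integer(0); e2 <- integer(0); p1 <- integer(0); p2 <- integer(0)
    for (a in unique(ag)) {
      raters_pos <- if (a == "self") NA_integer_ else
        match(paste0("rho.raters.", a), nm)
      ee <- which(ag == a)
      for (q1 in ee) for (q2 in ee) {
        if (q1 == q2) next
        i <- g$member[q1]; j <- g$member[q2]
        if (i == j) {
          e1 <- c(e1, q1); e2 <- c(e2, q2)
          p1 <- c(p1, raters_pos); p2 <- c(p2, NA_integer_)
        } else if (is_twin(mem$role[i]) && is_twin(mem$role[j])) {
          zk <- if (identical(mem$zygosity[i], "MZ")) "mz" else "dz"
          e1 <- c(e1, q1); e2 <- c(e2, q2)
          p1 <- c(p1, raters_pos)
          p2 <- c(p2, match(paste0("rho.twin.", zk, ".", a), nm))
        }
      }
    }
    if (length(e1)) res <- list(e1 = e1, e2 = e2, p1 = p1, p2 = p2)
  }
  g$res_pairs <- res
  g
}

## fast implied covariance for a cached group (identical to
## implied_cov(g$design, params) by construction; asserted in the tests)
group_cov <- function(g, v) {
  lam <- v[g$lam_pos]
  s2 <- v[g$sig_pos]
  Rent <- v[g$corr_pos_ent]
  Rent[is.na(Rent)] <- 1
  E <- length(lam)
  S <- outer(lam, lam) * matrix(Rent, E, E)
  diag(S) <- diag(S) + s2
  rp <- g$res_pairs
  if (!is.null(rp)) {
    f1 <- v[rp$p1]; f1[is.na(f1)] <- 1
    f2 <- v[rp$p2]; f2[is.na(f2)] <- 1
    sd_ <- sqrt(s2)
    S[cbind(rp$e1, rp$e2)] <- S[cbind(rp$e1, rp$e2)] +
      f1 * f2 * sd_[rp$e1] * sd_[rp$e2]
  }
  S
}

#' @export
print.family_data <- function(x, ...) {
  cat("<family_data>", x$n_families, "families in", length(x$groups),
      "configuration groups (cohort:", x$schema$cohort, ")\n")
  invisible(x)
}

group_means <- function(g, v) {
  mu <- v[g$mu_pos] + v[g$bsex_pos] * g$sexnum
  M <- matrix(mu, g$n, length(mu), byrow = TRUE)
  if (v[[g$bage_pos]] != 0 && any(g$use_age)) {
    A <- g$AGE[, g$use_age, drop = FALSE]
    if (anyNA(A))
      stop("missing age at an age-adjusted indicator while beta.age != 0")
    M[, g$use_age] <- M[, g$use_age] + v[[g$bage_pos]] * A
  }
  bsnp <- v[g$bsnp_pos]
  lam <- v[g$lam_pos]
  if (any(bsnp * lam != 0)) {
    Gd <- g$G[, g$member, drop = FALSE]
    Gd[is.na(Gd)] <- 0
    M <- M + Gd * matrix(bsnp * lam, g$n, length(lam), byrow = TRUE)
  }
  if (!is.null(g$GB)) {
    if (v[["beta.snp.b"]] != 0)
      M <- M + g$GB[, g$member, drop = FALSE] *
        matrix(v[["beta.snp.b"]] * lam, g$n, length(lam), byrow = TRUE)
    if (v[["beta.snp.w"]] != 0)
      M <- M + g$GW[, g$member, drop = FALSE] *
        matrix(v[["beta.snp.w"]] * lam, g$n, length(lam), byrow = TRUE)
  }
  M
}

#' Full-information maximum-likelihood log-likelihood
#'
#' Sum over families of the multivariate-normal log-density of each family's
#' observed phenotype sub-vector under the model-implied mean and covariance
#' restricted to the observed entries. Returns `-Inf` when the implied
#' covariance of any configuration is not positive definite, so optimizers
#' reject such parameter values.
#'
#' @param fd A `family_data` object.
#' @param params A `model_params` object.
#' @return Scalar log-likelihood.
#' @export
fiml_loglik <- function(fd, params) {
  v <- params$values
  total <- 0
  for (g in fd$groups) {
    S <- group_cov(g, v)
    U <- tryCatch(chol(S), error = function(e) NULL)
    if (is.null(U)) return(-Inf)
    M <- group_means(g, v)
    E <- ncol(g$Y)
    W <- backsolve(U, t(g$Y - M), transpose = TRUE)
    q <- colSums(W^2)
    logdet <- 2 * sum(log(diag(U)))
    total <- total + (-0.5) * (g$n * (E * log(2 * pi) + logdet) + sum(q))
  }
  total
}

## latent correlation parameters actually identified by the data (appearing
## in at least one multi-member family configuration)
free_correlations <- function(fd) {
  rnames <- param_block(model_params(fd$schema$cohort), "correlations")
  probe <- stats::setNames(seq_along(rnames) + 100, rnames)
  used <- character(0)
  for (g in fd$groups) {
    mem <- g$design$members
    n <- nrow(mem)
    if (n < 2) next
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      val <- relative_corr(mem$role[i], mem$sex[i], mem$zygosity[i],
                           mem$role[j], mem$sex[j], probe)
      used <- c(used, names(probe)[probe == val])
    }
  }
  unique(used)
}

## measurement parameters identified by the data
free_measurement <- function(fd) {
  combos <- unique(unlist(lapply(fd$groups, function(g)
    paste(g$sex, g$lab, sep = "."))))
  labs <- unique(unlist(lapply(fd$groups, function(g) g$lab)))
  has_age <- any(vapply(fd$groups, function(g)
    any(g$use_age), TRUE))
  sexes <- unique(unlist(lapply(fd$groups, function(g) g$sex)))
  c(paste0("mu.", labs),
    if (has_age) "beta.age",
    if (length(sexes) > 1) "beta.sex",
    paste0("lambda.", combos), paste0("sigma2.", combos))
}

#' Fit the model by quasi-Newton FIML
#'
#' Maximizes [fiml_loglik()] over the designated free parameters, starting
#' from `init`. Variances are optimized on the log scale and correlations on
#' the atanh scale, so the search is unconstrained; estimates are reported on
#' the natural scale. Standard errors, when requested, come from the
#' numerically differentiated observed information at the optimum.
#'
#' @param fd A `family_data` object.
#' @param init A `model_params` object giving starting values and the values
#'   of all fixed parameters.
#' @param free Character vector of free parameter names (at least one).
#' @param se Compute observed-information standard errors (costs
#'   O(free^2) extra likelihood evaluations).
#' @param control Control list passed to [stats::nlminb()]; the default
#'   stops when the relative change in -2lnL falls below 1e-9.
#' @return An object of class `fit_result`: estimates (`params`),
#'   `minus2LL`, `n_params_free`, `free`, `convergence`, `boundary`,
#'   optional `se`.
#' @export
fit_model <- function(fd, init, free, se = FALSE,
                      control = list(rel.tol = 1e-9, iter.max = 500,
                                     eval.max = 2000)) {
  stopifnot(length(free) >= 1, all(free %in% names(init$values)))
  start <- par_to_opt(init$values[free])
  free_pos <- match(free, names(init$values))
  is_sig <- startsWith(free, "sigma2.")
  is_corr <- grepl("^(r|rho)\\.", free)
  p <- init
  obj <- function(ov) {
    nat <- ov
    nat[is_sig] <- exp(ov[is_sig])
    nat[is_corr] <- tanh(ov[is_corr])
    p$values[free_pos] <- nat
    ll <- fiml_loglik(fd, p)
    if (!is.finite(ll)) return(1e10)
    -ll
  }
  opt <- stats::nlminb(start, obj, control = control)
  est <- par_from_opt(stats::setNames(opt$par, free))
  params <- set_params(init, est)
  boundary <- any(abs(opt$par[grepl("^(r|rho)\\.", free)]) > 4) ||
    any(est[startsWith(free, "sigma2.")] < 1e-6)
  ses <- NULL
  if (se) {
    H <- fd_hessian(function(vals) {
      -fiml_loglik(fd, set_params(init, stats::setNames(vals, free)))
    }, est)
    ses <- rep(NA_real_, length(free))
    V <- tryCatch(solve(H), error = function(e) NULL)
    if (!is.null(V)) {
      d <- diag(V)
      ses[d > 0] <- sqrt(d[d > 0])
    }
    names(ses) <- free
  }
  structure(list(params = params, minus2LL = 2 * opt$objective,
                 n_params_free = length(free), free = free,
                 estimates = est, se = ses,
                 convergence = opt$convergence == 0,
                 boundary = boundary, message = opt$message),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("<fit_result> -2lnL =", format(x$minus2LL, digits = 10), "(",
      x$n_params_free, "free parameters;",
      if (x$convergence) "converged" else "NOT converged", ")\n")
  tab <- data.frame(estimate = x$estimates)
  if (!is.null(x$se)) tab$se <- x$se
  print(round(tab, 4))
  invisible(x)
}

## central-difference Hessian (no numDeriv in the stack)
fd_hessian <- function(f, x, h = NULL) {
  n <- length(x)
  if (is.null(h)) h <- pmax(abs(x), 0.1) * 1e-4
  H <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) for (j in i:n) {
    ei <- ej <- numeric(n); ei[i] <- h[i]; ej[j] <- h[j]
    H[i, j] <- H[j, i] <-
      (f(x + ei + ej) - f(x + ei - ej) - f(x - ei + ej) + f(x - ei - ej)) /
      (4 * h[i] * h[j])
  }
  H
}

#' Likelihood-ratio test of nested FIML fits
#'
#' @param full Fit with the larger free-parameter set.
#' @param reduced Fit of a nested restriction on the same data.
#' @return List with `statistic` (difference in -2lnL), `df` (difference in
#'   free-parameter counts) and `p` (central chi-square upper tail).
#' @export
lrt <- function(full, reduced) {
  stat <- reduced$minus2LL - full$minus2LL
  df <- full$n_params_free - reduced$n_params_free
  if (df <= 0) stop("'reduced' must free fewer parameters than 'full'")
  if (stat < -1e-4)
    warning("negative LRT statistic (", format(stat),
            "): the full model appears under-converged; refit advised")
  stat <- max(stat, 0)
  list(statistic = stat, df = df,
       p = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' Two-stage estimation protocol for genetic association
#'
#' Stage 1 fits the full measurement model (intercepts, covariate effects,
#' loadings, residual structure, familial correlations) on the total sample
#' without genotypes. Stage 2 fixes the loadings and residual terms at the
#' stage-1 estimates and, on the genotyped subsample, re-estimates the means,
#' covariate effects and familial correlations freely together with the
#' sex-specific SNP effects: the familial correlations must be free because
#' they vary as a function of the SNP's effect on the latent factor.
#'
#' @param total_fd `family_data` for the total sample (no genotypes needed).
#' @param geno_fd `family_data` for the genotyped subsample with a SNP
#'   attached.
#' @param init Starting `model_params`.
#' @param se Compute standard errors in stage 2.
#' @return List with elements `stage1` and `stage2` (both `fit_result`).
#' @export
two_stage_protocol <- function(total_fd, geno_fd, init, se = FALSE) {
  free1 <- c(free_measurement(total_fd), free_correlations(total_fd))
  stage1 <- fit_model(total_fd, init, free1)
  free2 <- unique(c(
    intersect(free_measurement(geno_fd),
              c(paste0("mu.", init$schema$indicators$label),
                "beta.age", "beta.sex")),
    free_correlations(geno_fd), "beta.snp.m", "beta.snp.f"))
  stage2 <- fit_model(geno_fd, stage1$params, free2, se = se)
  list(stage1 = stage1, stage2 = stage2)
}
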