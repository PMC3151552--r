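test_that("FIML equals the direct MVN oracle on complete data", {
  p <- adult_model_params(beta.snp.m = 0.2, beta.snp.f = 0.1)
  cfg <- cohort_config(data.frame(type = "DOS", parents = TRUE,
                                  brothers = 1, n = 3), "adult",
                       maf = c(s = 0.4), seed = 31)
  ped <- build_families(cfg)
  geno <- simulate_genotypes(ped, cfg$maf, seed = 31)
  phen <- simulate_phenotypes(ped, p, geno, seed = 32)
  fd <- build_family_data(ped, phen, "adult", geno, "s")
  ll <- fiml_loglik(fd, p)
  ## oracle: per family, textbook MVN density at the full implied moments
  ll_direct <- 0
  for (f in unique(ped$fid)) {
    rows <- which(ped$fid == f)
    fam <- family_design(ped$role[rows], ped$sex[rows], ped$zygosity[rows],
                         "adult",
                         ages = t(vapply(rows, function(r)
                           as.numeric(phen[match(ped$iid[r], phen$iid),
                                           paste0("age.", adult_labels)]),
                           numeric(5))),
                         dosage = geno[ped$iid[rows], "s"])
    idx <- twinfactor:::design_index(fam)
    y <- vapply(seq_len(nrow(idx)), function(e)
      phen[match(ped$iid[rows[idx$member[e]]], phen$iid),
           adult_labels[idx$ind[e]]], 0)
    ll_direct <- ll_direct +
      mvn_logdens(y, implied_mean(fam, p), implied_cov(fam, p))
  }
  expect_equal(ll, ll_direct, tolerance = 1e-8)
})

test_that("one member, one occasion reduces to a univariate normal", {
  p <- plain_adult(beta.snp.f = 0.3)
  ped <- make_ped(list(list(n = 1, roles = "twin1", sexes = "f",
                            zyg = "DZ")))
  phen <- data.frame(iid = ped$iid, ad1997 = 1.3)
  geno <- matrix(2, 1, 1, dimnames = list(ped$iid, "s"))
  fd <- build_family_data(ped, phen, "adult", geno, "s")
  v <- p$values
  mu <- v[["mu.ad1997"]] + 0.3 * v[["lambda.f.ad1997"]] * 2
  s2 <- v[["lambda.f.ad1997"]]^2 + v[["sigma2.f.ad1997"]]
  expect_equal(fiml_loglik(fd, p),
               dnorm(1.3, mu, sqrt(s2), log = TRUE))
})

test_that("deleting an entry marginalizes the likelihood", {
  p <- plain_adult()
  ped <- make_ped(list(list(n = 1, roles = c("twin1", "twin2"),
                            sexes = c("f", "f"), zyg = "MZ")))
  phen <- simulate_phenotypes(ped, p, seed = 33)
  phen$ad1995[1] <- NA  # delete one entry
  fd <- build_family_data(ped, phen, "adult")
  ll <- fiml_loglik(fd, p)
  ## oracle: MVN density with that row/column dropped from the full moments
  fam <- family_design(c("twin1", "twin2"), c("f", "f"), "MZ", "adult")
  S <- implied_cov(fam, p)
  m <- implied_mean(fam, p)
  keep <- setdiff(1:10, 2)
  y <- c(as.numeric(phen[1, adult_labels]),
         as.numeric(phen[2, adult_labels]))[keep]
  expect_equal(ll, mvn_logdens(y, m[keep], S[keep, keep]), tolerance = 1e-8)
})

test_that("log-likelihood is invariant to family and member order", {
  p <- adult_model_params()
  cfg <- cohort_config(data.frame(type = c("MZF", "DZM"),
                                  parents = c(TRUE, FALSE), n = c(4, 4)),
                       "adult", maf = c(s = 0.3), seed = 35)
  ped <- build_families(cfg)
  geno <- simulate_genotypes(ped, cfg$maf, seed = 35)
  phen <- simulate_phenotypes(ped, p, geno, seed = 36)
  fd <- build_family_data(ped, phen, "adult", geno, "s")
  shuffle <- sample(nrow(ped))
  fd2 <- build_family_data(ped[shuffle, ], phen, "adult", geno, "s")
  expect_equal(fiml_loglik(fd, p), fiml_loglik(fd2, p), tolerance = 1e-10)
})

test_that("a free mean recovers the closed-form sample mean", {
  p <- plain_adult()
  ped <- make_ped(list(list(n = 400, roles = "twin1", sexes = "f",
                            zyg = "DZ")))
  phen <- simulate_phenotypes(ped, p, seed = 37)
  phen[, setdiff(adult_labels, "ad2000")] <- NA_real_
  fd <- build_family_data(ped, phen, "adult")
  fit <- fit_model(fd, p, "mu.ad2000")
  expect_equal(unname(fit$estimates), mean(phen$ad2000), tolerance = 1e-4)
  expect_true(fit$convergence)
})

test_that("nested restrictions never beat the fuller model", {
  p <- plain_adult()
  cfg <- cohort_config(data.frame(type = "MZF", n = 60), "adult",
                       maf = c(s = 0.5), seed = 38)
  ped <- build_families(cfg)
  geno <- simulate_genotypes(ped, cfg$maf, seed = 38)
  phen <- simulate_phenotypes(ped, p, geno, seed = 39)
  fd <- build_family_data(ped, phen, "adult", geno, "s")
  full <- fit_model(fd, p, c("r.mzf", "beta.snp.f"))
  red <- fit_model(fd, p, "r.mzf")
  expect_lte(full$minus2LL, red$minus2LL + 1e-6)
  tst <- lrt(full, red)
  expect_equal(tst$df, 1)
  expect_gte(tst$p, 0)
})

test_that("SNP effect is recovered within 3 SE at 800 families", {
  beta_true <- 0.25
  p <- plain_adult(beta.snp.f = beta_true)
  cfg <- cohort_config(data.frame(type = c("MZF", "DZF"), n = c(300, 500)),
                       "adult", maf = c(s = 0.3), seed = 41)
  ped <- build_families(cfg)
  geno <- simulate_genotypes(ped, cfg$maf, seed = 41)
  phen <- simulate_phenotypes(ped, p, geno, seed = 42)
  fd <- build_family_data(ped, phen, "adult", geno, "s")
  init <- plain_adult()  # truth with beta zeroed
  fit <- fit_model(fd, init, "beta.snp.f", se = TRUE)
  expect_true(fit$convergence)
  expect_lt(abs(fit$estimates[["beta.snp.f"]] - beta_true),
            3 * fit$se[["beta.snp.f"]])
})

test_that("LRT bookkeeping: identical fits and df counting", {
  p <- plain_adult()
  ped <- make_ped(list(list(n = 40, roles = c("twin1", "twin2"),
                            sexes = c("m", "f"), zyg = "DZ")))
  geno <- simulate_genotypes(ped, c(s = 0.5), seed = 43)
  phen <- simulate_phenotypes(ped, p, geno, seed = 44)
  fd <- build_family_data(ped, phen, "adult", geno, "s")
  f1 <- fit_model(fd, p, c("r.dos", "beta.snp.m", "beta.snp.f"))
  f2 <- fit_model(fd, p, c("r.dos", "beta.snp.m", "beta.snp.f"))
  same <- lrt(f1, twinfactor::fit_model(fd, p, c("r.dos", "beta.snp.m")))
  expect_equal(same$df, 1)
  joint <- lrt(f1, fit_model(fd, p, "r.dos"))
  expect_equal(joint$df, 2)  # joint beta_m = beta_f = 0 test
  ident <- list(statistic = f1$minus2LL - f2$minus2LL)
  expect_equal(ident$statistic, 0, tolerance = 1e-6)
  expect_error(lrt(f2, f1), "fewer parameters")
})

test_that("two-stage protocol fixes loadings and recovers sex-specific effects", {
  truth <- plain_adult(beta.snp.f = 0.25, beta.snp.m = 0)
  cfg_total <- cohort_config(data.frame(type = c("MZF", "DZF", "MZM", "DZM"),
                                        n = c(120, 120, 120, 120)),
                             "adult", maf = c(s = 0.5), seed = 45)
  ped <- build_families(cfg_total)
  geno <- simulate_genotypes(ped, cfg_total$maf, seed = 45)
  phen <- simulate_phenotypes(ped, truth, geno, seed = 46)
  total_fd <- build_family_data(ped, phen, "adult")
  geno_fd <- build_family_data(ped, phen, "adult", geno, "s")
  init <- plain_adult()
  ts <- two_stage_protocol(total_fd, geno_fd, init, se = TRUE)
  lam_names <- grep("^(lambda|sigma2)", names(init$values), value = TRUE)
  ## stage 2 loadings/residuals equal stage 1 exactly (fixed by protocol)
  expect_identical(ts$stage2$params$values[lam_names],
                   ts$stage1$params$values[lam_names])
  expect_false(any(lam_names %in% ts$stage2$free))
  ## recovery of both SNP effects within 3 SE
  expect_lt(abs(ts$stage2$estimates[["beta.snp.f"]] - 0.25),
            3 * ts$stage2$se[["beta.snp.f"]])
  expect_lt(abs(ts$stage2$estimates[["beta.snp.m"]] - 0),
            3 * ts$stage2$se[["beta.snp.m"]])
  ## genotyped = total, beta = 0 in truth: stage-2 correlations stay close
  ## to the stage-1 values
  rn <- intersect(c("r.mzf", "r.dzf", "r.mzm", "r.dzm"), ts$stage2$free)
  expect_lt(max(abs(ts$stage2$params$values[rn] -
                      ts$stage1$params$values[rn])), 0.1)
})

test_that("null LRT statistics follow the chi-square reference", {
  ## joint 2-df test over null replicates: distribution matches chi2(2)
  p <- plain_adult()
  ped <- make_ped(list(list(n = 40, roles = c("twin1", "twin2"),
                            sexes = c("m", "m"), zyg = "MZ"),
                       list(n = 40, roles = c("twin1", "twin2"),
                            sexes = c("f", "f"), zyg = "MZ")))
  base <- c("mu.ad1997", "mu.ad2000", "mu.ad2002", "beta.sex",
            "r.mzm", "r.mzf")
  nrep <- 300
  stats <- numeric(nrep)
  for (r in seq_len(nrep)) {
    geno <- simulate_genotypes(ped, c(s = 0.5), seed = 5000 + r)
    phen <- simulate_phenotypes(ped, p, geno, seed = 9000 + r)
    phen[, c("ad1991", "ad1995")] <- NA_real_
    fd <- build_family_data(ped, phen, "adult", geno, "s")
    full <- fit_model(fd, p, c(base, "beta.snp.m", "beta.snp.f"))
    init_red <- full$params
    init_red$values[c("beta.snp.m", "beta.snp.f")] <- 0
    red <- fit_model(fd, init_red, base)
    stats[r] <- max(red$minus2LL - full$minus2LL, 0)
  }
  ks <- suppressWarnings(ks.test(stats, pchisq, df = 2))
  expect_gt(ks$p.value, 0.01)
})
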