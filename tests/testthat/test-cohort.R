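test_that("build_families realizes the requested configurations exactly", {
  cfg <- cohort_config(data.frame(type = "MZF", n = 10), "adult", seed = 1)
  ped <- build_families(cfg)
  expect_equal(nrow(ped), 20)
  expect_equal(length(unique(ped$fid)), 10)
  expect_true(all(ped$zygosity == "MZ"))
  expect_true(all(ped$sex == "f"))

  cfg2 <- cohort_config(data.frame(type = "DOS", parents = TRUE, n = 5),
                        "adult", seed = 1)
  ped2 <- build_families(cfg2)
  expect_equal(nrow(ped2), 20)
  tw <- ped2[ped2$role %in% c("twin1", "twin2"), ]
  sexes <- tapply(tw$sex, tw$fid, function(s) paste(sort(s), collapse = ""))
  expect_true(all(sexes == "fm"))

  ## co-twins (and siblings) always share both parent links
  cfg3 <- cohort_config(data.frame(
    type = c("MZM", "DZF", "DOS"), parents = c(TRUE, TRUE, FALSE),
    brothers = c(1, 0, 0), sisters = c(0, 2, 0), n = c(3, 3, 3)), "adult")
  ped3 <- build_families(cfg3)
  for (f in unique(ped3$fid)) {
    off <- ped3[ped3$fid == f & !ped3$role %in% c("father", "mother"), ]
    expect_equal(length(unique(off$pat)), 1)
    expect_equal(length(unique(off$mat)), 1)
  }
  expect_identical(build_families(cfg3), build_families(cfg3))
})

test_that("invalid configurations are rejected", {
  expect_error(cohort_config(data.frame(type = "MZX", n = 1), "adult"),
               "unknown family type")
  expect_error(cohort_config(data.frame(type = "MZM", parents = TRUE,
                                        n = 1), "child"),
               "twin pairs only")
  expect_error(cohort_config(data.frame(type = "MZM", n = 1), "adult",
                             maf = 0.7), "maf")
  expect_error(cohort_config(data.frame(type = "MZM", n = -1), "adult"),
               "nonnegative")
})

test_that("genotype simulation is Mendelian with MZ sharing and HWE founders", {
  cfg <- cohort_config(data.frame(type = c("MZF", "DZM"),
                                  parents = c(TRUE, TRUE),
                                  sisters = c(0, 1), n = c(400, 2100)),
                       "adult", maf = c(snp1 = 0.2), seed = 42)
  ped <- build_families(cfg)
  geno <- simulate_genotypes(ped, cfg$maf, seed = 7)

  ## MZ co-twins concordant at every SNP
  tw <- ped[ped$zygosity %in% "MZ", ]
  for (f in unique(tw$fid)) {
    ids <- tw$iid[tw$fid == f]
    expect_identical(geno[ids[1], ], geno[ids[2], ])
  }

  ## founder (parental) allele frequency: 5000 founders, 3 binomial SE
  founders <- ped$iid[ped$role %in% c("father", "mother")]
  n_founder <- length(founders)
  expect_equal(n_founder, 5000)
  fhat <- mean(geno[founders, "snp1"]) / 2
  se <- sqrt(0.2 * 0.8 / (2 * n_founder))
  expect_lt(abs(fhat - 0.2), 3 * se)

  ## DZ twin dosage correlation approximately 0.5
  dz <- ped[ped$zygosity %in% "DZ" & ped$role %in% c("twin1", "twin2"), ]
  g1 <- geno[dz$iid[dz$role == "twin1"], "snp1"]
  g2 <- geno[dz$iid[dz$role == "twin2"], "snp1"]
  r <- cor(g1, g2)
  expect_lt(abs(r - 0.5), 3 / sqrt(length(g1)))

  ## transmission is Mendelian by construction
  expect_equal(nrow(mendelian_check(ped, geno)), 0)

  ## bit-reproducible given the seed
  expect_identical(geno, simulate_genotypes(ped, cfg$maf, seed = 7))
})

test_that("latent founders keep DZ genotype correlation 0.5 without parents", {
  cfg <- cohort_config(data.frame(type = "DZM", n = 4000), "child",
                       maf = c(s = 0.3), seed = 3)
  ped <- build_families(cfg)
  geno <- simulate_genotypes(ped, cfg$maf, seed = 3)
  g1 <- geno[ped$iid[ped$role == "twin1"], "s"]
  g2 <- geno[ped$iid[ped$role == "twin2"], "s"]
  expect_lt(abs(cor(g1, g2) - 0.5), 3 / sqrt(4000))
})

test_that("phenotype simulation reproduces the implied moments", {
  ## zero loadings: observed covariances are the diagonal residual variances
  p0 <- plain_adult()
  p0$values[startsWith(names(p0$values), "lambda.")] <- 0
  cfg <- cohort_config(data.frame(type = "DZF", n = 3000), "adult")
  ped <- build_families(cfg)
  phen <- simulate_phenotypes(ped, p0, seed = 5)
  Y <- as.matrix(phen[, adult_labels])
  C <- cov(Y)
  offdiag <- C[upper.tri(C)]
  expect_lt(max(abs(offdiag)), 3 * 1 / sqrt(nrow(Y)))

  ## MZ pairs at lambda = .7, rMZ = .7: cross-twin same-occasion
  ## covariance .7 * .7 * .7 = .343
  lam <- setNames(rep(.7, 10), c(paste0("lambda.m.", adult_labels),
                                 paste0("lambda.f.", adult_labels)))
  p1 <- plain_adult(r.mzf = .7)
  p1$values[names(lam)] <- lam
  cfg1 <- cohort_config(data.frame(type = "MZF", n = 5000), "adult")
  ped1 <- build_families(cfg1)
  ph1 <- simulate_phenotypes(ped1, p1, seed = 6)
  y1 <- ph1$ad1997[match(ped1$iid[ped1$role == "twin1"], ph1$iid)]
  y2 <- ph1$ad1997[match(ped1$iid[ped1$role == "twin2"], ph1$iid)]
  expect_lt(abs(cov(y1, y2) - 0.343), 3 * 1.1 / sqrt(5000))

  ## SNP effect: male occasion-1 phenotype regressed on dosage gives
  ## beta_snp,m * lambda_1,m
  p2 <- plain_adult(beta.snp.m = 0.3)
  cfg2 <- cohort_config(data.frame(type = "MZM", n = 6000), "adult",
                        maf = c(s = 0.5))
  ped2 <- build_families(cfg2)
  g2 <- simulate_genotypes(ped2, cfg2$maf, seed = 8)
  ph2 <- simulate_phenotypes(ped2, p2, g2, seed = 9)
  fit <- lm(ph2$ad1991 ~ g2[ph2$iid, "s"])
  slope <- coef(fit)[2]
  expected <- 0.3 * p2$values[["lambda.m.ad1991"]]
  expect_lt(abs(slope - expected), 3 * summary(fit)$coefficients[2, 2])
})

test_that("child simulation matches implied_cov including residual structure", {
  p <- plain_child()
  cfg <- cohort_config(data.frame(type = c("MZM", "DOS"), n = c(5000, 5000)),
                       "child")
  ped <- build_families(cfg)
  phen <- simulate_phenotypes(ped, p, seed = 11)
  for (type in c("MZ", "DOS")) {
    sel <- if (type == "MZ") which(ped$zygosity == "MZ") else
      which(ped$zygosity == "DZ")
    pedt <- ped[sel, ]
    i1 <- match(pedt$iid[pedt$role == "twin1"], phen$iid)
    i2 <- match(pedt$iid[pedt$role == "twin2"], phen$iid)
    Y <- cbind(as.matrix(phen[i1, child_labels]),
               as.matrix(phen[i2, child_labels]))
    emp <- cov(Y)
    fam <- family_design(c("twin1", "twin2"),
                         if (type == "MZ") c("m", "m") else c("m", "f"),
                         if (type == "MZ") "MZ" else "DZ", "child")
    S <- implied_cov(fam, p)
    n <- nrow(Y)
    se <- sqrt((outer(diag(S), diag(S)) + S^2) / n)
    expect_lt(max(abs((emp - S) / se)), 3.6)  # 196 entries, fixed seed
  }
})

test_that("missingness is applied per occasion at the configured rate", {
  cfg <- cohort_config(data.frame(type = "DZF", n = 5000), "adult",
                       participation = c(ad1991 = 1, ad1995 = 0,
                                         ad1997 = 0.6, ad2000 = 1,
                                         ad2002 = 1))
  ped <- build_families(cfg)
  phen <- simulate_phenotypes(ped, plain_adult(), seed = 12)
  miss <- apply_missingness(phen, ped, cfg, seed = 13)
  expect_identical(miss$ad1991, phen$ad1991)
  expect_true(all(is.na(miss$ad1995)))
  frac <- mean(!is.na(miss$ad1997))
  expect_lt(abs(frac - 0.6), 3 * sqrt(0.6 * 0.4 / nrow(phen)))
  ## individuals stay in the pedigree even if fully missing
  expect_equal(nrow(miss), nrow(ped))
})
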