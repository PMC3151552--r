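test_that("implied means follow the SNP mean equation", {
  p <- plain_adult()
  p$values[paste0("mu.", adult_labels)] <- 0
  p$values[paste0("lambda.m.", adult_labels)] <- 0.7
  p$values[["beta.snp.m"]] <- 0.3
  fam <- family_design("twin1", "m", "DZ", "adult", dosage = 2)
  m <- implied_mean(fam, p)
  expect_equal(m, rep(0.3 * 0.7 * 2, 5))  # 0.42 per occasion

  ## g = 0 vs g = 2 differ by exactly 2 beta lambda_t
  fam0 <- family_design("twin1", "m", "DZ", "adult", dosage = 0)
  p2 <- adult_model_params(beta.snp.m = 0.25, beta.age = 0)
  fam2 <- family_design("twin1", "m", "DZ", "adult", dosage = 2)
  lam <- p2$values[paste0("lambda.m.", adult_labels)]
  expect_equal(implied_mean(fam2, p2) - implied_mean(fam0, p2),
               unname(2 * 0.25 * lam))

  ## no covariates, no SNP: mean is mu_t everywhere
  p3 <- plain_adult()
  fam3 <- family_design(c("twin1", "twin2"), c("f", "f"), "MZ", "adult")
  expect_equal(implied_mean(fam3, p3),
               rep(unname(p3$values[paste0("mu.", adult_labels)]), 2))
})

test_that("missing dosage omits the SNP term; missing age errors", {
  p <- plain_adult(beta.snp.f = 0.4)
  fam <- family_design(c("twin1", "twin2"), c("f", "f"), "MZ", "adult",
                       dosage = c(2, NA))
  m <- implied_mean(fam, p)
  lam <- unname(p$values[paste0("lambda.f.", adult_labels)])
  expect_equal(m[1:5] - m[6:10], 0.8 * lam)
  p_age <- adult_model_params(beta.age = 0.1, beta.sex = 0)
  expect_error(implied_mean(fam, p_age), "missing age")
})

test_that("implied covariance has the one-factor structure", {
  p <- plain_adult()
  fam <- family_design("twin1", "f", "DZ", "adult")
  S <- implied_cov(fam, p)
  lam <- p$values[paste0("lambda.f.", adult_labels)]
  s2 <- p$values[paste0("sigma2.f.", adult_labels)]
  ## within person: own variance lambda^2 + sigma2, cross-occasion
  ## lambda_t lambda_u
  expect_equal(diag(S), unname(lam^2 + s2))
  expect_equal(S[1, 3], unname(lam[1] * lam[3]))

  ## MZ co-twins, same occasion: lambda^2 rMZ = .7^3 when all are .7
  pm <- plain_adult(r.mzf = 0.7)
  pm$values[startsWith(names(pm$values), "lambda.")] <- 0.7
  fam2 <- family_design(c("twin1", "twin2"), c("f", "f"), "MZ", "adult")
  S2 <- implied_cov(fam2, pm)
  expect_equal(S2[1, 6], 0.343)
})

test_that("member permutation permutes the implied moments consistently", {
  p <- adult_model_params(beta.snp.m = 0.2)
  ages <- matrix(rnorm(4 * 5), 4, 5)
  fam <- family_design(c("twin1", "twin2", "father", "mother"),
                       c("m", "f", "m", "f"), c("DZ", "DZ", NA, NA),
                       "adult", ages = ages, dosage = c(0, 1, 2, 1))
  fam_rev <- family_design(rev(c("twin1", "twin2", "father", "mother")),
                           rev(c("m", "f", "m", "f")),
                           rev(c("DZ", "DZ", NA, NA)), "adult",
                           ages = ages[4:1, ], dosage = c(1, 2, 1, 0))
  S <- implied_cov(fam, p); Sr <- implied_cov(fam_rev, p)
  m <- implied_mean(fam, p); mr <- implied_mean(fam_rev, p)
  ## members: twins have 5 occasions, parents 1 -> entry blocks 5,5,1,1
  perm <- c(12, 11, 6:10, 1:5)
  expect_equal(mr, m[perm])
  expect_equal(Sr, S[perm, perm], ignore_attr = TRUE)
})

test_that("child residual structure produces rater and twin covariance", {
  p <- plain_child(rho.raters.a10 = 0.3, rho.twin.mz.a10 = 0.4,
                   rho.twin.mz.self = 0.2)
  fam <- family_design(c("twin1", "twin2"), c("m", "m"), "MZ", "child")
  S <- implied_cov(fam, p)
  idx <- attr(S, "index")
  lab <- cohort_schema("child")$indicators$label
  ent <- function(mem, l) which(idx$member == mem & idx$ind == match(l, lab))
  v <- p$values
  sd_m10 <- sqrt(v[["sigma2.m.mot10"]]); sd_f10 <- sqrt(v[["sigma2.m.fat10"]])
  lamm <- v[["lambda.m.mot10"]]; lamf <- v[["lambda.m.fat10"]]
  ## within child, mother vs father rating at age 10
  expect_equal(S[ent(1, "mot10"), ent(1, "fat10")],
               lamm * lamf + 0.3 * sd_m10 * sd_f10)
  ## cross-twin same rater at age 10: lam^2 rMZ + rho_twin * share * s2
  expect_equal(S[ent(1, "mot10"), ent(2, "mot10")],
               lamm^2 * v[["r.mzm"]] + 0.4 * 0.3 * sd_m10^2)
  ## cross-twin self-report: lam^2 rMZ + rho_twin_self * s2_self
  expect_equal(S[ent(1, "self"), ent(2, "self")],
               v[["lambda.m.self"]]^2 * v[["r.mzm"]] +
                 0.2 * v[["sigma2.m.self"]])
  ## different ages share only the factor pathway
  expect_equal(S[ent(1, "mot7"), ent(2, "fat12")],
               v[["lambda.m.mot7"]] * v[["lambda.m.fat12"]] * v[["r.mzm"]])
})

test_that("non-PSD assemblies are rejected", {
  p <- plain_adult(r.mzf = 0, r.dzf = 0.95)
  ## uncorrelated MZ twins each correlated .95 with the same sister is not
  ## a correlation structure
  fam <- family_design(c("twin1", "twin2", "sister"), c("f", "f", "f"),
                       c("MZ", "MZ", NA), "adult")
  expect_error(implied_cov(fam, p), "positive semi-definite")
  expect_error(family_design("father", "m", NA, "child"), "invalid role")
})

test_that("snp_variance_explained matches its closed form and simulation", {
  expect_equal(snp_variance_explained(0, 0.5), 0)
  expect_equal(snp_variance_explained(0.2, 0.5), 0.02 / 1.02)
  ## empirical: variance of beta * g in a large HWE founder sample
  set.seed(4)
  g <- rbinom(2e5, 2, 0.5)
  beta <- 0.2
  ve_emp <- var(beta * g) / (1 + var(beta * g))
  expect_equal(snp_variance_explained(0.2, 0.5), ve_emp, tolerance = 0.01)
  ## strictly increasing in |beta|
  ves <- vapply(seq(0.05, 1, by = 0.05),
                function(b) snp_variance_explained(b, 0.3), 0)
  expect_true(all(diff(ves) > 0))
  ## inverse round-trips
  expect_equal(snp_variance_explained(
    twinfactor:::ve_to_beta(0.023, 0.4), 0.4), 0.023)
  expect_error(snp_variance_explained(0.2, 0.7), "maf")
})

test_that("factor share of occasion variance follows the published pattern", {
  p <- adult_model_params()
  for (s in c("m", "f")) {
    lam <- p$values[paste0("lambda.", s, ".", adult_labels)]
    s2 <- p$values[paste0("sigma2.", s, ".", adult_labels)]
    share <- unname(lam^2 / (lam^2 + s2))
    expected <- if (s == "m") c(.43, .55, .62, .65, .62)
                else c(.45, .59, .64, .73, .62)
    expect_equal(share, expected, tolerance = 1e-12)
    ## rises across the first occasions, falls at the last
    expect_true(all(diff(share[1:4]) > 0))
    expect_lt(share[5], share[4])
  }
})

test_that("implied covariance equals empirical moments of a large adult sample", {
  p <- plain_adult()
  cfg <- cohort_config(data.frame(type = "DZF", parents = TRUE,
                                  n = 5000), "adult")
  ped <- build_families(cfg)
  phen <- simulate_phenotypes(ped, p, seed = 21)
  ## assemble per-family vectors: twin1, twin2 (5 occ each), father, mother
  i1 <- match(ped$iid[ped$role == "twin1"], phen$iid)
  i2 <- match(ped$iid[ped$role == "twin2"], phen$iid)
  ifa <- match(ped$iid[ped$role == "father"], phen$iid)
  imo <- match(ped$iid[ped$role == "mother"], phen$iid)
  Y <- cbind(as.matrix(phen[i1, adult_labels]),
             as.matrix(phen[i2, adult_labels]),
             phen$ad2002[ifa], phen$ad2002[imo])
  fam <- family_design(c("twin1", "twin2", "father", "mother"),
                       c("f", "f", "m", "f"), c("DZ", "DZ", NA, NA),
                       "adult")
  S <- implied_cov(fam, p)
  emp <- cov(Y)
  se <- sqrt((outer(diag(S), diag(S)) + S^2) / nrow(Y))
  expect_lt(max(abs((emp - S) / se)), 3.6)  # 144 entries, fixed seed
})
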