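#' Measurement schemas for the two cohorts
#'
#' The adult cohort has five measurement occasions (survey years 1991, 1995,
#' 1997, 2000, 2002). Twins can be measured at all five, parents only at the
#' last, siblings at the last three. The child cohort has seven indicators
#' per twin: maternal and paternal ratings at ages 7, 10 and 12 plus one
#' adolescent self-report; only twins are phenotyped.
#'
#' @param cohort `"adult"` or `"child"`.
#' @return A list with the indicator table (`indicators`), the indicator
#'   indices valid for each role (`role_indicators`), and the cohort label.
#' @export
cohort_schema <- function(cohort = c("adult", "child")) {
  cohort <- match.arg(cohort)
  if (cohort == "adult") {
    ind <- data.frame(
      label   = c("ad1991", "ad1995", "ad1997", "ad2000", "ad2002"),
      agegrp  = c("o1", "o2", "o3", "o4", "o5"),
      rater   = "self",
      use_age = TRUE,
      stringsAsFactors = FALSE
    )
    role_ind <- list(
      twin1 = 1:5, twin2 = 1:5,
      father = 5L, mother = 5L,
      brother = 3:5, sister = 3:5
    )
  } else {
    ind <- data.frame(
      label   = c("mot7", "fat7", "mot10", "fat10", "mot12", "fat12", "self"),
      agegrp  = c("a7", "a7", "a10", "a10", "a12", "a12", "self"),
      rater   = c("mother", "father", "mother", "father", "mother", "father",
                  "self"),
      use_age = c(rep(FALSE, 6), TRUE),
      stringsAsFactors = FALSE
    )
    role_ind <- list(twin1 = 1:7, twin2 = 1:7)
  }
  structure(list(cohort = cohort, indicators = ind,
                 role_indicators = role_ind),
            class = "cohort_schema")
}

par_names <- function(schema) {
  lab <- schema$indicators$label
  common <- c(paste0("mu.", lab), "beta.age", "beta.sex",
              paste0("lambda.m.", lab), paste0("lambda.f.", lab),
              paste0("sigma2.m.", lab), paste0("sigma2.f.", lab))
  if (schema$cohort == "adult") {
    rs <- c("r.mzm", "r.mzf", "r.dzm", "r.dzf", "r.dos",
            "r.fs", "r.fd", "r.ms", "r.md", "r.sp")
    extra <- character(0)
  } else {
    rs <- c("r.mzm", "r.mzf", "r.dzm", "r.dzf", "r.dos")
    ages <- c("a7", "a10", "a12")
    extra <- c(paste0("rho.raters.", ages),
               paste0("rho.twin.mz.", c(ages, "self")),
               paste0("rho.twin.dz.", c(ages, "self")))
  }
  ## beta.snp.b / beta.snp.w are the sex-free between/within-family dosage
  ## coefficients of the stratification decomposition (0 unless that model
  ## is requested)
  c(common, rs, extra, "beta.snp.m", "beta.snp.f", "beta.snp.b",
    "beta.snp.w")
}

#' Construct a model parameter set
#'
#' Holds every parameter of the one-factor longitudinal family model: occasion
#' intercepts, age and sex covariate effects, sex-specific factor loadings and
#' residual variances, latent-factor correlations between relatives, the
#' child-cohort residual correlation structure, and sex-specific additive SNP
#' effects on the latent factor. The latent factor variance is fixed to 1 for
#' identification and is not a parameter.
#'
#' @param cohort `"adult"` or `"child"`.
#' @param values Named numeric vector; unnamed parameters take the default 0
#'   (variances 1, loadings 0.7 unless supplied).
#' @return An object of class `model_params`.
#' @seealso [adult_model_params()], [child_model_params()] for parameter sets
#'   pre-filled with the published estimates.
#' @export
model_params <- function(cohort = c("adult", "child"), values = numeric(0)) {
  schema <- cohort_schema(match.arg(cohort))
  nm <- par_names(schema)
  v <- stats::setNames(numeric(length(nm)), nm)
  v[startsWith(nm, "sigma2.")] <- 1
  v[startsWith(nm, "lambda.")] <- 0.7
  if (length(values)) {
    bad <- setdiff(names(values), nm)
    if (length(bad))
      stop("unknown parameter(s): ", paste(bad, collapse = ", "))
    v[names(values)] <- values
  }
  p <- structure(list(cohort = schema$cohort, schema = schema, values = v),
                 class = "model_params")
  validate_params(p)
  p
}

#' @export
print.model_params <- function(x, ...) {
  cat("<model_params> cohort:", x$cohort, "-", length(x$values),
      "parameters\n")
  print(round(x$values, 4))
  invisible(x)
}

validate_params <- function(p) {
  v <- p$values
  corr <- v[grepl("^(r|rho)\\.", names(v))]
  if (any(abs(corr) > 1))
    stop("correlation parameters must lie in [-1, 1]")
  if (any(v[startsWith(names(v), "sigma2.")] < 0))
    stop("residual variances must be nonnegative")
  invisible(p)
}

#' Adult-cohort parameters at the published total-sample estimates
#'
#' Loadings are the square roots of the proportions of occasion variance
#' explained by the latent factor (men .43/.55/.62/.65/.62, women
#' .45/.59/.64/.73/.62 on the unit-variance normalized scale, so residual
#' variances are their complements). Latent twin correlations are .69 (MZM),
#' .70 (MZF), .31 (DZM), .30 (DZF) and .29 (DOS). Parent-offspring
#' correlations are never printed; they default to 0.30 (about the DZ level,
#' the additive expectation) and the spousal correlation to 0.
#'
#' @param ... Named parameter overrides passed to [model_params()].
#' @return A `model_params` object.
#' @export
adult_model_params <- function(...) {
  ve_m <- c(.43, .55, .62, .65, .62)
  ve_f <- c(.45, .59, .64, .73, .62)
  lab <- cohort_schema("adult")$indicators$label
  v <- c(
    stats::setNames(sqrt(ve_m), paste0("lambda.m.", lab)),
    stats::setNames(sqrt(ve_f), paste0("lambda.f.", lab)),
    stats::setNames(1 - ve_m, paste0("sigma2.m.", lab)),
    stats::setNames(1 - ve_f, paste0("sigma2.f.", lab)),
    r.mzm = .69, r.mzf = .70, r.dzm = .31, r.dzf = .30, r.dos = .29,
    r.fs = .30, r.fd = .30, r.ms = .30, r.md = .30, r.sp = 0,
    beta.age = .005, beta.sex = .30
  )
  ov <- list(...)
  if (length(ov)) v[names(ov)] <- unlist(ov)
  model_params("adult", v)
}

#' Child-cohort parameters at the published total-sample estimates
#'
#' Loadings are square roots of the printed per-indicator variance-explained
#' fractions (boys: maternal .51/.61/.55, paternal .46/.56/.53, self .06;
#' girls: maternal .52/.57/.55, paternal .46/.51/.50, self .09). Latent twin
#' correlations: .77 (MZM), .74 (MZF), .40 (DZM), .43 (DZF), .48 (DOS).
#' The residual correlation structure (rater-shared residual share per age,
#' zygosity-dependent cross-twin residual correlations) is not printed;
#' defaults are 0.20 for the rater share and 0.25/0.15 (MZ/DZ) for the
#' cross-twin residual correlations, values typical of parental-rating data.
#'
#' @param ... Named parameter overrides passed to [model_params()].
#' @return A `model_params` object.
#' @export
child_model_params <- function(...) {
  ve_m <- c(.51, .46, .61, .56, .55, .53, .06)
  ve_f <- c(.52, .46, .57, .51, .55, .50, .09)
  lab <- cohort_schema("child")$indicators$label
  v <- c(
    stats::setNames(sqrt(ve_m), paste0("lambda.m.", lab)),
    stats::setNames(sqrt(ve_f), paste0("lambda.f.", lab)),
    stats::setNames(1 - ve_m, paste0("sigma2.m.", lab)),
    stats::setNames(1 - ve_f, paste0("sigma2.f.", lab)),
    r.mzm = .77, r.mzf = .74, r.dzm = .40, r.dzf = .43, r.dos = .48,
    rho.raters.a7 = .20, rho.raters.a10 = .20, rho.raters.a12 = .20,
    rho.twin.mz.a7 = .25, rho.twin.mz.a10 = .25, rho.twin.mz.a12 = .25,
    rho.twin.mz.self = .25,
    rho.twin.dz.a7 = .15, rho.twin.dz.a10 = .15, rho.twin.dz.a12 = .15,
    rho.twin.dz.self = .15,
    beta.age = .05, beta.sex = .10
  )
  ov <- list(...)
  if (length(ov)) v[names(ov)] <- unlist(ov)
  model_params("child", v)
}

#' Names of the measurement parameters
#'
#' The measurement block (intercepts, covariate effects, loadings, residual
#' variances and the child residual correlation structure) is what the
#' two-stage protocol estimates in the total sample and then fixes in the
#' genotyped subsample; the latent familial correlations and SNP effects are
#' re-estimated there.
#'
#' @param params A `model_params` object.
#' @param what `"measurement"`, `"correlations"` or `"snp"`.
#' @return Character vector of parameter names.
#' @export
param_block <- function(params, what = c("measurement", "correlations",
                                         "snp")) {
  what <- match.arg(what)
  nm <- names(params$values)
  switch(what,
    measurement = nm[grepl("^(mu|beta\\.age|beta\\.sex|lambda|sigma2|rho)",
                           nm)],
    correlations = nm[grepl("^r\\.", nm)],
    snp = c("beta.snp.m", "beta.snp.f")
  )
}

## optimizer-scale transforms: variances on log scale, correlations on atanh
## scale, everything else untouched
par_to_opt <- function(values) {
  nm <- names(values)
  out <- values
  i <- startsWith(nm, "sigma2.")
  out[i] <- log(pmax(values[i], 1e-12))
  j <- grepl("^(r|rho)\\.", nm)
  out[j] <- atanh(pmin(pmax(values[j], -0.999999), 0.999999))
  out
}

par_from_opt <- function(values) {
  nm <- names(values)
  out <- values
  i <- startsWith(nm, "sigma2.")
  out[i] <- exp(values[i])
  j <- grepl("^(r|rho)\\.", nm)
  out[j] <- tanh(values[j])
  out
}

set_params <- function(params, values) {
  params$values[names(values)] <- values
  params
}

#' Write / read model parameters as a flat key-value text file
#'
#' @param params A `model_params` object.
#' @param path File path.
#' @return `write_params()` returns `path` invisibly; `read_params()` returns
#'   a `model_params` object.
#' @export
write_params <- function(params, path) {
  lines <- c(paste0("cohort\t", params$cohort),
             sprintf("%s\t%.17g", names(params$values), params$values))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  kv <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE,
                          col.names = c("key", "value"))
  cohort <- kv$value[kv$key == "cohort"]
  kv <- kv[kv$key != "cohort", ]
  model_params(cohort, stats::setNames(as.numeric(kv$value), kv$key))
}
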