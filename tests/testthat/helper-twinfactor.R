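## independent multivariate-normal log-density oracle: textbook formula via
## solve()/determinant(), deliberately not the chol/backsolve route the
## package likelihood uses
mvn_logdens <- function(x, mu, S) {
  k <- length(x)
  r <- x - mu
  as.numeric(-0.5 * (k * log(2 * pi) +
                       determinant(S, logarithm = TRUE)$modulus +
                       t(r) %*% solve(S) %*% r))
}

## hand-rolled pedigree of unrelated family units for fitting tests:
## spec entries are lists with n, roles, sexes, zyg
make_ped <- function(spec, prefix = "U") {
  rows <- list()
  fi <- 0L
  for (s in spec) for (i in seq_len(s$n)) {
    fi <- fi + 1L
    fid <- sprintf("%s%05d", prefix, fi)
    rows[[length(rows) + 1L]] <- data.frame(
      fid = fid, iid = paste0(fid, "_", seq_along(s$roles)),
      pat = "0", mat = "0", sex = s$sexes, role = s$roles,
      zygosity = ifelse(s$roles %in% c("twin1", "twin2"), s$zyg,
                        NA_character_),
      stringsAsFactors = FALSE)
  }
  ped <- do.call(rbind, rows)
  rownames(ped) <- NULL
  class(ped) <- c("pedigree", "data.frame")
  ped
}

## adult parameters without covariate effects (cleaner closed forms)
plain_adult <- function(...) adult_model_params(beta.age = 0, beta.sex = 0,
                                                ...)
plain_child <- function(...) child_model_params(beta.age = 0, beta.sex = 0,
                                                ...)

adult_labels <- cohort_schema("adult")$indicators$label
child_labels <- cohort_schema("child")$indicators$label
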