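## rows of `geno` to drop so that each fully genotyped MZ pair is counted
## once (the first co-twin in ID sort order is kept: a deterministic
## tie-break)
mz_duplicate_ids <- function(ped, geno, snp = NULL) {
  tw <- ped[ped$role %in% c("twin1", "twin2") &
              !is.na(ped$zygosity) & ped$zygosity == "MZ", ]
  if (!nrow(tw)) return(character(0))
  genotyped <- function(iid) {
    if (!iid %in% rownames(geno)) return(FALSE)
    gg <- geno[iid, , drop = FALSE]
    if (!is.null(snp)) gg <- gg[, snp, drop = FALSE]
    any(!is.na(gg))
  }
  drop <- character(0)
  for (f in unique(tw$fid)) {
    ids <- sort(tw$iid[tw$fid == f])
    if (length(ids) == 2 && genotyped(ids[1]) && genotyped(ids[2]))
      drop <- c(drop, ids[2])
  }
  drop
}

#' Minor allele frequency of a SNP
#'
#' Computed from the observed 0/1/2 dosages as half the mean dosage, folded
#' to the minor side. When a pedigree is supplied, each fully genotyped MZ
#' pair's shared genotype is counted once.
#'
#' @param geno Dosage matrix (individuals x SNPs, rownames = IDs).
#' @param snp SNP column name (default first).
#' @param ped Optional `pedigree` enabling MZ deduplication.
#' @return Frequency in [0, 0.5].
#' @export
maf <- function(geno, snp = colnames(geno)[1], ped = NULL) {
  g <- geno[, snp]
  if (!is.null(ped)) g <- g[!names(g) %in% mz_duplicate_ids(ped, geno, snp)]
  g <- g[!is.na(g)]
  if (!length(g)) stop("all genotypes missing for SNP ", snp)
  f <- mean(g) / 2
  min(f, 1 - f)
}

#' Flip dosage orientation so that dosages count the minor allele
#'
#' @inheritParams maf
#' @return The dosage matrix with columns at frequency > 0.5 flipped 0<->2.
#' @export
orient_minor <- function(geno, ped = NULL) {
  for (s in colnames(geno)) {
    g <- geno[, s]
    if (!is.null(ped)) g <- g[!names(g) %in% mz_duplicate_ids(ped, geno, s)]
    if (mean(g, na.rm = TRUE) / 2 > 0.5) geno[, s] <- 2 - geno[, s]
  }
  geno
}

## Wigginton-style exact Hardy-Weinberg test (two-sided, by probability
## ordering of heterozygote counts)
hwe_exact_p <- function(n0, n1, n2) {
  n_rare <- 2 * min(n0, n2) + n1
  n <- n0 + n1 + n2
  het_probs <- rep(0, n_rare + 1)
  mid <- floor(n_rare * (2 * n - n_rare) / (2 * n))
  if (mid %% 2 != n_rare %% 2) mid <- mid + 1
  het_probs[mid + 1] <- 1
  hom_r <- (n_rare - mid) / 2
  hom_c <- n - mid - hom_r
  if (mid >= 2) for (h in seq(mid, 2, by = -2)) {
    het_probs[h - 1] <- het_probs[h + 1] * h * (h - 1) /
      (4 * (hom_r + 1) * (hom_c + 1))
    hom_r <- hom_r + 1; hom_c <- hom_c + 1
  }
  hom_r <- (n_rare - mid) / 2
  hom_c <- n - mid - hom_r
  if (mid <= n_rare - 2) for (h in seq(mid, n_rare - 2, by = 2)) {
    het_probs[h + 3] <- het_probs[h + 1] * 4 * hom_r * hom_c /
      ((h + 2) * (h + 1))
    hom_r <- hom_r - 1; hom_c <- hom_c - 1
  }
  het_probs <- het_probs / sum(het_probs)
  obs <- het_probs[min(n1, n_rare) + 1]
  min(1, sum(het_probs[het_probs <= obs]))
}

#' Hardy-Weinberg equilibrium test
#'
#' One-degree-of-freedom chi-square goodness of fit of the observed genotype
#' counts against the Hardy-Weinberg proportions p^2, 2pq, q^2 (the default,
#' matching common genotype-QC practice), or an exact test. With a pedigree
#' supplied, one individual per fully genotyped MZ pair is used.
#'
#' @inheritParams maf
#' @param method `"chisq"` or `"exact"`.
#' @return List with `chi2` (NA for the exact test), `p`, and the genotype
#'   `counts`. Monomorphic SNPs return chi2 = 0, p = 1 by convention.
#' @export
hwe_test <- function(geno, snp = colnames(geno)[1], ped = NULL,
                     method = c("chisq", "exact")) {
  method <- match.arg(method)
  g <- geno[, snp]
  if (!is.null(ped)) g <- g[!names(g) %in% mz_duplicate_ids(ped, geno, snp)]
  g <- g[!is.na(g)]
  counts <- c(n0 = sum(g == 0), n1 = sum(g == 1), n2 = sum(g == 2))
  n <- sum(counts)
  if (n == 0) stop("all genotypes missing for SNP ", snp)
  monomorphic <- counts[["n1"]] == 0 &&
    (counts[["n0"]] == 0 || counts[["n2"]] == 0)
  if (monomorphic)
    return(list(chi2 = 0, p = 1, counts = counts, method = method))
  if (method == "exact")
    return(list(chi2 = NA_real_,
                p = hwe_exact_p(counts[1], counts[2], counts[3]),
                counts = counts, method = method))
  q <- (counts[["n1"]] + 2 * counts[["n2"]]) / (2 * n)
  expd <- n * c((1 - q)^2, 2 * q * (1 - q), q^2)
  ok <- expd > 0
  chi2 <- sum((counts[ok] - expd[ok])^2 / expd[ok])
  list(chi2 = chi2, p = stats::pchisq(chi2, 1, lower.tail = FALSE),
       counts = counts, method = method)
}

#' Check Mendelian consistency of genotypes in a pedigree
#'
#' Flags offspring whose dosage is impossible given both parents' observed
#' dosages (a parent with dosage 0 transmits only the major allele, a parent
#' with dosage 2 only the minor allele), and MZ co-twin pairs with
#' discordant observed genotypes (a zygosity/genotype inconsistency).
#'
#' @param ped A `pedigree`.
#' @param geno Dosage matrix.
#' @return Data frame with columns `fid`, `iid`, `snp`, `type`
#'   (`"mendelian"` or `"mz_discordance"`); zero rows when clean.
#' @export
mendelian_check <- function(ped, geno) {
  res <- list()
  dose <- function(iid, s)
    if (iid %in% rownames(geno)) geno[iid, s] else NA_real_
  possible <- function(gf, gm) {
    tr <- function(g) if (g == 0) 0L else if (g == 2) 1L else 0:1
    unique(outer(tr(gf), tr(gm), `+`))
  }
  kids <- ped[ped$pat != "0" & ped$mat != "0", ]
  for (s in colnames(geno)) {
    for (i in seq_len(nrow(kids))) {
      gc <- dose(kids$iid[i], s)
      gf <- dose(kids$pat[i], s)
      gm <- dose(kids$mat[i], s)
      if (anyNA(c(gc, gf, gm))) next
      if (!gc %in% possible(gf, gm))
        res[[length(res) + 1L]] <- data.frame(
          fid = kids$fid[i], iid = kids$iid[i], snp = s, type = "mendelian",
          stringsAsFactors = FALSE)
    }
    tw <- ped[ped$role %in% c("twin1", "twin2") &
                !is.na(ped$zygosity) & ped$zygosity == "MZ", ]
    for (f in unique(tw$fid)) {
      ids <- tw$iid[tw$fid == f]
      if (length(ids) != 2) next
      g1 <- dose(ids[1], s); g2 <- dose(ids[2], s)
      if (!anyNA(c(g1, g2)) && g1 != g2)
        res[[length(res) + 1L]] <- data.frame(
          fid = f, iid = ids[2], snp = s, type = "mz_discordance",
          stringsAsFactors = FALSE)
    }
  }
  if (!length(res))
    return(data.frame(fid = character(0), iid = character(0),
                      snp = character(0), type = character(0)))
  do.call(rbind, res)
}

#' Number of unique genotypes of one sex
#'
#' MZ co-twins share a genotype, so a sample of genotyped individuals
#' contains fewer independent genotypes than persons: the count is the
#' number of genotyped individuals of the given sex minus one per fully
#' genotyped MZ pair of that sex.
#'
#' @param ped A `pedigree`.
#' @param geno Dosage matrix.
#' @param sex `"m"` or `"f"`.
#' @param snp Restrict "genotyped" to a single SNP (default: any SNP
#'   observed).
#' @return Integer count.
#' @export
unique_genotype_count <- function(ped, geno, sex, snp = NULL) {
  gg <- if (is.null(snp)) geno else geno[, snp, drop = FALSE]
  genotyped <- rownames(gg)[rowSums(!is.na(gg)) > 0]
  n <- sum(ped$iid %in% genotyped & ped$sex == sex)
  tw <- ped[ped$role %in% c("twin1", "twin2") &
              !is.na(ped$zygosity) & ped$zygosity == "MZ" &
              ped$sex == sex, ]
  pairs <- 0L
  for (f in unique(tw$fid)) {
    ids <- tw$iid[tw$fid == f]
    if (length(ids) == 2 && all(ids %in% genotyped)) pairs <- pairs + 1L
  }
  n - pairs
}

#' Recode dosages to a recessive model
#'
#' Dosage 2 (two minor alleles) becomes 1, dosages 0 and 1 become 0, missing
#' stays missing: the recoded dosage contrasts minor-allele homozygotes
#' against everyone else.
#'
#' @param geno Dosage matrix.
#' @param snp SNP column(s) to recode (default all).
#' @return Recoded dosage matrix.
#' @export
code_recessive <- function(geno, snp = colnames(geno)) {
  for (s in snp) geno[, s] <- ifelse(is.na(geno[, s]), NA_real_,
                                     as.numeric(geno[, s] == 2))
  geno
}

#' Per-SNP and per-sample quality-control summary
#'
#' Mirrors the usual genotyping QC report: per SNP the minor allele
#' frequency, missing fraction, Hardy-Weinberg chi-square and p-value and
#' Mendelian error count; per sample the call rate. SNPs failing HWE at
#' p < 0.01 are flagged but not excluded.
#'
#' @param ped A `pedigree`.
#' @param geno Dosage matrix.
#' @param hwe_method Passed to [hwe_test()].
#' @return List of class `qc_summary` with data frames `snps` and `samples`.
#' @export
qc_summary <- function(ped, geno, hwe_method = "chisq") {
  mend <- mendelian_check(ped, geno)
  snps <- do.call(rbind, lapply(colnames(geno), function(s) {
    h <- hwe_test(geno, s, ped, method = hwe_method)
    data.frame(snp = s,
               maf = maf(geno, s, ped),
               missing = mean(is.na(geno[, s])),
               hwe_chi2 = h$chi2, hwe_p = h$p,
               mendel_errors = sum(mend$snp == s),
               hwe_flag = h$p < 0.01,
               stringsAsFactors = FALSE)
  }))
  samples <- data.frame(iid = rownames(geno),
                        call_rate = rowMeans(!is.na(geno)),
                        stringsAsFactors = FALSE)
  structure(list(snps = snps, samples = samples), class = "qc_summary")
}

#' @export
print.qc_summary <- function(x, ...) {
  cat("<qc_summary>", nrow(x$snps), "SNPs,", nrow(x$samples), "samples\n")
  print(x$snps, digits = 4)
  invisible(x)
}
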