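#' Read and write the delimited text formats of the pipeline
#'
#' The pedigree is stored PLINK-FAM-like (FID, IID, PAT, MAT, SEX with
#' 1 = male / 2 = female, plus `role` and `zygosity` columns), genotypes as
#' a tab-delimited dosage matrix (rows = individuals, columns = SNPs,
#' missing = NA), phenotypes as a wide tab-delimited table with `age.*`
#' columns. All tables round-trip losslessly.
#'
#' @param ped,geno,phen Objects to write.
#' @param path File path.
#' @name pipeline_io
NULL

#' @rdname pipeline_io
#' @export
write_pedigree <- function(ped, path) {
  out <- ped
  out$sex <- ifelse(ped$sex == "m", 1L, 2L)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_pedigree <- function(path) {
  if (!file.exists(path)) stop("pedigree file not found: ", path)
  ped <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE,
                           colClasses = list(fid = "character",
                                             iid = "character",
                                             pat = "character",
                                             mat = "character"))
  ped$sex <- ifelse(ped$sex == 1, "m", "f")
  ped$zygosity <- as.character(ped$zygosity)
  class(ped) <- c("pedigree", "data.frame")
  ped
}

#' @rdname pipeline_io
#' @export
write_dosage <- function(geno, path) {
  tab <- data.frame(iid = rownames(geno), geno, check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_dosage <- function(path) {
  if (!file.exists(path)) stop("genotype file not found: ", path)
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = list(iid = "character"))
  G <- as.matrix(tab[, -1, drop = FALSE])
  rownames(G) <- tab$iid
  G
}

#' @rdname pipeline_io
#' @export
write_phenotypes <- function(phen, path) {
  out <- phen
  num <- vapply(out, is.numeric, TRUE)
  for (j in which(num)) out[[j]] <- sprintf("%.17g", out[[j]])
  out[out == "NA"] <- NA
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_phenotypes <- function(path) {
  if (!file.exists(path)) stop("phenotype file not found: ", path)
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE,
                    colClasses = list(iid = "character"))
}

#' Import dosages from a VCF file
#'
#' Converts the GT field of a (possibly minimal) VCF into a minor-allele
#' dosage matrix via the Bioconductor VariantAnnotation reader; `./.`
#' becomes NA.
#'
#' @param path VCF file path.
#' @return Dosage matrix (individuals x SNPs).
#' @export
read_vcf_dosage <- function(path) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE))
    stop("read_vcf_dosage requires the VariantAnnotation package")
  if (!file.exists(path)) stop("VCF file not found: ", path)
  vcf <- VariantAnnotation::readVcf(path)
  gt <- VariantAnnotation::geno(vcf)$GT
  dose <- function(x) {
    if (is.na(x) || x %in% c("./.", ".")) return(NA_real_)
    sum(as.integer(strsplit(x, "[/|]")[[1]]) > 0)
  }
  G <- apply(gt, c(1, 2), dose)
  t(G)  # individuals x SNPs
}
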