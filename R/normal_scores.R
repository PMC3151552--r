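#' Rank-based normal-scores transformation
#'
#' Replaces the observed values by the expected normal order statistics of
#' their ranks (Blom's approximation, qnorm((r - 3/8) / (n + 1/4))), with
#' ties receiving the mean of their tied positions' scores, and then
#' linearly rescales to the original observed mean and standard deviation.
#' Missing entries stay missing. This reproduces the classic "normal scores"
#' treatment of skewed sum scores applied before latent-variable modeling;
#' it is computed on the pooled total sample before any subsetting to a
#' genotyped subsample.
#'
#' @param x Numeric vector with possible `NA`s; at least 3 observed values.
#' @param group Optional grouping factor: the transform is applied within
#'   each group separately (default pools everything).
#' @return Numeric vector, same length and missingness as `x`.
#' @export
normal_scores <- function(x, group = NULL) {
  if (!is.null(group)) {
    stopifnot(length(group) == length(x))
    for (gl in unique(group[!is.na(group)])) {
      i <- which(group == gl)
      x[i] <- normal_scores(x[i])
    }
    return(x)
  }
  obs <- which(!is.na(x))
  if (length(obs) < 3) stop("normal_scores needs at least 3 observed values")
  xv <- x[obs]
  if (length(unique(xv)) == 1L) {
    warning("all observed values identical; returning input unchanged")
    return(x)
  }
  n <- length(xv)
  ## mean of the tied positions' Blom scores == Blom score of the mean rank
  ## is NOT exact for ties, so average explicitly over tied positions
  ord <- order(xv)
  blom <- stats::qnorm((seq_len(n) - 3 / 8) / (n + 1 / 4))
  sc <- numeric(n)
  sc[ord] <- blom
  tied <- ave(sc, xv, FUN = mean)
  out <- tied * stats::sd(xv) / stats::sd(tied) +
    mean(xv) - mean(tied) * stats::sd(xv) / stats::sd(tied)
  x[obs] <- out
  x
}

#' Normal-score every indicator column of a wide phenotype table
#'
#' @param phen Wide phenotype table (as from [simulate_phenotypes()]).
#' @param cohort `"adult"` or `"child"` (selects the indicator columns).
#' @param group Optional grouping vector (e.g. sex) of length `nrow(phen)`.
#' @return The table with indicator columns transformed.
#' @export
normalize_phenotypes <- function(phen, cohort = "adult", group = NULL) {
  schema <- if (inherits(cohort, "cohort_schema")) cohort else
    cohort_schema(cohort)
  for (labx in schema$indicators$label)
    if (labx %in% names(phen))
      phen[[labx]] <- normal_scores(phen[[labx]], group)
  phen
}
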