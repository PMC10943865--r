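# SNP quality control and the VanRaden Method-2 genomic relationship matrix.

#' Default SNP / animal quality-control thresholds
#'
#' SNP call rate >= 0.95, minor allele frequency >= 0.05, Hardy-Weinberg
#' chi-square p-value >= 1e-8, animal call rate >= 0.90.
#'
#' @param snp_call_rate_min,maf_min,hwe_p_min,animal_call_rate_min thresholds
#'   in `[0, 1]`.
#' @return a list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(snp_call_rate_min = 0.95, maf_min = 0.05,
                          hwe_p_min = 1e-8, animal_call_rate_min = 0.90) {
  for (v in c(snp_call_rate_min, maf_min, hwe_p_min, animal_call_rate_min))
    check_scalar(v, "qc threshold", 0, 1)
  structure(list(snp_call_rate_min = snp_call_rate_min, maf_min = maf_min,
                 hwe_p_min = hwe_p_min,
                 animal_call_rate_min = animal_call_rate_min),
            class = "qc_thresholds")
}

hwe_pvalue <- function(dosage) {
  d <- dosage[!is.na(dosage)]
  n <- length(d)
  if (n == 0L) return(NA_real_)
  obs <- c(sum(d == 0), sum(d == 1), sum(d == 2))
  p <- mean(d) / 2
  expd <- n * c((1 - p)^2, 2 * p * (1 - p), p^2)
  keep <- expd > 0
  stat <- sum((obs[keep] - expd[keep])^2 / expd[keep])
  stats::pchisq(stat, df = 1, lower.tail = FALSE)
}

#' Quality-control filter for a genotype dosage matrix
#'
#' Removal order: SNP call rate, then minor allele frequency, then deviation
#' from Hardy-Weinberg proportions (1-df chi-square on genotype counts,
#' removal when p < `hwe_p_min`), then animal call rate; remaining missing
#' dosages are mean-imputed per SNP. The filter is idempotent.
#'
#' @param dosages animals x SNPs matrix with values in `{0, 1, 2, NA}` and
#'   dimnames giving animal and SNP identifiers.
#' @param thresholds a [qc_thresholds()] object.
#' @return list with `dosages` (filtered, imputed matrix), `allele_freq`
#'   (per retained SNP) and `report` (counts removed per criterion).
#' @export
qc_filter <- function(dosages, thresholds = qc_thresholds()) {
  stopifnot(is.matrix(dosages))
  bad <- !(dosages %in% c(0, 1, 2) | is.na(dosages))
  if (any(bad)) stopf("invalid dosage codes (must be 0/1/2/NA)")
  t <- thresholds
  rep <- list()

  cr_snp <- colMeans(!is.na(dosages))
  drop_cr <- cr_snp < t$snp_call_rate_min
  rep$snp_call_rate <- sum(drop_cr)
  dosages <- dosages[, !drop_cr, drop = FALSE]

  p <- colMeans(dosages, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  drop_maf <- is.na(maf) | maf < t$maf_min
  rep$maf <- sum(drop_maf)
  dosages <- dosages[, !drop_maf, drop = FALSE]

  hwe <- apply(dosages, 2L, hwe_pvalue)
  drop_hwe <- !is.na(hwe) & hwe < t$hwe_p_min
  rep$hwe <- sum(drop_hwe)
  dosages <- dosages[, !drop_hwe, drop = FALSE]

  if (ncol(dosages) == 0L) stopf("all SNPs removed by quality control")

  cr_an <- rowMeans(!is.na(dosages))
  drop_an <- cr_an < t$animal_call_rate_min
  rep$animal_call_rate <- sum(drop_an)
  dosages <- dosages[!drop_an, , drop = FALSE]
  if (nrow(dosages) == 0L) stopf("all animals removed by quality control")

  # mean-impute residual missing dosages per SNP
  if (anyNA(dosages)) {
    mu <- colMeans(dosages, na.rm = TRUE)
    idx <- which(is.na(dosages), arr.ind = TRUE)
    dosages[idx] <- mu[idx[, 2L]]
  }
  list(dosages = dosages,
       allele_freq = colMeans(dosages) / 2,
       report = rep)
}

#' Genomic relationship matrix (VanRaden Method 2)
#'
#' `G = (1/m) * sum_i z_i z_i' / (2 p_i (1 - p_i))` with `z_i = dosage_i - 2
#' p_i`: each SNP is centred by twice its observed allele frequency and
#' standardised by its expected binomial variance before averaging, so the
#' diagonal averages ~1 under Hardy-Weinberg equilibrium. Allele frequencies
#' are estimated from the current (observed) data.
#'
#' @param dosages animals x SNPs numeric matrix, no missing values (run
#'   [qc_filter()] first).
#' @return symmetric animals x animals matrix with animal ids as dimnames.
#' @export
compute_grm <- function(dosages) {
  stopifnot(is.matrix(dosages))
  if (anyNA(dosages)) stopf("missing dosages: apply qc_filter() first")
  p <- colMeans(dosages) / 2
  if (any(p <= 0 | p >= 1))
    stopf("monomorphic SNPs present (allele frequency 0 or 1): apply qc_filter() first")
  z <- sweep(dosages, 2L, 2 * p, "-")
  z <- sweep(z, 2L, sqrt(2 * p * (1 - p)), "/")
  g <- tcrossprod(z) / ncol(dosages)
  dimnames(g) <- list(rownames(dosages), rownames(dosages))
  g
}
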