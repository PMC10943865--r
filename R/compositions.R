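# Compositional processing of microbial gene (KEGG ortholog) counts:
# core-microbiome filter, geometric Bayesian-multiplicative zero replacement,
# alr reference selection and the alr transform itself.

#' Core-microbiome filter on a count table
#'
#' Keeps microbial genes (MG) with a nonzero count in at least
#' `ceil(presence_frac * n_samples)` samples. With the default 70% threshold
#' and 359 samples the cut-off is presence in 252 samples.
#'
#' @param counts samples x MG matrix of non-negative integers with dimnames.
#' @param presence_frac required presence fraction in `(0, 1]`.
#' @return list with `counts` (filtered matrix), `retained_fraction` (share of
#'   total counts kept) and `cutoff_samples`.
#' @export
filter_core_mg <- function(counts, presence_frac = 0.70) {
  stopifnot(is.matrix(counts))
  check_scalar(presence_frac, "presence_frac", .Machine$double.eps, 1)
  if (any(counts < 0)) stopf("negative counts")
  cutoff <- ceiling(presence_frac * nrow(counts))
  present <- colSums(counts > 0)
  keep <- present >= cutoff
  if (!any(keep)) stopf("core filter removed every MG (cutoff %d samples)", cutoff)
  list(counts = counts[, keep, drop = FALSE],
       retained_fraction = sum(counts[, keep]) / sum(counts),
       cutoff_samples = cutoff)
}

#' Geometric Bayesian-multiplicative zero replacement
#'
#' Converts counts to strictly positive compositions. Zeros in a sample with
#' total depth `n` are replaced by `t_j * s / (n + s)`, where `t_j` are prior
#' proportions from the column geometric means of the positive proportions and
#' `s` is the prior strength (default: square root of the mean depth). The
#' non-zero parts of the sample are multiplied by `1 - sum(replaced)` so each
#' row still sums to one; ratios between non-zero parts are unchanged.
#'
#' @param counts samples x MG count matrix, no all-zero columns (apply
#'   [filter_core_mg()] first) and no all-zero rows.
#' @param s prior strength; `NULL` for the default `sqrt(mean(depth))`.
#' @return samples x MG matrix of strictly positive proportions (rows sum to 1).
#' @export
impute_zeros_gbm <- function(counts, s = NULL) {
  stopifnot(is.matrix(counts))
  depth <- rowSums(counts)
  if (any(depth == 0)) stopf("sample(s) with all-zero counts")
  if (any(colSums(counts) == 0)) stopf("all-zero MG column(s): apply filter_core_mg() first")
  if (is.null(s)) s <- sqrt(mean(depth))
  check_scalar(s, "s", .Machine$double.eps)
  prop <- counts / depth
  # prior proportions: geometric mean of the observed positive proportions
  tj <- apply(prop, 2L, function(x) exp(mean(log(x[x > 0]))))
  tj <- tj / sum(tj)
  out <- prop
  for (i in seq_len(nrow(prop))) {
    z <- prop[i, ] == 0
    if (!any(z)) next
    repl <- tj[z] * s / (depth[i] + s)
    out[i, z] <- repl
    out[i, !z] <- prop[i, !z] * (1 - sum(repl))
  }
  out
}

#' Procrustes correlation between two sample geometries
#'
#' Both matrices are column-centred; the correlation is the sum of singular
#' values of the cross-product divided by the geometric mean of the two total
#' sums of squares: `sum(svd(A'B)$d) / sqrt(tr(A'A) * tr(B'B))`. It is 1 when
#' the configurations agree up to rotation/scaling.
#'
#' @param exact samples x D matrix (e.g. the clr geometry).
#' @param approx samples x D' matrix (e.g. an alr geometry), same row count.
#' @return a scalar in `[0, 1]`.
#' @export
procrustes_correlation <- function(exact, approx) {
  stopifnot(is.matrix(exact), is.matrix(approx))
  if (nrow(exact) != nrow(approx)) stopf("row counts differ")
  a <- center_cols(exact)
  b <- center_cols(approx)
  ssa <- sum(a^2); ssb <- sum(b^2)
  if (ssa == 0 || ssb == 0) stopf("zero-variance geometry")
  sum(svd(crossprod(a, b))$d) / sqrt(ssa * ssb)
}

clr_transform <- function(prop) {
  lp <- log(prop)
  sweep(lp, 1L, rowMeans(lp), "-")
}

#' Additive log-ratio transform
#'
#' `alr(s, j) = ln(x_sj / x_s,ref)` for every part `j` other than the
#' reference. Scale-invariant per sample, so raw positive counts and closed
#' proportions give the same result.
#'
#' @param prop samples x MG matrix of strictly positive values with column
#'   names.
#' @param ref column name (or index) of the reference part.
#' @return samples x (MG - 1) matrix of log-ratios; attribute `reference_mg`
#'   records the reference.
#' @export
alr_transform <- function(prop, ref) {
  stopifnot(is.matrix(prop))
  if (any(prop <= 0)) stopf("alr requires strictly positive entries; impute zeros first")
  if (is.character(ref)) {
    j <- match(ref, colnames(prop))
    if (is.na(j)) stopf("reference '%s' not found in table", ref)
  } else j <- as.integer(ref)
  out <- log(prop[, -j, drop = FALSE] / prop[, j])
  attr(out, "reference_mg") <- if (!is.null(colnames(prop))) colnames(prop)[j] else j
  out
}

#' Invert an alr table back to a composition
#'
#' Pads the log-ratios with a zero at the reference position and applies a
#' row-wise softmax. Exact inverse of [alr_transform()] on closed data.
#'
#' @param alr samples x (MG - 1) alr matrix (as from [alr_transform()]).
#' @param ref name of the reference part.
#' @return samples x MG matrix of proportions summing to one per row.
#' @export
alr_inverse <- function(alr, ref = attr(alr, "reference_mg")) {
  stopifnot(is.matrix(alr))
  full <- cbind(alr, 0)
  colnames(full) <- c(colnames(alr), ref)
  e <- exp(full - apply(full, 1L, max))
  e / rowSums(e)
}

#' Select the alr reference part
#'
#' Greenacre-style trade-off: a good reference (i) preserves the exact
#' log-ratio (clr) geometry of the samples -- measured by the Procrustes
#' correlation between the clr configuration and each candidate alr
#' configuration -- and (ii) has low variance in its own log relative
#' abundance, so the transformed values can be read as properties of the
#' numerator. Among candidates whose Procrustes correlation falls in the top
#' `top_quantile` share, the one with minimum log-abundance variance wins.
#'
#' @param prop samples x MG matrix of strictly positive proportions.
#' @param top_quantile share of candidates ranked best by Procrustes
#'   correlation that remain eligible (default 0.10).
#' @param candidates optional subset of column names to score (default: all).
#' @return list with `reference` (selected column name) and `diagnostics`, a
#'   data frame with `candidate_mg`, `procrustes_corr`, `logratio_variance`
#'   and `cv_percent` (100 * sd/|mean| of the log relative abundance).
#' @export
select_alr_reference <- function(prop, top_quantile = 0.10, candidates = NULL) {
  stopifnot(is.matrix(prop))
  if (ncol(prop) < 3L) stopf("need at least 3 parts to choose a reference")
  if (any(prop <= 0)) stopf("strictly positive proportions required")
  if (is.null(colnames(prop))) colnames(prop) <- paste0("MG", seq_len(ncol(prop)))
  if (is.null(candidates)) candidates <- colnames(prop)
  clr <- clr_transform(prop)
  lp <- log(prop)
  diag_df <- do.call(rbind, lapply(candidates, function(cand) {
    a <- alr_transform(prop, cand)
    v <- stats::var(lp[, cand])
    m <- mean(lp[, cand])
    data.frame(candidate_mg = cand,
               procrustes_corr = procrustes_correlation(clr, a),
               logratio_variance = v,
               cv_percent = 100 * sqrt(v) / abs(m),
               stringsAsFactors = FALSE)
  }))
  thr <- stats::quantile(diag_df$procrustes_corr, probs = 1 - top_quantile,
                         names = FALSE, type = 7)
  eligible <- diag_df[diag_df$procrustes_corr >= thr, ]
  sel <- eligible$candidate_mg[which.min(eligible$logratio_variance)]
  list(reference = sel, diagnostics = diag_df)
}
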