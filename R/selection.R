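# Candidate filtering and round-robin forward-AIC selection of the microbial
# trait subsets used in genomic evaluation.

#' Filter candidate alr-MG for breeding use
#'
#' Keeps microbial traits with a non-zero genomic correlation (`P0 >=
#' p0_min`) with at least one ADG trait AND mean relative abundance of the
#' numerator at or above `min_rel_abundance` (0.001% = 1e-5 as a proportion).
#' Both bounds are inclusive.
#'
#' @param catalog data frame as produced by [scan_mg_adg_correlations()]
#'   (`mg_id`, `adg_trait`, `p0`, `rel_abundance` columns).
#' @param p0_min evidence threshold (default 0.85).
#' @param min_rel_abundance abundance threshold as a proportion (default 1e-5).
#' @return character vector of candidate MG ids.
#' @export
filter_candidates <- function(catalog, p0_min = 0.85, min_rel_abundance = 1e-5) {
  ab <- tapply(catalog$rel_abundance, catalog$mg_id, function(x) x[1L])
  p0max <- tapply(catalog$p0, catalog$mg_id, max)
  ids <- names(p0max)[p0max >= p0_min &
                        (is.na(ab[names(p0max)]) | ab[names(p0max)] >= min_rel_abundance)]
  if (length(ids) == 0L) stopf("no candidate MG passes the filters")
  sort(ids)
}

#' Restrict candidates to those with a sign-uniform rg across all four ADG traits
#'
#' Keeps MG whose four rg posterior medians all share one sign, regardless of
#' magnitude; an exact-zero median cannot assert a sign and excludes the MG.
#'
#' @param candidates character vector of MG ids.
#' @param catalog catalog with `mg_id`, `adg_trait`, `rg_median`.
#' @return restricted character vector.
#' @export
uniform_sign_subset <- function(candidates, catalog) {
  keep <- vapply(candidates, function(id) {
    rg <- catalog$rg_median[catalog$mg_id == id]
    length(rg) == 4L && (all(rg > 0) || all(rg < 0))
  }, logical(1))
  candidates[keep]
}

adj_r2_of <- function(y, Xmat) {
  n <- length(y)
  fit <- stats::lm.fit(cbind(1, Xmat), y)
  rss <- sum(fit$residuals^2)
  tss <- sum((y - mean(y))^2)
  1 - (rss / (n - fit$rank)) / (tss / (n - 1))
}

aic_of <- function(y, Xmat) {
  n <- length(y)
  fit <- stats::lm.fit(cbind(1, Xmat), y)
  rss <- sum(fit$residuals^2)
  n * log(rss / n) + 2 * (fit$rank + 1)
}

#' Round-robin forward-AIC selection of microbial traits
#'
#' Cycles over ADG_1 -> ADG_2 -> ADG_3 -> ADG_4 repeatedly. At each step the
#' dependent variable is the current trait's GEBV; the predictors are the
#' other three ADG GEBV, all previously selected MG GEBV, and one candidate.
#' The candidate giving the lowest `AIC = n log(RSS/n) + 2k` is added
#' (ties broken by MG id order), until `4 * quota_per_trait` are selected.
#'
#' @param gebv_adg animals x 4 matrix of ADG GEBV (from univariate fits).
#' @param gebv_mg animals x candidates matrix of MG GEBV, columns named by
#'   MG id.
#' @param quota_per_trait selections attributed to each ADG trait (default 8).
#' @param label subset label stored in the result.
#' @return list of class `selection_result`: `selected` (ordered ids),
#'   `attribution` (trait per step), `trace` (step, trait, mg_id, aic),
#'   `adj_r2` (per ADG trait, final model), `label`. Issues a warning and
#'   returns a partial result if candidates run out.
#' @export
stepwise_select <- function(gebv_adg, gebv_mg, quota_per_trait = 8,
                            label = "non-uniform") {
  stopifnot(is.matrix(gebv_adg), ncol(gebv_adg) == 4L, is.matrix(gebv_mg))
  traits <- colnames(gebv_adg) %||% paste0("ADG_", 1:4)
  cand <- sort(colnames(gebv_mg))
  target <- 4L * quota_per_trait
  if (length(cand) < target)
    warnf("only %d candidates for %d selection slots", length(cand), target)
  selected <- character(0)
  trace <- list()
  step <- 0L
  while (length(selected) < target && length(cand) > 0L) {
    k <- (step %% 4L) + 1L
    y <- gebv_adg[, k]
    base <- cbind(gebv_adg[, -k, drop = FALSE],
                  gebv_mg[, selected, drop = FALSE])
    aics <- vapply(cand, function(id)
      aic_of(y, cbind(base, gebv_mg[, id])), numeric(1))
    best <- cand[which.min(aics)]         # which.min takes the first = id order
    selected <- c(selected, best)
    cand <- setdiff(cand, best)
    step <- step + 1L
    trace[[step]] <- data.frame(step = step, trait = traits[k], mg_id = best,
                                aic = min(aics), stringsAsFactors = FALSE)
  }
  if (length(selected) < target)
    warnf("candidate pool exhausted: %d of %d selected", length(selected), target)
  attribution <- rep(traits, length.out = length(selected))
  adj_r2 <- vapply(1:4, function(k)
    adj_r2_of(gebv_adg[, k], cbind(gebv_adg[, -k, drop = FALSE],
                                   gebv_mg[, selected, drop = FALSE])),
    numeric(1))
  names(adj_r2) <- traits
  structure(list(selected = selected, attribution = attribution,
                 trace = do.call(rbind, trace), adj_r2 = adj_r2, label = label),
            class = "selection_result")
}
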