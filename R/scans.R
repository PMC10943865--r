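# Estimation campaign: per-MG heritability scan, MG x ADG genomic-correlation
# scan, ADG genetic parameters from pairwise bivariate models, permutation
# null for h2, and prior sensitivity.

#' Heritability scan over alr-transformed microbial traits
#'
#' Fits one univariate genomic animal model per alr-MG column. Each model
#' gets its own seed derived from the master seed and the MG identifier, so
#' the scan is order-independent and resumable. Chains with |Geweke Z| > 3 or
#' failing the MCSE check are flagged, not dropped.
#'
#' @param alr samples x MG matrix of alr values (animals in rows, aligned
#'   with `grm`).
#' @param grm genomic relationship matrix over the rows of `alr`.
#' @param fixed factor (or level vector) of the combined fixed effect.
#' @param prior a [prior_spec()]; @param mcmc an [mcmc_settings()] (its seed
#'   is the master seed).
#' @param mg_ids subset of columns to scan (default all).
#' @return data frame, one row per MG: h2 posterior summary columns plus
#'   `converged`.
#' @export
scan_mg_heritability <- function(alr, grm, fixed, prior = prior_spec(),
                                 mcmc = mcmc_settings(), mg_ids = colnames(alr)) {
  stopifnot(is.matrix(alr))
  if (nrow(alr) != nrow(grm)) stopf("alr rows (%d) do not match GRM order (%d)",
                                    nrow(alr), nrow(grm))
  out <- lapply(mg_ids, function(id) {
    m2 <- mcmc; m2$seed <- derive_seed(mcmc$seed, id)
    fit <- gibbs_sample(alr[, id], fixed, grm, prior = prior, mcmc = m2)
    par <- derive_genetic_parameters(fit)
    s <- par$h2_summary
    data.frame(mg_id = id, h2_median = s$median, h2_hpd_low = s$hpd95_low,
               h2_hpd_high = s$hpd95_high, h2_sd = s$sd,
               geweke_z = s$geweke_z, mcse_ok = s$mcse_ok,
               converged = is.na(s$geweke_z) || abs(s$geweke_z) <= 3,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Genomic-correlation scan between microbial traits and the four ADG traits
#'
#' Fits 4 bivariate models per alr-MG (one against each ADG trait) and
#' catalogues the rg posterior median, HPD95 interval and P0, flagging the
#' correlation as non-zero when `P0 >= p0_threshold`. Also records the MG's
#' h2 (from the bivariate fits, pooled) and, when `rel_abundance` is given,
#' the mean relative abundance of the MG numerator.
#'
#' @param alr samples x MG alr matrix; @param adg matching animals x 4 ADG
#'   matrix; @param grm,fixed,prior,mcmc as in [scan_mg_heritability()].
#' @param p0_threshold evidence threshold for a non-zero rg (default 0.85).
#' @param rel_abundance optional named vector of mean relative abundances of
#'   the MG numerators (proportions).
#' @param mg_ids subset of MG columns to scan.
#' @return list with `catalog` (one row per MG x ADG pair) and
#'   `n_nonzero_per_adg`.
#' @export
scan_mg_adg_correlations <- function(alr, adg, grm, fixed,
                                     prior = prior_spec(), mcmc = mcmc_settings(),
                                     p0_threshold = 0.85, rel_abundance = NULL,
                                     mg_ids = colnames(alr)) {
  stopifnot(is.matrix(alr), is.matrix(adg), ncol(adg) == 4L)
  if (nrow(alr) != nrow(adg)) stopf("alr and adg row counts differ")
  rows <- list()
  for (id in mg_ids) {
    for (k in 1:4) {
      m2 <- mcmc; m2$seed <- derive_seed(mcmc$seed, paste0(id, ":ADG", k))
      y <- cbind(adg[, k], alr[, id])
      colnames(y) <- c(colnames(adg)[k], id)
      fit <- gibbs_sample(y, fixed, grm, prior = prior, mcmc = m2)
      par <- derive_genetic_parameters(fit)
      rs <- par$rg_summary
      h2mg <- par$h2_summary[2L, ]
      rows[[paste(id, k)]] <- data.frame(
        mg_id = id, adg_trait = colnames(adg)[k],
        rg_median = rs$median, rg_hpd_low = rs$hpd95_low,
        rg_hpd_high = rs$hpd95_high, p0 = rs$p0,
        nonzero = rs$p0 >= p0_threshold,
        h2_mg_median = h2mg$median,
        rel_abundance = if (!is.null(rel_abundance)) rel_abundance[[id]] else NA_real_,
        converged = is.na(rs$geweke_z) || abs(rs$geweke_z) <= 3,
        stringsAsFactors = FALSE)
    }
  }
  catalog <- do.call(rbind, rows)
  rownames(catalog) <- NULL
  list(catalog = catalog,
       n_nonzero_per_adg = tapply(catalog$nonzero, catalog$adg_trait, sum))
}

#' Genetic parameters of the four ADG traits from six bivariate models
#'
#' Fits the six pairwise bivariate models among the ADG traits. Each trait's
#' h2 posterior is the pooled (concatenated) thinned h2 chain from the three
#' bivariates involving it; rg is summarised per pair.
#'
#' @param adg animals x 4 ADG matrix; @param grm,fixed,prior,mcmc as above.
#' @return list with `h2_summary` (4 rows), `rg_summary` (6 rows),
#'   `h2_chains` (pooled, per trait), `G_pairs` and `R_pairs` (per-pair 2x2
#'   posterior-median and posterior-sd covariance blocks, the raw material of
#'   covariance assembly).
#' @export
estimate_adg_parameters <- function(adg, grm, fixed, prior = prior_spec(),
                                    mcmc = mcmc_settings()) {
  stopifnot(is.matrix(adg), ncol(adg) == 4L)
  traits <- colnames(adg) %||% paste0("ADG_", 1:4)
  colnames(adg) <- traits
  pairs <- utils::combn(4L, 2L)
  h2_chains <- rep(list(NULL), 4L)
  rg_rows <- list(); G_pairs <- list(); R_pairs <- list()
  for (m in seq_len(ncol(pairs))) {
    i <- pairs[1L, m]; j <- pairs[2L, m]
    m2 <- mcmc; m2$seed <- derive_seed(mcmc$seed, paste0(traits[i], "x", traits[j]))
    fit <- gibbs_sample(adg[, c(i, j)], fixed, grm, prior = prior, mcmc = m2)
    par <- derive_genetic_parameters(fit)
    h2_chains[[i]] <- c(h2_chains[[i]], par$h2[, 1L])
    h2_chains[[j]] <- c(h2_chains[[j]], par$h2[, 2L])
    rs <- par$rg_summary
    rg_rows[[m]] <- cbind(data.frame(pair = paste(traits[i], traits[j], sep = ":")),
                          rs[, -1L])
    med <- function(ch) apply(ch, 2L, stats::median)
    sdv <- function(ch) apply(ch, 2L, stats::sd)
    blk <- function(v) matrix(c(v["1.1"], v["1.2"], v["1.2"], v["2.2"]), 2L, 2L,
                              dimnames = list(traits[c(i, j)], traits[c(i, j)]))
    G_pairs[[m]] <- list(traits = traits[c(i, j)],
                         median = blk(med(fit$G_chain)), se = blk(sdv(fit$G_chain)))
    R_pairs[[m]] <- list(traits = traits[c(i, j)],
                         median = blk(med(fit$R_chain)), se = blk(sdv(fit$R_chain)))
  }
  h2_summary <- do.call(rbind, lapply(1:4, function(k) {
    cbind(data.frame(trait = traits[k]), summarize_posterior(h2_chains[[k]]))
  }))
  list(h2_summary = h2_summary, rg_summary = do.call(rbind, rg_rows),
       h2_chains = stats::setNames(h2_chains, traits),
       G_pairs = G_pairs, R_pairs = R_pairs)
}

#' Permutation null distribution of a heritability estimate
#'
#' Breaks the genotype-phenotype link by permuting the phenotype vector
#' across animals (the fixed-effect design stays aligned with the genotypes;
#' set `permute_fixed = TRUE` to carry the fixed-effect rows along), then
#' re-estimates h2 per permutation.
#'
#' @param y phenotype vector; @param grm,fixed,prior,mcmc as above.
#' @param n_perm number of permutations.
#' @param permute_fixed carry fixed-effect assignment with the phenotype.
#' @param seed permutation seed (the model seed comes from `mcmc`).
#' @return list with `observed` (h2 median on unpermuted data) and
#'   `null_h2_medians` (length `n_perm`).
#' @export
permutation_null <- function(y, grm, fixed, n_perm = 1000,
                             prior = prior_spec(), mcmc = mcmc_settings(),
                             permute_fixed = FALSE, seed = 1) {
  check_scalar(n_perm, "n_perm", 1)
  h2_of <- function(yy, ff, s) {
    m2 <- mcmc; m2$seed <- s
    fit <- gibbs_sample(yy, ff, grm, prior = prior, mcmc = m2)
    stats::median(derive_genetic_parameters(fit)$h2[, 1L])
  }
  observed <- h2_of(y, fixed, mcmc$seed)
  null_meds <- vapply(seq_len(n_perm), function(b) {
    set.seed(derive_seed(seed, paste0("perm", b)))
    idx <- sample.int(length(y))
    ff <- if (permute_fixed) fixed[idx] else fixed
    h2_of(y[idx], ff, derive_seed(mcmc$seed, paste0("fit", b)))
  }, numeric(1))
  list(observed = observed, null_h2_medians = null_meds)
}

#' Prior-sensitivity reruns over prior degrees of freedom
#'
#' Re-fits a model for each prior df0 value, recomputing the prior scale via
#' [compute_prior_scale()] each time, and tabulates the posterior medians.
#'
#' @param y phenotype vector or matrix; @param grm,fixed,mcmc as above.
#' @param df0_list genomic-prior df values (univariate default 1, 5, 10, 20;
#'   use e.g. 2, 3, 10, 20 for bivariate models).
#' @param R2 prior proportion of variance explained.
#' @return data frame: `df0`, `h2_median` per trait and (if multivariate)
#'   `rg_median` per pair.
#' @export
prior_sensitivity <- function(y, grm, fixed, df0_list = c(1, 5, 10, 20),
                              mcmc = mcmc_settings(), R2 = 0.5) {
  rows <- lapply(df0_list, function(df0) {
    fit <- gibbs_sample(y, fixed, grm,
                        prior = prior_spec(df0_genomic = df0, R2 = R2),
                        mcmc = mcmc)
    par <- derive_genetic_parameters(fit)
    h2 <- apply(par$h2, 2L, stats::median)
    row <- data.frame(df0 = df0)
    for (k in seq_along(h2)) row[[paste0("h2_", colnames(par$h2)[k])]] <- h2[k]
    if (!is.null(par$rg))
      for (k in seq_len(ncol(par$rg)))
        row[[paste0("rg_", colnames(par$rg)[k])]] <- stats::median(par$rg[, k])
    row
  })
  do.call(rbind, rows)
}
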