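# Assembly of multi-trait genomic and residual covariance matrices from
# pairwise bivariate estimates, and bending to positive definiteness.

#' Assemble a t x t covariance matrix from pairwise 2 x 2 estimates
#'
#' Off-diagonal entries come from the unique bivariate model that estimated
#' the pair; diagonal entries are the arithmetic mean of the trait's variance
#' estimates across all models that include it. Each pair must be covered
#' exactly once.
#'
#' @param pairs list of pairwise estimates; each element is a list with
#'   `traits` (length-2 character) and `median` (2 x 2 matrix), optionally
#'   `se` (2 x 2 posterior sds).
#' @param trait_order character vector giving the trait order of the result.
#' @return list with `matrix` (t x t symmetric), `se` (t x t, NA where no SE
#'   was supplied) and `n_models` per trait.
#' @export
assemble_covariances <- function(pairs, trait_order) {
  t <- length(trait_order)
  M <- matrix(NA_real_, t, t, dimnames = list(trait_order, trait_order))
  SE <- M
  diag_vals <- stats::setNames(rep(list(numeric(0)), t), trait_order)
  diag_ses <- diag_vals
  for (pr in pairs) {
    ij <- match(pr$traits, trait_order)
    if (anyNA(ij)) stopf("pair (%s) has traits outside trait_order",
                         paste(pr$traits, collapse = ", "))
    i <- ij[1L]; j <- ij[2L]
    if (!is.na(M[i, j])) stopf("pair (%s, %s) covered more than once",
                               trait_order[i], trait_order[j])
    M[i, j] <- M[j, i] <- pr$median[1L, 2L]
    if (!is.null(pr$se)) SE[i, j] <- SE[j, i] <- pr$se[1L, 2L]
    diag_vals[[i]] <- c(diag_vals[[i]], pr$median[1L, 1L])
    diag_vals[[j]] <- c(diag_vals[[j]], pr$median[2L, 2L])
    if (!is.null(pr$se)) {
      diag_ses[[i]] <- c(diag_ses[[i]], pr$se[1L, 1L])
      diag_ses[[j]] <- c(diag_ses[[j]], pr$se[2L, 2L])
    }
  }
  miss <- which(is.na(M) & upper.tri(M), arr.ind = TRUE)
  if (nrow(miss) > 0L)
    stopf("missing pairwise estimate(s): %s",
          paste(apply(miss, 1L, function(ij)
            paste0("(", trait_order[ij[1L]], ", ", trait_order[ij[2L]], ")")),
            collapse = ", "))
  n_models <- vapply(diag_vals, length, integer(1))
  if (any(n_models == 0L))
    stopf("trait(s) with no variance estimate: %s",
          paste(trait_order[n_models == 0L], collapse = ", "))
  diag(M) <- vapply(diag_vals, mean, numeric(1))
  diag(SE) <- vapply(diag_ses, function(v) if (length(v)) mean(v) else NA_real_,
                     numeric(1))
  list(matrix = M, se = SE, n_models = n_models)
}

#' Bend a symmetric matrix to positive definiteness by eigenvalue flooring
#'
#' Eigendecomposes, floors all eigenvalues at `min_eig`, and reconstructs.
#' Eigenvectors are unchanged and the operation is idempotent; matrices whose
#' smallest eigenvalue already exceeds the floor are returned untouched.
#'
#' @param M symmetric matrix.
#' @param min_eig eigenvalue floor (default 1e-3).
#' @return list with `matrix` (bent), `report` (min eigenvalue before/after,
#'   max absolute entrywise change, `bent` flag).
#' @export
bend_matrix <- function(M, min_eig = 1e-3) {
  if (!is_symmetric(M)) stopf("bend_matrix requires a symmetric matrix")
  e <- eigen((M + t(M)) / 2, symmetric = TRUE)
  min_before <- min(e$values)
  if (min_before >= min_eig) {
    return(list(matrix = M,
                report = list(min_eig_before = min_before,
                              min_eig_after = min_before,
                              max_change = 0, bent = FALSE)))
  }
  vals <- pmax(e$values, min_eig)
  B <- e$vectors %*% (vals * t(e$vectors))
  B <- (B + t(B)) / 2
  dimnames(B) <- dimnames(M)
  list(matrix = B,
       report = list(min_eig_before = min_before,
                     min_eig_after = min(eigen(B, symmetric = TRUE,
                                               only.values = TRUE)$values),
                     max_change = max(abs(B - M)), bent = TRUE))
}

#' Validate a bent genomic covariance matrix
#'
#' Two checks, both inclusive: (i) no entry moved by more than its posterior
#' standard error; (ii) no trait's heritability (against the supplied
#' residual variances) shifted by more than `h2_tolerance` relative to its
#' pre-bending value.
#'
#' @param original,bent t x t genomic covariance matrices.
#' @param posterior_se t x t matrix of posterior standard errors (NA entries
#'   are skipped).
#' @param residual_diag residual variances per trait (for h2).
#' @param h2_tolerance maximum relative h2 shift (default 0.05).
#' @return list with `entry_ok` (logical matrix), `h2_shift` (per trait),
#'   `h2_ok`, and overall `pass`.
#' @export
validate_bending <- function(original, bent, posterior_se, residual_diag,
                             h2_tolerance = 0.05) {
  stopifnot(all(dim(original) == dim(bent)))
  entry_ok <- abs(bent - original) <= posterior_se
  entry_ok[is.na(posterior_se)] <- NA
  h2_orig <- diag(original) / (diag(original) + residual_diag)
  h2_bent <- diag(bent) / (diag(bent) + residual_diag)
  h2_shift <- ifelse(h2_orig == 0, 0, abs(h2_bent - h2_orig) / abs(h2_orig))
  h2_ok <- h2_shift <= h2_tolerance
  list(entry_ok = entry_ok, h2_shift = h2_shift, h2_ok = h2_ok,
       pass = all(entry_ok, na.rm = TRUE) && all(h2_ok))
}
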