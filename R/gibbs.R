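# Gibbs sampler for uni- and multivariate genomic animal models
#
#   y = Xb + u + e,   u ~ N(0, G (x) K),   e ~ N(0, R (x) I)
#
# with K a genomic relationship matrix, flat priors on b, scaled-inverse
# chi-square / inverse-Wishart priors on the (co)variances, and data
# augmentation for missing phenotypes. A one-time eigendecomposition of K
# plus, per iteration, a joint diagonalisation of (G, R) reduce the breeding
# value update to elementwise operations, which makes scans over thousands of
# microbial traits feasible.

#' Prior specification for the genomic model
#'
#' Defaults mirror common Bayesian GBLUP practice: prior degrees of freedom 5
#' for residual (co)variances, 5 for the genomic variance in univariate models
#' and 3 for the genomic (co)variance matrix in multivariate models; prior
#' scales are derived from the phenotypic variance via [compute_prior_scale()]
#' with `R2 = 0.5` unless given explicitly.
#'
#' @param df0_genomic prior df for the genomic (co)variance; `NULL` selects 5
#'   (univariate) or 3 (multivariate) at fit time.
#' @param df0_residual prior df for the residual (co)variance.
#' @param S0_g,S0_r optional prior scales (scalar or t x t matrix); computed
#'   from the data when `NULL`.
#' @param R2 a-priori proportion of variance explained, used when deriving
#'   scales from the phenotypic variance.
#' @return list of class `prior_spec`.
#' @export
prior_spec <- function(df0_genomic = NULL, df0_residual = 5,
                       S0_g = NULL, S0_r = NULL, R2 = 0.5) {
  if (!is.null(df0_genomic)) check_scalar(df0_genomic, "df0_genomic", 1e-8)
  check_scalar(df0_residual, "df0_residual", 1e-8)
  check_scalar(R2, "R2", 0, 1)
  structure(list(df0_genomic = df0_genomic, df0_residual = df0_residual,
                 S0_g = S0_g, S0_r = S0_r, R2 = R2),
            class = "prior_spec")
}

#' MCMC run-length settings
#'
#' @param n_iter total iterations; @param burn_in discarded iterations;
#' @param thin keep one draw in `thin`; @param seed RNG seed.
#' @return list of class `mcmc_settings`.
#' @export
mcmc_settings <- function(n_iter = 5000, burn_in = 1000, thin = 5, seed = 1) {
  check_scalar(n_iter, "n_iter", 1)
  check_scalar(burn_in, "burn_in", 0)
  check_scalar(thin, "thin", 1)
  if (burn_in >= n_iter) stopf("burn_in (%d) must be < n_iter (%d)", burn_in, n_iter)
  structure(list(n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
                 thin = as.integer(thin), seed = as.integer(seed)),
            class = "mcmc_settings")
}

#' Prior scale from the phenotypic variance
#'
#' `S0 = var(Y) * (df0 + n_traits + 1) * R2`: the scale that makes the prior
#' mode of the (co)variance equal to `R2` times the phenotypic variance.
#'
#' @param varY phenotypic variance (scalar) or covariance matrix.
#' @param df0 prior degrees of freedom.
#' @param n_traits number of traits in the model.
#' @param R2 a-priori proportion of variance explained (default 0.5).
#' @return scalar or matrix prior scale.
#' @export
compute_prior_scale <- function(varY, df0, n_traits, R2 = 0.5) {
  check_scalar(df0, "df0", 1e-8)
  check_scalar(R2, "R2", 0, 1)
  if (is.matrix(varY)) {
    ev <- eigen(varY, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 0 && R2 > 0) stopf("varY must be positive definite")
  } else if (varY <= 0 && R2 > 0) stopf("varY must be positive")
  varY * (df0 + n_traits + 1) * R2
}

#' Draw genomic variances from their scaled-inverse-chi-square full conditional
#'
#' Given the current breeding values, the univariate genomic (or residual)
#' variance has full conditional `(quad + df0 * S0) / chisq(df0 + q)`, where
#' `quad` is the relevant quadratic form (`u' K^-1 u` or `e'e`) and `q` the
#' number of effects. This is the exact draw the univariate sampler performs;
#' it is exposed so the conditional can be validated against its closed form.
#'
#' @param quad quadratic form of the current effects.
#' @param q number of effect levels contributing to `quad`.
#' @param df0,S0 prior degrees of freedom and scale.
#' @param n number of draws.
#' @return numeric vector of `n` variance draws.
#' @export
sample_variance_conditional <- function(quad, q, df0, S0, n = 1) {
  check_scalar(quad, "quad", 0)
  (quad + df0 * S0) / stats::rchisq(n, df = df0 + q)
}

riwish <- function(df, S) {
  solve(stats::rWishart(1L, df, solve(S))[, , 1L])
}

# Group rows of a missingness mask into patterns; returns list of groups
# with row indices and missing/observed trait indices.
missing_patterns <- function(mask) {
  key <- apply(mask, 1L, paste, collapse = "")
  lapply(split(seq_len(nrow(mask)), key), function(rows) {
    m <- mask[rows[1L], ]
    list(rows = rows, mis = which(m), obs = which(!m))
  })
}

#' Gibbs sampler for the multi-trait genomic animal model
#'
#' Fits `y = Xb + u + e` with `u ~ N(0, G (x) K)` and `e ~ N(0, R (x) I)` by
#' Gibbs sampling. Fixed effects get flat priors; genomic and residual
#' (co)variances get scaled-inverse-chi-square (univariate) or inverse-Wishart
#' (multivariate) priors, or are held fixed when `fixed_covariances` is given
#' (the GBLUP evaluation mode). Missing phenotypes are imputed by data
#' augmentation from their conditional normal, so animals with genotypes but
#' no records (e.g. sires) receive breeding values.
#'
#' The breeding-value update is accelerated by a one-time eigendecomposition
#' `K = V D V'` and a per-iteration joint diagonalisation of (G, R), after
#' which every animal x trait coordinate is conditionally independent.
#'
#' @param y numeric vector (univariate) or animals x traits matrix with `NA`
#'   for missing records; rows must align with `grm`.
#' @param X fixed-effect design: a factor (one level set shared by all
#'   traits) or a full-column-rank incidence matrix.
#' @param grm symmetric genomic relationship matrix over the rows of `y`. A
#'   numerically singular matrix is jittered by +1e-6 on its eigenvalues.
#' @param prior a [prior_spec()].
#' @param mcmc an [mcmc_settings()].
#' @param fixed_covariances optional `list(G = , R = )` of positive-definite
#'   matrices; when given, (co)variance updates are skipped.
#' @param store_u logical; store the retained breeding-value draws (needed
#'   for GEBV posterior distributions; memory grows with n x t x samples).
#' @return object of class `gibbs_fit` with elements `G_chain`, `R_chain`
#'   (retained draws, columns `i.j` over the upper triangle), `b_chain`,
#'   `u_mean`, `u_sd`, optionally `u_chain` (samples x animals x traits),
#'   `traits`, `n_retained`, and the settings used.
#' @export
gibbs_sample <- function(y, X, grm, prior = prior_spec(),
                         mcmc = mcmc_settings(), fixed_covariances = NULL,
                         store_u = FALSE) {
  if (is.vector(y)) y <- matrix(y, ncol = 1L)
  y <- as.matrix(y)
  n <- nrow(y); t <- ncol(y)
  if (is.null(colnames(y))) colnames(y) <- paste0("trait", seq_len(t))
  traits <- colnames(y)

  if (is.factor(X) || is.character(X)) {
    f <- factor(X)
    X <- matrix(0, length(f), nlevels(f),
                dimnames = list(NULL, levels(f)))
    X[cbind(seq_along(f), as.integer(f))] <- 1
  }
  X <- as.matrix(X)
  if (nrow(X) != n) stopf("X has %d rows but y has %d", nrow(X), n)
  p <- ncol(X)
  if (qr(X)$rank < p) stopf("singular fixed-effect design (rank-deficient X)")

  if (!is_symmetric(grm)) stopf("GRM must be symmetric")
  if (nrow(grm) != n) stopf("GRM order (%d) does not match records (%d)", nrow(grm), n)

  eg <- eigen(grm, symmetric = TRUE)
  d <- eg$values
  jittered <- FALSE
  if (min(d) < 1e-8) { d <- d + 1e-6; jittered <- TRUE }
  if (min(d) <= 0) stopf("GRM is not positive semidefinite even after jitter")
  V <- eg$vectors

  fixed <- !is.null(fixed_covariances)
  if (fixed) {
    G <- as.matrix(fixed_covariances$G); R <- as.matrix(fixed_covariances$R)
    if (!is_symmetric(G) || !is_symmetric(R) || nrow(G) != t || nrow(R) != t)
      stopf("fixed covariance matrices must be symmetric %d x %d", t, t)
    for (M in list(G, R)) {
      ok <- try(chol(M), silent = TRUE)
      if (inherits(ok, "try-error")) stopf("fixed covariance matrix is not positive definite")
    }
  }

  # prior scales from observed phenotypic (co)variance
  df0_g <- if (!is.null(prior$df0_genomic)) prior$df0_genomic else if (t == 1L) 5 else 3
  df0_r <- prior$df0_residual
  obs_rows <- stats::complete.cases(y)
  varY <- if (sum(obs_rows) > t + 1L) stats::cov(y[obs_rows, , drop = FALSE]) else diag(t)
  if (t == 1L) varY <- as.numeric(varY)
  if (is.matrix(varY)) {
    # guard against degenerate observed covariance (e.g. all-missing traits)
    ev <- eigen(varY, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < 1e-10) varY <- varY + diag(t) * (1e-6 + abs(min(ev)))
  } else if (!is.finite(varY) || varY <= 0) varY <- 1
  # S0 as computed by compute_prior_scale() is the software-style scale that
  # enters the conditional numerator directly (it equals df0 times the
  # textbook per-df scale of the scaled-inverse-chi-square prior).
  S0_g <- if (!is.null(prior$S0_g)) prior$S0_g else compute_prior_scale(varY, df0_g, t, prior$R2)
  S0_r <- if (!is.null(prior$S0_r)) prior$S0_r else compute_prior_scale(varY, df0_r, t, prior$R2)
  S0_g_use <- as.matrix(S0_g)
  S0_r_use <- as.matrix(S0_r)

  mask <- is.na(y)
  pats <- missing_patterns(mask)
  any_missing <- any(mask)

  set.seed(mcmc$seed)

  # initial values
  Y <- y
  for (j in seq_len(t)) {
    mu0 <- mean(y[!mask[, j], j])
    if (!is.finite(mu0)) mu0 <- 0
    Y[mask[, j], j] <- mu0
  }
  XtX <- crossprod(X)
  Cx <- chol(XtX)
  B <- backsolve(Cx, forwardsolve(t(Cx), crossprod(X, Y)))
  U <- matrix(0, n, t)
  if (!fixed) {
    vY <- if (t == 1L) as.matrix(varY) else varY
    G <- vY / 2 + diag(t) * 1e-8
    R <- vY / 2 + diag(t) * 1e-8
  }

  keep <- seq(mcmc$burn_in + mcmc$thin, mcmc$n_iter, by = mcmc$thin)
  n_keep <- length(keep)
  if (n_keep < 1L) stopf("no retained samples: increase n_iter or reduce thin")
  ut_idx <- which(upper.tri(diag(t), diag = TRUE), arr.ind = TRUE)
  cov_names <- paste0(ut_idx[, 1L], ".", ut_idx[, 2L])
  G_chain <- matrix(NA_real_, n_keep, nrow(ut_idx), dimnames = list(NULL, cov_names))
  R_chain <- matrix(NA_real_, n_keep, nrow(ut_idx), dimnames = list(NULL, cov_names))
  b_chain <- matrix(NA_real_, n_keep, p * t)
  u_sum <- matrix(0, n, t); u_sq <- matrix(0, n, t)
  u_chain <- if (store_u) array(NA_real_, dim = c(n_keep, n, t)) else NULL

  s <- 0L
  for (it in seq_len(mcmc$n_iter)) {
    mu <- X %*% B + U

    # 1. data augmentation for missing phenotypes
    if (any_missing) {
      for (g in pats) {
        if (length(g$mis) == 0L) next
        rows <- g$rows; mis <- g$mis; obs <- g$obs
        if (length(obs) == 0L) {
          L <- t(chol(R))
          Y[rows, ] <- mu[rows, , drop = FALSE] +
            matrix(stats::rnorm(length(rows) * t), length(rows), t) %*% t(L)
        } else {
          Roo <- R[obs, obs, drop = FALSE]
          A <- R[mis, obs, drop = FALSE] %*% solve(Roo)
          S <- R[mis, mis, drop = FALSE] - A %*% R[obs, mis, drop = FALSE]
          S <- (S + t(S)) / 2
          L <- t(chol(S + diag(nrow(S)) * 1e-12))
          cond_mu <- mu[rows, mis, drop = FALSE] +
            (Y[rows, obs, drop = FALSE] - mu[rows, obs, drop = FALSE]) %*% t(A)
          Y[rows, mis] <- cond_mu +
            matrix(stats::rnorm(length(rows) * length(mis)), length(rows)) %*% t(L)
        }
      }
    }

    # 2. fixed effects: vec(B) | . ~ N(vec(Bhat), R (x) (X'X)^-1)
    Bhat <- backsolve(Cx, forwardsolve(t(Cx), crossprod(X, Y - U)))
    Cr <- chol(R)
    B <- Bhat + backsolve(Cx, matrix(stats::rnorm(p * t), p, t)) %*% Cr

    # 3. breeding values in the doubly rotated basis
    W <- Y - X %*% B
    Wstar <- crossprod(V, W)
    Lr <- t(Cr)                                  # R = Lr Lr'
    M <- forwardsolve(Lr, t(forwardsolve(Lr, G)))
    M <- (M + t(M)) / 2
    em <- eigen(M, symmetric = TRUE)
    lam <- pmax(em$values, 0)
    Q <- em$vectors
    Sinv <- crossprod(Q, forwardsolve(Lr, diag(t)))   # S^-1 = Q' Lr^-1
    Wtil <- Wstar %*% t(Sinv)
    dl <- outer(d, lam)
    v <- dl / (1 + dl)
    Util <- v * Wtil + sqrt(v) * matrix(stats::rnorm(n * t), n, t)
    Smat <- Lr %*% Q
    Ustar <- Util %*% t(Smat)
    U <- V %*% Ustar

    # 4. (co)variance components
    if (!fixed) {
      Sg <- crossprod(Ustar, Ustar / d)
      Sg <- (Sg + t(Sg)) / 2
      if (t == 1L) {
        G <- as.matrix(sample_variance_conditional(Sg[1L, 1L], n, df0_g,
                                                   S0_g_use[1L, 1L] / df0_g))
      } else {
        G <- riwish(df0_g + n, S0_g_use + Sg)
      }
      E <- W - U
      Se <- crossprod(E)
      if (t == 1L) {
        R <- as.matrix(sample_variance_conditional(Se[1L, 1L], n, df0_r,
                                                   S0_r_use[1L, 1L] / df0_r))
      } else {
        R <- riwish(df0_r + n, S0_r_use + Se)
      }
    }

    # 5. store
    if (it > mcmc$burn_in && (it - mcmc$burn_in) %% mcmc$thin == 0L) {
      s <- s + 1L
      G_chain[s, ] <- G[upper.tri(G, diag = TRUE)]
      R_chain[s, ] <- R[upper.tri(R, diag = TRUE)]
      b_chain[s, ] <- as.numeric(B)
      u_sum <- u_sum + U
      u_sq <- u_sq + U^2
      if (store_u) u_chain[s, , ] <- U
    }
  }

  u_mean <- u_sum / n_keep
  u_sd <- sqrt(pmax(u_sq / n_keep - u_mean^2, 0) * n_keep / max(1L, n_keep - 1L))
  dimnames(u_mean) <- dimnames(u_sd) <- list(rownames(y), traits)

  structure(list(G_chain = G_chain, R_chain = R_chain, b_chain = b_chain,
                 u_mean = u_mean, u_sd = u_sd, u_chain = u_chain,
                 traits = traits, n_traits = t, n_retained = n_keep,
                 prior = list(df0_genomic = df0_g, df0_residual = df0_r,
                              S0_g = S0_g, S0_r = S0_r, R2 = prior$R2),
                 mcmc = mcmc, fixed_covariances = fixed,
                 grm_jittered = jittered),
            class = "gibbs_fit")
}

#' Extract a (co)variance chain element from a fit
#'
#' @param chain a `G_chain`/`R_chain` matrix from [gibbs_sample()].
#' @param i,j trait indices (upper triangle, `i <= j`).
#' @param t number of traits.
#' @return numeric vector of retained draws.
#' @export
cov_chain <- function(chain, i, j, t) {
  if (i > j) { k <- i; i <- j; j <- k }
  chain[, paste0(i, ".", j)]
}

#' Heritability and genomic-correlation chains from a fit
#'
#' Per retained draw, `h2_k = G_kk / (G_kk + R_kk)` and
#' `rg_kl = G_kl / sqrt(G_kk * G_ll)`. Draws with zero total variance for a
#' trait are excluded and counted.
#'
#' @param fit a `gibbs_fit`.
#' @return list with `h2` (draws x traits matrix), `rg` (draws x pairs,
#'   columns `k.l`), `h2_summary`, `rg_summary` (via
#'   [summarize_posterior()]) and `n_excluded`.
#' @export
derive_genetic_parameters <- function(fit) {
  t <- fit$n_traits
  gd <- sapply(seq_len(t), function(k) cov_chain(fit$G_chain, k, k, t))
  rd <- sapply(seq_len(t), function(k) cov_chain(fit$R_chain, k, k, t))
  gd <- matrix(gd, ncol = t); rd <- matrix(rd, ncol = t)
  tot <- gd + rd
  bad <- apply(tot <= 0, 1L, any)
  h2 <- gd[!bad, , drop = FALSE] / tot[!bad, , drop = FALSE]
  colnames(h2) <- fit$traits
  rg <- NULL
  if (t > 1L) {
    pairs <- utils::combn(t, 2L)
    rg <- apply(pairs, 2L, function(pr) {
      num <- cov_chain(fit$G_chain, pr[1L], pr[2L], t)[!bad]
      num / sqrt(gd[!bad, pr[1L]] * gd[!bad, pr[2L]])
    })
    rg <- matrix(rg, ncol = ncol(pairs))
    colnames(rg) <- apply(pairs, 2L, paste, collapse = ".")
  }
  h2_summary <- do.call(rbind, lapply(seq_len(t), function(k) summarize_posterior(h2[, k])))
  h2_summary <- cbind(trait = fit$traits, h2_summary)
  rg_summary <- NULL
  if (!is.null(rg)) {
    rg_summary <- do.call(rbind, lapply(seq_len(ncol(rg)), function(k) summarize_posterior(rg[, k])))
    rg_summary <- cbind(pair = colnames(rg), rg_summary)
  }
  list(h2 = h2, rg = rg, h2_summary = h2_summary, rg_summary = rg_summary,
       n_excluded = sum(bad))
}
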