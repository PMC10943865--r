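# Synthetic-data module: genotypes, true breeding values, weekly weight
# series and compositional microbiome counts with known ground truth, so the
# whole pipeline can be validated by parameter recovery.

#' Build a positive-semidefinite genetic correlation matrix over ADG + MG traits
#'
#' Constructs a Gram matrix: the four ADG traits get the supplied correlation
#' block; each microbial trait is embedded as a unit vector whose projection
#' on the ADG space reproduces its target ADG correlations (equal across the
#' four ADG traits, alternating sign, magnitudes drawn uniformly from
#' `mg_rg_range`), plus a private orthogonal component. Positive
#' semidefiniteness holds by construction.
#'
#' @param n_mg number of microbial traits.
#' @param adg_corr 4 x 4 correlation block for the ADG traits.
#' @param mg_rg_range range of |rg| between an MG trait and the ADG traits.
#' @param seed RNG seed for the magnitudes.
#' @return `(4 + n_mg) x (4 + n_mg)` correlation matrix.
#' @export
default_genetic_corr <- function(n_mg, adg_corr = NULL,
                                 mg_rg_range = c(0.15, 0.42), seed = 1) {
  if (is.null(adg_corr)) {
    adg_corr <- diag(4)
    adg_corr[1, 2] <- adg_corr[2, 1] <- 0.31
    adg_corr[1, 3] <- adg_corr[3, 1] <- 0.39
    adg_corr[1, 4] <- adg_corr[4, 1] <- 0.07
    adg_corr[2, 3] <- adg_corr[3, 2] <- 0.25
    adg_corr[2, 4] <- adg_corr[4, 2] <- 0.15
    adg_corr[3, 4] <- adg_corr[4, 3] <- -0.13
  }
  La <- chol(adg_corr)                      # upper: adg_corr = La' La
  tsize <- 4L + n_mg
  C <- diag(tsize)
  C[1:4, 1:4] <- adg_corr
  if (n_mg > 0L) {
    set.seed(seed)
    mags <- stats::runif(n_mg, mg_rg_range[1L], mg_rg_range[2L])
    signs <- rep_len(c(1, -1), n_mg)
    W <- matrix(0, n_mg, 4L)
    for (j in seq_len(n_mg)) {
      cj <- signs[j] * mags[j] * rep(1, 4L)
      wj <- forwardsolve(t(La), cj)          # La' w = c
      if (sqrt(sum(wj^2)) > 0.95) wj <- wj * 0.95 / sqrt(sum(wj^2))
      W[j, ] <- wj
    }
    cross <- W %*% La                        # MG x ADG correlations
    C[4L + seq_len(n_mg), 1:4] <- cross
    C[1:4, 4L + seq_len(n_mg)] <- t(cross)
    mgmg <- tcrossprod(W)
    diag(mgmg) <- 1
    C[4L + seq_len(n_mg), 4L + seq_len(n_mg)] <- mgmg
  }
  C
}

#' Simulation configuration
#'
#' Defaults reproduce the structure of the study population this package is
#' designed around: 359 phenotyped beef cattle plus 30 genotyped-only sires,
#' SNP dosages at Hardy-Weinberg equilibrium, 17 weekly weights per animal
#' over four 4-week stages with mean daily gains 1.57/1.50/1.48/1.41 kg/day,
#' stage heritabilities 0.31/0.27/0.29/0.27, a 17-level diet x breed x year
#' fixed effect, microbial-trait heritabilities drawn from 0.19-0.44 and
#' multinomial sequencing counts with variable depth.
#'
#' @param n_animals phenotyped animals.
#' @param n_sires_extra genotyped animals without phenotypes.
#' @param n_snps SNP count (independent loci).
#' @param maf_range allele-frequency interval within `(0, 0.5]`.
#' @param n_mg number of microbial gene (MG) latent traits.
#' @param h2_adg heritabilities of the 4 ADG traits.
#' @param h2_mg per-MG heritabilities, or a length-2 range to draw from.
#' @param genetic_corr correlation matrix over `4 + n_mg` traits; `NULL`
#'   builds [default_genetic_corr()].
#' @param adg_means stage mean daily gains (kg/day).
#' @param varp_adg phenotypic variances of the latent ADG traits (kg/day)^2.
#' @param varp_mg latent log-abundance phenotypic variance per MG.
#' @param n_fixed_levels levels of the combined fixed effect.
#' @param fixed_effect_sd sd of the level effects (ADG scale kg/day; the same
#'   value is used on the MG log scale).
#' @param weight_noise_sd measurement noise of a single weighing (kg).
#' @param depth_range total sequencing counts per sample (min, max).
#' @param missing_geno_rate fraction of dosages set missing (exercises QC).
#' @param structure `"sire"` (default): phenotyped animals are half-sib
#'   offspring of the `n_sires_extra` genotyped sires, mirroring the
#'   sire-structured study population whose relatedness identifies the
#'   variance components; `"unrelated"`: all animals independent draws.
#' @param mg_ref_stable append one extra microbial trait with zero
#'   heritability and very low residual variance, emulating a stable
#'   reference gene for the alr transform (default TRUE when `n_mg > 0`).
#' @param seed master seed.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_animals = 359, n_sires_extra = 30, n_snps = 5000,
                       maf_range = c(0.05, 0.5), n_mg = 100,
                       h2_adg = c(0.31, 0.27, 0.29, 0.27),
                       h2_mg = c(0.19, 0.44), genetic_corr = NULL,
                       adg_means = c(1.57, 1.50, 1.48, 1.41),
                       varp_adg = rep(0.18, 4), varp_mg = 1,
                       n_fixed_levels = 17, fixed_effect_sd = 0.1,
                       weight_noise_sd = 2, depth_range = c(5e4, 2e5),
                       missing_geno_rate = 0,
                       structure = c("sire", "unrelated"),
                       mg_ref_stable = NULL, seed = 1) {
  structure_mode <- match.arg(structure)
  if (is.null(mg_ref_stable)) mg_ref_stable <- n_mg > 0L
  check_scalar(n_animals, "n_animals", 2)
  check_scalar(n_snps, "n_snps", 1)
  if (length(maf_range) != 2L || maf_range[1L] <= 0 || maf_range[2L] > 0.5 ||
      maf_range[1L] > maf_range[2L])
    stopf("maf_range must be an interval within (0, 0.5]")
  if (length(h2_adg) != 4L || any(h2_adg < 0 | h2_adg > 1))
    stopf("h2_adg must be 4 values in [0, 1]")
  if (length(h2_mg) == 2L && n_mg != 2L) {
    set.seed(seed + 11L)
    h2_mg <- stats::runif(n_mg, h2_mg[1L], h2_mg[2L])
  }
  if (length(h2_mg) != n_mg || any(h2_mg < 0 | h2_mg > 1))
    stopf("h2_mg must be n_mg values in [0, 1] (or a range)")
  if (is.null(genetic_corr))
    genetic_corr <- default_genetic_corr(n_mg, seed = seed + 7L)
  tsize <- 4L + n_mg
  if (!is_symmetric(genetic_corr) || nrow(genetic_corr) != tsize)
    stopf("genetic_corr must be a symmetric %d x %d matrix", tsize, tsize)
  if (max(abs(diag(genetic_corr) - 1)) > 1e-8)
    stopf("genetic_corr must have unit diagonal")
  ev <- eigen(genetic_corr, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stopf("genetic_corr is not positive semidefinite (min eigenvalue %g)", min(ev))
  if (length(adg_means) != 4L) stopf("adg_means must have 4 values")
  check_scalar(weight_noise_sd, "weight_noise_sd", 0)
  check_scalar(missing_geno_rate, "missing_geno_rate", 0, 1)
  if (length(depth_range) != 2L || depth_range[1L] > depth_range[2L] ||
      depth_range[1L] < 1)
    stopf("depth_range must be an increasing interval of positive depths")
  structure(list(n_animals = as.integer(n_animals),
                 n_sires_extra = as.integer(n_sires_extra),
                 n_snps = as.integer(n_snps), maf_range = maf_range,
                 n_mg = as.integer(n_mg), h2_adg = h2_adg, h2_mg = h2_mg,
                 genetic_corr = genetic_corr, adg_means = adg_means,
                 varp_adg = varp_adg, varp_mg = varp_mg,
                 n_fixed_levels = as.integer(n_fixed_levels),
                 fixed_effect_sd = fixed_effect_sd,
                 weight_noise_sd = weight_noise_sd,
                 depth_range = depth_range,
                 missing_geno_rate = missing_geno_rate,
                 structure = structure_mode,
                 mg_ref_stable = mg_ref_stable,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate SNP dosages
#'
#' Each allele is a Bernoulli draw at a per-SNP frequency drawn uniformly on
#' `maf_range` (independent loci, Hardy-Weinberg proportions marginally). In
#' `"sire"` mode the phenotyped animals are half-sib offspring of the
#' genotyped sires: the paternal allele is transmitted from the sire's
#' genotype, the maternal allele drawn from the population, so half-sib
#' families share kinship ~0.25 as in a sire-structured cattle population.
#' In `"unrelated"` mode all animals are independent.
#'
#' @param cfg a [sim_config()].
#' @return animals x SNPs integer matrix with dimnames (`NA` injected at
#'   `missing_geno_rate` if configured); attribute `sire` gives each
#'   phenotyped animal's sire index in sire mode.
#' @export
simulate_genotypes <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 1L)
  n_off <- cfg$n_animals
  n_sire <- cfg$n_sires_extra
  n <- n_off + n_sire
  m <- cfg$n_snps
  p <- stats::runif(m, cfg$maf_range[1L], cfg$maf_range[2L])
  sire_of <- NULL
  if (cfg$structure == "sire" && n_sire > 0L) {
    sires <- matrix(stats::rbinom(n_sire * m, 2L, rep(p, each = n_sire)),
                    n_sire, m)
    sire_of <- sort(rep_len(seq_len(n_sire), n_off))
    paternal <- matrix(stats::rbinom(n_off * m, 1L,
                                     (sires / 2)[sire_of, , drop = FALSE]),
                       n_off, m)
    maternal <- matrix(stats::rbinom(n_off * m, 1L, rep(p, each = n_off)),
                       n_off, m)
    g <- rbind(paternal + maternal, sires)
  } else {
    g <- matrix(stats::rbinom(n * m, 2L, rep(p, each = n)), n, m)
  }
  g <- matrix(as.integer(g), nrow = n)
  if (cfg$missing_geno_rate > 0) {
    miss <- stats::runif(length(g)) < cfg$missing_geno_rate
    g[miss] <- NA_integer_
  }
  rownames(g) <- c(sprintf("A%03d", seq_len(n_off)),
                   if (n_sire > 0) sprintf("S%03d", seq_len(n_sire)))
  colnames(g) <- sprintf("snp%05d", seq_len(m))
  attr(g, "sire") <- sire_of
  g
}

# matrix square root via eigendecomposition (handles PSD input)
mat_sqrt <- function(M) {
  e <- eigen((M + t(M)) / 2, symmetric = TRUE)
  e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
}

#' Simulate true genetic, fixed and residual effects
#'
#' Breeding values are drawn with covariance `Sigma_g (x) K` where `Sigma_g`
#' scales the genetic correlation matrix by per-trait genomic standard
#' deviations chosen so the heritability targets hold against the configured
#' phenotypic variances; `K` is either a supplied genomic relationship matrix
#' (realistic mode) or the identity (unit-test mode). Fixed-effect levels are
#' assigned uniformly; level effects are Gaussian. Latent MG log-abundances
#' (genetic + fixed + residual) are populated for the phenotyped animals
#' around Gaussian baselines.
#'
#' @param cfg a [sim_config()].
#' @param grm genomic relationship matrix over all genotyped animals, or
#'   `NULL` for the identity.
#' @return list of class `true_parameters`: `true_u` (all animals x traits),
#'   `true_b` (levels x traits), `true_sigma_u2`, `true_sigma_e2`, `fixed_level`
#'   (per phenotyped animal), `adg_residual` (animals x 4),
#'   `latent_log_abundance` (phenotyped animals x MG).
#' @export
simulate_true_effects <- function(cfg, grm = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  n_all <- cfg$n_animals + cfg$n_sires_extra
  n_ref <- as.integer(isTRUE(cfg$mg_ref_stable) && cfg$n_mg > 0L)
  n_mg_tot <- cfg$n_mg + n_ref
  tsize <- 4L + n_mg_tot
  if (is.null(grm)) grm <- diag(n_all)
  if (!is_symmetric(grm) || nrow(grm) != n_all)
    stopf("grm must be symmetric of order %d", n_all)
  ev <- eigen(grm, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-6) stopf("grm is not positive semidefinite")

  # the stable reference trait: no genetic variance, tiny residual variance
  varp <- c(cfg$varp_adg, rep(cfg$varp_mg, cfg$n_mg), if (n_ref) 0.02)
  h2 <- c(cfg$h2_adg, cfg$h2_mg, if (n_ref) 0)
  corr <- diag(tsize)
  corr[seq_len(4L + cfg$n_mg), seq_len(4L + cfg$n_mg)] <- cfg$genetic_corr
  sigma_u2 <- h2 * varp
  sigma_e2 <- (1 - h2) * varp
  su <- sqrt(sigma_u2)
  Sg <- diag(su, tsize) %*% corr %*% diag(su, tsize)

  set.seed(cfg$seed + 2L)
  Lk <- mat_sqrt(grm)
  Lg <- mat_sqrt(Sg)
  Z <- matrix(stats::rnorm(n_all * tsize), n_all, tsize)
  true_u <- Lk %*% Z %*% t(Lg)
  trait_names <- c(paste0("ADG_", 1:4), sprintf("MG%04d", seq_len(cfg$n_mg)),
                   if (n_ref) "MGREF")
  dimnames(true_u) <- list(rownames(grm) %||% sprintf("A%03d", seq_len(n_all)),
                           trait_names)

  fixed_level <- sample.int(cfg$n_fixed_levels, cfg$n_animals, replace = TRUE)
  true_b <- matrix(stats::rnorm(cfg$n_fixed_levels * tsize, 0, cfg$fixed_effect_sd),
                   cfg$n_fixed_levels, tsize, dimnames = list(NULL, trait_names))

  ph <- seq_len(cfg$n_animals)
  adg_residual <- matrix(stats::rnorm(cfg$n_animals * 4L), cfg$n_animals, 4L) *
    rep(sqrt(sigma_e2[1:4]), each = cfg$n_animals)

  latent <- NULL
  if (n_mg_tot > 0L) {
    baseline <- c(stats::rnorm(cfg$n_mg, 0, 1.5), if (n_ref) 0)
    mg_idx <- 4L + seq_len(n_mg_tot)
    res_mg <- matrix(stats::rnorm(cfg$n_animals * n_mg_tot), cfg$n_animals) *
      rep(sqrt(sigma_e2[mg_idx]), each = cfg$n_animals)
    latent <- sweep(true_u[ph, mg_idx, drop = FALSE] +
                      true_b[fixed_level, mg_idx, drop = FALSE] + res_mg,
                    2L, baseline, "+")
    colnames(latent) <- trait_names[mg_idx]
    rownames(latent) <- rownames(true_u)[ph]
  }

  structure(list(true_u = true_u, true_b = true_b, fixed_level = fixed_level,
                 true_sigma_u2 = stats::setNames(sigma_u2, trait_names),
                 true_sigma_e2 = stats::setNames(sigma_e2, trait_names),
                 adg_residual = adg_residual,
                 latent_log_abundance = latent),
            class = "true_parameters")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate weekly body-weight series
#'
#' Each phenotyped animal gets 17 weekly weights (days 0, 7, ..., 112): a
#' continuous piecewise-linear latent trajectory whose slope over 4-week stage
#' `k` is `adg_means[k] + b + u_k + e_k`, plus i.i.d. Gaussian measurement
#' noise on every weighing. Initial weights are drawn around 450 kg (sd 40),
#' typical for finishing beef cattle.
#'
#' @param true a [simulate_true_effects()] result.
#' @param cfg the matching [sim_config()].
#' @return long data frame with columns `animal`, `day`, `weight_kg`.
#' @export
simulate_weight_series <- function(true, cfg) {
  stopifnot(inherits(true, "true_parameters"), inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 3L)
  n <- cfg$n_animals
  days <- seq(0L, 112L, by = 7L)
  slopes <- sweep(true$true_u[seq_len(n), 1:4, drop = FALSE] +
                    true$true_b[true$fixed_level, 1:4, drop = FALSE] +
                    true$adg_residual, 2L, cfg$adg_means, "+")
  w0 <- stats::rnorm(n, 450, 40)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    stage <- pmin(pmax(ceiling(days / 28), 1L), 4L)    # stage of each interval end
    # cumulative latent trajectory: slope changes at days 28, 56, 84
    incr <- c(0, diff(days)) * slopes[i, stage]
    latent <- w0[i] + cumsum(incr)
    obs <- latent + stats::rnorm(length(days), 0, cfg$weight_noise_sd)
    out[[i]] <- data.frame(animal = rownames(true$true_u)[i], day = days,
                           weight_kg = obs, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Simulate multinomial microbiome counts
#'
#' Per sample, a sequencing depth is drawn uniformly from `depth_range` and
#' counts are multinomial with probabilities `softmax(latent log-abundance)`;
#' structural zeros arise naturally at low depth.
#'
#' @param true a [simulate_true_effects()] result with populated latent
#'   log-abundances.
#' @param cfg the matching [sim_config()].
#' @return samples x MG integer count matrix.
#' @export
simulate_mg_counts <- function(true, cfg) {
  stopifnot(inherits(true, "true_parameters"), inherits(cfg, "sim_config"))
  if (is.null(true$latent_log_abundance)) stopf("latent log-abundances not populated")
  if (cfg$depth_range[1L] < cfg$n_mg)
    warnf("minimum depth (%g) below MG count (%d): extreme zero inflation",
          cfg$depth_range[1L], cfg$n_mg)
  set.seed(cfg$seed + 4L)
  lat <- true$latent_log_abundance
  depths <- floor(stats::runif(nrow(lat), cfg$depth_range[1L], cfg$depth_range[2L] + 1))
  counts <- matrix(0L, nrow(lat), ncol(lat), dimnames = dimnames(lat))
  for (i in seq_len(nrow(lat))) {
    pr <- exp(lat[i, ] - max(lat[i, ]))
    counts[i, ] <- stats::rmultinom(1L, depths[i], pr / sum(pr))[, 1L]
  }
  counts
}

#' Simulate a complete dataset with ground truth
#'
#' Runs the full generative chain: genotypes, (optionally) the realised GRM,
#' true effects, weight series and microbiome counts.
#'
#' @param cfg a [sim_config()].
#' @param grm_mode `"computed"` (GRM from the simulated genotypes; realistic)
#'   or `"identity"` (independent animals; unit-test mode).
#' @return list with `genotypes`, `grm`, `true`, `weights`, `counts`,
#'   `fixed` (data frame animal/level) and `cfg`.
#' @export
simulate_dataset <- function(cfg, grm_mode = c("computed", "identity")) {
  grm_mode <- match.arg(grm_mode)
  geno <- simulate_genotypes(cfg)
  grm <- if (grm_mode == "computed") {
    compute_grm(qc_filter(geno)$dosages)
  } else {
    diag(nrow(geno))
  }
  if (is.null(rownames(grm))) dimnames(grm) <- list(rownames(geno), rownames(geno))
  true <- simulate_true_effects(cfg, grm)
  weights <- simulate_weight_series(true, cfg)
  counts <- if (cfg$n_mg > 0L) simulate_mg_counts(true, cfg) else NULL
  fixed <- data.frame(animal = rownames(true$true_u)[seq_len(cfg$n_animals)],
                      level = true$fixed_level, stringsAsFactors = FALSE)
  list(genotypes = geno, grm = grm, true = true, weights = weights,
       counts = counts, fixed = fixed, cfg = cfg)
}

#' Write a simulated dataset in the pipeline's canonical TSV formats
#'
#' Emits `weights.tsv` (animal, day, weight_kg), `genotypes.tsv` (animals x
#' SNPs), `mg_counts.tsv` (samples x MG), `fixed_effects.tsv` (animal, level)
#' and `ground_truth.json` (simulation parameters and true values).
#'
#' @param sim a [simulate_dataset()] result.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv(sim$weights, file.path(dir, "weights.tsv"))
  write_tsv(as.data.frame(sim$genotypes), file.path(dir, "genotypes.tsv"),
            rownames_as = "animal")
  if (!is.null(sim$counts))
    write_tsv(as.data.frame(sim$counts), file.path(dir, "mg_counts.tsv"),
              rownames_as = "sample")
  write_tsv(sim$fixed, file.path(dir, "fixed_effects.tsv"))
  gt <- list(seed = sim$cfg$seed,
             adg_means = sim$cfg$adg_means,
             h2 = as.list(sim$true$true_sigma_u2 /
                            (sim$true$true_sigma_u2 + sim$true$true_sigma_e2)),
             true_sigma_u2 = as.list(sim$true$true_sigma_u2),
             true_sigma_e2 = as.list(sim$true$true_sigma_e2),
             true_u = apply(sim$true$true_u, 2L, identity, simplify = FALSE))
  jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
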