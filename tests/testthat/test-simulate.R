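test_that("genotype simulation is seeded, in-range and respects allele frequency", {
  cfg <- sim_config(n_animals = 5, n_sires_extra = 0, n_snps = 3, n_mg = 0, seed = 41)
  g1 <- simulate_genotypes(cfg)
  g2 <- simulate_genotypes(cfg)
  expect_identical(g1, g2)
  expect_equal(dim(g1), c(5L, 3L))
  expect_true(all(g1 %in% 0:2))
  # fixed p = 0.5: mean dosage ~ 1 within 3 binomial SEs
  cfgp <- sim_config(n_animals = 10000, n_sires_extra = 0, n_snps = 4, n_mg = 0,
                     maf_range = c(0.5, 0.5), structure = "unrelated", seed = 42)
  gp <- simulate_genotypes(cfgp)
  se <- sqrt(2 * 0.5 * 0.5 / 10000)
  expect_true(all(abs(colMeans(gp) - 1) < 3 * se))
  expect_error(sim_config(maf_range = c(0, 0.6)), "maf_range")
})

test_that("sire mode yields elevated half-sib kinship", {
  cfg <- sim_config(n_animals = 120, n_sires_extra = 6, n_snps = 800, n_mg = 0,
                    structure = "sire", seed = 43)
  g <- simulate_genotypes(cfg)
  K <- compute_grm(qc_filter(g)$dosages)
  sire_of <- attr(g, "sire")
  off <- K[1:120, 1:120]
  same <- outer(sire_of, sire_of, "==") & upper.tri(off)
  diff <- (!outer(sire_of, sire_of, "==")) & upper.tri(off)
  expect_gt(mean(off[same]), mean(off[diff]) + 0.15)  # half sibs ~ 0.25
})

test_that("true effects honour the genetic correlation matrix and h2 targets", {
  # 2 MG traits with engineered rg 0.4 to nothing else, identity GRM
  corr <- diag(6); corr[5, 6] <- corr[6, 5] <- 0.4
  cfg <- sim_config(n_animals = 2000, n_sires_extra = 0, n_snps = 10, n_mg = 2,
                    h2_mg = c(0.5, 0.5), genetic_corr = corr, mg_ref_stable = FALSE,
                    seed = 44)
  true <- simulate_true_effects(cfg, grm = NULL)
  emp <- cor(true$true_u[, 5], true$true_u[, 6])
  expect_lt(abs(emp - 0.4), 0.05)
  # independence under identity correlation
  corr0 <- diag(6)
  cfg0 <- sim_config(n_animals = 5000, n_sires_extra = 0, n_snps = 10, n_mg = 2,
                     h2_mg = c(0.5, 0.5), genetic_corr = corr0, mg_ref_stable = FALSE,
                     seed = 45)
  t0 <- simulate_true_effects(cfg0, grm = NULL)
  cc <- cor(t0$true_u)
  expect_lt(max(abs(cc[upper.tri(cc)])), 0.05)
  # zero heritability: exact zero breeding values
  cfgz <- sim_config(n_animals = 50, n_sires_extra = 0, n_snps = 10, n_mg = 0,
                     h2_adg = c(0, 0.3, 0.3, 0.3), seed = 46)
  tz <- simulate_true_effects(cfgz, grm = NULL)
  expect_equal(unname(tz$true_u[, 1]), rep(0, 50))
  expect_equal(unname(tz$true_sigma_u2[["ADG_1"]]), 0)
  # non-PSD correlation is rejected, not bent
  bad <- diag(6); bad[1, 2] <- bad[2, 1] <- 0.9; bad[1, 3] <- bad[3, 1] <- 0.9
  bad[2, 3] <- bad[3, 2] <- -0.9
  expect_error(sim_config(n_mg = 2, h2_mg = c(0.3, 0.3), genetic_corr = bad,
                          mg_ref_stable = FALSE),
               "positive semidefinite")
})

test_that("noiseless weight series round-trip to the configured ADG means", {
  cfg <- sim_config(n_animals = 12, n_sires_extra = 0, n_snps = 10, n_mg = 0,
                    adg_means = c(1.57, 1.50, 1.48, 1.41),
                    h2_adg = rep(0, 4), varp_adg = rep(0, 4),
                    fixed_effect_sd = 0, weight_noise_sd = 0, seed = 47)
  true <- simulate_true_effects(cfg, grm = NULL)
  w <- simulate_weight_series(true, cfg)
  expect_equal(nrow(w), 12 * 17)
  expect_equal(sort(unique(w$day)), seq(0, 112, by = 7))
  tab <- adg_table(w)
  for (k in 1:4)
    expect_equal(unname(tab[[paste0("ADG_", k)]]), rep(cfg$adg_means[k], 12),
                 tolerance = 1e-10)
})

test_that("microbiome counts close to depth, concentrate at high depth, zero-inflate at low", {
  cfg <- sim_config(n_animals = 100, n_sires_extra = 0, n_snps = 10, n_mg = 30,
                    h2_mg = rep(0.3, 30), depth_range = c(1e3, 1e3), seed = 48)
  true <- simulate_true_effects(cfg, grm = NULL)
  c_low <- simulate_mg_counts(true, cfg)
  expect_true(all(rowSums(c_low) == 1e3))          # compositional closure
  cfg_hi <- cfg; cfg_hi$depth_range <- c(1e6, 1e6)
  c_hi <- simulate_mg_counts(true, cfg_hi)
  expect_gt(mean(c_low == 0), mean(c_hi == 0))     # monotone zero fraction
  # multinomial concentration: observed proportions -> softmax(latent)
  cfg1 <- sim_config(n_animals = 2, n_sires_extra = 0, n_snps = 10, n_mg = 10,
                     h2_mg = rep(0.3, 10), depth_range = c(1e9, 1e9), seed = 49)
  t1 <- simulate_true_effects(cfg1, grm = NULL)
  c1 <- simulate_mg_counts(t1, cfg1)
  soft <- exp(t1$latent_log_abundance[1, ])
  soft <- soft / sum(soft)
  expect_lt(max(abs(c1[1, ] / sum(c1[1, ]) - soft)), 1e-3)
  # seeded determinism
  expect_identical(simulate_mg_counts(true, cfg), c_low)
})

test_that("dataset writer emits the canonical TSVs and ground truth", {
  dir <- withr::local_tempdir()
  cfg <- sim_config(n_animals = 10, n_sires_extra = 2, n_snps = 20, n_mg = 5,
                    h2_mg = rep(0.3, 5), seed = 50)
  sim <- simulate_dataset(cfg, grm_mode = "identity")
  write_dataset(sim, dir)
  expect_true(all(file.exists(file.path(dir, c("weights.tsv", "genotypes.tsv",
                                               "mg_counts.tsv", "fixed_effects.tsv",
                                               "ground_truth.json")))))
  gt <- jsonlite::read_json(file.path(dir, "ground_truth.json"))
  expect_equal(gt$adg_means[[1]], 1.57)
})
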