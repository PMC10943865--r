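test_that("core filter keeps MG by presence count and reports retained counts", {
  counts <- matrix(5L, 10, 3, dimnames = list(paste0("s", 1:10), paste0("MG", 1:3)))
  counts[1:4, 2] <- 0L   # present in 6/10 < 0.7
  counts[1, 3] <- 0L     # present in 9/10
  res <- filter_core_mg(counts, 0.70)
  expect_equal(colnames(res$counts), c("MG1", "MG3"))
  expect_equal(res$retained_fraction,
               sum(counts[, c(1, 3)]) / sum(counts))
  # the 70% cut-off on 359 samples is presence in 252
  expect_equal(ceiling(0.70 * 359), 252)
  expect_equal(filter_core_mg(matrix(1L, 359, 2), 0.70)$cutoff_samples, 252)
})

test_that("GBM zero replacement matches the closed-form rule and preserves ratios", {
  # toy sample (0, 5, 5), depth 10: replaced value = t1 * s / (10 + s)
  counts <- rbind(c(0L, 5L, 5L), c(2L, 4L, 4L))
  colnames(counts) <- paste0("MG", 1:3)
  s <- 3.7
  out <- impute_zeros_gbm(counts, s = s)
  # independent straight-line computation of the prior proportions
  prop <- counts / rowSums(counts)
  tj <- apply(prop, 2, function(x) exp(mean(log(x[x > 0]))))
  tj <- tj / sum(tj)
  repl <- tj[1] * s / (10 + s)
  expect_equal(unname(out[1, 1]), unname(repl), tolerance = 1e-14)
  # non-zero parts: ratios unchanged, closure restored
  expect_equal(unname(out[1, 2] / out[1, 3]), 1)
  expect_equal(unname(rowSums(out)), c(1, 1), tolerance = 1e-12)
  # sample without zeros is returned as plain proportions
  expect_equal(out[2, ], prop[2, ], tolerance = 1e-14)
})

test_that("alr transform matches hand computation and is scale invariant", {
  p <- matrix(c(1, 2, 4) / 7, 1, 3, dimnames = list("s1", c("a", "b", "c")))
  a <- alr_transform(p, "c")
  expect_equal(as.numeric(a), c(log(1 / 4), log(2 / 4)), tolerance = 1e-12)
  expect_error(alr_transform(p, "zz"), "not found")
  x <- tiny_comp(8, 5)
  expect_equal(alr_transform(x * 3.14, "MG2"), alr_transform(x, "MG2"))
  # reference column comes out as all zeros against itself
  expect_equal(alr_transform(x, "MG1") - alr_transform(x, "MG1"),
               matrix(0, 8, 4), ignore_attr = TRUE)
})

test_that("alr round-trips through the inverse softmax to 1e-12", {
  x <- tiny_comp(15, 7, seed = 11)
  a <- alr_transform(x, "MG3")
  back <- alr_inverse(a)
  expect_lt(max(abs(back[, colnames(x)] - x)), 1e-12)
})

test_that("Procrustes correlation is 1 under identity and rotation, matches oracle", {
  set.seed(12)
  A <- matrix(rnorm(40), 8, 5)
  expect_equal(procrustes_correlation(A, A), 1, tolerance = 1e-12)
  Q <- qr.Q(qr(matrix(rnorm(25), 5, 5)))
  expect_equal(procrustes_correlation(A, A %*% Q), 1, tolerance = 1e-12)
  # brute-force oracle on a 4-sample, 3-part toy
  B <- matrix(rnorm(12), 4, 3)
  C <- matrix(rnorm(12), 4, 3)
  bc <- scale(B, scale = FALSE); cc <- scale(C, scale = FALSE)
  oracle <- sum(svd(t(bc) %*% cc)$d) / sqrt(sum(bc^2) * sum(cc^2))
  expect_equal(procrustes_correlation(B, C), oracle, tolerance = 1e-12)
})

test_that("Procrustes correlation agrees with vegan's symmetric protest statistic", {
  set.seed(13)
  A <- matrix(rnorm(60), 12, 5)
  B <- A + matrix(rnorm(60, 0, 0.3), 12, 5)
  ours <- procrustes_correlation(A, B)
  ref <- sqrt(1 - vegan::procrustes(scale(A, scale = FALSE),
                                    scale(B, scale = FALSE), symmetric = TRUE)$ss)
  expect_equal(ours, ref, tolerance = 1e-10)
})

test_that("reference selection favours the engineered low-variance part", {
  set.seed(14)
  n <- 50; d <- 20
  lat <- matrix(rnorm(n * d, sd = 1), n, d)
  lat[, 7] <- rnorm(n, 0, 0.02)            # nearly constant part
  x <- exp(lat) / rowSums(exp(lat))
  colnames(x) <- paste0("MG", 1:d)
  sel <- select_alr_reference(x, top_quantile = 0.25)
  # exhaustive independent scoring
  clr <- t(apply(log(x), 1, function(r) r - mean(r)))
  score <- sapply(1:d, function(j) {
    a <- log(x[, -j, drop = FALSE] / x[, j])
    procrustes_correlation(clr, a)
  })
  vars <- apply(log(x), 2, var)
  elig <- which(score >= quantile(score, 0.75))
  expect_equal(sel$reference, paste0("MG", elig[which.min(vars[elig])]))
  expect_equal(sel$reference, "MG7")
  expect_equal(sel$diagnostics$logratio_variance[7], unname(vars[7]))
})

test_that("degenerate compositional inputs are rejected", {
  counts <- rbind(c(0L, 0L, 0L), c(1L, 2L, 3L))
  expect_error(impute_zeros_gbm(counts), "all-zero")
  x <- tiny_comp(5, 4)
  x[2, 1] <- 0
  expect_error(alr_transform(x, "MG2"), "positive")
})
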