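toy_catalog <- function(p0s, abunds, rgs = NULL) {
  ids <- sprintf("K%02d", seq_along(p0s))
  do.call(rbind, lapply(seq_along(p0s), function(i) {
    rg <- if (is.null(rgs)) rep(0.2, 4) else rgs[[i]]
    data.frame(mg_id = ids[i], adg_trait = paste0("ADG_", 1:4),
               rg_median = rg, p0 = c(p0s[i], 0.6, 0.6, 0.6),
               rel_abundance = abunds[i], stringsAsFactors = FALSE)
  }))
}

test_that("candidate filter applies inclusive P0 and abundance bounds", {
  cat10 <- toy_catalog(p0s = c(0.85, 0.80, 0.99, 0.95, 0.84, 0.90, 0.86, 0.99, 0.92, 0.87),
                       abunds = c(2e-5, 5e-5, 5e-6, 1e-5, 4e-5, 9e-6, 3e-5, 2e-5, 1e-4, 8e-6))
  got <- filter_candidates(cat10, 0.85, 1e-5)
  # manual application of both rules
  manual <- c("K01", "K04", "K07", "K08", "K09")
  expect_equal(got, manual)
  expect_error(filter_candidates(toy_catalog(0.5, 1e-4)), "no candidate")
})

test_that("uniform-sign restriction keeps only sign-consistent rg profiles", {
  cat3 <- toy_catalog(p0s = c(0.9, 0.9, 0.9, 0.9), abunds = rep(1e-4, 4),
                      rgs = list(c(0.3, 0.2, 0.1, 0.05),
                                 c(0.3, -0.2, 0.1, 0.05),
                                 c(-0.3, -0.2, -0.1, -0.05),
                                 c(0.3, 0, 0.1, 0.05)))
  keep <- uniform_sign_subset(sprintf("K%02d", 1:4), cat3)
  expect_equal(keep, c("K01", "K03"))   # mixed sign and exact zero are dropped
})

test_that("first stepwise pick per trait equals exhaustive enumeration", {
  set.seed(62)
  n <- 50
  gebv_adg <- matrix(rnorm(4 * n), n, 4, dimnames = list(NULL, paste0("ADG_", 1:4)))
  gebv_mg <- matrix(rnorm(3 * n), n, 3, dimnames = list(NULL, c("Ka", "Kb", "Kc")))
  sel <- stepwise_select(gebv_adg, gebv_mg, quota_per_trait = 0.75)  # 3 picks
  # brute-force oracle for the first pick (trait 1)
  aic <- function(y, X) {
    f <- lm.fit(cbind(1, X), y); r <- sum(f$residuals^2)
    n * log(r / n) + 2 * (f$rank + 1)
  }
  first <- names(which.min(sapply(c("Ka", "Kb", "Kc"), function(id)
    aic(gebv_adg[, 1], cbind(gebv_adg[, -1], gebv_mg[, id])))))
  expect_equal(sel$selected[1], first)
  expect_equal(sel$trace$trait[1:3], c("ADG_1", "ADG_2", "ADG_3"))
})

test_that("a perfectly collinear candidate is selected first", {
  set.seed(63)
  n <- 40
  gebv_adg <- matrix(rnorm(4 * n), n, 4, dimnames = list(NULL, paste0("ADG_", 1:4)))
  resid1 <- lm.fit(cbind(1, gebv_adg[, -1]), gebv_adg[, 1])$residuals
  gebv_mg <- cbind(Kperfect = resid1, Knoise = rnorm(n), Kother = rnorm(n))
  sel <- stepwise_select(gebv_adg, gebv_mg, quota_per_trait = 0.25)
  expect_equal(sel$selected[1], "Kperfect")
})

test_that("completed runs attribute the quota per trait and R2 beats the baseline", {
  set.seed(64)
  n <- 80
  gebv_adg <- matrix(rnorm(4 * n), n, 4, dimnames = list(NULL, paste0("ADG_", 1:4)))
  gebv_mg <- 0.5 * gebv_adg[, rep(1:4, each = 3)] + matrix(rnorm(12 * n), n, 12)
  colnames(gebv_mg) <- sprintf("K%02d", 1:12)
  sel <- stepwise_select(gebv_adg, gebv_mg, quota_per_trait = 2)
  expect_equal(length(sel$selected), 8L)
  expect_equal(as.integer(table(sel$attribution)), rep(2L, 4))
  expect_false(anyDuplicated(sel$selected) > 0)
  base_r2 <- sapply(1:4, function(k) {
    f <- lm(gebv_adg[, k] ~ gebv_adg[, -k]); summary(f)$adj.r.squared
  })
  expect_true(all(sel$adj_r2 >= base_r2 - 1e-12))
  # determinism
  sel2 <- stepwise_select(gebv_adg, gebv_mg, quota_per_trait = 2)
  expect_identical(sel$selected, sel2$selected)
})

test_that("candidate exhaustion yields a partial result with a warning", {
  set.seed(65)
  gebv_adg <- matrix(rnorm(4 * 30), 30, 4, dimnames = list(NULL, paste0("ADG_", 1:4)))
  gebv_mg <- matrix(rnorm(2 * 30), 30, 2, dimnames = list(NULL, c("K1", "K2")))
  w <- capture_warnings(sel <- stepwise_select(gebv_adg, gebv_mg, quota_per_trait = 2))
  expect_true(any(grepl("exhausted|candidates", w)))
  expect_equal(length(sel$selected), 2L)
})
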