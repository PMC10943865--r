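# Shared fixtures, built in code.

# small genotype matrix under HWE
tiny_geno <- function(n = 20, m = 50, seed = 1, maf = c(0.1, 0.5)) {
  set.seed(seed)
  p <- runif(m, maf[1], maf[2])
  g <- matrix(rbinom(n * m, 2, rep(p, each = n)), n, m)
  dimnames(g) <- list(sprintf("A%03d", 1:n), sprintf("s%04d", 1:m))
  g
}

# positive composition matrix (rows sum to 1)
tiny_comp <- function(n = 12, d = 6, seed = 2) {
  set.seed(seed)
  x <- matrix(rexp(n * d) + 0.05, n, d)
  colnames(x) <- paste0("MG", 1:d)
  x / rowSums(x)
}

# quick univariate animal-model dataset with known h2
tiny_mixed <- function(n = 120, m = 400, h2 = 0.4, nlev = 5, seed = 3) {
  g <- tiny_geno(n, m, seed = seed, maf = c(0.05, 0.5))
  K <- compute_grm(g)
  set.seed(seed + 100)
  eg <- eigen(K, symmetric = TRUE)
  L <- eg$vectors %*% (sqrt(pmax(eg$values, 0)) * t(eg$vectors))
  u <- as.numeric(L %*% rnorm(n)) * sqrt(h2)
  f <- factor(sample(seq_len(nlev), n, TRUE))
  b <- rnorm(nlev, 0, 0.3)
  y <- b[f] + u + rnorm(n, 0, sqrt(1 - h2))
  list(y = y, f = f, K = K, u = u)
}
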