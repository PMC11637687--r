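test_that("GRM closed forms: single SNP, duplicated individuals, oracle", {
  d <- matrix(c(0, 2), 1, 2)
  K <- computeGrm(d)
  expect_equal(unname(K), matrix(c(2, -2, -2, 2), 2, 2))

  # duplicated individuals have identical rows/columns
  d2 <- random_dosage(40, 6, miss = 0, seed = 2)
  d2 <- cbind(d2, dup = d2[, 3])
  K2 <- computeGrm(d2)
  expect_equal(unname(K2[3, ]), unname(K2[7, ]))

  # brute-force double loop on a 20 x 50 fixture with missingness
  d3 <- random_dosage(20, 50, miss = 0.1, seed = 5)
  K3 <- computeGrm(d3)
  dimp <- d3
  for (s in 1:20) dimp[s, is.na(dimp[s, ])] <- mean(d3[s, ], na.rm = TRUE)
  f <- rowMeans(dimp) / 2
  poly <- f > 0 & f < 1
  denom <- 2 * sum(f[poly] * (1 - f[poly]))
  ora <- matrix(0, 50, 50)
  for (i in 1:50) for (j in 1:50)
    ora[i, j] <- sum((dimp[poly, i] - 2 * f[poly]) *
                       (dimp[poly, j] - 2 * f[poly])) / denom
  expect_equal(unname(K3), ora, tolerance = 1e-12)
})

test_that("GRM diagonal averages about 1 under Hardy-Weinberg", {
  set.seed(6)
  f <- runif(500, 0.1, 0.9)
  d <- matrix(rbinom(500 * 80, 2, f), 500, 80)
  colnames(d) <- paste0("i", 1:80)
  K <- computeGrm(d)
  expect_lt(abs(mean(diag(K)) - 1), 0.1)
})

test_that("LMM Wald p equals closed-form OLS under identity kinship", {
  set.seed(7)
  n <- 80; L <- 200
  d <- random_dosage(L, n, miss = 0, seed = 7)
  y <- rnorm(n); names(y) <- colnames(d)
  covar <- cbind(c1 = rnorm(n))
  K <- diag(n); dimnames(K) <- list(colnames(d), colnames(d))
  sc <- lmmWaldScan(y, d, K, covariates = covar)
  for (s in seq_len(L)) {
    X <- cbind(1, covar, d[s, ])
    b <- solve(crossprod(X), crossprod(X, y))
    r <- y - X %*% b
    s2 <- sum(r^2) / n  # ML residual variance
    vb <- s2 * solve(crossprod(X))[3, 3]
    p <- pchisq(b[3]^2 / vb, 1, lower.tail = FALSE)
    expect_equal(sc$p[s], p, tolerance = 1e-6)
  }
})

test_that("LMM p-values are invariant to affine trait rescaling", {
  set.seed(8)
  n <- 60
  d <- random_dosage(100, n, miss = 0.05, seed = 8)
  K <- computeGrm(d)
  y <- rnorm(n); names(y) <- colnames(d)
  a <- lmmWaldScan(y, d, K)
  y2 <- 5 * y - 3
  b <- lmmWaldScan(y2, d, K)
  expect_equal(a$p, b$p, tolerance = 1e-6)
  expect_error(lmmWaldScan(rep(1, n), d, K), "constant")
})

test_that("multitrait omnibus tracks a multivariate regression test", {
  set.seed(9)
  n <- 100; L <- 100
  d <- random_dosage(L, n, miss = 0, seed = 9)
  K <- diag(n); dimnames(K) <- list(colnames(d), colnames(d))
  Y <- matrix(rnorm(n * 3), n, 3)
  Y[, 1] <- Y[, 1] + 0.4 * d[7, ]
  rownames(Y) <- colnames(d)
  om <- multitraitScan(Y, d, K)
  # oracle: per-SNP multivariate regression (Pillai) p
  ora_p <- sapply(seq_len(L), function(s) {
    fit <- stats::manova(Y ~ d[s, ])
    summary(fit)$stats[1, "Pr(>F)"]
  })
  lo <- pmin(om$p, ora_p); hi <- pmax(om$p, ora_p)
  # agreement within one order of magnitude for informative sites
  idx <- which(hi < 0.1)
  expect_true(all(log10(hi[idx]) - log10(lo[idx]) <= 1))
  expect_lt(om$p[7], 1e-3)

  # pure-noise traits give roughly uniform omnibus p
  Y0 <- matrix(rnorm(n * 3), n, 3, dimnames = list(colnames(d), NULL))
  om0 <- multitraitScan(Y0, d, K)
  expect_gt(ks.test(om0$p, "punif")$p.value, 0.01)
})

test_that("phenotype PCA: rank-1 data, reconstruction identity,
          planted factors", {
  # two duplicated sample clusters -> PC1 explains everything
  base <- matrix(rnorm(2 * 6), 2, 6)
  peaks <- base[rep(1:2, each = 10), ]
  pc <- phenotypePca(peaks, n_pcs = 2)
  expect_equal(pc$var_fraction[1], 1, tolerance = 1e-10)

  set.seed(10)
  m <- matrix(rnorm(30 * 8), 30, 8)
  pc2 <- phenotypePca(m, n_pcs = 8)
  centred <- sweep(m, 2, colMeans(m))
  rec <- pc2$scores %*% t(pc2$loadings)
  expect_equal(unname(rec), unname(centred), tolerance = 1e-8)

  # 26 peaks driven by 4 latent factors: first 4 PCs capture the planted
  # variance fraction
  fac <- matrix(rnorm(200 * 4), 200, 4)
  load <- matrix(rnorm(4 * 26, sd = 2), 4, 26)
  peaks4 <- fac %*% load + matrix(rnorm(200 * 26, sd = 0.5), 200, 26)
  p4 <- phenotypePca(peaks4, n_pcs = 4)
  planted_frac <- sum(diag(var(fac %*% load))) /
    sum(diag(var(peaks4)))
  expect_gte(sum(p4$var_fraction), planted_frac - 0.02)
})

test_that("p-value adjustment matches the step-up oracle and validates
          input", {
  p <- c(0.001, 0.01, 0.02, 0.04, 0.9)
  # direct BH step-up transcription
  m <- length(p)
  o <- order(p)
  stepup <- rev(cummin(rev(p[o] * m / seq_len(m))))
  exp_bh <- numeric(m); exp_bh[o] <- pmin(1, stepup)
  expect_equal(adjustPvalues(p, "BH"), exp_bh)
  expect_equal(exp_bh, c(0.005, 0.025, 1 / 30, 0.05, 0.9),
               tolerance = 1e-12)

  expect_equal(adjustPvalues(0.03, "BH"), 0.03)
  expect_equal(adjustPvalues(rep(1, 4), "BH"), rep(1, 4))
  expect_equal(adjustPvalues(c(0.01, 0.5), "bonferroni"), c(0.02, 1))
  expect_error(adjustPvalues(c(0.5, 0)), "0, 1")
  expect_error(adjustPvalues(c(0.5, 1.2)), "0, 1")

  # monotone in the order statistics
  set.seed(11)
  pr <- runif(50)
  adj <- adjustPvalues(pr, "BH")
  expect_true(all(diff(adj[order(pr)]) >= -1e-12))
})
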