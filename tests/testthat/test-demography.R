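# small helper: population map for two 5-diploid populations + outgroup
two_pop_gd <- function(d, outg = NULL) {
  n1 <- 5; n2 <- 5
  no <- if (is.null(outg)) 0 else ncol(outg)
  dos <- cbind(d, outg)
  pm <- data.frame(
    population = rep(c("P1", "P2", "OG"), c(n1, n2, no)),
    species = rep(c("A", "B", "O"), c(n1, n2, no)),
    context = "allopatric", lat = 0, lon = 0)
  rownames(pm) <- colnames(dos) <- paste0("i", seq_len(ncol(dos)))
  GenotypeData(dos, rep("c1", nrow(dos)), seq_len(nrow(dos)),
               sampleData = pm)
}

test_that("joint SFS construction places derived counts correctly", {
  # species A fixed derived (10 alleles), B fixed ancestral
  d <- cbind(matrix(2, 1, 5), matrix(0, 1, 5))
  og <- matrix(0, 1, 3)
  gd <- two_pop_gd(d, og)
  sfs <- buildJointSfs(gd, "P1", "P2", outgroup = "OG")
  expect_equal(sfsCounts(sfs)[11, 1], 1)
  expect_equal(sum(sfsCounts(sfs)), 1)

  # all-monomorphic-ancestral sites land in the masked (0,0) corner
  d0 <- matrix(0, 4, 10)
  gd0 <- two_pop_gd(d0, matrix(0, 4, 3))
  sfs0 <- buildJointSfs(gd0, "P1", "P2", outgroup = "OG")
  expect_equal(sfsCounts(sfs0)[1, 1], 4)
  expect_false(sfsMask(sfs0)[1, 1])
})

test_that("on-the-fly projection equals per-site hypergeometric sums", {
  set.seed(33)
  L <- 200
  d <- random_dosage(L, 10, miss = 0.15, seed = 33)
  og <- matrix(0, L, 3)
  gd <- two_pop_gd(d, og)
  tgt <- c(6, 6)
  sfs <- buildJointSfs(gd, "P1", "P2", outgroup = "OG", project = TRUE,
                       target = tgt)
  # oracle: direct summation of dhyper weights per site
  exp_counts <- matrix(0, tgt[1] + 1, tgt[2] + 1)
  for (s in seq_len(L)) {
    d1 <- d[s, 1:5]; d2 <- d[s, 6:10]
    k1 <- sum(d1, na.rm = TRUE); m1 <- 2 * sum(!is.na(d1))
    k2 <- sum(d2, na.rm = TRUE); m2 <- 2 * sum(!is.na(d2))
    if (m1 < tgt[1] || m2 < tgt[2]) next
    w1 <- dhyper(0:tgt[1], k1, m1 - k1, tgt[1])
    w2 <- dhyper(0:tgt[2], k2, m2 - k2, tgt[2])
    exp_counts <- exp_counts + outer(w1, w2)
  }
  expect_equal(sfsCounts(sfs), exp_counts, tolerance = 1e-12)
})

test_that("SFS projection: closed form, identity and mass conservation", {
  m <- matrix(0, 7, 3)
  m[4, 1] <- 1  # entry (3, 0) with n1 = 6
  sfs <- JointSFS(m)
  pr <- projectSfs(sfs, 4, 2)
  expect_equal(sfsCounts(pr)[, 1],
               c(0, 3, 9, 3, 0) / 15, tolerance = 1e-12)

  same <- projectSfs(sfs, 6, 2)
  expect_equal(sfsCounts(same), sfsCounts(sfs))

  set.seed(4)
  big <- JointSFS(matrix(rpois(9 * 7, 5), 9, 7))
  down <- projectSfs(big, 4, 3)
  expect_equal(sum(sfsCounts(down)), sum(sfsCounts(big)), tolerance = 1e-9)
  expect_error(projectSfs(big, 10, 3), "upward")
})

test_that("expected SFS recovers the neutral 1/i law in the single-deme
          limit", {
  es <- expectedSfs("no_mig", list(nu1 = 1, nu2 = 1, T1 = 1e-9), 2, 2,
                    n_reps = 10000, seed = 2)
  # pool cells by total derived count: expect proportional to 1, 1/2, 1/3
  tot <- sapply(1:3, function(k) {
    s <- 0
    for (i in 0:2) for (j in 0:2) if (i + j == k) s <- s + es[i + 1, j + 1]
    s
  })
  ratio <- tot / tot[1]
  se <- 3 * 0.5 / sqrt(10000)  # generous MC bound
  expect_lt(abs(ratio[2] - 1 / 2), 3 * se)
  expect_lt(abs(ratio[3] - 1 / 3), 3 * se)
})

test_that("deep divergence concentrates mass in the fixed-difference
          margins", {
  es <- expectedSfs("no_mig", list(nu1 = 1, nu2 = 1, T1 = 20), 6, 6,
                    n_reps = 4000, seed = 3)
  es[1, 1] <- es[7, 7] <- 0
  interior <- es
  interior[1, ] <- 0; interior[, 1] <- 0
  # almost all non-corner mass sits in the margins (one species fixed)
  expect_lt(sum(interior) / sum(es), 0.05)

  sim <- simulateJointSfs("no_mig", list(nu1 = 1, nu2 = 1, T1 = 20), 6, 6,
                          n_loci = 2000, seed = 5)
  cnt <- sfsCounts(sim)
  marg <- sum(cnt[, 1]) + sum(cnt[1, ]) + cnt[7, 7]
  expect_gte(marg / sum(cnt), 0.95)
})

test_that("common random numbers make expected spectra reproducible", {
  a <- expectedSfs("sym_mig", list(nu1 = 1, nu2 = 2, T1 = 1, m = 1), 4, 4,
                   n_reps = 1500, seed = 11)
  b <- expectedSfs("sym_mig", list(nu1 = 1, nu2 = 2, T1 = 1, m = 1), 4, 4,
                   n_reps = 1500, seed = 11)
  expect_identical(a, b)
  s1 <- simulateJointSfs("anc_mig", list(nu1 = 1, nu2 = 1, T1 = 2, T2 = 1,
                                         m = 2), 4, 4, 500, seed = 9)
  s2 <- simulateJointSfs("anc_mig", list(nu1 = 1, nu2 = 1, T1 = 2, T2 = 1,
                                         m = 2), 4, 4, 500, seed = 9)
  expect_identical(sfsCounts(s1), sfsCounts(s2))
})

test_that("high migration pulls the spectrum towards panmixia", {
  pan <- expectedSfs("no_mig", list(nu1 = 1, nu2 = 1, T1 = 1e-9), 4, 4,
                     n_reps = 6000, seed = 13)
  hi <- expectedSfs("sym_mig", list(nu1 = 1, nu2 = 1, T1 = 2, m = 10), 4, 4,
                    n_reps = 6000, seed = 14)
  none <- expectedSfs("no_mig", list(nu1 = 1, nu2 = 1, T1 = 2), 4, 4,
                      n_reps = 6000, seed = 15)
  nrm <- function(m) m / sum(m)
  d_hi <- sqrt(sum((nrm(hi) - nrm(pan))^2))
  d_no <- sqrt(sum((nrm(none) - nrm(pan))^2))
  expect_lt(d_hi, d_no)
})

test_that("label swap transposes the expected spectrum (statistically)", {
  a <- expectedSfs("no_mig", list(nu1 = 0.5, nu2 = 2, T1 = 1), 4, 4,
                   n_reps = 8000, seed = 21)
  b <- expectedSfs("no_mig", list(nu1 = 2, nu2 = 0.5, T1 = 1), 4, 4,
                   n_reps = 8000, seed = 22)
  expect_lt(max(abs(a - t(b))) / max(a), 0.15)
})

test_that("theta profiling makes the likelihood scale-invariant", {
  obs <- sfsCounts(simulateJointSfs("no_mig", list(nu1 = 1, nu2 = 1, T1 = 1),
                                    4, 4, 1000, seed = 3))
  mask <- matrix(TRUE, 5, 5); mask[1, 1] <- mask[5, 5] <- FALSE
  m <- matrix(runif(25, 0.1, 1), 5, 5)
  l1 <- barrierscan:::.sfsLogLik(obs, m, mask)
  l2 <- barrierscan:::.sfsLogLik(obs, 7.3 * m, mask)
  expect_equal(l1, l2, tolerance = 1e-9)
})

test_that("AIC arithmetic and model ranking follow definitions", {
  fake <- function(model, k, ll) structure(
    list(model = model, params = list(), logLik = ll, k = k,
         AIC = 2 * k - 2 * ll, obs_signature = c(8, 8, 100)),
    class = "demogFit")
  expect_equal(fake("no_mig", 3, -100)$AIC, 206)
  cmp <- compareModels(list(fake("a", 4, -50), fake("b", 3, -50)))
  expect_equal(cmp$model, c("b", "a"))  # tie in lnL: smaller k first
  expect_equal(cmp$deltaAIC, c(0, 2))
  one <- compareModels(list(fake("solo", 3, -10)))
  expect_equal(one$deltaAIC, 0)
  bad <- fake("c", 3, -10); bad$obs_signature <- c(4, 4, 50)
  expect_error(compareModels(list(fake("a", 3, -1), bad)), "different")
})

test_that("fitting the generating spectrum approaches the saturated bound", {
  obs <- simulateJointSfs("no_mig", list(nu1 = 1, nu2 = 1, T1 = 1), 6, 6,
                          n_loci = 3000, seed = 7)
  cnt <- sfsCounts(obs); mask <- sfsMask(obs)
  # Poisson saturated bound: mu = obs
  o <- cnt[mask]
  sat <- sum(ifelse(o > 0, o * log(o) - o - lgamma(o + 1), 0))
  mexp <- expectedSfs("no_mig", list(nu1 = 1, nu2 = 1, T1 = 1), 6, 6,
                      n_reps = 4000, seed = 8)
  ll <- barrierscan:::.sfsLogLik(cnt, mexp, mask)
  expect_lte(ll, sat + 1e-9)
  expect_gt(ll, sat - 60)  # within MC + model noise of the ceiling
})
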