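test_that("between-species FST calibrates to the Balding-Nichols target", {
  # 2 populations per species, 20 diploids each, neutral sites only
  pops <- rbind(
    data.frame(id = c("A1", "A2"), species = "A", context = "allopatric",
               lat = 0, lon = 0, n = 20),
    data.frame(id = c("B1", "B2"), species = "B", context = "allopatric",
               lat = 0, lon = 0, n = 20))
  means <- sapply(1:10, function(sd_) {
    cfg <- simulationConfig(seed = sd_, populations = pops, n_sites = 2000,
                            F_between = 0.10, F_within = 0.01,
                            missing_rate = 0)
    gd <- simulateSnpDataset(cfg)$data
    wcFst(dosages(gd), popMap(gd)$species)$mean_of_ratios
  })
  expect_lt(abs(mean(means) - 0.10), 0.03)
})

test_that("frequency mixing collapses between-species differentiation", {
  # mixing applied in every population by marking all of them sympatric
  pops <- rbind(
    data.frame(id = c("A1", "A2"), species = "A", context = "sympatric",
               lat = 0, lon = 0, n = 15),
    data.frame(id = c("B1", "B2"), species = "B", context = "sympatric",
               lat = 0, lon = 0, n = 15))
  for (sd_ in 1:10) {
    base <- simulateSnpDataset(simulationConfig(
      seed = sd_, populations = pops, n_sites = 1000, alpha = 0))$data
    mixed <- simulateSnpDataset(simulationConfig(
      seed = sd_, populations = pops, n_sites = 1000, alpha = 0.5))$data
    f0 <- wcFst(dosages(base), popMap(base)$species)$mean_of_ratios
    f1 <- wcFst(dosages(mixed), popMap(mixed)$species)$mean_of_ratios
    expect_lt(f1, f0)
  }
})

test_that("the no-drift limit gives near-zero within-species FST", {
  cfg <- simulationConfig(seed = 5, n_sites = 3000, F_within = 0.001,
                          missing_rate = 0)
  gd <- simulateSnpDataset(cfg)$data
  pm <- popMap(gd)
  keep <- pm$species == "A"
  res <- wcFst(dosages(gd)[, keep], pm$population[keep])
  expect_lt(res$mean_of_ratios, 0.01)
})

test_that("dosages are Hardy-Weinberg consistent within populations", {
  cfg <- simulationConfig(seed = 17, n_sites = 400, missing_rate = 0,
                          populations = defaultPopulations(n_per_pop = 30))
  gd <- simulateSnpDataset(cfg)$data
  pm <- popMap(gd)
  d <- dosages(gd)[, pm$population == "AL1"]
  pvals <- apply(d, 1, function(g) {
    p <- mean(g) / 2
    if (p <= 0.05 || p >= 0.95) return(NA)
    expc <- length(g) * c((1 - p)^2, 2 * p * (1 - p), p^2)
    obs <- c(sum(g == 0), sum(g == 1), sum(g == 2))
    suppressWarnings(chisq.test(obs, p = expc / sum(expc))$p.value)
  })
  # chi-square failure rate near nominal 5%
  expect_lt(mean(pvals < 0.05, na.rm = TRUE), 0.12)
})

test_that("truth roles partition sites and generation is reproducible", {
  cfg <- simulationConfig(seed = 3, n_sites = 500, barrier_fraction = 0.05,
                          barrier_F = 0.5, alpha = 0.2,
                          introgressed_fraction = 0.5)
  sim1 <- simulateSnpDataset(cfg)
  sim2 <- simulateSnpDataset(cfg)
  expect_identical(dosages(sim1$data), dosages(sim2$data))
  expect_identical(sim1$truth, sim2$truth)
  expect_equal(nrow(sim1$truth), 500)
  expect_true(all(sim1$truth$role %in%
                    c("neutral", "barrier", "introgressed")))
  expect_equal(sum(sim1$truth$role == "barrier"), 25)

  expect_error(simulationConfig(barrier_fraction = 0.1, barrier_F = 0.05),
               "barrier_F")
  expect_error(simulationConfig(alpha = 1), "alpha")
})

test_that("conditioned hard sweeps reach high frequency at s = 0.1", {
  hits <- sapply(1:10, function(sd_) {
    fw <- simulateForwardRegion(
      n_diploid = 100, region_bp = 2e4, mu = 1e-7, r = 1e-7,
      generations = 400, selection = list(site = 1e4, s = 0.1),
      burn_in = 0, seed = sd_)
    fw$sel_freq > 0.8
  })
  expect_gte(sum(hits), 8)
})

test_that("forward-simulation degenerate limits behave", {
  none <- simulateForwardRegion(n_diploid = 30, region_bp = 1e4, mu = 0,
                                r = 1e-7, generations = 50, seed = 2)
  expect_equal(length(none$positions), 0L)

  # no recombination: every haplotype's mutation set is nested along its
  # lineage; with r = 0 two haplotypes never interleave ancestries, so
  # any two final haplotypes are identical, disjoint, or nested on the
  # founder mutations
  fw <- simulateForwardRegion(n_diploid = 25, region_bp = 1e4, mu = 2e-5,
                              r = 0, generations = 30, burn_in = 60,
                              seed = 3)
  expect_gt(length(fw$positions), 0)
  expect_error(simulateForwardRegion(selection = list(site = 1, s = -0.1)),
               "hard sweeps")
  expect_error(simulateForwardRegion(n_diploid = 10), "n_diploid")

  # reproducibility
  a <- simulateForwardRegion(n_diploid = 30, region_bp = 1e4, mu = 1e-5,
                             r = 1e-6, generations = 20, burn_in = 40,
                             seed = 11)
  b <- simulateForwardRegion(n_diploid = 30, region_bp = 1e4, mu = 1e-5,
                             r = 1e-6, generations = 20, burn_in = 40,
                             seed = 11)
  expect_identical(a$haplotypes, b$haplotypes)
})

test_that("planted QTLs explain the requested variance fraction", {
  set.seed(20)
  pops <- data.frame(id = c("P1", "P2"), species = c("A", "B"),
                     context = "allopatric", lat = 0, lon = 0, n = 200)
  cfg <- simulationConfig(seed = 21, populations = pops, n_sites = 100,
                          missing_rate = 0)
  gd <- simulateSnpDataset(cfg)$data
  r2 <- sapply(1:10, function(sd_) {
    g <- dosages(gd)[50, ]
    eff <- sqrt(0.2 / 0.8 / var(g))
    ph <- simulatePhenotypes(gd, qtl_spec = list(
      song_1 = data.frame(site = 50, effect = eff)),
      h2_polygenic = 0, noise_sd = 1, seed = sd_)
    summary(lm(ph$phenotypes$song_1 ~ g))$r.squared
  })
  expect_lt(abs(mean(r2) - 0.2), 0.05)

  # null effects give near-zero trait-dosage correlations
  ph0 <- simulatePhenotypes(gd, qtl_spec = list(), h2_polygenic = 0,
                            noise_sd = 1, seed = 30)
  n <- ncol(gd)
  cors <- abs(cor(ph0$phenotypes$song_3, t(dosages(gd))))
  expect_lt(mean(cors > 3 / sqrt(n)), 0.05)

  # CHC peaks are non-negative; covariates correlate with the focal trait
  expect_true(all(ph0$phenotypes[, grep("^chc_", colnames(ph0$phenotypes))]
                  >= 0))
  expect_gt(cor(ph0$phenotypes$mass, ph0$phenotypes$song_1), 0.2)
  expect_error(simulatePhenotypes(gd, h2_polygenic = 1.2), "h2")
})

test_that("two traits sharing a QTL both map to it in a genome scan", {
  pops <- data.frame(id = c("P1", "P2"), species = c("A", "B"),
                     context = "allopatric", lat = 0, lon = 0, n = 200)
  cfg <- simulationConfig(seed = 31, populations = pops, n_sites = 300,
                          missing_rate = 0)
  gd <- simulateSnpDataset(cfg)$data
  g <- dosages(gd)[100, ]
  eff <- sqrt(0.25 / var(g))
  spec <- list(song_1 = data.frame(site = 100, effect = eff),
               song_2 = data.frame(site = 100, effect = eff))
  ph <- simulatePhenotypes(gd, qtl_spec = spec, h2_polygenic = 0,
                           noise_sd = 1, seed = 32)
  K <- computeGrm(gd)
  for (tr in c("song_1", "song_2")) {
    y <- ph$phenotypes[[tr]]
    names(y) <- ph$phenotypes$sample
    sc <- lmmWaldScan(y, gd, K)
    expect_equal(sc$site[which.min(sc$p)], rownames(gd)[100])
  }
})
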