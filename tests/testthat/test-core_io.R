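test_that("VCF ingest transcribes dosages, phase and missingness", {
  f <- tempfile(fileext = ".vcf")
  write_toy_vcf(f, chrom = rep("sc1", 3), pos = c(100, 200, 300),
                ref = c("A", "C", "G"), alt = c("T", "G", "A"),
                qual = c(50, 60, 70),
                gts = list(c("0/0", "0/1"), c("1/1", "./."),
                           c("0|1", "1|1")))
  gd <- readVcfGenotypes(f)
  expect_equal(unname(dosages(gd)),
               matrix(c(0, 2, 1, 1, NA, 2), 3, 2), ignore_attr = TRUE)
  # phase preserved only when every call is phased: site 3 alone is phased,
  # so no genome-wide haplotype matrix
  expect_null(haplotypes(gd))
  expect_identical(S4Vectors::metadata(gd)$n_skipped, 0L)

  # fully phased file keeps haplotypes
  f2 <- tempfile(fileext = ".vcf")
  write_toy_vcf(f2, "sc1", c(1, 2), c("A", "C"), c("T", "G"), c(9, 9),
                gts = list(c("0|1", "1|1"), c("0|0", "1|0")))
  gd2 <- readVcfGenotypes(f2)
  expect_equal(unname(haplotypes(gd2)),
               matrix(c(0L, 1L, 1L, 1L, 0L, 0L, 1L, 0L), 2, 4,
                      byrow = TRUE))
  expect_equal(unname(dosages(gd2)), matrix(c(1, 0, 2, 1), 2, 2))
})

test_that("multi-allelic and indel records are skipped and counted", {
  f <- tempfile(fileext = ".vcf")
  write_toy_vcf(f, rep("sc1", 3), c(10, 20, 30),
                ref = c("A", "C", "GT"), alt = c("A,T", "G", "G"),
                qual = c(50, 50, 50),
                gts = list(c("0/1", "0/0"), c("0/0", "0/1"),
                           c("0/0", "0/0")))
  gd <- readVcfGenotypes(f)
  expect_equal(nrow(gd), 1L)
  expect_identical(S4Vectors::metadata(gd)$n_skipped, 2L)
})

test_that("empty VCF body yields a 0-site matrix without error", {
  f <- tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT", "S1", "S2"),
                     collapse = "\t")), f)
  gd <- readVcfGenotypes(f)
  expect_equal(nrow(gd), 0L)
  expect_equal(ncol(gd), 2L)
})

test_that("write/read round-trip preserves dosages, phase and order", {
  set.seed(7)
  d <- random_dosage(30, 6, miss = 0.15)
  gd <- GenotypeData(d, chrom = rep("sc2", 30), pos = sort(sample(1e5, 30)),
                     qual = round(runif(30, 30, 90), 2))
  f <- tempfile(fileext = ".vcf")
  writeVcfGenotypes(gd, f)
  back <- readVcfGenotypes(f)
  expect_equal(unname(dosages(back)), unname(dosages(gd)))
  expect_equal(GenomicRanges::start(siteRanges(back)),
               GenomicRanges::start(siteRanges(gd)))

  # phased round-trip
  h <- matrix(rbinom(20 * 8, 1, 0.5), 20, 8)
  gp <- GenotypeData(h[, c(1, 3, 5, 7)] + h[, c(2, 4, 6, 8)],
                     chrom = rep("sc1", 20), pos = 1:20, haplotypes = h)
  f2 <- tempfile(fileext = ".vcf")
  writeVcfGenotypes(gp, f2)
  back2 <- readVcfGenotypes(f2)
  expect_equal(unname(haplotypes(back2)), unname(h))
})

test_that("filters apply in the documented order with correct thresholds", {
  # QUAL threshold edge: a site at QUAL 29 among clean sites is removed
  set.seed(3)
  d <- matrix(rbinom(50, 2, 0.5), 5, 10,
              dimnames = list(paste0("s", 1:5), paste0("i", 1:10)))
  gd <- GenotypeData(d, rep("c1", 5), 1:5,
                     qual = c(80, 29, 80, 80, 80),
                     depth = matrix(30, 5, 10))
  res <- applyFilters(gd, min_mac = 0)
  expect_equal(res$report$sites_qual, 1L)
  expect_false("c1:2" %in% rownames(res$data))

  # 6 of 10 calls missing (0.6 > 0.5) drops the site
  d2 <- d
  d2[3, 1:6] <- NA
  gd2 <- GenotypeData(d2, rep("c1", 5), 1:5, qual = rep(80, 5),
                      depth = matrix(30, 5, 10))
  res2 <- applyFilters(gd2, min_mac = 0)
  expect_false("c1:3" %in% rownames(res2$data))
  expect_equal(res2$report$sites_missing, 1L)

  # all sites removed -> empty flag, no exception
  gd3 <- GenotypeData(d, rep("c1", 5), 1:5, qual = rep(10, 5),
                      depth = matrix(30, 5, 10))
  res3 <- applyFilters(gd3)
  expect_true(res3$empty)
  expect_equal(nrow(res3$data), 0L)
})

test_that("filtering matches an independent rule transcription and is
          idempotent", {
  set.seed(11)
  L <- 50; n <- 12
  d <- random_dosage(L, n, miss = 0.12, seed = 11)
  dp <- matrix(rpois(L * n, 14), L, n)
  qual <- round(runif(L, 10, 90))
  gd <- GenotypeData(d, rep("c1", L), seq_len(L) * 10, qual = qual,
                     depth = dp)
  res <- applyFilters(gd)

  # oracle: direct transcription of the rules in order
  dd <- d
  dd[!is.na(dd) & dp < 10] <- NA
  mac <- function(m) {
    alt <- rowSums(m, na.rm = TRUE); tot <- 2 * rowSums(!is.na(m))
    pmin(alt, tot - alt)
  }
  keep_site <- qual >= 30 & rowMeans(is.na(dd)) <= 0.5 & mac(dd) >= 3
  m2 <- dd[keep_site, , drop = FALSE]
  keep_samp <- colMeans(is.na(m2)) < 0.5
  m3 <- m2[, keep_samp, drop = FALSE]
  keep2 <- mac(m3) >= 3
  expect_equal(unname(dosages(res$data)),
               unname(m3[keep2, , drop = FALSE]))

  # idempotence
  res2 <- applyFilters(res$data)
  expect_equal(dosages(res2$data), dosages(res$data))
})

test_that("windows tile chromosomes without gaps and truncate at ends", {
  w <- makeWindows(c(chrA = 25000))
  expect_equal(GenomicRanges::start(w) - 1L, c(0L, 10000L, 20000L))
  expect_equal(GenomicRanges::end(w), c(10000L, 20000L, 25000L))
  w2 <- makeWindows(c(chrA = 10000))
  expect_equal(length(w2), 1L)
  expect_equal(GenomicRanges::end(w2), 10000L)
  w3 <- makeWindows(c(chrA = 1))
  expect_equal(GenomicRanges::start(w3), 1L)
  expect_equal(GenomicRanges::end(w3), 1L)
  expect_error(makeWindows(c(chrA = 100), size = 10, step = 20), "gaps")
})

test_that("SNP-to-gene mapping honors the flank boundary exactly", {
  genes <- GenomicRanges::GRanges("c1",
    IRanges::IRanges(start = 50001, end = 60000))
  S4Vectors::mcols(genes)$gene_id <- "g1"
  near <- GenomicRanges::GRanges("c1", IRanges::IRanges(65000, width = 1))
  far <- GenomicRanges::GRanges("c1", IRanges::IRanges(70001, width = 1))
  edge <- GenomicRanges::GRanges("c1", IRanges::IRanges(70000, width = 1))
  expect_equal(nrow(mapFeatures(near, genes)), 1L)
  expect_equal(nrow(mapFeatures(far, genes)), 0L)   # 10,001 bp away
  expect_equal(nrow(mapFeatures(edge, genes)), 1L)  # exactly 10,000 bp
})

test_that("feature mapping equals a brute-force all-pairs interval check", {
  set.seed(5)
  gstart <- sort(sample(1e5, 20))
  genes <- GenomicRanges::GRanges("c1",
    IRanges::IRanges(start = gstart + 1, end = gstart + sample(500:2000, 20)))
  S4Vectors::mcols(genes)$gene_id <- paste0("g", 1:20)
  pos <- sort(sample(1.2e5, 100))
  snps <- GenomicRanges::GRanges("c1", IRanges::IRanges(pos, width = 1))
  for (flank in c(0, 5000)) {
    got <- mapFeatures(snps, genes, flank = flank)
    exp <- do.call(rbind, lapply(seq_along(pos), function(i) {
      hit <- which(pos[i] - 1 >= gstart - flank &
                     pos[i] - 1 < GenomicRanges::end(genes) + flank)
      if (length(hit)) data.frame(feature = i, gene_id = paste0("g", hit))
    }))
    got <- got[order(got$feature, got$gene_id), ]
    exp <- exp[order(exp$feature, exp$gene_id), ]
    expect_equal(got$feature, exp$feature)
    expect_equal(got$gene_id, exp$gene_id)
  }
})

test_that("population map and gene annotation readers validate input", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("sample\tpopulation\tspecies\tcontext\tlat\tlon",
               "s1\tP1\tA\tsympatric\t-27.1\t153.0"), f)
  pm <- readPopMap(f)
  expect_equal(pm$population, "P1")
  writeLines(c("sample\tpopulation\tspecies\tcontext\tlat\tlon",
               "s1\tP1\tA\tweird\t0\t0"), f)
  expect_error(readPopMap(f), "context")

  bed <- tempfile(fileext = ".bed")
  writeLines(c("c1\t100\t200\tgeneX\t0\t+"), bed)
  gr <- readGenes(bed)
  expect_equal(GenomicRanges::start(gr), 101L)  # 0-based BED to 1-based
  expect_equal(GenomicRanges::end(gr), 200L)
  gff <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "c1\tsrc\tgene\t101\t200\t.\t+\t.\tID=geneY;Name=geneY"),
             gff)
  gr2 <- readGenes(gff)
  expect_equal(GenomicRanges::start(gr2), 101L)
  expect_equal(S4Vectors::mcols(gr2)$gene_id, "geneY")
})
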