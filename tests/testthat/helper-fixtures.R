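# Small in-code fixtures shared across test files.

# write a VCF text file from parallel vectors; gts is a list of per-site
# character vectors like c("0/0", "0|1")
write_toy_vcf <- function(path, chrom, pos, ref, alt, qual, gts,
                          samples = paste0("S", seq_along(gts[[1]])),
                          format = "GT") {
  hdr <- c("##fileformat=VCFv4.2",
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Depth">',
           '##FORMAT=<ID=GQ,Number=1,Type=Integer,Description="GQ">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  body <- vapply(seq_along(pos), function(i)
    paste(c(chrom[i], pos[i], ".", ref[i], alt[i], qual[i], "PASS", ".",
            format, gts[[i]]), collapse = "\t"), character(1))
  writeLines(c(hdr, body), path)
  path
}

# random dosage matrix with missingness
random_dosage <- function(L, n, miss = 0.1, seed = 1) {
  set.seed(seed)
  d <- matrix(rbinom(L * n, 2, runif(L, 0.1, 0.9)), L, n)
  d[matrix(runif(L * n) < miss, L, n)] <- NA
  rownames(d) <- paste0("s", seq_len(L))
  colnames(d) <- paste0("i", seq_len(n))
  d
}

# scalar, loop-based transcription of the Weir & Cockerham (1984)
# variance components for one biallelic site (independent oracle)
wc84_site_oracle <- function(dosage, pop) {
  pops <- unique(pop[!is.na(dosage) | TRUE])
  ni <- pi_ <- hi <- numeric(0)
  for (p in unique(pop)) {
    g <- dosage[pop == p]
    g <- g[!is.na(g)]
    if (!length(g)) next
    ni <- c(ni, length(g))
    pi_ <- c(pi_, sum(g) / (2 * length(g)))
    hi <- c(hi, mean(g == 1))
  }
  r <- length(ni)
  if (r < 2) return(c(a = NA, b = NA, c = NA, fst = NA))
  nbar <- mean(ni)
  nc <- (sum(ni) - sum(ni^2) / sum(ni)) / (r - 1)
  pbar <- sum(ni * pi_) / sum(ni)
  s2 <- sum(ni * (pi_ - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(ni * hi) / sum(ni)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 -
       (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  if (pbar <= 0 || pbar >= 1 || a + b + cc == 0)
    return(c(a = NA, b = NA, c = NA, fst = NA))
  c(a = a, b = b, c = cc, fst = a / (a + b + cc))
}
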