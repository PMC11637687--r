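#' Extended haplotype homozygosity decay from a core site
#'
#' EHH at flank distance x is the probability that two random haplotypes
#' of the core allele class are identical over [core, x]:
#' sum over identity groups g of C(n_g, 2), divided by C(n, 2). Computed
#' outward in both directions until EHH falls below \code{cutoff} (that
#' value is recorded) or the chromosome ends.
#'
#' @param hap haplotype matrix, rows = haplotypes, columns = sites (0/1).
#' @param positions physical positions per site (ascending).
#' @param core core site index (1-based column).
#' @param allele core allele class, 0 (ancestral) or 1 (derived).
#' @param cutoff EHH stopping threshold (default 0.05).
#' @return data.frame: site, position, distance, ehh, side
#'   (\code{"left"}/\code{"right"}); \code{NULL} when the class has < 2
#'   haplotypes.
#' @export
ehhDecay <- function(hap, positions, core, allele = 1, cutoff = 0.05) {
  stopifnot(ncol(hap) == length(positions))
  if (sum(hap[, core] == allele) < 2) return(NULL)
  r <- .ehh_decay_cpp(hap, core - 1L, as.integer(allele), cutoff)
  out <- data.frame(
    site = c(r$left_index, r$right_index) + 1L,
    ehh = c(r$left_ehh, r$right_ehh),
    side = rep(c("left", "right"),
               c(length(r$left_index), length(r$right_index))))
  if (!nrow(out)) return(out)
  out$position <- positions[out$site]
  out$distance <- abs(out$position - positions[core])
  out[, c("site", "position", "distance", "ehh", "side")]
}

#' Raw integrated haplotype score scan
#'
#' For each qualifying site, iHH for the ancestral and derived allele
#' classes is the trapezoidal integral of their EHH curves against
#' physical distance (both directions summed, starting from EHH = 1 at
#' the core); iHS_raw = ln(iHH_A / iHH_D). Sites where either class's EHH
#' never falls below \code{cutoff} before the data end are flagged
#' truncated (kept by default).
#'
#' @param hap phased haplotype matrix (rows = haplotypes, 0 = ancestral,
#'   1 = derived).
#' @param positions physical positions (bp), ascending.
#' @param maf_min minimum minor allele frequency (default 0.05).
#' @param cutoff EHH integration cutoff (default 0.05).
#' @param keep_truncated retain truncated-integral sites.
#' @return data.frame: site, position, freq (derived), ihh_a, ihh_d,
#'   ihs_raw, truncated.
#' @export
ihsScan <- function(hap, positions, maf_min = 0.05, cutoff = 0.05,
                    keep_truncated = TRUE) {
  stopifnot(ncol(hap) == length(positions))
  freq <- colMeans(hap)
  maf <- pmin(freq, 1 - freq)
  nhap <- nrow(hap)
  cand <- which(maf >= maf_min & freq * nhap >= 2 & (1 - freq) * nhap >= 2)
  rows <- lapply(cand, function(j) {
    r <- .ihs_core_cpp(hap, as.numeric(positions), j - 1L, cutoff)
    if (r$ihh_a <= 0 || r$ihh_d <= 0) return(NULL)
    data.frame(site = j, position = positions[j], freq = freq[j],
               ihh_a = r$ihh_a, ihh_d = r$ihh_d,
               ihs_raw = log(r$ihh_a / r$ihh_d), truncated = r$truncated)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(site = integer(), position = numeric(),
                      freq = numeric(), ihh_a = numeric(),
                      ihh_d = numeric(), ihs_raw = numeric(),
                      truncated = logical())
  if (!keep_truncated) out <- out[!out$truncated, , drop = FALSE]
  out
}

#' Standardize iHS within derived-frequency bins and call outliers
#'
#' Sites are binned by derived-allele frequency into \code{n_bins}
#' equal-width bins; within each bin iHS_std = (raw - bin mean) / bin SD.
#' Outliers are sites with |iHS_std| at or above its empirical
#' \code{q}-quantile. When gene annotations are supplied, outlier sites
#' are mapped to genes via \code{\link{mapFeatures}}.
#'
#' @param scan output of \code{\link{ihsScan}}.
#' @param n_bins number of frequency bins (default 20).
#' @param q outlier quantile on |iHS_std| (default 0.99).
#' @param genes optional GRanges of genes; \code{chrom} names the scan's
#'   chromosome.
#' @param flank gene flank in bp for mapping.
#' @param chrom chromosome name for the scanned region.
#' @return list: \code{scan} (input plus bin, ihs_std, outlier),
#'   \code{threshold}, \code{outlier_genes} (character, possibly empty).
#' @export
standardizeIhs <- function(scan, n_bins = 20, q = 0.99, genes = NULL,
                           flank = 10000, chrom = "chr1") {
  if (!nrow(scan)) stop("empty scan")
  breaks <- seq(0, 1, length.out = n_bins + 1)
  bin <- cut(scan$freq, breaks, include.lowest = TRUE, labels = FALSE)
  occ <- table(bin)
  if (any(occ < 50))
    warning("some frequency bins hold < 50 sites; standardization noisy")
  mu <- tapply(scan$ihs_raw, bin, mean)
  # population (1/n) SD so that a 2-site bin standardizes to exactly +-1
  sdv <- tapply(scan$ihs_raw, bin, function(v) sqrt(mean((v - mean(v))^2)))
  if (any(is.na(sdv) | sdv == 0))
    warning("bin(s) with zero/undefined SD: scores undefined there")
  key <- as.character(bin)
  std <- (scan$ihs_raw - mu[key]) / sdv[key]
  std[!is.finite(std)] <- NA
  scan$bin <- bin
  scan$ihs_std <- as.numeric(std)
  absok <- abs(scan$ihs_std)
  thr <- stats::quantile(absok, q, na.rm = TRUE, names = FALSE)
  scan$outlier <- !is.na(absok) & absok >= thr
  genes_hit <- character()
  if (!is.null(genes) && any(scan$outlier)) {
    pts <- GenomicRanges::GRanges(chrom, IRanges::IRanges(
      start = round(scan$position[scan$outlier]), width = 1L))
    mp <- mapFeatures(pts, genes, flank = flank)
    genes_hit <- unique(mp$gene_id)
  }
  list(scan = scan, threshold = thr, outlier_genes = genes_hit)
}
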