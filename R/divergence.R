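#' Site-wise Weir-Cockerham FST
#'
#' The Weir & Cockerham (1984) variance-components estimator computed per
#' site from per-population sample sizes, allele frequencies and observed
#' heterozygosity: components a (among populations), b (among individuals
#' within populations) and c (within individuals); FST = a / (a + b + c).
#' Missing calls are excluded from that site's counts. Sites monomorphic
#' across all analyzed populations have an undefined estimate (NA) and are
#' excluded from the means. Negative per-site estimates are retained by
#' default (set \code{clamp = TRUE} to truncate at 0).
#'
#' @param d sites x samples dosage matrix (0/1/2/NA) or a
#'   \linkS4class{GenotypeData}.
#' @param pop factor/character of population labels, one per sample.
#' @param clamp truncate negative per-site estimates at zero.
#' @return list: \code{sites} (data.frame with a, b, c, fst per site),
#'   \code{mean_of_ratios} (mean of per-site fst, the convention used for
#'   the headline averages), \code{ratio_of_sums} (sum(a)/sum(a+b+c),
#'   the weighted multi-site form).
#' @export
wcFst <- function(d, pop, clamp = FALSE) {
  if (is(d, "GenotypeData")) d <- dosages(d)
  pop <- as.character(pop)
  stopifnot(length(pop) == ncol(d))
  pops <- unique(pop)
  r_full <- length(pops)
  if (r_full < 2) stop("need >= 2 populations")
  L <- nrow(d)
  # per-pop per-site counts
  nmat <- hmat <- pmat <- matrix(0, L, r_full)
  for (k in seq_len(r_full)) {
    dk <- d[, pop == pops[k], drop = FALSE]
    nk <- rowSums(!is.na(dk))
    nmat[, k] <- nk
    pmat[, k] <- ifelse(nk > 0, rowSums(dk, na.rm = TRUE) / (2 * nk), NA)
    hmat[, k] <- ifelse(nk > 0, rowSums(dk == 1, na.rm = TRUE) / nk, NA)
  }
  use <- nmat > 0
  r <- rowSums(use)
  nsum <- rowSums(nmat)
  nbar <- nsum / r
  nsq <- rowSums(nmat^2)
  nc <- (nsum - nsq / nsum) / (r - 1)
  pbar <- rowSums(nmat * ifelse(use, pmat, 0)) / nsum
  s2 <- rowSums(nmat * ifelse(use, (pmat - pbar)^2, 0)) / ((r - 1) * nbar)
  hbar <- rowSums(nmat * ifelse(use, hmat, 0)) / nsum
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  denom <- a + b + cc
  mono <- pbar <= 0 | pbar >= 1
  bad <- r < 2 | mono | !is.finite(denom) | denom == 0
  fst <- ifelse(bad, NA, a / denom)
  if (clamp) fst <- pmax(fst, 0)
  a[bad] <- b[bad] <- cc[bad] <- NA
  sites <- data.frame(site = rownames(d) %||% seq_len(L),
                      a = a, b = b, c = cc, fst = fst)
  ok <- !is.na(fst)
  list(sites = sites,
       mean_of_ratios = if (any(ok)) mean(fst[ok]) else NA_real_,
       ratio_of_sums = if (any(ok))
         sum(a[ok]) / sum((a + b + cc)[ok]) else NA_real_)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Windowed nucleotide diversity and divergence with callable-site
#' denominators
#'
#' Per window: pi (within each population) = sum over sites of differing
#' allele pairs / sum of allele pairs; dXY (between each population pair)
#' analogous over between-population allele pairs. Invariant callable
#' sites contribute comparisons with zero differences; missing alleles are
#' excluded pairwise per site. Without callable-site counts the
#' denominator falls back to variant sites only (flagged).
#'
#' @param x \linkS4class{GenotypeData} (dosages are used; haplotype phase
#'   is irrelevant for these pairwise statistics).
#' @param pop population labels per sample (default from \code{popMap}).
#' @param windows GRanges from \code{\link{makeWindows}}.
#' @param callable_sites optional integer vector, per window, of invariant
#'   callable sites (assumed genotyped in all samples).
#' @return data.frame: window index, chrom, start, end, stat
#'   (\code{"pi"}/\code{"dxy"}), pop1, pop2 (NA for pi), value,
#'   n_valid_sites, n_comparisons, callable_flag.
#' @export
windowDiversity <- function(x, pop = NULL, windows, callable_sites = NULL) {
  d <- dosages(x)
  if (is.null(pop)) pop <- popMap(x)$population
  pop <- as.character(pop)
  rr <- siteRanges(x)
  fallback <- is.null(callable_sites)
  if (fallback) {
    warning("no callable-site counts: denominators use variant sites only")
    callable_sites <- rep(0L, length(windows))
  }
  ov <- GenomicRanges::findOverlaps(rr, windows, ignore.strand = TRUE)
  pops <- unique(pop)
  nP <- length(pops)
  # per-pop per-site derived counts and called-allele counts
  kmat <- mmat <- matrix(0, nrow(d), nP)
  for (j in seq_len(nP)) {
    dj <- d[, pop == pops[j], drop = FALSE]
    kmat[, j] <- rowSums(dj, na.rm = TRUE)
    mmat[, j] <- 2 * rowSums(!is.na(dj))
  }
  nfull <- vapply(pops, function(p) 2L * sum(pop == p), integer(1))
  out <- list()
  for (w in seq_along(windows)) {
    sites <- S4Vectors::queryHits(ov)[S4Vectors::subjectHits(ov) == w]
    inv <- callable_sites[w]
    for (j in seq_len(nP)) {
      k <- kmat[sites, j]; m <- mmat[sites, j]
      valid <- m >= 2
      diffs <- sum(k[valid] * (m[valid] - k[valid]))
      pairs <- sum(m[valid] * (m[valid] - 1) / 2) +
        inv * nfull[j] * (nfull[j] - 1) / 2
      out[[length(out) + 1]] <- data.frame(
        window = w, stat = "pi", pop1 = pops[j], pop2 = NA,
        value = if (pairs > 0) diffs / pairs else NA_real_,
        n_valid_sites = sum(valid), n_comparisons = pairs)
    }
    if (nP >= 2) for (j1 in seq_len(nP - 1)) for (j2 in (j1 + 1):nP) {
      k1 <- kmat[sites, j1]; m1 <- mmat[sites, j1]
      k2 <- kmat[sites, j2]; m2 <- mmat[sites, j2]
      valid <- m1 >= 1 & m2 >= 1
      diffs <- sum(k1[valid] * (m2[valid] - k2[valid]) +
                     k2[valid] * (m1[valid] - k1[valid]))
      pairs <- sum(m1[valid] * m2[valid]) + inv * nfull[j1] * nfull[j2]
      out[[length(out) + 1]] <- data.frame(
        window = w, stat = "dxy", pop1 = pops[j1], pop2 = pops[j2],
        value = if (pairs > 0) diffs / pairs else NA_real_,
        n_valid_sites = sum(valid), n_comparisons = pairs)
    }
  }
  res <- do.call(rbind, out)
  res$chrom <- as.character(GenomicRanges::seqnames(windows))[res$window]
  res$start <- GenomicRanges::start(windows)[res$window] - 1L  # 0-based
  res$end <- GenomicRanges::end(windows)[res$window]
  res$callable_flag <- !fallback
  res[, c("window", "chrom", "start", "end", "stat", "pop1", "pop2",
          "value", "n_valid_sites", "n_comparisons", "callable_flag")]
}

#' Empirical-quantile outlier calling
#'
#' Threshold is the empirical q-quantile (linear interpolation, the
#' default quantile type); outliers are values \code{>= threshold} (ties
#' at the threshold all included). Undefined values are excluded and
#' flagged FALSE.
#'
#' @param values numeric vector (NA allowed).
#' @param q quantile, default 0.99.
#' @return list: \code{outlier} (logical, same length as \code{values}),
#'   \code{threshold}.
#' @export
callOutliers <- function(values, q = 0.99) {
  ok <- !is.na(values)
  if (!any(ok)) stop("all values undefined")
  if (sum(ok) < 100)
    warning("fewer than 100 defined values; quantile threshold is unstable")
  v <- values[ok]
  thr <- stats::quantile(v, q, type = 7, names = FALSE)
  if (max(v) == min(v))
    warning("constant values: every value sits at the threshold")
  out <- !is.na(values) & values >= thr
  list(outlier = out, threshold = thr)
}
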