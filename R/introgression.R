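#' Patterson's D and f4 with block-jackknife significance
#'
#' Site-pattern sums from derived-allele frequencies (polarized by the
#' outgroup p4): ABBA = sum (1-p1) p2 p3 (1-p4), BABA = sum p1 (1-p2) p3
#' (1-p4), D = (ABBA - BABA) / (ABBA + BABA); f4 = mean (p1-p2)(p3-p4).
#' The standard error comes from a delete-one block jackknife over
#' contiguous equal-SNP blocks; Z = D / SE with a two-sided normal p.
#'
#' @param p1,p2,p3,p4 per-site derived-allele frequencies (equal length;
#'   sites with any NA are dropped).
#' @param n_blocks number of contiguous jackknife blocks (default 20).
#' @return list: D, f4, abba, baba, se, Z, p, n_blocks,
#'   n_informative_sites. D is NA when ABBA + BABA = 0; Z is Inf with a
#'   warning when SE = 0 but D != 0.
#' @export
pattersonD <- function(p1, p2, p3, p4, n_blocks = 20) {
  keep <- !(is.na(p1) | is.na(p2) | is.na(p3) | is.na(p4))
  p1 <- p1[keep]; p2 <- p2[keep]; p3 <- p3[keep]; p4 <- p4[keep]
  L <- length(p1)
  abba_s <- (1 - p1) * p2 * p3 * (1 - p4)
  baba_s <- p1 * (1 - p2) * p3 * (1 - p4)
  f4_s <- (p1 - p2) * (p3 - p4)
  ABBA <- sum(abba_s); BABA <- sum(baba_s)
  informative <- abba_s + baba_s > 0
  if (ABBA + BABA == 0)
    return(list(D = NA_real_, f4 = mean(f4_s), abba = ABBA, baba = BABA,
                se = NA_real_, Z = NA_real_, p = NA_real_,
                n_blocks = n_blocks, n_informative_sites = 0L))
  D <- (ABBA - BABA) / (ABBA + BABA)
  B <- min(n_blocks, L)
  block <- ceiling(seq_len(L) / (L / B))
  abba_b <- tapply(abba_s, block, sum)
  baba_b <- tapply(baba_s, block, sum)
  Dj <- (ABBA - abba_b - (BABA - baba_b)) / (ABBA - abba_b + BABA - baba_b)
  Dj[!is.finite(Dj)] <- D  # block removal leaving no informative sites
  se <- sqrt((B - 1) / B * sum((Dj - mean(Dj))^2))
  if (se == 0 && D != 0) {
    warning("jackknife SE is zero with non-zero D; Z reported as Inf")
    Z <- Inf
  } else Z <- if (se > 0) D / se else 0
  p <- 2 * stats::pnorm(-abs(Z))
  list(D = D, f4 = mean(f4_s), abba = ABBA, baba = BABA, se = se, Z = Z,
       p = p, n_blocks = B, n_informative_sites = sum(informative))
}

#' Per-population derived-allele frequencies
#'
#' @param x \linkS4class{GenotypeData}.
#' @param pop population labels per sample.
#' @return sites x populations matrix of ALT (derived) frequencies; NA
#'   where a population has no genotyped call.
#' @export
populationFrequencies <- function(x, pop = NULL) {
  d <- dosages(x)
  if (is.null(pop)) pop <- popMap(x)$population
  pop <- as.character(pop)
  pops <- unique(pop)
  f <- vapply(pops, function(p) {
    dk <- d[, pop == p, drop = FALSE]
    n <- rowSums(!is.na(dk))
    ifelse(n > 0, rowSums(dk, na.rm = TRUE) / (2 * n), NA_real_)
  }, numeric(nrow(d)))
  if (nrow(d) == 1) f <- matrix(f, 1, dimnames = list(NULL, pops))
  colnames(f) <- pops
  rownames(f) <- rownames(d)
  f
}

#' Exhaustive trio testing with the three-part significance rule
#'
#' Tests every unordered set of three non-outgroup populations. Within a
#' set the taxa are canonically ordered: P3 is chosen so the BBAA-like
#' pattern sum (P1, P2 sharing the derived allele) is maximal, and P1/P2
#' are ordered so D >= 0. p-values are Benjamini-Hochberg corrected across
#' all trios; a trio is flagged significant iff Z > Zmin, q < q_max and
#' D > Dmin.
#'
#' Sites where the outgroup is polymorphic are excluded (fixed-only
#' polarization) by default.
#'
#' @param x \linkS4class{GenotypeData} or a sites x populations frequency
#'   matrix from \code{\link{populationFrequencies}}.
#' @param outgroup outgroup population id (must not be a test population).
#' @param populations test population ids (default: all non-outgroup).
#' @param n_blocks jackknife blocks.
#' @param Zmin,q_max,Dmin the significance rule.
#' @param outgroup_max_maf maximum outgroup minor-allele frequency for a
#'   site to be considered polarizable (default 0 = fixed-only).
#' @return data.frame, one row per trio: P1, P2, P3, outgroup, D, f4, Z,
#'   p, q, significant, n_blocks, n_informative_sites.
#' @export
enumerateTrios <- function(x, outgroup, populations = NULL, n_blocks = 20,
                           Zmin = 3, q_max = 0.05, Dmin = 0.05,
                           outgroup_max_maf = 0) {
  f <- if (is(x, "GenotypeData")) populationFrequencies(x) else x
  if (!outgroup %in% colnames(f)) stop("outgroup not found")
  if (is.null(populations)) populations <- setdiff(colnames(f), outgroup)
  if (outgroup %in% populations)
    stop("outgroup must not be among the test populations")
  if (length(populations) < 3) stop("need >= 3 non-outgroup populations")
  po <- f[, outgroup]
  # polarize: derived = allele absent (or rare) in the outgroup
  maf_o <- pmin(po, 1 - po)
  usable <- !is.na(po) & maf_o <= outgroup_max_maf
  flip <- usable & po > 0.5  # outgroup fixed for ALT: REF is derived
  fpol <- f
  fpol[flip, ] <- 1 - f[flip, , drop = FALSE]
  fpol <- fpol[usable, , drop = FALSE]
  p4 <- fpol[, outgroup]

  combos <- utils::combn(populations, 3, simplify = FALSE)
  rows <- lapply(combos, function(trio) {
    # BBAA-like sum for each choice of P3
    bbaa <- vapply(trio, function(p3) {
      ab <- setdiff(trio, p3)
      sum(fpol[, ab[1]] * fpol[, ab[2]] * (1 - fpol[, p3]) * (1 - p4),
          na.rm = TRUE)
    }, numeric(1))
    P3 <- trio[which.max(bbaa)]
    ab <- setdiff(trio, P3)
    res <- pattersonD(fpol[, ab[1]], fpol[, ab[2]], fpol[, P3], p4,
                      n_blocks = n_blocks)
    P1 <- ab[1]; P2 <- ab[2]
    if (!is.na(res$D) && res$D < 0) {  # swapping P1/P2 negates D and f4
      res <- pattersonD(fpol[, ab[2]], fpol[, ab[1]], fpol[, P3], p4,
                        n_blocks = n_blocks)
      P1 <- ab[2]; P2 <- ab[1]
    }
    data.frame(P1 = P1, P2 = P2, P3 = P3, outgroup = outgroup, D = res$D,
               f4 = res$f4, Z = res$Z, p = res$p,
               n_blocks = res$n_blocks,
               n_informative_sites = res$n_informative_sites,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out$significant <- !is.na(out$D) & out$Z > Zmin & out$q < q_max &
    out$D > Dmin
  out
}
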