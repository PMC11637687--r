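#' @import methods
#' @importFrom Rcpp sourceCpp
#' @importClassesFrom SummarizedExperiment RangedSummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#' @importFrom S4Vectors metadata mcols
#' @useDynLib barrierscan, .registration = TRUE
NULL

#' GenotypeData: biallelic SNP genotypes with coordinates and sample metadata
#'
#' A \linkS4class{RangedSummarizedExperiment} holding a sites x samples
#' dosage matrix (values 0, 1, 2 or \code{NA}) in the \code{"dosage"} assay,
#' site coordinates (1-based positions, one-width ranges) as
#' \code{rowRanges}, and the population map (columns \code{population},
#' \code{species}, \code{context}, \code{lat}, \code{lon}) as \code{colData}.
#' Optional per-call depth and genotype quality live in \code{"depth"} and
#' \code{"gq"} assays; site-level ref/alt alleles and QUAL in
#' \code{mcols(rowRanges())}. Phased haplotypes, when available, are a
#' sites x (2 * samples) 0/1 matrix in the \code{haplotypes} slot with
#' columns \code{<sample>_1}, \code{<sample>_2}.
#'
#' @slot haplotypes \code{NULL} or an integer matrix, sites x 2*samples.
#' @export
setClass("GenotypeData",
  contains = "RangedSummarizedExperiment",
  slots = c(haplotypes = "ANY")
)

setValidity("GenotypeData", function(object) {
  msg <- character()
  if (!"dosage" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'dosage' is required")
  else {
    d <- SummarizedExperiment::assay(object, "dosage")
    bad <- d[!is.na(d)]
    if (length(bad) && !all(bad %in% 0:2))
      msg <- c(msg, "dosage values must be 0, 1, 2 or NA")
  }
  h <- object@haplotypes
  if (!is.null(h)) {
    if (!is.matrix(h) || nrow(h) != nrow(object) ||
        ncol(h) != 2L * ncol(object))
      msg <- c(msg, "haplotypes must be a sites x 2*samples matrix")
    else {
      d <- SummarizedExperiment::assay(object, "dosage")
      hs <- h[, seq(1, ncol(h), by = 2), drop = FALSE] +
        h[, seq(2, ncol(h), by = 2), drop = FALSE]
      ok <- is.na(d) | d == hs
      if (!all(ok)) msg <- c(msg, "dosage must equal haplotype-pair sum")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct a GenotypeData object
#'
#' @param dosage sites x samples matrix with values 0/1/2/NA.
#' @param chrom,pos chromosome names and 1-based positions per site.
#' @param sampleData data.frame of per-sample metadata (see
#'   \code{\link{readPopMap}}); rownames or a \code{sample} column identify
#'   samples.
#' @param haplotypes optional sites x 2*samples 0/1 matrix (phased).
#' @param ref,alt,qual optional per-site alleles and quality.
#' @param depth,gq optional per-call matrices.
#' @return A \linkS4class{GenotypeData} object.
#' @export
GenotypeData <- function(dosage, chrom, pos, sampleData = NULL,
                         haplotypes = NULL, ref = NULL, alt = NULL,
                         qual = NULL, depth = NULL, gq = NULL) {
  dosage <- as.matrix(dosage)
  stopifnot(length(chrom) == nrow(dosage), length(pos) == nrow(dosage))
  rr <- GenomicRanges::GRanges(
    seqnames = as.character(chrom),
    ranges = IRanges::IRanges(start = as.integer(pos), width = 1L)
  )
  S4Vectors::mcols(rr)$ref <- if (is.null(ref)) rep("A", nrow(dosage)) else ref
  S4Vectors::mcols(rr)$alt <- if (is.null(alt)) rep("T", nrow(dosage)) else alt
  S4Vectors::mcols(rr)$qual <-
    if (is.null(qual)) rep(NA_real_, nrow(dosage)) else qual
  if (nrow(dosage) > 0)
    names(rr) <- paste0(as.character(chrom), ":", as.integer(pos))
  if (is.null(colnames(dosage)))
    colnames(dosage) <- paste0("S", seq_len(ncol(dosage)))
  if (is.null(sampleData)) {
    sampleData <- S4Vectors::DataFrame(row.names = colnames(dosage))
  } else {
    sampleData <- S4Vectors::DataFrame(sampleData)
    if ("sample" %in% colnames(sampleData)) {
      rownames(sampleData) <- sampleData$sample
      sampleData$sample <- NULL
    }
    sampleData <- sampleData[colnames(dosage), , drop = FALSE]
  }
  rownames(dosage) <- names(rr)
  assays <- list(dosage = dosage)
  if (!is.null(depth)) {
    assays$depth <- as.matrix(depth)
    dimnames(assays$depth) <- dimnames(dosage)
  }
  if (!is.null(gq)) {
    assays$gq <- as.matrix(gq)
    dimnames(assays$gq) <- dimnames(dosage)
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = assays, rowRanges = rr, colData = sampleData
  )
  if (!is.null(haplotypes)) haplotypes <- as.matrix(haplotypes)
  new("GenotypeData", se, haplotypes = haplotypes)
}

#' @describeIn GenotypeData dosage matrix accessor (sites x samples).
#' @param x,object a GenotypeData object.
#' @export
dosages <- function(x) SummarizedExperiment::assay(x, "dosage")

#' @describeIn GenotypeData phased haplotype matrix (or NULL).
#' @export
haplotypes <- function(x) x@haplotypes

#' @describeIn GenotypeData sample metadata as a data.frame.
#' @export
popMap <- function(x) {
  df <- as.data.frame(SummarizedExperiment::colData(x))
  df$sample <- rownames(df)
  df[, c("sample", setdiff(colnames(df), "sample")), drop = FALSE]
}

#' @describeIn GenotypeData site coordinates as a GRanges.
#' @export
siteRanges <- function(x) SummarizedExperiment::rowRanges(x)

setMethod("show", "GenotypeData", function(object) {
  cat("GenotypeData:", nrow(object), "sites x", ncol(object), "samples\n")
  cat("  chromosomes:",
      paste(utils::head(unique(as.character(
        GenomicRanges::seqnames(SummarizedExperiment::rowRanges(object)))), 5),
        collapse = ", "), "\n")
  cat("  haplotypes:", if (is.null(object@haplotypes)) "absent" else "phased",
      "\n")
  cd <- SummarizedExperiment::colData(object)
  if ("population" %in% colnames(cd))
    cat("  populations:", length(unique(cd$population)), "\n")
})

#' JointSFS: two-population joint site-frequency spectrum
#'
#' Counts of sites with derived-allele count i in population 1 and j in
#' population 2 among n1 and n2 sampled haploid genomes; a
#' (n1+1) x (n2+1) matrix. The fixed corners (0,0) and (n1,n2) carry no
#' information about polymorphism and are masked in all likelihoods.
#'
#' @slot counts numeric matrix, (n1+1) x (n2+1).
#' @slot n1,n2 haploid sample sizes.
#' @slot folded logical; TRUE when the spectrum is minor-allele folded.
#' @export
setClass("JointSFS", representation(
  counts = "matrix", n1 = "integer", n2 = "integer", folded = "logical"
))

setValidity("JointSFS", function(object) {
  msg <- character()
  if (!identical(dim(object@counts),
                 c(object@n1 + 1L, object@n2 + 1L)))
    msg <- c(msg, "counts must be (n1+1) x (n2+1)")
  if (any(object@counts < 0)) msg <- c(msg, "counts must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Construct a JointSFS
#' @param counts (n1+1) x (n2+1) matrix of site counts.
#' @param folded whether the spectrum is folded.
#' @return A \linkS4class{JointSFS}.
#' @export
JointSFS <- function(counts, folded = FALSE) {
  counts <- as.matrix(counts)
  new("JointSFS", counts = counts, n1 = nrow(counts) - 1L,
      n2 = ncol(counts) - 1L, folded = folded)
}

#' @describeIn JointSFS count matrix accessor.
#' @param x,object a JointSFS.
#' @export
sfsCounts <- function(x) x@counts

#' @describeIn JointSFS haploid sample sizes, c(n1, n2).
#' @export
sfsSizes <- function(x) c(x@n1, x@n2)

#' @describeIn JointSFS logical mask matrix; TRUE for cells used in
#'   likelihoods (fixed corners FALSE).
#' @export
sfsMask <- function(x) {
  m <- matrix(TRUE, x@n1 + 1L, x@n2 + 1L)
  m[1, 1] <- FALSE
  m[x@n1 + 1L, x@n2 + 1L] <- FALSE
  m
}

setMethod("show", "JointSFS", function(object) {
  cat("JointSFS: n1 =", object@n1, ", n2 =", object@n2,
      if (object@folded) "(folded)" else "(unfolded)", "\n")
  cat("  segregating sites (unmasked):",
      sum(object@counts[sfsMask(object)]), "\n")
})
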