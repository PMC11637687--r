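#' Read biallelic SNP genotypes from a VCF file
#'
#' Ingests a VCF v4.x file (optionally bgzipped) into a
#' \linkS4class{GenotypeData}. Only biallelic SNP records are kept;
#' multi-allelic records and indels are skipped and counted. Missing and
#' half-calls (\code{./.}, \code{0/.}) become \code{NA}. Phase is preserved
#' into the haplotype matrix only when every call at every retained site is
#' phased; otherwise haplotypes are left \code{NULL}.
#'
#' @param path VCF file path.
#' @param region optional \code{"chrom"} or \code{"chrom:start-end"} string
#'   restricting ingest (1-based, inclusive).
#' @return A \linkS4class{GenotypeData}; the number of skipped records is in
#'   \code{metadata(x)$n_skipped}.
#' @export
readVcfGenotypes <- function(path, region = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  gt <- v@gt
  if (nrow(fix) == 0) {
    samples <- if (ncol(gt) > 1) colnames(gt)[-1] else character()
    d <- matrix(NA_real_, 0, length(samples),
                dimnames = list(NULL, samples))
    gd <- GenotypeData(d, character(), integer())
    S4Vectors::metadata(gd)$n_skipped <- 0L
    return(gd)
  }
  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  snp <- !is.na(alt) & nchar(ref) == 1L & nchar(alt) == 1L &
    !grepl(",", alt, fixed = TRUE)
  n_skipped <- sum(!snp)
  if (!is.null(region)) {
    m <- regmatches(region, regexec("^([^:]+)(:(\\d+)-(\\d+))?$", region))[[1]]
    keep_chr <- fix[, "CHROM"] == m[2]
    if (m[3] != "")
      keep_chr <- keep_chr & as.integer(fix[, "POS"]) >= as.integer(m[4]) &
        as.integer(fix[, "POS"]) <= as.integer(m[5])
    snp <- snp & keep_chr
  }
  fix <- fix[snp, , drop = FALSE]
  gt <- gt[snp, , drop = FALSE]
  samples <- colnames(gt)[-1]
  gtfield <- gt[, -1, drop = FALSE]
  fmt <- gt[, 1]

  extract_sub <- function(field) {
    out <- matrix(NA_character_, nrow(gtfield), ncol(gtfield))
    for (i in seq_len(nrow(gtfield))) {
      keys <- strsplit(fmt[i], ":", fixed = TRUE)[[1]]
      k <- match(field, keys)
      if (is.na(k)) next
      parts <- strsplit(gtfield[i, ], ":", fixed = TRUE)
      out[i, ] <- vapply(parts, function(p)
        if (length(p) >= k) p[k] else NA_character_, character(1))
    }
    out
  }
  gtstr <- extract_sub("GT")
  phased_all <- nrow(gtstr) > 0 && all(grepl("|", gtstr, fixed = TRUE))
  a1 <- substr(gtstr, 1, 1)
  a2 <- substr(gtstr, 3, 3)
  tonum <- function(a) {
    x <- suppressWarnings(as.numeric(a))
    x[!(a %in% c("0", "1"))] <- NA
    x
  }
  h1 <- matrix(tonum(a1), nrow(gtstr)); h2 <- matrix(tonum(a2), nrow(gtstr))
  d <- h1 + h2  # half-calls become NA
  colnames(d) <- samples
  haps <- NULL
  if (phased_all && !anyNA(d)) {
    haps <- matrix(0L, nrow(d), 2L * ncol(d))
    haps[, seq(1, ncol(haps), by = 2)] <- as.integer(h1)
    haps[, seq(2, ncol(haps), by = 2)] <- as.integer(h2)
    colnames(haps) <- paste0(rep(samples, each = 2), "_", 1:2)
  }
  dp <- suppressWarnings(matrix(as.numeric(extract_sub("DP")), nrow(d)))
  gq <- suppressWarnings(matrix(as.numeric(extract_sub("GQ")), nrow(d)))
  if (all(is.na(dp))) dp <- NULL else colnames(dp) <- samples
  if (all(is.na(gq))) gq <- NULL else colnames(gq) <- samples
  gd <- GenotypeData(
    d, chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
    haplotypes = haps, ref = fix[, "REF"], alt = fix[, "ALT"],
    qual = suppressWarnings(as.numeric(fix[, "QUAL"])),
    depth = dp, gq = gq
  )
  S4Vectors::metadata(gd)$n_skipped <- n_skipped
  gd
}

#' Write a GenotypeData back to VCF v4.2 text
#'
#' Writes dosages (and phase, when haplotypes are present) so that
#' \code{readVcfGenotypes(writeVcfGenotypes(x, f))} round-trips dosages,
#' phase and site order.
#'
#' @param x a \linkS4class{GenotypeData}.
#' @param path output file path (plain text).
#' @return \code{path}, invisibly.
#' @export
writeVcfGenotypes <- function(x, path) {
  rr <- siteRanges(x)
  d <- dosages(x)
  h <- haplotypes(x)
  qual <- S4Vectors::mcols(rr)$qual
  lines <- c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", colnames(d)), collapse = "\t")
  )
  if (nrow(d)) {
    gtmat <- matrix("./.", nrow(d), ncol(d))
    if (!is.null(h)) {
      h1 <- h[, seq(1, ncol(h), by = 2), drop = FALSE]
      h2 <- h[, seq(2, ncol(h), by = 2), drop = FALSE]
      gtmat[] <- paste0(h1, "|", h2)
    } else {
      gtmat[d == 0] <- "0/0"; gtmat[d == 1] <- "0/1"; gtmat[d == 2] <- "1/1"
    }
    body <- vapply(seq_len(nrow(d)), function(i) paste(c(
      as.character(GenomicRanges::seqnames(rr))[i],
      GenomicRanges::start(rr)[i], ".",
      S4Vectors::mcols(rr)$ref[i], S4Vectors::mcols(rr)$alt[i],
      if (is.na(qual[i])) "." else format(qual[i]), "PASS", ".", "GT",
      gtmat[i, ]), collapse = "\t"), character(1))
    lines <- c(lines, body)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a population map
#'
#' Tab-separated with header \code{sample population species context lat lon};
#' \code{context} must be \code{"allopatric"} or \code{"sympatric"}.
#'
#' @param path file path.
#' @return data.frame, one row per sample.
#' @export
readPopMap <- function(path) {
  pm <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("sample", "population", "species", "context", "lat", "lon")
  if (!all(need %in% colnames(pm)))
    stop("population map must have columns: ", paste(need, collapse = " "))
  bad <- setdiff(unique(pm$context), c("allopatric", "sympatric"))
  if (length(bad)) stop("unknown context value(s): ", paste(bad, collapse = ","))
  pm
}

#' Read gene annotations from BED or GFF3
#'
#' BED3+ (0-based half-open, columns chrom/start/end[/name]) or a minimal
#' GFF3 subset (1-based inclusive; \code{gene} features; ID/Name parsed from
#' attributes). Returned as a 1-based GRanges with \code{gene_id} metadata.
#'
#' @param path file path; format from extension (\code{.bed} vs
#'   \code{.gff}/\code{.gff3}) or the \code{format} argument.
#' @param format \code{"bed"}, \code{"gff"} or \code{"auto"}.
#' @return GRanges of genes.
#' @export
readGenes <- function(path, format = c("auto", "bed", "gff")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.gff3?$", path, ignore.case = TRUE)) "gff" else "bed"
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (format == "bed") {
    f <- strsplit(lines, "\t")
    chrom <- vapply(f, `[`, "", 1)
    start0 <- as.integer(vapply(f, `[`, "", 2))
    end0 <- as.integer(vapply(f, `[`, "", 3))
    id <- vapply(f, function(x) if (length(x) >= 4) x[4] else NA, "")
    strand <- vapply(f, function(x) if (length(x) >= 6) x[6] else "*", "")
    gr <- GenomicRanges::GRanges(chrom,
      IRanges::IRanges(start = start0 + 1L, end = end0),
      strand = ifelse(strand %in% c("+", "-"), strand, "*"))
  } else {
    f <- strsplit(lines, "\t")
    f <- f[vapply(f, function(x) length(x) >= 9 && x[3] == "gene", TRUE)]
    chrom <- vapply(f, `[`, "", 1)
    start1 <- as.integer(vapply(f, `[`, "", 4))
    end1 <- as.integer(vapply(f, `[`, "", 5))
    strand <- vapply(f, `[`, "", 7)
    attr <- vapply(f, `[`, "", 9)
    id <- sub(".*ID=([^;]+).*", "\\1", attr)
    gr <- GenomicRanges::GRanges(chrom,
      IRanges::IRanges(start = start1, end = end1),
      strand = ifelse(strand %in% c("+", "-"), strand, "*"))
  }
  id[is.na(id) | id == ""] <- paste0("gene", seq_along(gr))[is.na(id) | id == ""]
  S4Vectors::mcols(gr)$gene_id <- id
  names(gr) <- id
  gr
}

#' Apply the standard variant and sample filters
#'
#' Filters in a fixed order: (1) calls with depth below \code{min_depth}
#' are set missing; (2) sites failing \code{min_qual}, site missingness
#' above \code{max_site_missing}, or minor allele count below
#' \code{min_mac} are dropped; (3) samples missing at \code{>=
#' max_indiv_missing} of retained sites are dropped; (4) MAC is re-checked
#' once after sample removal. Depth/quality filters are skipped with a
#' warning when those fields are absent.
#'
#' @param x \linkS4class{GenotypeData}.
#' @param min_depth per-call depth threshold (calls below become missing).
#' @param max_site_missing maximum tolerated fraction of missing calls at a
#'   site (sites strictly above are dropped).
#' @param min_qual minimum site QUAL.
#' @param min_mac minimum minor allele count.
#' @param max_indiv_missing samples with missing fraction at or above this
#'   are dropped.
#' @return list with \code{data} (filtered \linkS4class{GenotypeData};
#'   possibly 0 sites, flagged via \code{empty}), \code{report} (counts
#'   removed at each step) and \code{empty}.
#' @export
applyFilters <- function(x, min_depth = 10, max_site_missing = 0.5,
                         min_qual = 30, min_mac = 3,
                         max_indiv_missing = 0.5) {
  d <- dosages(x)
  rr <- siteRanges(x)
  report <- list(calls_set_missing_depth = 0L, sites_qual = 0L,
                 sites_missing = 0L, sites_mac = 0L, samples_removed = 0L,
                 sites_mac_recheck = 0L)
  an <- SummarizedExperiment::assayNames(x)
  if ("depth" %in% an) {
    dp <- SummarizedExperiment::assay(x, "depth")
    low <- !is.na(d) & !is.na(dp) & dp < min_depth
    report$calls_set_missing_depth <- sum(low)
    d[low] <- NA
  } else warning("no depth assay; depth filter skipped")
  qual <- S4Vectors::mcols(rr)$qual
  if (all(is.na(qual))) {
    warning("no site QUAL; quality filter skipped")
    keep_q <- rep(TRUE, nrow(d))
  } else keep_q <- !is.na(qual) & qual >= min_qual
  report$sites_qual <- sum(!keep_q)

  missfrac <- rowMeans(is.na(d))
  keep_m <- missfrac <= max_site_missing
  report$sites_missing <- sum(keep_q & !keep_m)

  mac <- .minorAlleleCount(d)
  keep_c <- mac >= min_mac
  report$sites_mac <- sum(keep_q & keep_m & !keep_c)

  keep_site <- keep_q & keep_m & keep_c
  d2 <- d[keep_site, , drop = FALSE]

  if (nrow(d2)) {
    sfrac <- colMeans(is.na(d2))
    keep_samp <- sfrac < max_indiv_missing
  } else keep_samp <- rep(TRUE, ncol(d2))
  report$samples_removed <- sum(!keep_samp)
  d3 <- d2[, keep_samp, drop = FALSE]

  if (nrow(d3) && ncol(d3)) {
    mac2 <- .minorAlleleCount(d3)
    keep2 <- mac2 >= min_mac
  } else keep2 <- rep(TRUE, nrow(d3))
  report$sites_mac_recheck <- sum(!keep2)

  site_idx <- which(keep_site)[keep2]
  samp_idx <- which(keep_samp)
  out <- .subsetGenotypeData(x, site_idx, samp_idx, dosage_override = d)
  list(data = out, report = report, empty = length(site_idx) == 0L)
}

.minorAlleleCount <- function(d) {
  alt <- rowSums(d, na.rm = TRUE)
  tot <- 2 * rowSums(!is.na(d))
  pmin(alt, tot - alt)
}

# subset by site/sample indices, optionally replacing the dosage matrix
# (used after the per-call depth masking step)
.subsetGenotypeData <- function(x, site_idx, samp_idx,
                                dosage_override = NULL) {
  d <- if (is.null(dosage_override)) dosages(x) else dosage_override
  rr <- siteRanges(x)[site_idx]
  h <- haplotypes(x)
  if (!is.null(h)) {
    hap_cols <- as.vector(rbind(2L * samp_idx - 1L, 2L * samp_idx))
    h <- h[site_idx, hap_cols, drop = FALSE]
  }
  extra <- list()
  for (nm in setdiff(SummarizedExperiment::assayNames(x), "dosage"))
    extra[[nm]] <- SummarizedExperiment::assay(x, nm)[site_idx, samp_idx,
                                                      drop = FALSE]
  gd <- GenotypeData(
    d[site_idx, samp_idx, drop = FALSE],
    chrom = as.character(GenomicRanges::seqnames(rr)),
    pos = GenomicRanges::start(rr),
    sampleData = as.data.frame(
      SummarizedExperiment::colData(x))[samp_idx, , drop = FALSE],
    haplotypes = h,
    ref = S4Vectors::mcols(rr)$ref, alt = S4Vectors::mcols(rr)$alt,
    qual = S4Vectors::mcols(rr)$qual,
    depth = extra$depth, gq = extra$gq
  )
  S4Vectors::metadata(gd) <- S4Vectors::metadata(x)
  gd
}

#' Tile chromosomes into fixed-size windows
#'
#' Windows are returned as a GRanges (1-based inclusive coordinates
#' internally; a window covering the 0-based half-open interval
#' \code{[s, e)} is stored as \code{start = s + 1, end = e}). Tiling starts
#' at the chromosome origin; the last window is truncated at the chromosome
#' end. With \code{step == size} every position is covered exactly once.
#'
#' @param chrom_lengths named vector of chromosome lengths (bp).
#' @param size,step window size and step in bp; \code{step > size} is an
#'   error (gaps are not permitted).
#' @return GRanges of windows.
#' @export
makeWindows <- function(chrom_lengths, size = 10000, step = 10000) {
  stopifnot(size > 0, step > 0)
  if (step > size) stop("step > size would leave gaps between windows")
  chroms <- names(chrom_lengths)
  if (is.null(chroms)) stop("chrom_lengths must be named")
  out <- lapply(chroms, function(ch) {
    len <- chrom_lengths[[ch]]
    starts0 <- seq(0L, max(0L, len - 1L), by = step)
    starts0 <- starts0[starts0 < len]
    ends0 <- pmin(starts0 + size, len)
    GenomicRanges::GRanges(ch, IRanges::IRanges(start = starts0 + 1L,
                                                end = ends0))
  })
  do.call(c, out)
}

#' Map SNPs or windows to gene annotations
#'
#' A SNP at 1-based position p maps to a gene iff its 0-based coordinate
#' p-1 lies in \code{[gene_start - flank, gene_end + flank)} (0-based
#' half-open gene coordinates). Windows map on any interval overlap with
#' the flanked gene. Many-to-many mappings are allowed; features on
#' chromosomes absent from the annotation are unmapped with a warning.
#'
#' @param features GRanges of SNPs (width-1) or windows.
#' @param genes GRanges of genes with a \code{gene_id} metadata column.
#' @param flank flank in bp added to both gene ends (default 10 kb).
#' @return data.frame with columns \code{feature} (index into
#'   \code{features}), \code{gene_id}.
#' @export
mapFeatures <- function(features, genes, flank = 10000) {
  fchr <- as.character(GenomicRanges::seqnames(features))
  gchr <- as.character(GenomicRanges::seqnames(genes))
  unknown <- setdiff(unique(fchr), unique(gchr))
  if (length(unknown))
    warning("features on chromosome(s) without annotation: ",
            paste(unknown, collapse = ", "))
  # expand genes by flank; clamp at 1 (positions are >= 1 anyway)
  ext <- GenomicRanges::GRanges(
    gchr,
    IRanges::IRanges(start = pmax(1L, GenomicRanges::start(genes) - flank),
                     end = GenomicRanges::end(genes) + flank))
  hits <- GenomicRanges::findOverlaps(features, ext, ignore.strand = TRUE)
  data.frame(
    feature = S4Vectors::queryHits(hits),
    gene_id = S4Vectors::mcols(genes)$gene_id[S4Vectors::subjectHits(hits)],
    stringsAsFactors = FALSE
  )
}
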