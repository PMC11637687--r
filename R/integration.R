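#' The five-comparison scan plan
#'
#' From the population map, builds the standard comparisons: (1) all of
#' species 1 vs all of species 2; (2) allopatric species 1 vs allopatric
#' species 2; (3) sympatric species 1 vs sympatric species 2; (4)
#' allopatric vs sympatric within species 1; (5) allopatric vs sympatric
#' within species 2. Comparisons with an empty side are skipped with a
#' warning.
#'
#' @param popmap data.frame with sample, population, species, context.
#' @param species optional two species labels (default: the two
#'   non-outgroup species with most samples, alphabetical).
#' @return named list of comparisons, each
#'   \code{list(samples1, samples2, between_species)}.
#' @export
scanPlan <- function(popmap, species = NULL) {
  if (is.null(species)) {
    tab <- sort(table(popmap$species), decreasing = TRUE)
    species <- sort(names(tab)[1:2])
  }
  spA <- species[1]; spB <- species[2]
  pick <- function(sp, ctx = NULL) {
    m <- popmap$species == sp
    if (!is.null(ctx)) m <- m & popmap$context == ctx
    popmap$sample[m]
  }
  plan <- list(
    between_species_all = list(samples1 = pick(spA), samples2 = pick(spB),
                               between_species = TRUE),
    between_species_allopatric = list(
      samples1 = pick(spA, "allopatric"), samples2 = pick(spB, "allopatric"),
      between_species = TRUE),
    between_species_sympatric = list(
      samples1 = pick(spA, "sympatric"), samples2 = pick(spB, "sympatric"),
      between_species = TRUE),
    within_species1_contexts = list(
      samples1 = pick(spA, "allopatric"), samples2 = pick(spA, "sympatric"),
      between_species = FALSE),
    within_species2_contexts = list(
      samples1 = pick(spB, "allopatric"), samples2 = pick(spB, "sympatric"),
      between_species = FALSE)
  )
  empty <- vapply(plan, function(cp)
    !length(cp$samples1) || !length(cp$samples2), TRUE)
  if (any(empty))
    warning("comparison(s) skipped (context absent): ",
            paste(names(plan)[empty], collapse = ", "))
  plan[!empty]
}

#' Run the scan plan: FST, windowed dXY, outliers and gene sets
#'
#' For each comparison: site-wise Weir-Cockerham FST between the two
#' sample sets, 99th-quantile FST outlier SNPs and their genes; for
#' between-species comparisons additionally windowed dXY, its outlier
#' windows and genes, and the best-supported set = genes in BOTH the FST
#' and dXY outlier regions.
#'
#' @param x \linkS4class{GenotypeData}.
#' @param windows GRanges from \code{\link{makeWindows}}; default 10 kb
#'   tiles over the observed span.
#' @param genes GRanges of genes (optional; gene sets empty without it).
#' @param q outlier quantile (default 0.99).
#' @param flank SNP-to-gene flank in bp.
#' @param callable_sites per-window invariant callable-site counts.
#' @param plan optionally a precomputed \code{\link{scanPlan}}.
#' @return list per comparison: fst (site table), mean_fst,
#'   fst_outliers (logical), fst_genes; for between-species comparisons
#'   also dxy (window table), dxy_outliers, dxy_genes, best_supported.
#' @export
runScanPlan <- function(x, windows = NULL, genes = NULL, q = 0.99,
                        flank = 10000, callable_sites = NULL, plan = NULL) {
  pm <- popMap(x)
  if (is.null(plan)) plan <- scanPlan(pm)
  rr <- siteRanges(x)
  if (is.null(windows)) {
    lens <- tapply(GenomicRanges::start(rr),
                   as.character(GenomicRanges::seqnames(rr)), max)
    windows <- makeWindows(lens + 1)
  }
  out <- list()
  for (nm in names(plan)) {
    cp <- plan[[nm]]
    sel <- pm$sample %in% c(cp$samples1, cp$samples2)
    grp <- ifelse(pm$sample[sel] %in% cp$samples1, "g1", "g2")
    sub <- .subsetGenotypeData(x, seq_len(nrow(x)), which(sel))
    fst <- wcFst(dosages(sub), grp)
    oc <- tryCatch(callOutliers(fst$sites$fst, q = q),
                   error = function(e) NULL)
    res <- list(fst = fst$sites, mean_fst = fst$mean_of_ratios,
                fst_threshold = if (is.null(oc)) NA else oc$threshold,
                fst_outliers = if (is.null(oc))
                  rep(FALSE, nrow(fst$sites)) else oc$outlier)
    res$fst_genes <- character()
    if (!is.null(genes) && any(res$fst_outliers)) {
      mp <- mapFeatures(rr[res$fst_outliers], genes, flank = flank)
      res$fst_genes <- unique(mp$gene_id)
    }
    if (isTRUE(cp$between_species)) {
      wd <- suppressWarnings(
        windowDiversity(sub, pop = grp, windows = windows,
                        callable_sites = callable_sites))
      dxy <- wd[wd$stat == "dxy", , drop = FALSE]
      res$dxy <- dxy
      odc <- tryCatch(callOutliers(dxy$value, q = q),
                      error = function(e) NULL)
      res$dxy_outliers <- if (is.null(odc))
        rep(FALSE, nrow(dxy)) else odc$outlier
      res$dxy_genes <- character()
      if (!is.null(genes) && any(res$dxy_outliers)) {
        mp <- mapFeatures(windows[dxy$window[res$dxy_outliers]], genes,
                          flank = 0)
        res$dxy_genes <- unique(mp$gene_id)
      }
      res$best_supported <- intersect(res$fst_genes, res$dxy_genes)
    }
    out[[nm]] <- res
  }
  out
}

#' Overlap report: gene-set intersections and divergence contrasts
#'
#' (a) Pairwise and full intersections of the supplied gene sets (with
#' union counts, so inclusion-exclusion can be checked); (b) Welch
#' two-sample t-tests comparing window statistics (e.g., mean FST, mean
#' dXY per 10 kb window) between windows containing at least one
#' trait-associated SNP and all remaining windows; (c) Wilcoxon rank-sum
#' tests comparing trait-associated-gene FST between sympatric and
#' allopatric comparisons.
#'
#' @param gene_sets named list of character vectors (e.g., fst_outlier,
#'   dxy_outlier, song, chc, ihs, gea).
#' @param window_values optional named list of per-window numeric vectors
#'   (one value per window; NA allowed).
#' @param trait_windows optional named list (per trait) of logical vectors
#'   marking trait-associated windows (same length as the window vectors).
#' @param context_gene_fst optional named list (per trait) of data.frames
#'   with columns \code{sympatric} and \code{allopatric}: per-gene FST in
#'   each spatial context.
#' @return list: \code{set_sizes}, \code{pairwise} (data.frame: set1,
#'   set2, n1, n2, intersection, union), \code{full_intersection} (genes
#'   in every set), \code{gene_lists}, \code{window_tests} (Welch t per
#'   statistic x trait), \code{context_tests} (Wilcoxon per trait),
#'   \code{notes}.
#' @export
overlapReport <- function(gene_sets, window_values = NULL,
                          trait_windows = NULL, context_gene_fst = NULL) {
  gene_sets <- lapply(gene_sets, unique)
  nm <- names(gene_sets)
  pairs <- if (length(nm) >= 2) utils::combn(nm, 2, simplify = FALSE)
  else list()
  pairwise <- do.call(rbind, lapply(pairs, function(pr) {
    a <- gene_sets[[pr[1]]]; b <- gene_sets[[pr[2]]]
    data.frame(set1 = pr[1], set2 = pr[2], n1 = length(a), n2 = length(b),
               intersection = length(intersect(a, b)),
               union = length(union(a, b)), stringsAsFactors = FALSE)
  }))
  full <- Reduce(intersect, gene_sets)
  notes <- character()
  window_tests <- list()
  if (!is.null(window_values) && !is.null(trait_windows)) {
    for (tr in names(trait_windows)) {
      marked <- trait_windows[[tr]]
      if (!any(marked, na.rm = TRUE)) {
        notes <- c(notes, paste0("trait '", tr,
                                 "': no associated windows; tests skipped"))
        next
      }
      for (st in names(window_values)) {
        v <- window_values[[st]]
        a <- v[marked & !is.na(v)]
        b <- v[!marked & !is.na(v)]
        if (length(a) < 2 || length(b) < 2) {
          notes <- c(notes, paste0(st, " x ", tr,
                                   ": too few windows; test skipped"))
          next
        }
        tt <- stats::t.test(a, b)  # Welch by default
        window_tests[[paste0(st, ".", tr)]] <- data.frame(
          stat = st, trait = tr, mean_assoc = mean(a),
          mean_background = mean(b), t = unname(tt$statistic),
          df = unname(tt$parameter), p = tt$p.value)
      }
    }
  }
  context_tests <- list()
  if (!is.null(context_gene_fst)) {
    for (tr in names(context_gene_fst)) {
      df <- context_gene_fst[[tr]]
      a <- df$sympatric[!is.na(df$sympatric)]
      b <- df$allopatric[!is.na(df$allopatric)]
      if (!length(a) || !length(b)) {
        notes <- c(notes, paste0("trait '", tr,
                                 "': empty context sets; Wilcoxon skipped"))
        next
      }
      wt <- suppressWarnings(stats::wilcox.test(a, b))
      context_tests[[tr]] <- data.frame(
        trait = tr, W = unname(wt$statistic), p = wt$p.value,
        median_sympatric = stats::median(a),
        median_allopatric = stats::median(b))
    }
  }
  list(set_sizes = vapply(gene_sets, length, 0L), pairwise = pairwise,
       full_intersection = full, gene_lists = gene_sets,
       window_tests = if (length(window_tests))
         do.call(rbind, window_tests) else NULL,
       context_tests = if (length(context_tests))
         do.call(rbind, context_tests) else NULL,
       notes = notes)
}
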