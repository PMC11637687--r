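#' Simulation configuration for the contact-zone SNP generator
#'
#' Defines a two-sister-species + outgroup sampling design across
#' allopatric and sympatric populations, with hierarchical
#' (Balding-Nichols) allele-frequency divergence. Per site an ancestral
#' frequency u ~ Uniform(0.05, 0.95) is drawn; each species' frequency is
#' Beta(u(1-F)/F, (1-u)(1-F)/F) with F = \code{F_between} (barrier loci use
#' \code{barrier_F}); each population's frequency is drawn the same way
#' around its species frequency with F = \code{F_within}. With
#' introgression \code{alpha > 0}, sympatric populations mix
#' \code{alpha} of the other species' frequency into their own.
#'
#' @param seed integer seed.
#' @param populations data.frame with columns \code{id}, \code{species},
#'   \code{context}, \code{lat}, \code{lon}, \code{n}; default: two species
#'   ("A", "B") with 3 allopatric + 3 sympatric populations each, 10
#'   diploids per population along a latitudinal transect, plus one
#'   10-sample outgroup population (species "O", used only for
#'   polarization).
#' @param n_sites number of unlinked SNP sites.
#' @param F_between,F_within divergence fractions in (0, 1).
#' @param barrier_fraction,barrier_F fraction of sites that are barrier
#'   loci and their (elevated) between-species divergence; must exceed
#'   \code{F_between}.
#' @param alpha introgression mixing fraction in [0, 1), applied only to
#'   sympatric populations (at \code{introgressed_fraction} of non-barrier
#'   sites).
#' @param introgressed_fraction fraction of non-barrier sites subject to
#'   mixing when \code{alpha > 0}.
#' @param F_outgroup divergence of the outgroup from the ancestral
#'   frequency.
#' @param missing_rate per-call missingness probability.
#' @param mean_depth,qual_mean depth (Poisson mean) and site quality
#'   (Normal mean, sd 10, floored at 0) models.
#' @return a validated config list of class \code{"simConfig"}.
#' @export
simulationConfig <- function(seed = 1L, populations = NULL, n_sites = 2000L,
                             F_between = 0.10, F_within = 0.02,
                             barrier_fraction = 0, barrier_F = 0.5,
                             alpha = 0, introgressed_fraction = 1,
                             F_outgroup = 0.2, missing_rate = 0.02,
                             mean_depth = 30, qual_mean = 60) {
  if (is.null(populations)) populations <- defaultPopulations()
  stopifnot(all(c("id", "species", "context", "lat", "lon", "n") %in%
                  colnames(populations)))
  if (any(populations$n < 2)) stop("at least 2 samples per population")
  for (f in c(F_between, F_within, F_outgroup))
    if (f <= 0 || f >= 1) stop("divergence fractions must be in (0,1)")
  if (alpha < 0 || alpha >= 1) stop("alpha must be in [0,1)")
  if (barrier_fraction > 0 && barrier_F <= F_between)
    stop("barrier_F must exceed F_between")
  structure(list(
    seed = as.integer(seed), populations = populations,
    n_sites = as.integer(n_sites), F_between = F_between,
    F_within = F_within, barrier_fraction = barrier_fraction,
    barrier_F = barrier_F, alpha = alpha,
    introgressed_fraction = introgressed_fraction,
    F_outgroup = F_outgroup, missing_rate = missing_rate,
    mean_depth = mean_depth, qual_mean = qual_mean
  ), class = "simConfig")
}

#' @rdname simulationConfig
#' @param n_per_pop diploid samples per population.
#' @param include_outgroup include the outgroup population.
#' @export
defaultPopulations <- function(n_per_pop = 10, include_outgroup = TRUE) {
  mk <- function(sp, ctx, k, lat, lon)
    data.frame(id = paste0(sp, ctx_tag(ctx), k), species = sp, context = ctx,
               lat = lat, lon = lon, n = n_per_pop,
               stringsAsFactors = FALSE)
  ctx_tag <- function(ctx) if (ctx == "sympatric") "S" else "L"
  pops <- rbind(
    mk("A", "allopatric", 1:3, lat = c(-34, -33, -32), lon = c(151, 150, 149)),
    mk("A", "sympatric", 1:3, lat = c(-28, -27, -26), lon = c(153, 153, 152)),
    mk("B", "allopatric", 1:3, lat = c(-18, -17, -16), lon = c(146, 145, 145)),
    mk("B", "sympatric", 1:3, lat = c(-28, -27, -26), lon = c(153, 153, 152))
  )
  if (include_outgroup)
    pops <- rbind(pops, data.frame(id = "OUT", species = "O",
                                   context = "allopatric", lat = 0, lon = 120,
                                   n = n_per_pop, stringsAsFactors = FALSE))
  pops
}

# Balding-Nichols draw around p with divergence F (vectorized)
.bnDraw <- function(p, F) {
  stats::rbeta(length(p), p * (1 - F) / F, (1 - p) * (1 - F) / F)
}

#' Simulate an unlinked contact-zone SNP dataset with planted truth
#'
#' Site-level generator (no linkage) used for FST/D/GWA/GEA testing; see
#' \code{\link{simulationConfig}} for the frequency model. The ALT allele
#' is the derived allele by construction.
#'
#' @param config a \code{\link{simulationConfig}}.
#' @return list with \code{data} (\linkS4class{GenotypeData} including
#'   depth/quality assays and population metadata) and \code{truth}
#'   (data.frame: \code{site}, \code{role} in
#'   \{neutral, barrier, introgressed\}).
#' @export
simulateSnpDataset <- function(config) {
  stopifnot(inherits(config, "simConfig"))
  set.seed(config$seed)
  pops <- config$populations
  L <- config$n_sites
  species <- setdiff(unique(pops$species), "O")
  if (length(species) != 2) stop("exactly two non-outgroup species required")

  role <- rep("neutral", L)
  n_bar <- round(config$barrier_fraction * L)
  if (n_bar > 0) role[sample.int(L, n_bar)] <- "barrier"
  mixable <- which(role == "neutral")
  mixed <- logical(L)
  if (config$alpha > 0 && length(mixable)) {
    n_mix <- round(config$introgressed_fraction * length(mixable))
    mixed[sample(mixable, n_mix)] <- TRUE
    role[mixed] <- "introgressed"
  }

  u <- stats::runif(L, 0.05, 0.95)
  Fb <- ifelse(role == "barrier", config$barrier_F, config$F_between)
  sp_freq <- list()
  for (sp in species) sp_freq[[sp]] <- .bnDraw(u, Fb)
  out_freq <- .bnDraw(u, config$F_outgroup)

  samples <- character(); spl_pop <- character()
  dos <- matrix(NA_real_, L, 0)
  for (k in seq_len(nrow(pops))) {
    p <- pops[k, ]
    base <- if (p$species == "O") out_freq else sp_freq[[p$species]]
    pf <- .bnDraw(base, config$F_within)
    if (p$species != "O" && p$context == "sympatric" && config$alpha > 0) {
      other <- sp_freq[[setdiff(species, p$species)]]
      pf[mixed] <- (1 - config$alpha) * pf[mixed] +
        config$alpha * other[mixed]
    }
    g <- matrix(stats::rbinom(L * p$n, 2, rep(pf, p$n)), L, p$n)
    ids <- paste0(p$id, "_", seq_len(p$n))
    colnames(g) <- ids
    dos <- cbind(dos, g)
    samples <- c(samples, ids)
    spl_pop <- c(spl_pop, rep(p$id, p$n))
  }

  depth <- matrix(stats::rpois(length(dos), config$mean_depth),
                  nrow(dos), dimnames = dimnames(dos))
  gq <- matrix(pmax(0, round(stats::rnorm(length(dos), 50, 10))),
               nrow(dos), dimnames = dimnames(dos))
  miss <- matrix(stats::runif(length(dos)) < config$missing_rate, nrow(dos))
  dos[miss] <- NA
  qual <- pmax(0, stats::rnorm(L, config$qual_mean, 10))

  sd <- pops[match(spl_pop, pops$id),
             c("id", "species", "context", "lat", "lon")]
  colnames(sd)[1] <- "population"
  rownames(sd) <- samples
  gd <- GenotypeData(
    dos, chrom = rep("chr1", L), pos = seq_len(L) * 100L,
    sampleData = sd, qual = qual, depth = depth, gq = gq
  )
  truth <- data.frame(site = rownames(gd), role = role,
                      stringsAsFactors = FALSE)
  list(data = gd, truth = truth)
}

#' Forward Wright-Fisher simulation of a recombining region
#'
#' Discrete generations, random mating, per-meiosis crossovers
#' Poisson(r * region_bp), infinite-sites mutations Poisson(mu * region_bp)
#' per gamete, optional additive hard sweep at one site (fitnesses
#' 1 : 1+s : 1+2s). Output haplotypes are phased by construction. Uses a
#' scaled small population with inflated mu and r; defaults are desk-scale.
#'
#' @param n_diploid population size (>= 20).
#' @param region_bp region length in bp.
#' @param mu,r per-bp per-generation mutation and recombination rates.
#' @param generations number of generations to run.
#' @param selection \code{NULL} or \code{list(site =, s =)} with site a
#'   position in [0, region_bp) and s > 0 (only hard sweeps are modeled).
#' @param init_count initial derived copies at the selected site.
#' @param condition_on_survival restart while the selected allele is lost.
#' @param max_restarts cap on restarts.
#' @param stop_freq optional derived-frequency threshold at which the run
#'   stops early (sample the population mid-sweep, while the swept site is
#'   still polymorphic); \code{NULL} runs all generations.
#' @param burn_in neutral generations run before the selected mutation is
#'   introduced (default 4N), bringing the region towards mutation-drift
#'   equilibrium so the background carries realistic diversity and LD.
#' @param seed integer seed.
#' @return list: \code{haplotypes} (2N x S 0/1 matrix), \code{positions}
#'   (bp, ascending), \code{truth} (data.frame with the selected site's
#'   position, s and final derived frequency; empty when neutral),
#'   \code{sel_freq}, \code{restarts}.
#' @export
simulateForwardRegion <- function(n_diploid = 100, region_bp = 1e5,
                                  mu = 1e-7, r = 1e-7, generations = 400,
                                  selection = NULL, init_count = 1,
                                  condition_on_survival = TRUE,
                                  max_restarts = 200, stop_freq = NULL,
                                  burn_in = 4 * n_diploid, seed = 1L) {
  if (n_diploid < 20) stop("n_diploid must be >= 20")
  sel_pos <- -1; s <- 0
  if (!is.null(selection)) {
    if (selection$s < 0) stop("only hard sweeps (s >= 0) are modeled")
    sel_pos <- selection$site; s <- selection$s
  }
  set.seed(seed)
  res <- .wf_forward(n_diploid, region_bp, mu, r, generations, sel_pos, s,
                     init_count, condition_on_survival, max_restarts,
                     if (is.null(stop_freq)) 0 else stop_freq,
                     as.integer(burn_in))
  truth <- if (s > 0)
    data.frame(position = sel_pos, s = s, final_freq = res$sel_freq)
  else data.frame(position = numeric(), s = numeric(),
                  final_freq = numeric())
  list(haplotypes = res$haplotypes, positions = res$positions,
       truth = truth, sel_freq = res$sel_freq, restarts = res$restarts)
}

#' Simulate quantitative phenotypes from genotypes with planted QTLs
#'
#' Each trait is sum(effect * dosage at its QTLs) + a polygenic term (many
#' tiny random background effects, scaled so it explains
#' \code{h2_polygenic} of the non-QTL variance) + Gaussian noise. CHC-style
#' peak abundances are made non-negative through a soft-plus transform;
#' body size covariates (mass, pronotum) are generated correlated with a
#' designated trait to exercise covariate correction.
#'
#' @param x \linkS4class{GenotypeData} (missing dosages mean-imputed).
#' @param qtl_spec named list: trait -> data.frame(site, effect); sites are
#'   row names or indices of \code{x}.
#' @param song_traits,chc_peaks numbers of song traits and CHC peaks.
#' @param h2_polygenic polygenic fraction of residual variance, in [0, 1).
#' @param noise_sd residual standard deviation.
#' @param covar_trait song trait index that mass/pronotum correlate with.
#' @param seed integer seed.
#' @return list: \code{phenotypes} (data.frame: sample, song_1..,
#'   chc_1.., mass, pronotum), \code{truth} (data.frame: site, trait,
#'   effect).
#' @export
simulatePhenotypes <- function(x, qtl_spec = list(), song_traits = 14,
                               chc_peaks = 26, h2_polygenic = 0.2,
                               noise_sd = 1, covar_trait = 1, seed = 1L) {
  if (h2_polygenic < 0 || h2_polygenic >= 1)
    stop("h2_polygenic must be in [0,1)")
  set.seed(seed)
  d <- dosages(x)
  n <- ncol(d)
  dimp <- .meanImpute(t(d))  # samples x sites
  traits <- c(paste0("song_", seq_len(song_traits)),
              paste0("chc_raw_", seq_len(chc_peaks)))
  truth <- data.frame(site = character(), trait = character(),
                      effect = numeric(), stringsAsFactors = FALSE)
  for (tr in names(qtl_spec)) {
    qs <- qtl_spec[[tr]]
    idx <- if (is.character(qs$site)) match(qs$site, rownames(d)) else qs$site
    if (anyNA(idx)) stop("QTL sites must exist in the genotype matrix")
    truth <- rbind(truth, data.frame(site = rownames(d)[idx], trait = tr,
                                     effect = qs$effect))
  }
  n_bg <- min(200L, nrow(d))
  bg_idx <- sample.int(nrow(d), n_bg)
  vals <- matrix(0, n, length(traits), dimnames = list(colnames(d), traits))
  for (tr in traits) {
    g <- numeric(n)
    if (tr %in% names(qtl_spec)) {
      qs <- qtl_spec[[tr]]
      idx <- if (is.character(qs$site)) match(qs$site, rownames(d)) else qs$site
      g <- as.vector(dimp[, idx, drop = FALSE] %*% qs$effect)
    }
    poly <- as.vector(dimp[, bg_idx, drop = FALSE] %*%
                        stats::rnorm(n_bg, 0, 1))
    vp <- stats::var(poly)
    target <- if (h2_polygenic > 0)
      h2_polygenic / (1 - h2_polygenic) * noise_sd^2 else 0
    if (vp > 0 && target > 0) poly <- poly * sqrt(target / vp) else poly <- 0
    vals[, tr] <- g + poly + stats::rnorm(n, 0, noise_sd)
  }
  ph <- as.data.frame(vals[, seq_len(song_traits), drop = FALSE])
  chc_raw <- vals[, song_traits + seq_len(chc_peaks), drop = FALSE]
  chc <- log1p(exp(chc_raw))  # soft-plus: non-negative abundances
  colnames(chc) <- paste0("chc_", seq_len(chc_peaks))
  focal <- vals[, covar_trait]
  mass <- 0.5 * scale(focal)[, 1] + stats::rnorm(n, 0, sqrt(1 - 0.25))
  pronotum <- 0.3 * scale(focal)[, 1] + stats::rnorm(n, 0, sqrt(1 - 0.09))
  out <- cbind(data.frame(sample = colnames(d), stringsAsFactors = FALSE),
               ph, as.data.frame(chc),
               data.frame(mass = mass, pronotum = pronotum))
  rownames(out) <- colnames(d)
  list(phenotypes = out, truth = truth)
}

#' Simulate a joint SFS from the structured coalescent
#'
#' Draws \code{n_loci} independent non-recombining genealogies under one of
#' the four divergence models (see \code{\link{expectedSfs}} for the
#' dynamics) and places mutations either one per locus proportional to
#' branch length (default) or Poisson with per-locus theta.
#'
#' @param model one of \code{"no_mig"}, \code{"sym_mig"}, \code{"anc_mig"},
#'   \code{"sec_contact"}.
#' @param params named list/vector: \code{nu1}, \code{nu2}, \code{T1}, and
#'   \code{m} (migration models) plus \code{T2} (epoch models).
#' @param n1,n2 haploid sample sizes.
#' @param n_loci number of independent loci (warning below 100).
#' @param mutation \code{"one_per_locus"} or \code{"poisson"}.
#' @param theta per-locus theta for \code{"poisson"}.
#' @param seed integer seed.
#' @return a \linkS4class{JointSFS}.
#' @export
simulateJointSfs <- function(model, params, n1, n2, n_loci = 5000,
                             mutation = c("one_per_locus", "poisson"),
                             theta = 1, seed = 1L) {
  mutation <- match.arg(mutation)
  if (n_loci < 100) warning("n_loci < 100: spectrum will be very noisy")
  mp <- .modelParams(model, params)
  set.seed(seed)
  cnt <- .coal_sample_sfs(n1, n2, mp$nu1, mp$nu2, mp$T1, mp$T2, mp$m,
                          mp$mode, n_loci, theta,
                          mutation == "one_per_locus")
  JointSFS(cnt)
}

# shared model-spec validation; mode codes match src/coalescent.cpp
.modelParams <- function(model, params) {
  model <- match.arg(model, c("no_mig", "sym_mig", "anc_mig", "sec_contact"))
  p <- as.list(params)
  need <- switch(model, no_mig = c("nu1", "nu2", "T1"),
                 sym_mig = c("nu1", "nu2", "T1", "m"),
                 c("nu1", "nu2", "T1", "T2", "m"))
  if (!all(need %in% names(p)))
    stop("model ", model, " needs parameters: ", paste(need, collapse = ", "))
  if (any(unlist(p[need]) <= 0)) stop("all parameters must be > 0")
  T2 <- if ("T2" %in% need) p$T2 else 0
  if ("T2" %in% need && T2 >= p$T1) stop("T2 must be < T1")
  list(nu1 = p$nu1, nu2 = p$nu2, T1 = p$T1, T2 = T2,
       m = if ("m" %in% need) p$m else 0,
       mode = switch(model, no_mig = 0L, sym_mig = 1L, anc_mig = 2L,
                     sec_contact = 3L),
       k = length(need), model = model)
}

.meanImpute <- function(m) {
  # m: samples x sites; impute column means
  cm <- colMeans(m, na.rm = TRUE)
  cm[is.nan(cm)] <- 0
  idx <- which(is.na(m))
  if (length(idx)) m[idx] <- cm[(idx - 1) %/% nrow(m) + 1]
  m
}

#' Contact-zone dataset with planted gene-level overlap truth
#'
#' Builds the full fixture for the outlier-overlap analysis: a two-species
#' SNP dataset with (i) pure barrier genes (clusters of strongly diverged
#' sites), (ii) dual-role loci that are simultaneously interspecific
#' barriers and intraspecific song QTLs (diverged between species yet
#' polymorphic within the focal species), (iii) QTL-only loci (polymorphic,
#' undiverged), (iv) neutral genes, plus phenotypes where each planted QTL
#' is the major-effect locus of its own song trait, and gene intervals
#' covering each planted class.
#'
#' @param seed integer seed.
#' @param n_sites total SNP count.
#' @param n_barrier_genes,sites_per_barrier_gene pure-barrier gene count
#'   and sites per gene.
#' @param n_dual,n_qtl_only dual-role and QTL-only locus counts (each gets
#'   its own song trait and its own gene).
#' @param n_neutral_genes neutral single-site genes.
#' @param n_per_pop diploid samples per population.
#' @param qtl_r2 fraction of trait variance explained by each planted QTL.
#' @param barrier_F,F_between divergence levels.
#' @param dual_pB species-B frequency at dual-role sites (species A stays
#'   at 0.5, keeping them mappable within A while diverged from B).
#' @return list: \code{data} (\linkS4class{GenotypeData}), \code{genes}
#'   (GRanges with \code{gene_id} and \code{class} in
#'   \{barrier, dual, qtl_only, neutral\}), \code{phenotypes},
#'   \code{truth} (site-level roles), \code{qtl_traits} (trait name per
#'   planted QTL site), \code{focal_species}.
#' @export
plantedOverlapDataset <- function(seed = 1L, n_sites = 2000,
                                  n_barrier_genes = 10,
                                  sites_per_barrier_gene = 3,
                                  n_dual = 5, n_qtl_only = 5,
                                  n_neutral_genes = 200, n_per_pop = 25,
                                  qtl_r2 = 0.2, barrier_F = 0.6,
                                  F_between = 0.1, dual_pB = 0.97) {
  cfg <- simulationConfig(
    seed = seed, n_sites = n_sites,
    populations = defaultPopulations(n_per_pop = n_per_pop),
    F_between = F_between
  )
  sim <- simulateSnpDataset(cfg)
  gd <- sim$data
  truth <- sim$truth
  pm <- popMap(gd)
  d <- dosages(gd)
  focal <- "A"
  isA <- pm$species == focal
  pops_tab <- unique(pm[, c("population", "species")])

  set.seed(seed + 1L)
  # barrier genes: contiguous runs of sites, re-drawn at barrier_F
  spb <- sites_per_barrier_gene
  gap <- floor(n_sites / (n_barrier_genes + n_dual + n_qtl_only + 2))
  starts <- gap * seq_len(n_barrier_genes + n_dual + n_qtl_only)
  bar_runs <- lapply(starts[seq_len(n_barrier_genes)],
                     function(st) st + seq_len(spb) - 1L)
  dual_idx <- starts[n_barrier_genes + seq_len(n_dual)]
  qtl_idx <- starts[n_barrier_genes + n_dual + seq_len(n_qtl_only)]

  redraw <- function(s, pA, pB) {
    for (k in seq_len(nrow(pops_tab))) {
      p <- pops_tab$population[k]
      sp <- pops_tab$species[k]
      if (sp == "O") next
      f <- .bnDraw(if (sp == focal) pA else pB, cfg$F_within)
      cols <- which(pm$population == p)
      g <- stats::rbinom(length(cols), 2, f)
      nas <- is.na(d[s, cols])
      d[s, cols] <<- g
      d[s, cols][nas] <<- NA
    }
  }
  for (run in bar_runs) for (s in run) {
    u <- stats::runif(1, 0.05, 0.95)
    redraw(s, .bnDraw(u, barrier_F), .bnDraw(u, barrier_F))
    truth$role[s] <- "barrier"
  }
  # dual-role: diverged between species yet polymorphic within A;
  # qtl-only: polymorphic within A, undiverged
  for (s in dual_idx) { redraw(s, 0.5, dual_pB); truth$role[s] <- "dual" }
  for (s in qtl_idx) { redraw(s, 0.5, 0.5); truth$role[s] <- "qtl" }

  gd <- GenotypeData(
    d, chrom = as.character(GenomicRanges::seqnames(siteRanges(gd))),
    pos = GenomicRanges::start(siteRanges(gd)),
    sampleData = as.data.frame(SummarizedExperiment::colData(gd)),
    qual = S4Vectors::mcols(siteRanges(gd))$qual,
    depth = SummarizedExperiment::assay(gd, "depth"),
    gq = SummarizedExperiment::assay(gd, "gq")
  )

  pos <- GenomicRanges::start(siteRanges(gd))
  mk_gene <- function(idx, id, cls)
    data.frame(start = min(pos[idx]) - 10L, end = max(pos[idx]) + 10L,
               gene_id = id, class = cls)
  genes <- do.call(rbind, c(
    lapply(seq_along(bar_runs), function(k)
      mk_gene(bar_runs[[k]], paste0("barrier_g", k), "barrier")),
    lapply(seq_along(dual_idx), function(k)
      mk_gene(dual_idx[k], paste0("dual_g", k), "dual")),
    lapply(seq_along(qtl_idx), function(k)
      mk_gene(qtl_idx[k], paste0("qtlonly_g", k), "qtl_only"))
  ))
  left <- which(truth$role == "neutral")
  neu <- sample(left, min(n_neutral_genes, length(left)))
  genes <- rbind(genes, do.call(rbind, lapply(seq_along(neu), function(k)
    mk_gene(neu[k], paste0("neutral_g", k), "neutral"))))
  gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(
    start = genes$start, end = genes$end))
  S4Vectors::mcols(gr)$gene_id <- genes$gene_id
  S4Vectors::mcols(gr)$class <- genes$class
  names(gr) <- genes$gene_id

  # phenotypes: each planted QTL drives its own song trait at qtl_r2
  dA <- d[, isA, drop = FALSE]
  qtl_sites <- c(dual_idx, qtl_idx)
  qtl_spec <- list()
  for (k in seq_along(qtl_sites)) {
    s <- qtl_sites[k]
    vg <- stats::var(dA[s, ], na.rm = TRUE)
    eff <- sqrt(qtl_r2 / (1 - qtl_r2) / vg)
    qtl_spec[[paste0("song_", k)]] <- data.frame(site = s, effect = eff)
  }
  ph <- simulatePhenotypes(gd, qtl_spec = qtl_spec, h2_polygenic = 0,
                           noise_sd = 1, covar_trait = 12, seed = seed + 2L)
  qtl_traits <- if (length(qtl_sites)) data.frame(
    site = rownames(d)[qtl_sites],
    trait = paste0("song_", seq_along(qtl_sites)),
    class = rep(c("dual", "qtl_only"), c(n_dual, n_qtl_only)),
    stringsAsFactors = FALSE)
  else data.frame(site = character(), trait = character(),
                  class = character(), stringsAsFactors = FALSE)
  list(data = gd, genes = gr, phenotypes = ph$phenotypes, truth = truth,
       qtl_traits = qtl_traits, focal_species = focal)
}
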