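#' Build a joint site-frequency spectrum from genotypes
#'
#' Per site, the derived-allele counts (i, j) among genotyped alleles of
#' the two populations increment cell (i, j). Polarization uses an
#' outgroup population (derived = allele absent from the outgroup; sites
#' with a polymorphic outgroup are excluded); without an outgroup the
#' spectrum is folded and flagged. Sites with missing calls are either
#' skipped (exact-size requirement) or redistributed by expected
#' hypergeometric projection onto the target sizes.
#'
#' @param x \linkS4class{GenotypeData}.
#' @param pop1,pop2 population ids (matched against \code{popMap}) or
#'   logical/index vectors over samples.
#' @param outgroup outgroup population id, or \code{NULL} to fold.
#' @param project \code{TRUE} to project sites with missing calls onto the
#'   target sizes; \code{FALSE} to require fully genotyped sites.
#' @param target optional haploid target sizes \code{c(n1, n2)} (defaults
#'   to the full sample sizes).
#' @return a \linkS4class{JointSFS}; skipped-site count in
#'   \code{attr(, "n_skipped")}.
#' @export
buildJointSfs <- function(x, pop1, pop2, outgroup = NULL, project = FALSE,
                          target = NULL) {
  pm <- popMap(x)
  sel <- function(p) {
    if (is.character(p) && length(p) <= length(unique(pm$population)))
      which(pm$population %in% p)
    else if (is.logical(p)) which(p) else p
  }
  i1 <- sel(pop1); i2 <- sel(pop2)
  d <- dosages(x)
  d1 <- d[, i1, drop = FALSE]; d2 <- d[, i2, drop = FALSE]
  n1f <- 2L * length(i1); n2f <- 2L * length(i2)
  if (is.null(target)) target <- c(n1f, n2f)
  n1t <- target[1]; n2t <- target[2]

  k1 <- rowSums(d1, na.rm = TRUE); m1 <- 2 * rowSums(!is.na(d1))
  k2 <- rowSums(d2, na.rm = TRUE); m2 <- 2 * rowSums(!is.na(d2))

  folded <- is.null(outgroup)
  keep <- rep(TRUE, nrow(d))
  if (!folded) {
    fo <- populationFrequencies(x)[, outgroup]
    keep <- !is.na(fo) & (fo == 0 | fo == 1)
    flip <- !is.na(fo) & fo == 1
    k1[flip] <- m1[flip] - k1[flip]
    k2[flip] <- m2[flip] - k2[flip]
  }
  counts <- matrix(0, n1t + 1, n2t + 1)
  n_skipped <- 0L
  for (s in which(keep)) {
    if (m1[s] < n1t || m2[s] < n2t) { n_skipped <- n_skipped + 1L; next }
    if (m1[s] == n1t && m2[s] == n2t) {
      counts[k1[s] + 1, k2[s] + 1] <- counts[k1[s] + 1, k2[s] + 1] + 1
    } else if (project) {
      w1 <- stats::dhyper(0:n1t, k1[s], m1[s] - k1[s], n1t)
      w2 <- stats::dhyper(0:n2t, k2[s], m2[s] - k2[s], n2t)
      counts <- counts + outer(w1, w2)
    } else n_skipped <- n_skipped + 1L
  }
  if (folded) counts <- .foldSfs(counts)
  sfs <- JointSFS(counts, folded = folded)
  attr(sfs, "n_skipped") <- n_skipped
  sfs
}

.foldSfs <- function(counts) {
  n1 <- nrow(counts) - 1; n2 <- ncol(counts) - 1
  out <- matrix(0, n1 + 1, n2 + 1)
  for (i in 0:n1) for (j in 0:n2) {
    if (2 * (i + j) > n1 + n2) out[n1 - i + 1, n2 - j + 1] <-
        out[n1 - i + 1, n2 - j + 1] + counts[i + 1, j + 1]
    else out[i + 1, j + 1] <- out[i + 1, j + 1] + counts[i + 1, j + 1]
  }
  out
}

#' Project a joint SFS down to smaller sample sizes
#'
#' Each entry (i, j) is redistributed over (k, l) with independent
#' hypergeometric weights C(i,k) C(n1-i, n1'-k) / C(n1, n1') (and the
#' analogous factor in j). Mass is conserved before masking.
#'
#' @param sfs a \linkS4class{JointSFS}.
#' @param n1,n2 target haploid sizes (must not exceed the current sizes).
#' @return a \linkS4class{JointSFS} of the projected sizes.
#' @export
projectSfs <- function(sfs, n1, n2) {
  sz <- sfsSizes(sfs)
  if (n1 > sz[1] || n2 > sz[2]) stop("cannot project upward")
  W1 <- outer(0:sz[1], 0:n1,
              function(i, k) stats::dhyper(k, i, sz[1] - i, n1))
  W2 <- outer(0:sz[2], 0:n2,
              function(j, l) stats::dhyper(l, j, sz[2] - j, n2))
  JointSFS(t(W1) %*% sfsCounts(sfs) %*% W2, folded = sfs@folded)
}

#' Expected joint SFS per unit theta via Monte Carlo coalescent
#'
#' Backward-time structured coalescent with two demes of sizes nu1, nu2
#' (relative to the reference), merging into an ancestral deme of size 1
#' at T1 (times in units of 2 N_ref generations). Migration epochs by
#' model: \code{sym_mig} throughout [0, T1); \code{anc_mig} only in
#' (T2, T1); \code{sec_contact} only in [0, T2); \code{no_mig} never.
#' Within a deme, coalescence occurs at rate C(k,2)/nu; lineages migrate
#' at rate m/2 each while migration is active. Each branch contributes its
#' length to the cell of its subtended sample configuration; the average
#' over replicates divided by 2 is the expected spectrum per unit theta
#' (theta = 4 N_ref mu per locus). A fixed seed gives common random
#' numbers across likelihood evaluations.
#'
#' @param model,params see \code{\link{simulateJointSfs}}.
#' @param n1,n2 haploid sample sizes.
#' @param n_reps Monte Carlo replicates (warning below 1000).
#' @param seed integer seed.
#' @return (n1+1) x (n2+1) numeric matrix.
#' @export
expectedSfs <- function(model, params, n1, n2, n_reps = 2000, seed = 1L) {
  if (n_reps < 1000)
    warning("n_reps < 1000: expected spectrum too noisy for inference")
  mp <- .modelParams(model, params)
  set.seed(seed)
  .coal_branch_sfs(n1, n2, mp$nu1, mp$nu2, mp$T1, mp$T2, mp$m, mp$mode,
                   n_reps) / 2
}

# Poisson composite log-likelihood with theta profiled analytically.
.sfsLogLik <- function(obs, model_spectrum, mask) {
  o <- obs[mask]
  mexp <- model_spectrum[mask]
  floorv <- 1e-10 * max(sum(mexp), 1)
  mexp <- pmax(mexp, floorv)
  theta <- sum(o) / sum(mexp)
  mu <- theta * mexp
  sum(o * log(mu) - mu - lgamma(o + 1))
}

# model parameter vector <-> unconstrained optimization scale
.toOpt <- function(p, mp) {
  v <- log(c(p$nu1, p$nu2, p$T1))
  if (mp$m_used) v <- c(v, log(p$m))
  if (mp$T2_used) v <- c(v, stats::qlogis(p$T2 / p$T1))
  v
}
.fromOpt <- function(v, mp) {
  p <- list(nu1 = exp(v[1]), nu2 = exp(v[2]), T1 = exp(v[3]))
  i <- 4
  if (mp$m_used) { p$m <- exp(v[i]); i <- i + 1 }
  if (mp$T2_used) p$T2 <- p$T1 * stats::plogis(v[i])
  p
}

#' Fit a demographic model to an observed joint SFS
#'
#' Poisson composite likelihood over unmasked cells with theta profiled
#' analytically; expected spectra from \code{\link{expectedSfs}} with
#' common random numbers (the same seed at every evaluation) to stabilize
#' Nelder-Mead on the Monte Carlo surface. Optimization proceeds in
#' consecutive rounds; each round launches the stated number of replicate
#' Nelder-Mead starts perturbing the incumbent best parameters by
#' log-uniform fold-changes whose range shrinks per round, and the best
#' log-likelihood seeds the next round. Bounds are enforced by
#' log-parameterization (T2 as a logit fraction of T1).
#'
#' @param obs observed \linkS4class{JointSFS} (must be polymorphic).
#' @param model model name (see \code{\link{simulateJointSfs}}).
#' @param rounds replicate counts per round (default \code{c(10,20,30,40)}).
#' @param n_reps Monte Carlo replicates per likelihood evaluation.
#' @param seed integer seed (drives both the CRN stream and the start
#'   perturbations).
#' @param init optional initial parameter list (defaults: nu = 1, T1 = 1,
#'   m = 1, T2 = T1/2).
#' @param maxit Nelder-Mead iterations per replicate.
#' @return list of class \code{"demogFit"}: model, params, logLik, k, AIC,
#'   theta, trace (round, replicate, logLik), n_reps, seed.
#' @export
fitDemographicModel <- function(obs, model, rounds = c(10, 20, 30, 40),
                                n_reps = 2000, seed = 1L, init = NULL,
                                maxit = 120) {
  stopifnot(is(obs, "JointSFS"))
  cnt <- sfsCounts(obs)
  mask <- sfsMask(obs)
  if (sum(cnt[mask]) <= 0) stop("observed spectrum is not polymorphic")
  sz <- sfsSizes(obs)
  mp0 <- .modelParams(model, c(nu1 = 1, nu2 = 1, T1 = 1, T2 = 0.5, m = 1))
  mp0$m_used <- mp0$mode != 0L
  mp0$T2_used <- mp0$mode %in% c(2L, 3L)
  if (is.null(init)) {
    init <- list(nu1 = 1, nu2 = 1, T1 = 1)
    if (mp0$m_used) init$m <- 1
    if (mp0$T2_used) init$T2 <- 0.5
  }
  crn_seed <- seed
  if (n_reps < 1000)
    warning("n_reps < 1000: Monte Carlo likelihood surface will be noisy")
  negll <- function(v) {
    p <- .fromOpt(v, mp0)
    mexp <- suppressWarnings(
      expectedSfs(model, p, sz[1], sz[2], n_reps = n_reps,
                  seed = crn_seed))
    ll <- .sfsLogLik(cnt, mexp, mask)
    if (!is.finite(ll)) 1e12 else -ll
  }
  set.seed(seed + 1L)
  best_v <- .toOpt(init, mp0)
  best_ll <- -negll(best_v)
  trace <- data.frame(round = integer(), replicate = integer(),
                      logLik = numeric())
  any_finite <- is.finite(best_ll)
  for (r in seq_along(rounds)) {
    fold <- 2^(2 / r)  # 4, 2, 1.59, 1.41, ...
    incumbent <- best_v
    for (rep in seq_len(rounds[r])) {
      v0 <- if (r == 1 && rep == 1) incumbent
      else incumbent + stats::runif(length(incumbent), -1, 1) * log(fold)
      fit <- tryCatch(
        stats::optim(v0, negll, method = "Nelder-Mead",
                     control = list(maxit = maxit, reltol = 1e-6)),
        error = function(e) NULL)
      if (is.null(fit)) next
      ll <- -fit$value
      trace <- rbind(trace, data.frame(round = r, replicate = rep,
                                       logLik = ll))
      if (is.finite(ll)) any_finite <- TRUE
      if (ll > best_ll) { best_ll <- ll; best_v <- fit$par }
    }
  }
  if (!any_finite) stop("non-finite likelihood at every start")
  pars <- .fromOpt(best_v, mp0)
  k <- mp0$k
  mexp <- suppressWarnings(
    expectedSfs(model, pars, sz[1], sz[2], n_reps = n_reps,
                seed = crn_seed))
  theta <- sum(cnt[mask]) / sum(pmax(mexp[mask], 1e-300))
  structure(list(model = model, params = pars, logLik = best_ll, k = k,
                 AIC = 2 * k - 2 * best_ll, theta = theta, trace = trace,
                 n_reps = n_reps, seed = seed,
                 obs_signature = c(sz, sum(cnt))),
            class = "demogFit")
}

#' Rank fitted demographic models by AIC
#'
#' @param fits list of \code{"demogFit"} results on the same observed SFS.
#' @return data.frame ranked by AIC with deltaAIC; ties in AIC broken by
#'   smaller k.
#' @export
compareModels <- function(fits) {
  if (!length(fits)) stop("no fits supplied")
  sig <- lapply(fits, `[[`, "obs_signature")
  if (length(unique(vapply(sig, paste, "", collapse = ","))) > 1)
    stop("fits were computed on different observed spectra")
  df <- data.frame(
    model = vapply(fits, `[[`, "", "model"),
    k = vapply(fits, `[[`, 0, "k"),
    logLik = vapply(fits, `[[`, 0, "logLik"),
    AIC = vapply(fits, `[[`, 0, "AIC")
  )
  df <- df[order(df$AIC, df$k), , drop = FALSE]
  df$deltaAIC <- df$AIC - df$AIC[1]
  rownames(df) <- NULL
  df
}
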