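#' Centered-genotype relatedness matrix (GRM)
#'
#' Missing dosages are mean-imputed per site; with Z = dosage - 2f per
#' site, K = Z'Z / (2 sum f(1-f)) over polymorphic sites (the standard
#' centered kinship used as the random-effect covariance in mixed-model
#' association).
#'
#' @param x \linkS4class{GenotypeData} or sites x samples dosage matrix.
#' @return samples x samples symmetric numeric matrix.
#' @export
computeGrm <- function(x) {
  d <- if (is(x, "GenotypeData")) dosages(x) else as.matrix(x)
  if (ncol(d) < 2) stop("need >= 2 samples")
  dt <- .meanImpute(t(d))  # samples x sites
  f <- colMeans(dt) / 2
  poly <- f > 0 & f < 1
  if (!any(poly)) stop("all sites monomorphic")
  Z <- sweep(dt[, poly, drop = FALSE], 2, 2 * f[poly])
  K <- tcrossprod(Z) / (2 * sum(f[poly] * (1 - f[poly])))
  dimnames(K) <- list(colnames(d), colnames(d))
  K
}

# EMMA-style single-SNP LMM machinery: y = W a + x b + u + e,
# u ~ N(0, sg2 K), e ~ N(0, se2 I). Rotate by the eigenvectors of K once;
# for a variance ratio lambda = sg2/se2 the GLS weights are
# 1/(lambda d_i + 1) and the ML profile likelihood is closed-form.
.lmmProfile <- function(lambda, dvals, yt, Xt) {
  w <- 1 / (lambda * dvals + 1)
  XtW <- Xt * w
  XX <- crossprod(Xt, XtW)
  Xy <- crossprod(XtW, yt)
  bh <- tryCatch(solve(XX, Xy), error = function(e) NULL)
  if (is.null(bh)) return(list(ll = -Inf))
  resid <- yt - Xt %*% bh
  rss <- sum(w * resid^2)
  n <- length(yt)
  sigma2 <- rss / n
  ll <- -0.5 * (n * log(2 * pi * sigma2) + n + sum(log(lambda * dvals + 1)))
  list(ll = ll, beta = bh, sigma2 = sigma2, XX = XX, w = w)
}

.lmmFitSnp <- function(dvals, yt, Xt, grid, bracket = NULL) {
  if (is.null(bracket)) {
    lls <- vapply(grid, function(l) .lmmProfile(l, dvals, yt, Xt)$ll,
                  numeric(1))
    i <- which.max(lls)
    bracket <- c(grid[max(1, i - 1)], grid[min(length(grid), i + 1)])
    best_grid <- grid[i]; best_ll <- lls[i]
  } else {
    best_grid <- sqrt(bracket[1] * bracket[2])
    best_ll <- -Inf
  }
  opt <- stats::optimize(function(lg)
    .lmmProfile(exp(lg), dvals, yt, Xt)$ll,
    interval = log(bracket), maximum = TRUE, tol = 5e-2)
  lam <- exp(opt$maximum)
  if (best_ll > opt$objective) lam <- best_grid
  fit <- .lmmProfile(lam, dvals, yt, Xt)
  fit$lambda <- lam
  fit
}

# vectorized profile-likelihood over a lambda grid for all SNPs at once:
# for each lambda, residualize the (rotated, weighted) trait and every SNP
# against the covariates with one QR and a couple of GEMMs; returns the
# per-SNP index of the best grid point.
.lmmGridBest <- function(dvals, yt, Wt, Gt, grid) {
  n <- length(yt)
  lls <- matrix(-Inf, ncol(Gt), length(grid))
  for (j in seq_along(grid)) {
    lam <- grid[j]
    sw <- 1 / sqrt(lam * dvals + 1)
    qrW <- qr(Wt * sw)
    yw <- yt * sw
    yres <- qr.resid(qrW, yw)
    rss0 <- sum(yres^2)
    Gw <- Gt * sw
    Gres <- Gw - qr.fitted(qrW, Gw)
    bx <- as.vector(crossprod(Gres, yres))
    xx <- colSums(Gres^2)
    rss <- pmax(rss0 - bx^2 / pmax(xx, 1e-300), 1e-300)
    lls[, j] <- -0.5 * (n * log(2 * pi * rss / n) + n +
                          sum(log(lam * dvals + 1)))
    lls[xx <= 1e-12, j] <- -Inf
  }
  max.col(lls, ties.method = "first")
}

#' Kinship-corrected per-SNP Wald scan (univariate LMM)
#'
#' Per SNP, the model y = W a + x b + u + e with u ~ N(0, sg2 K),
#' e ~ N(0, se2 I) is fitted by maximum likelihood over the variance
#' ratio lambda = sg2/se2 (coarse log-grid then Brent refinement on
#' log lambda in [1e-5, 1e5]), after a single eigendecomposition of K.
#' The Wald statistic b^2 / Var(b) is referred to chi-square(1).
#'
#' @param trait named numeric vector (names = samples) or a column of the
#'   phenotype table.
#' @param x \linkS4class{GenotypeData} or sites x samples dosage matrix.
#' @param K kinship from \code{\link{computeGrm}}.
#' @param covariates optional samples x c matrix/data.frame (an intercept
#'   is always included).
#' @param adjust multiple-testing method for the adjusted column.
#' @return data.frame: site, beta, se, wald, lambda, p, p_adj. Monomorphic
#'   SNPs are skipped.
#' @export
lmmWaldScan <- function(trait, x, K, covariates = NULL, adjust = "BH") {
  d <- if (is(x, "GenotypeData")) dosages(x) else as.matrix(x)
  samples <- colnames(d)
  if (!is.null(names(trait))) trait <- trait[samples]
  if (stats::var(trait, na.rm = TRUE) == 0) stop("constant trait")
  W <- cbind(`(Intercept)` = rep(1, length(trait)))
  if (!is.null(covariates)) W <- cbind(W, as.matrix(covariates))
  keep <- !is.na(trait) & stats::complete.cases(W)
  y <- trait[keep]; W <- W[keep, , drop = FALSE]
  Ku <- K[keep, keep]
  eg <- eigen(Ku, symmetric = TRUE)
  dvals <- pmax(eg$values, 0)
  U <- eg$vectors
  yt <- crossprod(U, y)
  Wt <- crossprod(U, W)
  dimp <- .meanImpute(t(d[, keep, drop = FALSE]))  # samples x sites
  grid <- exp(seq(log(1e-5), log(1e5), length.out = 25))
  poly <- apply(dimp, 2, stats::var) > 0
  Gt <- crossprod(U, dimp[, poly, drop = FALSE])
  best <- .lmmGridBest(dvals, yt, Wt, Gt, grid)
  sites <- which(poly)
  ns <- length(sites)
  beta <- se <- wald <- lam <- rep(NA_real_, ns)
  Xt <- cbind(Wt, snp = 0)
  j <- ncol(Xt)
  for (k in seq_len(ns)) {
    Xt[, j] <- Gt[, k]
    i <- best[k]
    bracket <- c(grid[max(1, i - 1)], grid[min(length(grid), i + 1)])
    fit <- .lmmFitSnp(dvals, yt, Xt, grid, bracket = bracket)
    if (!is.finite(fit$ll)) next
    vb <- fit$sigma2 * solve(fit$XX)[j, j]
    beta[k] <- fit$beta[j]
    se[k] <- sqrt(vb)
    wald[k] <- beta[k]^2 / vb
    lam[k] <- fit$lambda
  }
  ok <- !is.na(wald)
  if (!any(ok)) stop("no polymorphic SNPs to test")
  out <- data.frame(
    site = (rownames(d) %||% seq_len(nrow(d)))[sites[ok]],
    beta = beta[ok], se = se[ok], wald = wald[ok], lambda = lam[ok],
    p = stats::pchisq(wald[ok], 1, lower.tail = FALSE))
  out$p_adj <- adjustPvalues(out$p, method = adjust)
  rownames(out) <- NULL
  out
}

#' Multi-trait omnibus scan (sum of squared per-trait LMM z-scores)
#'
#' Runs the univariate LMM per trait, forms per-SNP z = sign(beta)
#' sqrt(Wald), and combines them as omnibus = sum z_t^2 referred to
#' chi-square(#traits). An approximation to a full multivariate mixed
#' model, exact when traits are uncorrelated given the covariates.
#'
#' @param traits samples x traits matrix/data.frame (>= 2 traits on shared
#'   samples).
#' @param x,K,covariates,adjust as in \code{\link{lmmWaldScan}}.
#' @return data.frame: site, omnibus, df, p, p_adj.
#' @export
multitraitScan <- function(traits, x, K, covariates = NULL, adjust = "BH") {
  traits <- as.matrix(traits)
  if (ncol(traits) < 2) stop("need >= 2 traits")
  if (any(colSums(!is.na(traits)) == 0) ||
      !any(stats::complete.cases(traits)))
    stop("traits must share observed samples")
  scans <- lapply(seq_len(ncol(traits)), function(j)
    lmmWaldScan(traits[, j], x, K, covariates = covariates, adjust = adjust))
  site <- scans[[1]]$site
  z2 <- sapply(scans, function(s) {
    stopifnot(identical(s$site, site))
    s$wald
  })
  omni <- rowSums(as.matrix(z2))
  df <- ncol(traits)
  out <- data.frame(site = site, omnibus = omni, df = df,
                    p = stats::pchisq(omni, df, lower.tail = FALSE))
  out$p_adj <- adjustPvalues(out$p, method = adjust)
  out
}

#' Phenotype principal components
#'
#' Column-centered PCA (unit-variance scaling optional) of a complete
#' peak/trait matrix; rows with missing values are dropped with a message.
#'
#' @param peaks samples x variables matrix/data.frame.
#' @param n_pcs number of components to return (default 4).
#' @param scale. unit-variance scaling.
#' @return list: scores (samples x n_pcs), loadings, var_fraction
#'   (per returned PC), sdev, dropped (row names removed).
#' @export
phenotypePca <- function(peaks, n_pcs = 4, scale. = FALSE) {
  m <- as.matrix(peaks)
  keep <- stats::complete.cases(m)
  if (sum(keep) < 2) stop("need >= 2 complete samples")
  if (any(!keep))
    message(sum(!keep), " sample(s) with missing peaks dropped")
  pc <- stats::prcomp(m[keep, , drop = FALSE], center = TRUE,
                      scale. = scale.)
  n_pcs <- min(n_pcs, ncol(pc$x))
  varfrac <- pc$sdev^2 / sum(pc$sdev^2)
  list(scores = pc$x[, seq_len(n_pcs), drop = FALSE],
       loadings = pc$rotation[, seq_len(n_pcs), drop = FALSE],
       var_fraction = varfrac[seq_len(n_pcs)], sdev = pc$sdev,
       dropped = rownames(m)[!keep])
}

#' Multiple-testing adjustment
#'
#' Benjamini-Hochberg step-up (with monotonicity enforcement) or
#' Bonferroni; input p-values must lie in (0, 1].
#'
#' @param p numeric vector of p-values.
#' @param method \code{"BH"} or \code{"bonferroni"}.
#' @return adjusted p-values, same length.
#' @export
adjustPvalues <- function(p, method = c("BH", "bonferroni")) {
  method <- match.arg(method)
  if (any(is.na(p)) || any(p <= 0 | p > 1))
    stop("p-values must lie in (0, 1]")
  stats::p.adjust(p, method = method)
}
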