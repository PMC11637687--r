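#' Fit a latent-factor model for genotype-environment association
#'
#' Alternating estimation on the centered, mean-imputed genotype matrix Y
#' (samples x sites) and centered environment matrix X (samples x d):
#' given the factors, the environmental effects are the ridge estimate
#' B' = (X'X + lambda I)^-1 X' (Y - U V'); given B, the rank-K truncated
#' SVD of (Y - X B') yields U (scores) and V (loadings). Iterates until
#' the relative objective change falls below \code{tol} or \code{max_iter}
#' iterations.
#'
#' @param x \linkS4class{GenotypeData} or sites x samples dosage matrix.
#' @param env samples x d environment matrix (e.g., cbind(lat, lon)).
#' @param K number of latent factors (>= 0; must be < min(n, p)).
#' @param lambda ridge penalty; default 1e-5 * n_sites.
#' @param tol,max_iter convergence controls.
#' @return list of class \code{"lfmmFit"}: K, U (n x K), V (p x K),
#'   B (p x d), lambda, objective (trace), center (site means),
#'   env_center.
#' @export
fitLatentFactors <- function(x, env, K, lambda = NULL, tol = 1e-6,
                             max_iter = 200) {
  d <- if (is(x, "GenotypeData")) dosages(x) else as.matrix(x)
  Y <- .meanImpute(t(d))  # samples x sites
  n <- nrow(Y); p <- ncol(Y)
  if (K >= min(n, p)) stop("K must be < min(n_samples, n_sites)")
  ctr <- colMeans(Y)
  Y <- sweep(Y, 2, ctr)
  X <- as.matrix(env)
  xc <- colMeans(X)
  X <- sweep(X, 2, xc)
  if (is.null(lambda)) lambda <- 1e-5 * p
  dX <- ncol(X)
  XtX <- crossprod(X) + lambda * diag(dX)
  UV <- matrix(0, n, p)
  obj <- numeric()
  B <- matrix(0, p, dX)
  U <- matrix(0, n, max(K, 0)); V <- matrix(0, p, max(K, 0))
  for (it in seq_len(max_iter)) {
    Bt <- solve(XtX, crossprod(X, Y - UV))  # d x p
    B <- t(Bt)
    R <- Y - X %*% Bt
    if (K > 0) {
      sv <- svd(R, nu = K, nv = K)
      U <- sv$u %*% diag(sv$d[seq_len(K)], K, K)
      V <- sv$v
      UV <- tcrossprod(U, V)
    }
    o <- sum((Y - X %*% Bt - UV)^2) + lambda * sum(Bt^2)
    obj <- c(obj, o)
    if (it > 1 && abs(obj[it - 1] - o) <=
        tol * max(obj[it - 1], .Machine$double.eps)) break
    if (K == 0) break
  }
  structure(list(K = K, U = U, V = V, B = B, lambda = lambda,
                 objective = obj, center = ctr, env_center = xc),
            class = "lfmmFit")
}

#' Genotype-environment association scan with genomic-inflation
#' calibration
#'
#' Per site and environmental variable, a z-score from the ordinary
#' regression of the (centered, imputed) genotype on [X, U]; the genomic
#' inflation factor GIF = median(z^2) / 0.4549 (the null median of a
#' 1-df chi-square) rescales z^2 before the chi-square(1) p-value. Hits
#' satisfy the dual criterion: calibrated p < \code{p_cut} for BOTH
#' variables (no further multiplicity correction).
#'
#' @param model an \code{"lfmmFit"}.
#' @param x genotypes as in \code{\link{fitLatentFactors}}.
#' @param env samples x d environment matrix; collinear columns (e.g.,
#'   constant latitude) are an error.
#' @param p_cut dual-criterion threshold (default 0.001).
#' @return list: \code{table} (data.frame: site plus z, p per variable,
#'   hit), \code{gif} (per variable).
#' @export
geaScan <- function(model, x, env, p_cut = 0.001) {
  d <- if (is(x, "GenotypeData")) dosages(x) else as.matrix(x)
  Y <- .meanImpute(t(d))
  Y <- sweep(Y, 2, colMeans(Y))
  X <- sweep(as.matrix(env), 2, colMeans(as.matrix(env)))
  if (qr(X)$rank < ncol(X))
    stop("degenerate environment matrix (collinear or constant variables)")
  D <- cbind(X, if (model$K > 0) model$U)
  n <- nrow(D); q <- ncol(D)
  qrD <- qr(D)
  if (qrD$rank < q) stop("design matrix rank-deficient")
  coefs <- qr.coef(qrD, Y)                      # q x p
  resid <- Y - D %*% coefs
  s2 <- colSums(resid^2) / (n - q)
  XtXinv <- chol2inv(qr.R(qrD))
  vars <- outer(diag(XtXinv), s2)               # q x p
  z <- coefs / sqrt(vars)
  z[, s2 <= 0] <- NA  # monomorphic / perfectly fitted sites: no test
  dvars <- seq_len(ncol(X))
  labels <- colnames(env)
  if (is.null(labels)) labels <- paste0("env", dvars)
  tab <- data.frame(site = colnames(Y) %||% seq_len(ncol(Y)))
  gif <- numeric(length(dvars)); names(gif) <- labels
  for (j in dvars) {
    zj <- z[j, ]
    gif[j] <- stats::median(zj^2, na.rm = TRUE) / stats::qchisq(0.5, 1)
    pj <- stats::pchisq(zj^2 / gif[j], 1, lower.tail = FALSE)
    tab[[paste0("z_", labels[j])]] <- zj
    tab[[paste0("p_", labels[j])]] <- pj
  }
  pcols <- paste0("p_", labels)
  tab$hit <- Reduce(`&`, lapply(pcols, function(cn)
    !is.na(tab[[cn]]) & tab[[cn]] < p_cut))
  list(table = tab, gif = gif)
}
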