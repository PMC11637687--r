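#' Sliding-window LD pruning
#'
#' Within sliding windows of \code{window} SNPs (advanced by \code{step}),
#' any pair of retained SNPs with squared dosage correlation above
#' \code{r2_max} loses one member: the SNP with more missing data, ties
#' broken by dropping the later position. Single pass.
#'
#' @param x \linkS4class{GenotypeData} or sites x samples dosage matrix.
#' @param window,step window and step in SNP counts (window >= step >= 1).
#' @param r2_max maximum tolerated squared correlation, in (0, 1].
#' @return logical vector over sites; TRUE = retained.
#' @export
ldPrune <- function(x, window = 50, step = 10, r2_max = 0.01) {
  d <- if (is(x, "GenotypeData")) dosages(x) else as.matrix(x)
  if (r2_max <= 0 || r2_max > 1) stop("r2_max must be in (0, 1]")
  stopifnot(window >= step, step >= 1)
  L <- nrow(d)
  keep <- rep(TRUE, L)
  nmiss <- rowSums(is.na(d))
  start <- 1
  repeat {
    end <- min(start + window - 1, L)
    idx <- which(keep[start:end]) + start - 1
    if (length(idx) >= 2) {
      r2 <- suppressWarnings(
        stats::cor(t(d[idx, , drop = FALSE]),
                   use = "pairwise.complete.obs"))^2
      repeat {
        live <- keep[idx]
        sub <- r2[live, live, drop = FALSE]
        diag(sub) <- 0
        sub[is.na(sub)] <- 0
        if (!any(sub > r2_max)) break
        w <- which(sub == max(sub), arr.ind = TRUE)[1, ]
        pair <- idx[live][c(w[1], w[2])]
        drop <- if (nmiss[pair[1]] != nmiss[pair[2]])
          pair[which.max(nmiss[pair])] else max(pair)
        keep[drop] <- FALSE
      }
    }
    if (end == L) break
    start <- start + step
  }
  keep
}

#' Genotype principal components
#'
#' Mean-imputes missing dosages, centers sites (unit-variance scaling
#' optional) and eigendecomposes the sample covariance.
#'
#' @param x \linkS4class{GenotypeData} or sites x samples dosage matrix.
#' @param n_pcs number of components.
#' @param scale. unit-variance scaling of sites.
#' @return list: scores (samples x n_pcs), var_fraction, sdev.
#' @export
genotypePca <- function(x, n_pcs = 4, scale. = FALSE) {
  d <- if (is(x, "GenotypeData")) dosages(x) else as.matrix(x)
  if (ncol(d) < 2) stop("need >= 2 samples")
  m <- .meanImpute(t(d))
  v <- apply(m, 2, stats::var)
  if (all(v == 0)) stop("zero-variance genotype data")
  if (scale.) m <- m[, v > 0, drop = FALSE]
  pc <- stats::prcomp(m, center = TRUE, scale. = scale.)
  n_pcs <- min(n_pcs, ncol(pc$x))
  varfrac <- pc$sdev^2 / sum(pc$sdev^2)
  list(scores = pc$x[, seq_len(n_pcs), drop = FALSE],
       var_fraction = varfrac[seq_len(n_pcs)], sdev = pc$sdev)
}

# exact simplex-constrained least squares for one row: minimize
# ||y - F q||^2 with q >= 0, sum q = 1, by enumerating active sets
# (K is small). Returns the best feasible solution.
.simplexLs <- function(Ft, FtF, Fty) {
  K <- ncol(Ft)
  best <- NULL; bestval <- Inf
  supports <- lapply(seq_len(2^K - 1), function(mask)
    which(bitwAnd(mask, 2^(seq_len(K) - 1)) > 0))
  for (sup in supports) {
    k <- length(sup)
    A <- FtF[sup, sup, drop = FALSE]
    # equality-constrained LS: minimize q'Aq/2 - q'b s.t. sum q = 1
    b <- Fty[sup]
    M <- rbind(cbind(A, 1), c(rep(1, k), 0))
    sol <- tryCatch(solve(M, c(b, 1)), error = function(e) NULL)
    if (is.null(sol)) next
    q <- sol[seq_len(k)]
    if (any(q < -1e-10)) next
    q <- pmax(q, 0); q <- q / sum(q)
    val <- sum(q * (A %*% q)) / 2 - sum(q * b)
    if (val < bestval - 1e-12) { bestval <- val; best <- list(sup = sup, q = q) }
  }
  out <- numeric(K)
  if (!is.null(best)) out[best$sup] <- best$q else out[] <- 1 / K
  out
}

#' Simplex-constrained ancestry estimation (alternating least squares)
#'
#' Minimizes ||D/2 - Q F'||^2 over admixture proportions Q (rows on the
#' simplex) and allele frequencies F in [0, 1], by exact alternating
#' minimization: each Q row solves a simplex-constrained least-squares
#' problem (active sets enumerated; K is small), each F entry a
#' box-constrained coordinate update. Three random restarts (best
#' objective kept); deterministic given \code{seed}. The objective is
#' non-increasing across iterations.
#'
#' @param x \linkS4class{GenotypeData} or sites x samples dosage matrix.
#' @param K number of ancestral clusters (1 <= K <= n_samples).
#' @param seed integer seed.
#' @param n_restarts random restarts.
#' @param max_iter,tol convergence controls.
#' @return list: Q (samples x K), F (sites x K), objective (final),
#'   trace (per-iteration objective of the winning restart).
#' @export
admixtureAls <- function(x, K, seed = 1L, n_restarts = 3, max_iter = 200,
                         tol = 1e-6) {
  d <- if (is(x, "GenotypeData")) dosages(x) else as.matrix(x)
  stopifnot(K >= 1)
  if (K > ncol(d)) stop("K > number of samples")
  P <- .meanImpute(t(d)) / 2  # samples x sites in [0,1]
  n <- nrow(P); L <- ncol(P)
  if (K == 1)
    return(list(Q = matrix(1, n, 1, dimnames = list(rownames(P), NULL)),
                F = matrix(colMeans(P), L, 1), objective = {
                  Fm <- matrix(colMeans(P), L, 1)
                  sum((P - matrix(1, n, 1) %*% t(Fm))^2)
                }, trace = numeric()))
  set.seed(seed)
  best <- NULL
  for (rs in seq_len(n_restarts)) {
    Fm <- matrix(stats::runif(L * K, 0.05, 0.95), L, K)
    Q <- matrix(stats::rexp(n * K), n, K)
    Q <- Q / rowSums(Q)
    trace <- numeric()
    obj_prev <- Inf
    for (it in seq_len(max_iter)) {
      # Q-step: exact per-row simplex LS
      FtF <- crossprod(Fm)
      FtP <- crossprod(Fm, t(P))  # K x n
      for (i in seq_len(n)) Q[i, ] <- .simplexLs(Fm, FtF, FtP[, i])
      # F-step: per-cluster box-constrained coordinate updates
      QtQ <- crossprod(Q)
      QtP <- crossprod(Q, P)      # K x L
      for (k in seq_len(K)) {
        if (QtQ[k, k] <= 0) next
        num <- QtP[k, ] - (QtQ[k, -k, drop = FALSE] %*%
                             t(Fm[, -k, drop = FALSE]))[1, ]
        Fm[, k] <- pmin(1, pmax(0, num / QtQ[k, k]))
      }
      obj <- sum((P - tcrossprod(Q, Fm))^2)
      trace <- c(trace, obj)
      if (obj_prev - obj <= tol * max(1, obj_prev)) break
      obj_prev <- obj
    }
    if (is.null(best) || trace[length(trace)] < best$objective)
      best <- list(Q = Q, F = Fm, objective = trace[length(trace)],
                   trace = trace)
  }
  rownames(best$Q) <- rownames(P)
  best
}
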