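#' Non-negative matrix factorisation of a beta-value matrix
#'
#' Factorises a non-negative probes-by-samples matrix `V` into `W %*% H`
#' (`W`: probes x k non-negative basis, the "metagenes"; `H`: k x samples
#' non-negative scores) by multiplicative updates minimising the Frobenius
#' reconstruction error. Beta values are used directly: they are naturally
#' non-negative, which the factorisation requires. The best of `n_restarts`
#' random non-negative initialisations is returned, with `W` columns scaled
#' to unit L2 norm (the scale is absorbed into `H`).
#'
#' @param V A [probe_matrix] or non-negative numeric matrix without missing
#'   values.
#' @param k Number of metagenes; must be smaller than both dimensions.
#' @param n_restarts Number of random initialisations (default 10).
#' @param max_iter Maximum multiplicative updates per restart (default 1000).
#' @param tol Relative objective-change convergence tolerance (default 1e-6).
#' @param seed Optional integer seed; results are deterministic given it.
#'
#' @return An object of class `metagene_nmf`: list with `W`, `H`, `k`,
#'   `objective` (final Frobenius residual), `objective_trace`, `converged`,
#'   `iterations`. Metagenes are named `V1..Vk`. A warning is issued if the
#'   best restart did not reach `tol` within `max_iter`.
#' @export
nmf_factorise <- function(V, k, n_restarts = 10, max_iter = 1000,
                          tol = 1e-6, seed = NULL) {
  V <- as.matrix(unclass(V))
  if (anyNA(V)) stop("V must not contain missing values")
  if (min(V) < 0) stop("V must be non-negative")
  if (k >= min(dim(V)) || k < 1) stop("k must satisfy 1 <= k < min(dim(V))")
  if (!is.null(seed)) set.seed(seed)

  best <- NULL
  for (r in seq_len(n_restarts)) {
    fit <- nmf_single(V, k, max_iter, tol)
    if (is.null(best) || fit$objective < best$objective) best <- fit
  }
  if (!best$converged) {
    warning("NMF did not converge to tol = ", tol, " within ", max_iter,
            " iterations")
  }
  # absorb column scale of W into H
  s <- sqrt(colSums(best$W^2))
  s[s == 0] <- 1
  W <- sweep(best$W, 2, s, "/")
  H <- best$H * s
  mg <- paste0("V", seq_len(k))
  dimnames(W) <- list(rownames(V), mg)
  dimnames(H) <- list(mg, colnames(V))
  structure(list(W = W, H = H, k = k, objective = best$objective,
                 objective_trace = best$trace, converged = best$converged,
                 iterations = length(best$trace)),
            class = "metagene_nmf")
}

nmf_single <- function(V, k, max_iter, tol) {
  p <- nrow(V); n <- ncol(V)
  scale0 <- sqrt(mean(V) / k)
  W <- matrix(stats::runif(p * k, 0, 2 * scale0), p, k)
  H <- matrix(stats::runif(k * n, 0, 2 * scale0), k, n)
  eps <- .Machine$double.eps
  v2 <- sum(V^2)
  trace <- numeric(0)
  prev <- Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    WtV <- crossprod(W, V)
    H <- H * WtV / (crossprod(W) %*% H + eps)
    VHt <- V %*% t(H)
    HHt <- tcrossprod(H)
    W <- W * VHt / (W %*% HHt + eps)
    # Frobenius residual via the factor Gram matrices (no p x n product)
    obj2 <- v2 - 2 * sum(W * VHt) + sum(crossprod(W) * HHt)
    obj <- sqrt(max(obj2, 0))
    trace <- c(trace, obj)
    if (is.finite(prev) && abs(prev - obj) <= tol * max(prev, eps)) {
      converged <- TRUE
      break
    }
    prev <- obj
  }
  list(W = W, H = H, objective = trace[length(trace)], trace = trace,
       converged = converged)
}

#' @export
print.metagene_nmf <- function(x, ...) {
  cat(sprintf(
    "metagene_nmf: k = %d, %d probes x %d samples, residual %.4g (%s)\n",
    x$k, nrow(x$W), ncol(x$H), x$objective,
    if (x$converged) "converged" else "max_iter reached"))
  invisible(x)
}

#' k-means clustering of metagene scores
#'
#' Standardises each metagene score across samples (z-scores, so that
#' high-magnitude metagenes do not dominate the Euclidean metric) and runs
#' k-means with multiple restarts, keeping the solution with the lowest
#' within-cluster sum of squares. The standardisation parameters are
#' returned so that independent cohorts can be classified in the same frozen
#' coordinate system.
#'
#' @param H k x samples score matrix (for example `fit$H` from
#'   [nmf_factorise()]).
#' @param k_clusters Number of clusters (>= 2, <= samples).
#' @param n_restarts Random restarts (default 100).
#' @param seed Optional integer seed.
#'
#' @return Object of class `metagene_kmeans`: `assignments` (named integer),
#'   `centers` (k_clusters x metagenes, standardised space), `scale_means`,
#'   `scale_sds`, `tot_withinss`.
#' @export
kmeans_metagene_cluster <- function(H, k_clusters, n_restarts = 100,
                                    seed = NULL) {
  if (k_clusters <= 1) stop("k_clusters must be at least 2")
  if (k_clusters > ncol(H)) stop("k_clusters exceeds the number of samples")
  if (anyNA(H) || any(!is.finite(H))) stop("H must be finite")
  if (!is.null(seed)) set.seed(seed)
  z <- standardise_scores(H)
  km <- stats::kmeans(t(z$scores), centers = k_clusters,
                      nstart = n_restarts, iter.max = 100)
  structure(list(assignments = stats::setNames(km$cluster, colnames(H)),
                 centers = km$centers, scale_means = z$means,
                 scale_sds = z$sds, tot_withinss = km$tot.withinss),
            class = "metagene_kmeans")
}

standardise_scores <- function(H, means = NULL, sds = NULL) {
  if (is.null(means)) means <- rowMeans(H)
  if (is.null(sds)) {
    sds <- apply(H, 1, stats::sd)
    sds[sds == 0 | is.na(sds)] <- 1  # constant metagene carries no signal
  }
  list(scores = (H - means) / sds, means = means, sds = sds)
}
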