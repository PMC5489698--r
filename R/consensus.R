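#' Optimal matching between two label sets
#'
#' Solves the maximum-agreement bipartite assignment between the labels of
#' two clusterings of the same samples (Hungarian-type matching on the
#' contingency table), so that clusterings can be compared up to label
#' permutation.
#'
#' @param a,b Vectors of cluster labels over the same samples (same length;
#'   if both are named, they are aligned by name).
#' @return List with `mapping` (named character: label of `b` -> matched
#'   label of `a`), `b_mapped` (relabelled `b`) and `agreement` (% of samples
#'   with identical label after matching).
#' @export
match_labels <- function(a, b) {
  if (!is.null(names(a)) && !is.null(names(b))) {
    if (!setequal(names(a), names(b))) stop("label vectors cover different samples")
    b <- b[names(a)]
  }
  if (length(a) != length(b)) stop("label vectors differ in length")
  tab <- table(factor(b), factor(a))
  map <- assignment_map(tab)
  b_mapped <- unname(map[as.character(b)])
  names(b_mapped) <- names(b)
  list(mapping = map, b_mapped = b_mapped,
       agreement = 100 * mean(b_mapped == as.character(a)))
}

# maximum-weight bipartite assignment rows(tab) -> cols(tab);
# unmatched rows keep their own label
assignment_map <- function(tab) {
  nr <- nrow(tab); nc <- ncol(tab)
  m <- max(nr, nc)
  w <- matrix(0, m, m)
  w[seq_len(nr), seq_len(nc)] <- tab
  rn <- c(rownames(tab), sprintf(".pad_r%d", seq_len(m - nr)))
  cn <- c(colnames(tab), sprintf(".pad_c%d", seq_len(m - nc)))
  dimnames(w) <- list(rn, cn)
  g <- igraph::graph_from_biadjacency_matrix(w + 1, weighted = TRUE)
  mm <- igraph::max_bipartite_match(g, weights = igraph::E(g)$weight)
  to <- mm$matching[rownames(tab)]
  unmatched <- is.na(to) | startsWith(to, ".pad_")
  to[unmatched] <- rownames(tab)[unmatched]
  stats::setNames(unname(to), rownames(tab))
}

#' Bootstrapped NMF consensus clustering
#'
#' Runs the class-discovery procedure: a full-data reference factorisation
#' and k-means clustering, followed by `n_iter` resampling iterations. Each
#' iteration resamples samples with replacement (or subsamples, see
#' `method`), refits NMF + k-means on the resampled matrix, and maps the
#' iteration clusters onto the reference clusters by maximum-overlap
#' bipartite matching. The consensus matrix entry for a sample pair is the
#' fraction of their co-appearances in which they co-clustered; a sample's
#' confidence is the fraction of iterations containing it in which it mapped
#' to its modal reference cluster.
#'
#' @param V A [probe_matrix] or non-negative matrix (no missing values).
#' @param k_metagenes Number of NMF metagenes.
#' @param k_clusters Number of k-means clusters.
#' @param n_iter Resampling iterations (default 250).
#' @param seed Optional integer seed.
#' @param method "bootstrap" (sampling with replacement, default) or
#'   "subsample".
#' @param subsample_fraction Fraction sampled when `method = "subsample"`
#'   (default 0.8).
#' @param nmf_restarts_ref,nmf_restarts_iter NMF restarts for the reference
#'   fit and per-iteration refits (defaults 10 and 1; refits start from fresh
#'   random initialisations, where one restart suffices because the consensus
#'   aggregates over iterations).
#' @param kmeans_restarts_ref,kmeans_restarts_iter k-means restarts
#'   (defaults 100 and 30; generous restarts inside the loop keep iteration
#'   clusterings out of poor local optima, which would otherwise depress
#'   assignment confidence).
#' @param max_iter,tol Passed to [nmf_factorise()] (defaults 500 and 1e-5
#'   within the resampling loop).
#'
#' @return Object of class `consensus_run`: `consensus` (samples x samples),
#'   `assignments` (modal reference cluster per sample), `confidence`,
#'   `cophenetic`, `k_metagenes`, `k_clusters`, `n_iterations`, and
#'   `reference` (the full-data `metagene_nmf` and `metagene_kmeans` fits).
#' @export
bootstrap_consensus <- function(V, k_metagenes, k_clusters, n_iter = 250,
                                seed = NULL,
                                method = c("bootstrap", "subsample"),
                                subsample_fraction = 0.8,
                                nmf_restarts_ref = 10, nmf_restarts_iter = 1,
                                kmeans_restarts_ref = 100,
                                kmeans_restarts_iter = 30,
                                max_iter = 500, tol = 1e-5) {
  method <- match.arg(method)
  if (n_iter < 2) stop("n_iter must be at least 2")
  V <- as.matrix(unclass(V))
  n <- ncol(V)
  ids <- colnames(V)
  if (!is.null(seed)) set.seed(seed)
  seeds <- sample.int(.Machine$integer.max - 1, n_iter + 2)

  ref_nmf <- nmf_factorise(V, k_metagenes, n_restarts = nmf_restarts_ref,
                           max_iter = max_iter, tol = tol, seed = seeds[1])
  ref_km <- kmeans_metagene_cluster(ref_nmf$H, k_clusters,
                                    n_restarts = kmeans_restarts_ref,
                                    seed = seeds[2])
  ref_lab <- ref_km$assignments

  co_cluster <- matrix(0, n, n, dimnames = list(ids, ids))
  co_present <- matrix(0, n, n, dimnames = list(ids, ids))
  lab_counts <- matrix(0, n, k_clusters, dimnames = list(ids, NULL))
  present_n <- stats::setNames(numeric(n), ids)

  for (it in seq_len(n_iter)) {
    set.seed(seeds[it + 2])
    idx <- if (method == "bootstrap") {
      sample.int(n, n, replace = TRUE)
    } else {
      sample.int(n, max(2, round(subsample_fraction * n)))
    }
    Vb <- V[, idx, drop = FALSE]
    colnames(Vb) <- sprintf("b%05d", seq_along(idx))
    fit <- suppressWarnings(
      nmf_factorise(Vb, k_metagenes, n_restarts = nmf_restarts_iter,
                    max_iter = max_iter, tol = tol))
    km <- try(kmeans_metagene_cluster(fit$H, k_clusters,
                                      n_restarts = kmeans_restarts_iter),
              silent = TRUE)
    if (inherits(km, "try-error")) next  # degenerate resample (too few
                                         # distinct points); skip iteration
    uniq <- !duplicated(idx)
    u_idx <- idx[uniq]
    it_lab <- unname(km$assignments)[uniq]
    map <- assignment_map(table(factor(it_lab, levels = seq_len(k_clusters)),
                                factor(ref_lab[u_idx],
                                       levels = seq_len(k_clusters))))
    mapped <- as.integer(map[as.character(it_lab)])
    same <- outer(mapped, mapped, "==")
    co_cluster[u_idx, u_idx] <- co_cluster[u_idx, u_idx] + same
    co_present[u_idx, u_idx] <- co_present[u_idx, u_idx] + 1
    present_n[u_idx] <- present_n[u_idx] + 1
    lab_counts[cbind(u_idx, mapped)] <- lab_counts[cbind(u_idx, mapped)] + 1
  }

  if (any(present_n == 0)) {
    stop("sample(s) absent from every iteration: ",
         paste(ids[present_n == 0], collapse = ", "))
  }
  consensus <- matrix(0, n, n, dimnames = list(ids, ids))
  seen <- co_present > 0
  consensus[seen] <- co_cluster[seen] / co_present[seen]
  if (any(!seen[upper.tri(seen)])) {
    warning("some sample pairs never co-appeared; their consensus is 0")
  }
  diag(consensus) <- 1

  modal <- max.col(lab_counts, ties.method = "first")
  confidence <- lab_counts[cbind(seq_len(n), modal)] / present_n
  coph <- tryCatch(cophenetic_index(consensus), error = function(e) NA_real_)

  structure(list(consensus = consensus,
                 assignments = stats::setNames(modal, ids),
                 confidence = stats::setNames(confidence, ids),
                 cophenetic = coph,
                 k_metagenes = k_metagenes, k_clusters = k_clusters,
                 n_iterations = n_iter,
                 reference = list(nmf = ref_nmf, kmeans = ref_km)),
            class = "consensus_run")
}

#' @export
print.consensus_run <- function(x, ...) {
  cat(sprintf(paste0("consensus_run: %d samples, %d metagenes / %d clusters,",
                     " %d iterations\n  cophenetic %.4f, mean confidence",
                     " %.3f\n"),
              ncol(x$consensus), x$k_metagenes, x$k_clusters, x$n_iterations,
              x$cophenetic, mean(x$confidence)))
  invisible(x)
}

#' Cophenetic index of a consensus matrix
#'
#' Measures cluster stability as the Pearson correlation between the
#' consensus dissimilarities (1 - consensus) and the cophenetic distances of
#' their average-linkage hierarchical clustering. Values near 1 indicate a
#' stable, nearly block-diagonal consensus.
#'
#' @param consensus Symmetric samples x samples matrix in \[0, 1\] with unit
#'   diagonal, or a `consensus_run`.
#' @return The cophenetic index (scalar in \[-1, 1\]).
#' @export
cophenetic_index <- function(consensus) {
  if (inherits(consensus, "consensus_run")) consensus <- consensus$consensus
  if (nrow(consensus) <= 2) stop("need more than 2 samples")
  d <- stats::as.dist(1 - consensus)
  if (stats::sd(d) == 0) {
    stop("cophenetic index undefined: dissimilarities have zero variance")
  }
  hc <- stats::hclust(d, method = "average")
  stats::cor(stats::cophenetic(hc), d)
}

#' Confidence-thresholded cluster assignment
#'
#' Samples whose resampling confidence reaches the threshold keep their modal
#' cluster; the rest are labelled non-classifiable ("NC").
#'
#' @param run A `consensus_run`.
#' @param threshold Confidence threshold in (0, 1\]; default 0.80.
#' @return Named character vector of cluster labels ("1".."k" or "NC").
#' @export
assign_with_confidence <- function(run, threshold = 0.80) {
  if (threshold <= 0 || threshold > 1) stop("threshold must lie in (0, 1]")
  lab <- as.character(run$assignments)
  lab[run$confidence < threshold] <- "NC"
  stats::setNames(lab, names(run$assignments))
}

#' Grid search over metagene and cluster counts
#'
#' Evaluates [bootstrap_consensus()] at every combination of metagene and
#' cluster counts and ranks the solutions by cophenetic index (descending),
#' breaking ties by mean confidence and then by the smaller cluster count.
#' The cluster count is allowed to exceed the metagene count.
#'
#' @param V A [probe_matrix] or non-negative matrix.
#' @param metagene_range,cluster_range Integer vectors (defaults 3:10).
#' @param n_iter Resampling iterations per grid cell (default 250).
#' @param seed Optional integer seed.
#' @param ... Further arguments to [bootstrap_consensus()].
#'
#' @return Object of class `grid_result`: a data frame with one row per grid
#'   cell (`k_metagenes`, `k_clusters`, `cophenetic`, `mean_confidence`,
#'   `rank`), ordered by rank, plus attribute `runs` (the `consensus_run`
#'   objects, named "m<k>_c<k>").
#' @export
grid_search <- function(V, metagene_range = 3:10, cluster_range = 3:10,
                        n_iter = 250, seed = NULL, ...) {
  if (!length(metagene_range) || !length(cluster_range)) {
    stop("empty metagene or cluster range")
  }
  if (!is.null(seed)) set.seed(seed)
  grid <- expand.grid(k_metagenes = metagene_range,
                      k_clusters = cluster_range)
  seeds <- sample.int(.Machine$integer.max - 1, nrow(grid))
  runs <- vector("list", nrow(grid))
  res <- grid
  res$cophenetic <- NA_real_
  res$mean_confidence <- NA_real_
  for (i in seq_len(nrow(grid))) {
    run <- bootstrap_consensus(V, grid$k_metagenes[i], grid$k_clusters[i],
                               n_iter = n_iter, seed = seeds[i], ...)
    runs[[i]] <- run
    res$cophenetic[i] <- run$cophenetic
    res$mean_confidence[i] <- mean(run$confidence)
  }
  ord <- order(-ifelse(is.na(res$cophenetic), -Inf, res$cophenetic),
               -res$mean_confidence, res$k_clusters, res$k_metagenes)
  res <- res[ord, ]
  res$rank <- seq_len(nrow(res))
  rownames(res) <- NULL
  names(runs) <- sprintf("m%d_c%d", grid$k_metagenes, grid$k_clusters)
  attr(res, "runs") <- runs[ord]
  class(res) <- c("grid_result", "data.frame")
  res
}
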