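#' Project discovery metagenes onto an independent cohort
#'
#' For each sample of the target cohort, finds the non-negative score vector
#' `h` minimising the least-squares reconstruction error `||v - W h||`
#' against the frozen discovery basis `W` (non-negative least squares,
#' solved per sample). Probe spaces must be harmonised first (see
#' [harmonise_probes()]): `W` and `V` must share identical, ordered probe
#' identifiers.
#'
#' @param W Probes x k non-negative basis from the discovery fit
#'   ([nmf_factorise()]`$W`), columns L2-normalised.
#' @param V A [probe_matrix] (or matrix) of the target cohort, same probes
#'   as `W` in the same order.
#' @param method "nnls" (default) or "pinv_clip" (unconstrained
#'   least squares with negative scores clipped to zero; comparison mode).
#'
#' @return Object of class `projection_result`: `H_projected` (k x samples),
#'   `residuals` (per-sample relative reconstruction error
#'   `||v - W h|| / ||v||`).
#' @export
project_metagenes <- function(W, V, method = c("nnls", "pinv_clip")) {
  method <- match.arg(method)
  V <- as.matrix(unclass(V))
  if (is.null(rownames(W)) || is.null(rownames(V)) ||
      !identical(rownames(W), rownames(V))) {
    stop("W and V must share identical probe identifiers in identical ",
         "order; run harmonise_probes() first")
  }
  if (anyNA(V)) stop("V must not contain missing values")
  k <- ncol(W)
  n <- ncol(V)
  H <- matrix(0, k, n, dimnames = list(colnames(W), colnames(V)))
  if (method == "nnls") {
    for (j in seq_len(n)) {
      H[, j] <- pracma::lsqnonneg(W, V[, j])$x
    }
  } else {
    H[] <- pmax(qr.solve(W, V), 0)
  }
  resid <- sqrt(colSums((V - W %*% H)^2))
  scale <- sqrt(colSums(V^2))
  structure(list(H_projected = H,
                 residuals = stats::setNames(resid / pmax(scale, 1e-300),
                                             colnames(V))),
            class = "projection_result")
}

#' @export
print.projection_result <- function(x, ...) {
  cat(sprintf(
    "projection_result: %d metagenes x %d samples, median residual %.4f\n",
    nrow(x$H_projected), ncol(x$H_projected), stats::median(x$residuals)))
  invisible(x)
}

#' Classify projected samples by nearest discovery centroid
#'
#' Standardises the projected metagene scores using the frozen discovery
#' standardisation (means/SDs of the discovery scores, carried by the
#' discovery [kmeans_metagene_cluster()] fit — nothing is re-estimated from
#' the target cohort) and assigns each sample to the nearest k-means centroid
#' in Euclidean distance. Exact ties go to the lower cluster index and are
#' flagged.
#'
#' @param projection A `projection_result` (or k x samples score matrix).
#' @param centroids A `metagene_kmeans` discovery fit.
#' @param nc_margin Optional non-negative margin: samples whose distance gap
#'   between the nearest and second-nearest centroid falls below it are
#'   labelled "NC".
#'
#' @return Named character vector of cluster labels ("1".."k", or "NC"),
#'   with attributes `margin` (per-sample distance gap) and `ties` (logical).
#' @export
classify_projected <- function(projection, centroids, nc_margin = NULL) {
  H <- if (inherits(projection, "projection_result")) {
    projection$H_projected
  } else {
    projection
  }
  if (nrow(H) != ncol(centroids$centers)) {
    stop("metagene count mismatch between projection and centroids")
  }
  z <- standardise_scores(H, centroids$scale_means, centroids$scale_sds)$scores
  cen <- centroids$centers
  # squared distances samples x centroids
  d2 <- outer(colSums(z^2), rowSums(cen^2), "+") - 2 * t(z) %*% t(cen)
  d2 <- pmax(d2, 0)
  nearest <- apply(d2, 1, which.min)  # ties -> lower index
  sorted <- t(apply(sqrt(d2), 1, sort))
  margin <- sorted[, 2] - sorted[, 1]
  ties <- margin == 0
  if (any(ties)) warning(sum(ties), " sample(s) equidistant to two centroids")
  lab <- as.character(nearest)
  if (!is.null(nc_margin)) lab[margin < nc_margin] <- "NC"
  structure(stats::setNames(lab, colnames(H)),
            margin = stats::setNames(margin, colnames(H)),
            ties = stats::setNames(ties, colnames(H)))
}

#' Concordance between two classifications
#'
#' Percentage of samples receiving the same label in two classifications of
#' the same cohort, after optimal label matching ([match_labels()]).
#' Non-classifiable samples are excluded by default.
#'
#' @param a,b Label vectors over the same samples (aligned by name when both
#'   are named).
#' @param exclude_nc Drop samples labelled "NC" (or `NA`) in either vector
#'   before comparing (default `TRUE`).
#' @param match Apply optimal label matching before comparing (default
#'   `TRUE`); set `FALSE` when the two vectors already share a label scheme.
#' @return Concordance percentage in \[0, 100\].
#' @export
concordance <- function(a, b, exclude_nc = TRUE, match = TRUE) {
  if (!is.null(names(a)) && !is.null(names(b))) {
    common <- intersect(names(a), names(b))
    if (!length(common)) stop("disjoint sample sets")
    a <- a[common]
    b <- b[common]
  }
  if (length(a) != length(b)) stop("label vectors differ in length")
  a <- as.character(a)
  b <- as.character(b)
  if (exclude_nc) {
    keep <- !(is.na(a) | is.na(b) | a == "NC" | b == "NC")
    a <- a[keep]
    b <- b[keep]
  }
  if (!length(a)) stop("no comparable samples remain")
  if (match) match_labels(a, b)$agreement else 100 * mean(a == b)
}
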