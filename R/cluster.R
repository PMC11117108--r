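#' k-means over coordinate vectors
#'
#' Lloyd's algorithm with random restarts over the pooled (all
#' subjects' voxels) coordinate vectors; the best solution by
#' within-cluster sum of squares is kept. Deterministic for a fixed
#' seed. No scaling of the coordinate dimensions is applied: cluster
#' centers stay on the coordinate scale.
#'
#' @param vectors \code{N x D} numeric matrix of coordinate vectors
#'   (rows with \code{NA} are not allowed; drop degenerate voxels
#'   first).
#' @param k number of clusters, \code{1 <= k <= N}.
#' @param n_restarts random restarts (default 20).
#' @param seed optional integer seed.
#' @return an object of class \code{"cluster_solution"}: list with
#'   \code{k}, \code{centers} (\code{k x D}), \code{labels} (integers
#'   in \code{1..k}), \code{inertia} (total within-cluster sum of
#'   squares) and \code{aic}.
#' @export
fit_kmeans <- function(vectors, k, n_restarts = 20L, seed = NULL) {
  vectors <- as.matrix(vectors)
  N <- nrow(vectors); D <- ncol(vectors)
  if (anyNA(vectors)) stop("'vectors' contains NA rows")
  if (k < 1L || k > N) stop("'k' must be between 1 and nrow(vectors)")
  if (!is.null(seed)) set.seed(seed)
  km <- if (k == 1L) {
    ctr <- matrix(colMeans(vectors), 1, D)
    list(centers = ctr, cluster = rep(1L, N),
         tot.withinss = sum(sweep(vectors, 2, ctr)^2))
  } else {
    # Lloyd warns when a restart produces an empty cluster; best-of-
    # restarts makes those runs harmless, so the warning is muffled.
    withCallingHandlers(
      stats::kmeans(vectors, centers = k, nstart = n_restarts,
                    iter.max = 100L, algorithm = "Lloyd"),
      warning = function(w) {
        if (grepl("empty cluster", conditionMessage(w)))
          invokeRestart("muffleWarning")
      })
  }
  sol <- list(k = as.integer(k), centers = km$centers,
              labels = as.integer(km$cluster),
              inertia = km$tot.withinss)
  sol$aic <- kmeans_aic(sol$inertia, N = N, D = D, k = k)
  class(sol) <- "cluster_solution"
  sol
}

#' @export
print.cluster_solution <- function(x, ...) {
  cat(sprintf("k-means solution: k = %d, inertia = %.4g, AIC = %.4g\n",
              x$k, x$inertia, x$aic))
  invisible(x)
}

#' AIC of a k-means solution
#'
#' Spherical-Gaussian form:
#' \deqn{AIC = N D \log(W / (N D)) + 2 k D,}
#' where \eqn{W} is the within-cluster sum of squares over \eqn{N}
#' points in \eqn{D} dimensions. Any monotone-equivalent variant shifts
#' the curve without moving the elbow on well-separated data.
#'
#' @param inertia within-cluster sum of squares (or a
#'   \code{cluster_solution}, from which \code{inertia} and \code{k}
#'   are taken).
#' @param N,D number of points and dimensions.
#' @param k number of clusters.
#' @return the AIC value.
#' @export
kmeans_aic <- function(inertia, N, D, k) {
  if (inherits(inertia, "cluster_solution")) {
    k <- inertia$k
    inertia <- inertia$inertia
  }
  N * D * log(inertia / (N * D)) + 2 * k * D
}

#' Scan cluster counts and pick the AIC elbow
#'
#' Fits k-means for each \code{k} in \code{k_range}, computes the AIC
#' curve, and selects the elbow — the interior \code{k} at which adding
#' clusters stops substantially decreasing the AIC.
#'
#' @inheritParams fit_kmeans
#' @param k_range integer vector of cluster counts (default
#'   \code{1:10}).
#' @return a list with \code{aic} (named by k), \code{k_best} (elbow
#'   choice), and \code{solutions} (one \code{cluster_solution} per
#'   k).
#' @export
cluster_scan <- function(vectors, k_range = 1:10, n_restarts = 20L,
                         seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sols <- lapply(k_range, function(k)
    fit_kmeans(vectors, k, n_restarts = n_restarts))
  aic <- vapply(sols, `[[`, numeric(1), "aic")
  names(aic) <- k_range
  list(aic = aic, k_best = elbow_select(aic), solutions = sols)
}

#' Elbow selection on an AIC curve
#'
#' Returns the interior \code{k} maximizing the discrete second
#' difference \eqn{AIC(k-1) - 2 AIC(k) + AIC(k+1)} — the point where
#' the decrease in AIC flattens most sharply. Ties go to the smallest
#' \code{k}; a strictly linear curve therefore yields the smallest
#' interior \code{k}.
#'
#' @param aic_by_k numeric vector of AIC values, named by the
#'   (consecutive) k values they belong to; at least 3 entries.
#' @return the selected integer k.
#' @export
elbow_select <- function(aic_by_k) {
  if (length(aic_by_k) < 3L)
    stop("need AIC values for at least 3 cluster counts")
  ks <- as.integer(names(aic_by_k))
  if (is.null(names(aic_by_k)) || anyNA(ks))
    ks <- seq_along(aic_by_k)
  m <- length(aic_by_k)
  curv <- aic_by_k[1:(m - 2)] - 2 * aic_by_k[2:(m - 1)] + aic_by_k[3:m]
  ks[1L + which.max(curv)]
}

#' Consensus cluster map across subjects
#'
#' Given per-subject voxel labels from one pooled clustering (labels
#' comparable across subjects by construction), returns each voxel's
#' modal label and the fraction of subjects agreeing with the mode —
#' the saturation channel of a consensus visualization. Modal ties go
#' to the lowest label and are flagged.
#'
#' @param labels \code{S x V} integer matrix (subjects by voxels),
#'   values in \code{1..k}.
#' @param k number of clusters.
#' @return a list with \code{mode} (length-\code{V} integer),
#'   \code{agreement} (length-\code{V} in \eqn{[0, 1]}) and \code{tie}
#'   (logical per voxel).
#' @export
consensus_map <- function(labels, k) {
  labels <- as.matrix(labels)
  S <- nrow(labels)
  counts <- apply(labels, 2L, function(col) tabulate(col, nbins = k))
  counts <- matrix(counts, nrow = k)
  mode_lab <- apply(counts, 2L, which.max)     # lowest index on ties
  best <- counts[cbind(mode_lab, seq_len(ncol(counts)))]
  tie <- colSums(counts == matrix(best, k, ncol(counts), byrow = TRUE)) > 1L
  list(mode = as.integer(mode_lab), agreement = best / S, tie = tie)
}

#' Adjusted Rand index
#'
#' Agreement between two labelings, corrected for chance; 1 is perfect
#' recovery, 0 is chance level.
#'
#' @param a,b integer label vectors of equal length.
#' @return the adjusted Rand index.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("label vectors must have equal length")
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(length(a))
  expected <- sum_a * sum_b / n2
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}
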