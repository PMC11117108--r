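#' Generate a synthetic seed--target pair
#'
#' Draws a standard normal seed series \eqn{x_t \sim N(0, 1)} and builds
#' the target as \eqn{y_t = f(x_t) + \epsilon_t} with
#' \eqn{\epsilon_t \sim N(0, \sigma^2)}, where \eqn{f} is either an
#' unweighted sum of normalized Hermite basis functions (the parameter
#' recovery scenarios) or one of the raw symmetric dependencies
#' \code{const1} (\eqn{y = 1}), \code{square} (\eqn{y = x^2}) or
#' \code{quartic} (\eqn{y = x^4}) used to demonstrate U-shaped relations
#' that Pearson correlation cannot see.
#'
#' @param n number of paired samples.
#' @param orders integer vector of basis orders (0-based) summed with
#'   unit weights; mutually exclusive with \code{fun}.
#' @param fun one of \code{"const1"}, \code{"square"}, \code{"quartic"};
#'   mutually exclusive with \code{orders}.
#' @param noise_sd standard deviation \eqn{\sigma \ge 0} of the additive
#'   Gaussian noise (default 0).
#' @param order,convention basis truncation and normalization used when
#'   \code{orders} is given (see \code{\link{basis_spec}}).
#' @param seed optional integer seed; identical arguments and seed give
#'   bit-identical output.
#' @return a data frame with columns \code{t}, \code{x}, \code{y};
#'   the generating scenario is attached as attribute
#'   \code{"scenario"}.
#' @examples
#' d <- sim_pair(1000, orders = 2, seed = 1)
#' coef(funcoord(d$x, d$y))  # ~one-hot on order 2
#' @export
sim_pair <- function(n, orders = NULL, fun = NULL, noise_sd = 0,
                     order = 5L, convention = c("simulation", "unit"),
                     seed = NULL) {
  convention <- match.arg(convention)
  if (!is.null(orders) && !is.null(fun))
    stop("give either 'orders' or 'fun', not both")
  if (is.null(orders) && is.null(fun))
    stop("one of 'orders' or 'fun' is required")
  if (n < 2L) stop("'n' must be >= 2")
  if (noise_sd < 0) stop("'noise_sd' must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  x <- stats::rnorm(n)
  f <- if (!is.null(orders)) {
    if (any(orders < 0) || any(orders != round(orders)))
      stop("'orders' must be non-negative integers")
    k <- hermite_norm_const(orders, convention)
    Reduce(`+`, lapply(seq_along(orders),
                       function(i) hermite_poly(x, orders[i]) / k[i]))
  } else {
    fun <- match.arg(fun, c("const1", "square", "quartic"))
    switch(fun, const1 = rep(1, n), square = x^2, quartic = x^4)
  }
  y <- f + if (noise_sd > 0) stats::rnorm(n, 0, noise_sd) else 0
  out <- data.frame(t = seq_len(n), x = x, y = y)
  attr(out, "scenario") <- list(n = n, orders = orders, fun = fun,
                                noise_sd = noise_sd, order = order,
                                convention = convention, seed = seed)
  out
}

#' Generate a planted-cluster synthetic volume
#'
#' Builds a fixture for the clustering and inference stages: one shared
#' seed series \eqn{x_t} and, for each of \code{k} clusters with known
#' coordinate-vector centers, \code{voxels_per_cluster} target series
#' \eqn{y_t = \sum_j c_j h_j(x_t) + \epsilon_t}. Ground-truth labels are
#' returned so that recovery (e.g. adjusted Rand index, AIC elbow
#' position) can be scored.
#'
#' @param centers \code{k x K} numeric matrix of generating coordinate
#'   vectors (rows must be distinct; duplicated rows trigger a warning
#'   since recovery is then not identifiable).
#' @param voxels_per_cluster voxels generated per center (may be 0).
#' @param n_time length \eqn{T} of the shared seed series.
#' @param noise_sd additive Gaussian noise SD per voxel series.
#' @param convention basis normalization for the generating functions.
#' @param seed optional integer seed.
#' @return a list with \code{x} (length-\code{n_time} seed),
#'   \code{y} (\code{V x n_time} matrix, \code{V = k *
#'   voxels_per_cluster}), \code{labels} (length-\code{V} integers in
#'   \code{1..k}) and \code{centers}.
#' @export
sim_clustered_maps <- function(centers, voxels_per_cluster, n_time,
                               noise_sd = 0.2,
                               convention = c("simulation", "unit"),
                               seed = NULL) {
  convention <- match.arg(convention)
  centers <- as.matrix(centers)
  k <- nrow(centers)
  if (k < 1L) stop("need at least one cluster center")
  if (anyDuplicated(centers))
    warning("duplicate cluster centers: label recovery is not guaranteed")
  if (!is.null(seed)) set.seed(seed)
  x <- stats::rnorm(n_time)
  V <- k * voxels_per_cluster
  B <- hermite_basis(x, basis_spec(ncol(centers), convention))
  labels <- rep(seq_len(k), each = voxels_per_cluster)
  y <- matrix(0, nrow = V, ncol = n_time)
  if (V > 0) {
    clean <- tcrossprod(centers, B)          # k x T
    y <- clean[labels, , drop = FALSE] +
      matrix(stats::rnorm(V * n_time, 0, noise_sd), V, n_time)
  }
  list(x = x, y = y, labels = labels, centers = centers)
}
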