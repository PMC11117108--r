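# 26-connectivity component labelling of a sparse voxel set.
# idx: linear indices into an array of dimension dims. Returns an
# integer component label per element of idx.
label_components_26 <- function(idx, dims) {
  n <- length(idx)
  if (n == 0L) return(integer(0))
  pos <- array(0L, dims)
  pos[idx] <- seq_len(n)
  coords <- arrayInd(idx, dims)
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  off <- off[rowSums(abs(off)) > 0L, , drop = FALSE]   # 26 neighbours
  labels <- integer(n)
  comp <- 0L
  for (i in seq_len(n)) {
    if (labels[i] > 0L) next
    comp <- comp + 1L
    stack <- i
    labels[i] <- comp
    while (length(stack)) {
      cur <- stack[length(stack)]
      stack <- stack[-length(stack)]
      nb <- off + matrix(coords[cur, ], nrow(off), 3, byrow = TRUE)
      ok <- nb[, 1] >= 1L & nb[, 1] <= dims[1] &
        nb[, 2] >= 1L & nb[, 2] <= dims[2] &
        nb[, 3] >= 1L & nb[, 3] <= dims[3]
      ids <- pos[nb[ok, , drop = FALSE]]
      ids <- ids[ids > 0L]
      new <- ids[labels[ids] == 0L]
      if (length(new)) {
        labels[new] <- comp
        stack <- c(stack, new)
      }
    }
  }
  labels
}

# Separable 3-D Gaussian smoothing with edge renormalization.
# sigma_vox: per-axis kernel SD in voxel units.
smooth3d <- function(arr, sigma_vox) {
  d <- dim(arr)
  out <- arr
  norm <- array(1, d)
  for (ax in 1:3) {
    s <- sigma_vox[ax]
    if (s <= 0) next
    half <- max(1L, ceiling(3 * s))
    kern <- stats::dnorm(-half:half, sd = s)
    conv_axis <- function(a) {
      perm <- c(ax, setdiff(1:3, ax))
      ap <- aperm(a, perm)
      m <- matrix(ap, d[ax])
      padded <- rbind(matrix(0, half, ncol(m)), m, matrix(0, half, ncol(m)))
      res <- vapply(seq_len(d[ax]), function(i)
        colSums(padded[i:(i + 2L * half), , drop = FALSE] * kern),
        numeric(ncol(m)))
      ap[] <- t(res)
      aperm(ap, order(perm))
    }
    out <- conv_axis(out)
    norm <- conv_axis(norm)
  }
  out / norm
}

#' Sign-flip permutation test with cluster-level FWE correction
#'
#' Across-subject one-tailed inference on a voxelwise loading map. The
#' voxel statistic is a pseudo-t: the across-subject mean divided by
#' its standard error, where the variance map may be spatially smoothed
#' with a Gaussian of given FWHM (FWHM 0 gives the ordinary one-sample
#' t). The null distribution is built by randomly flipping the sign of
#' whole subject maps — valid under symmetry of the per-subject maps
#' about zero. When \code{2^S <= n_permutations} the flips are fully
#' enumerated, otherwise Monte-Carlo sampled with the identity flip
#' always included. Suprathreshold voxels (statistic above the
#' cluster-forming threshold) are grouped into 26-connected components,
#' and each observed cluster's family-wise-error p-value is the
#' proportion of permutations whose maximum cluster size reaches its
#' size.
#'
#' @param maps \code{S x V} matrix: one loading map per subject over
#'   the mask voxels.
#' @param mask 3-D logical array with \code{V} \code{TRUE} entries,
#'   giving each map column a grid position.
#' @param tail \code{"positive"} or \code{"negative"} (the map is
#'   negated, so the test is always run in the upper tail).
#' @param cluster_forming_p voxel-level tail probability defining the
#'   cluster-forming threshold, in \eqn{(0, 0.5)}; default
#'   \code{1e-4}.
#' @param n_permutations permutations including the identity (default
#'   5000).
#' @param variance_smooth_fwhm_mm FWHM of the variance-map smoothing
#'   kernel in mm (default 0 = no smoothing).
#' @param voxel_size_mm voxel edge lengths in mm (for the smoothing
#'   kernel).
#' @param threshold_type \code{"permutation"} (default): the threshold
#'   is the \code{1 - cluster_forming_p} quantile of the pooled
#'   permutation statistics, keeping the procedure fully
#'   nonparametric; \code{"parametric"}: the Student-t quantile with
#'   \code{S - 1} degrees of freedom.
#' @param seed optional integer seed for the Monte-Carlo flips.
#' @return an object of class \code{"perm_result"}: list with
#'   \code{pseudo_t} (length \code{V}), \code{threshold},
#'   \code{cluster_table} (data frame: \code{id}, \code{size},
#'   \code{mass} = sum of suprathreshold statistics, \code{p_fwe}),
#'   \code{cluster_labels} (length \code{V}, 0 = subthreshold),
#'   \code{max_null_sizes}, and the test settings.
#' @export
signflip_cluster_test <- function(maps, mask,
                                  tail = c("positive", "negative"),
                                  cluster_forming_p = 1e-4,
                                  n_permutations = 5000L,
                                  variance_smooth_fwhm_mm = 0,
                                  voxel_size_mm = c(1, 1, 1),
                                  threshold_type = c("permutation",
                                                     "parametric"),
                                  seed = NULL) {
  tail <- match.arg(tail)
  threshold_type <- match.arg(threshold_type)
  maps <- as.matrix(maps)
  S <- nrow(maps); V <- ncol(maps)
  if (S < 2L) stop("need at least 2 subject maps")
  if (sum(mask) != V)
    stop("mask voxel count does not match the number of map columns")
  if (any(!is.finite(maps))) stop("non-finite values in 'maps'")
  if (cluster_forming_p <= 0 || cluster_forming_p >= 0.5)
    stop("'cluster_forming_p' must lie in (0, 0.5)")
  if (tail == "negative") maps <- -maps
  if (!is.null(seed)) set.seed(seed)

  full <- 2^S <= n_permutations
  flips <- if (full) {
    F <- as.matrix(expand.grid(rep(list(c(1, -1)), S)))
    id <- which(rowSums(F == 1) == S)   # identity flip goes first
    rbind(F[id, , drop = FALSE], F[-id, , drop = FALSE])
  } else {
    rbind(rep(1, S),
          matrix(sample(c(1, -1), (n_permutations - 1L) * S, replace = TRUE),
                 n_permutations - 1L, S))
  }
  P <- nrow(flips)

  ssq <- colSums(maps^2)                      # invariant under sign flips
  mean_mat <- (flips %*% maps) / S            # P x V
  var_mat <- (matrix(ssq, P, V, byrow = TRUE) - S * mean_mat^2) / (S - 1)
  var_mat[var_mat < 0] <- 0
  mask_idx <- which(mask)
  if (variance_smooth_fwhm_mm > 0) {
    sig <- (variance_smooth_fwhm_mm / 2.35482) / voxel_size_mm
    vol <- array(0, dim(mask))
    for (p in seq_len(P)) {
      vol[] <- 0; vol[mask_idx] <- var_mat[p, ]
      sm <- smooth3d(vol, sig)
      var_mat[p, ] <- sm[mask_idx]
    }
  }
  tstat <- mean_mat / sqrt(var_mat / S)
  tstat[!is.finite(tstat)] <- 0

  thr <- if (threshold_type == "permutation") {
    stats::quantile(tstat, 1 - cluster_forming_p, names = FALSE)
  } else {
    stats::qt(1 - cluster_forming_p, df = S - 1)
  }

  max_sizes <- numeric(P)
  obs <- NULL
  for (p in seq_len(P)) {
    supra <- which(tstat[p, ] > thr)
    if (length(supra) == 0L) { max_sizes[p] <- 0; next }
    lab <- label_components_26(mask_idx[supra], dim(mask))
    sizes <- tabulate(lab)
    max_sizes[p] <- max(sizes)
    if (p == 1L) obs <- list(supra = supra, lab = lab, sizes = sizes)
  }

  cluster_labels <- integer(V)
  tab <- data.frame(id = integer(0), size = integer(0),
                    mass = numeric(0), p_fwe = numeric(0))
  if (!is.null(obs)) {
    ord <- order(-obs$sizes)
    for (j in seq_along(ord)) {
      cl <- ord[j]
      vox <- obs$supra[obs$lab == cl]
      cluster_labels[vox] <- j
      tab <- rbind(tab, data.frame(
        id = j, size = obs$sizes[cl],
        mass = sum(tstat[1L, vox]),
        p_fwe = mean(max_sizes >= obs$sizes[cl])))
    }
  }
  structure(list(pseudo_t = tstat[1L, ], threshold = thr,
                 cluster_table = tab, cluster_labels = cluster_labels,
                 max_null_sizes = max_sizes,
                 n_permutations = P, full_enumeration = full,
                 tail = tail, cluster_forming_p = cluster_forming_p,
                 variance_smooth_fwhm_mm = variance_smooth_fwhm_mm,
                 threshold_type = threshold_type),
            class = "perm_result")
}

#' @export
print.perm_result <- function(x, ...) {
  cat(sprintf(
    "Sign-flip cluster test: %d permutations (%s), %s tail\n",
    x$n_permutations,
    if (x$full_enumeration) "full enumeration" else "Monte-Carlo",
    x$tail))
  cat(sprintf("cluster-forming p = %g (threshold %.3f, %s)\n",
              x$cluster_forming_p, x$threshold, x$threshold_type))
  if (nrow(x$cluster_table) == 0L) cat("No suprathreshold clusters.\n")
  else print(x$cluster_table, row.names = FALSE)
  invisible(x)
}

#' Regress linear loadings out of nonlinear loading maps
#'
#' For each subject, replaces every non-linear-order loading map by its
#' residual after an across-voxel ordinary least-squares regression on
#' the linear (order-1) loading map plus an intercept. The result
#' isolates nonlinear spatial structure decoupled from the linear
#' connectivity pattern, for downstream
#' \code{\link{signflip_cluster_test}}.
#'
#' @param coord_maps \code{S x V x D} array of per-subject coordinate
#'   maps (orders \code{0..D-1} along the third axis).
#' @param linear_order the order treated as linear (default 1).
#' @return an array of the same shape; the linear order's maps are
#'   returned unchanged.
#' @export
regress_out_linear <- function(coord_maps, linear_order = 1L) {
  d <- dim(coord_maps)
  if (length(d) != 3L) stop("'coord_maps' must be an S x V x D array")
  if (d[3] < 2L) stop("need at least 2 orders")
  lin_col <- linear_order + 1L
  out <- coord_maps
  for (s in seq_len(d[1])) {
    lin <- coord_maps[s, , lin_col]
    if (stats::sd(lin) == 0)
      stop("constant linear loading map for subject ", s)
    X <- cbind(1, lin)
    qrX <- qr(X)
    for (j in setdiff(seq_len(d[3]), lin_col))
      out[s, , j] <- qr.resid(qrX, coord_maps[s, , j])
  }
  out
}

#' Split-run order selection and confirmatory testing
#'
#' Uses one run to pick the basis orders worth testing and independent
#' data to test them, reducing the multiple-comparison burden: orders
#' whose run-1 across-subject mean loading differs from zero at level
#' \code{alpha} (two-sided one-sample t on the per-subject,
#' voxel-averaged loadings) are selected, then tested on run 2 with
#' Bonferroni correction within the selected set only.
#'
#' @param run1_maps,run2_maps \code{S x V x D} arrays (or \code{S x D}
#'   matrices of already voxel-averaged loadings) from two independent
#'   runs.
#' @param alpha selection level (default 0.05); \code{alpha = 1}
#'   selects every order.
#' @return a list with \code{selected} (0-based orders), \code{p_run1},
#'   \code{p_run2} (NA for unselected orders),
#'   \code{p_run2_bonferroni}, and \code{significant} (selected orders
#'   with adjusted run-2 p below \code{alpha}).
#' @export
split_run_selection <- function(run1_maps, run2_maps, alpha = 0.05) {
  collapse <- function(a) {
    if (length(dim(a)) == 3L) apply(a, c(1, 3), mean)
    else as.matrix(a)
  }
  m1 <- collapse(run1_maps); m2 <- collapse(run2_maps)
  if (!all(dim(m1) == dim(m2)))
    stop("run 1 and run 2 must have matching subjects and orders")
  D <- ncol(m1)
  p1 <- vapply(seq_len(D), function(j)
    stats::t.test(m1[, j])$p.value, numeric(1))
  selected <- which(p1 <= alpha)
  p2 <- rep(NA_real_, D)
  p2[selected] <- vapply(selected, function(j)
    stats::t.test(m2[, j])$p.value, numeric(1))
  p2_adj <- pmin(p2 * length(selected), 1)
  list(selected = selected - 1L,
       p_run1 = p1, p_run2 = p2, p_run2_bonferroni = p2_adj,
       significant = (selected - 1L)[!is.na(p2_adj[selected]) &
                                       p2_adj[selected] <= alpha])
}
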