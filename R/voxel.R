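#' CompCor-style nuisance removal
#'
#' Removes anatomically defined noise from voxel time series by
#' regressing out the leading principal-component time courses of a
#' noise compartment (typically white matter plus CSF): each noise
#' voxel's series is centered, the top \code{n_components} PC time
#' courses are extracted, and each data voxel's series is replaced by
#' its residual after ordinary least squares on those components plus
#' an intercept.
#'
#' @param data \code{V x T} matrix of voxel time series (rows are
#'   voxels).
#' @param noise_data \code{W x T} matrix of noise-compartment series.
#' @param n_components number of principal components to remove
#'   (default 5). If the noise series have lower rank, the count is
#'   reduced with a warning.
#' @return the \code{V x T} residual matrix.
#' @export
compcor_denoise <- function(data, noise_data, n_components = 5L) {
  data <- as.matrix(data); noise_data <- as.matrix(noise_data)
  Tn <- ncol(data)
  if (ncol(noise_data) != Tn)
    stop("'data' and 'noise_data' must have the same number of time points")
  if (Tn <= n_components)
    stop("need more time points than components")
  pc <- stats::prcomp(t(noise_data), center = TRUE, scale. = FALSE)
  avail <- sum(pc$sdev > max(pc$sdev) * 1e-10)
  if (avail < n_components) {
    warning(sprintf("noise series support only %d components (requested %d)",
                    avail, n_components))
    n_components <- avail
  }
  X <- cbind(1, pc$x[, seq_len(n_components), drop = FALSE])
  qrX <- qr(X)
  # residuals of each voxel (rows) on the component design
  t(qr.resid(qrX, t(data)))
}

#' Select a seed region of interest around a statistic peak
#'
#' Locates the peak of a statistic map within a mask, collects all mask
#' voxels whose center lies within \code{radius_mm} of the peak voxel's
#' center (Euclidean distance in millimeters through the affine,
#' inclusive boundary) and keeps the \code{n_voxels} with the largest
#' statistic. Ties at the cutoff are broken by ascending linear voxel
#' index, so the selection is deterministic.
#'
#' @param stat_map 3-D numeric array of voxelwise statistics.
#' @param mask 3-D logical array, same dimensions; the analysis mask.
#' @param affine \code{4 x 4} voxel-to-mm transform (NIfTI convention,
#'   0-based voxel indices). Default: identity scaled by
#'   \code{voxel_size_mm}.
#' @param voxel_size_mm voxel edge lengths used when no affine is
#'   given.
#' @param radius_mm sphere radius (default 9).
#' @param n_voxels number of voxels to keep (default 80); if fewer lie
#'   in the sphere, all are returned with a warning.
#' @return integer vector of linear voxel indices into the arrays.
#' @export
define_seed_roi <- function(stat_map, mask, affine = NULL,
                            voxel_size_mm = c(1, 1, 1),
                            radius_mm = 9, n_voxels = 80L) {
  if (!any(mask)) stop("empty mask")
  if (!all(dim(stat_map) == dim(mask)))
    stop("'stat_map' and 'mask' dimensions differ")
  if (is.null(affine))
    affine <- diag(c(voxel_size_mm, 1))
  idx <- which(mask)
  stat <- stat_map[idx]
  if (any(!is.finite(stat))) stop("non-finite statistic inside mask")
  peak <- idx[which.max(stat)]
  ijk <- arrayInd(idx, dim(mask)) - 1L          # 0-based voxel coords
  mm <- ijk %*% t(affine[1:3, 1:3]) +
    matrix(affine[1:3, 4], length(idx), 3, byrow = TRUE)
  peak_mm <- mm[which.max(stat), ]
  d <- sqrt(rowSums((mm - matrix(peak_mm, length(idx), 3, byrow = TRUE))^2))
  in_sphere <- which(d <= radius_mm)
  if (length(in_sphere) < n_voxels) {
    warning(sprintf("sphere contains only %d voxels (requested %d)",
                    length(in_sphere), n_voxels))
    sel <- in_sphere
  } else {
    # largest statistic first; ties by ascending linear index
    ord <- order(-stat[in_sphere], idx[in_sphere])
    sel <- in_sphere[ord[seq_len(n_voxels)]]
  }
  sort(idx[sel])
}

#' Mean time course of a region of interest
#'
#' @param data \code{V x T} matrix of masked voxel series.
#' @param roi integer vector of row indices into \code{data}.
#' @return length-\code{T} numeric vector, the across-voxel mean at
#'   each time point.
#' @export
seed_mean <- function(data, roi) {
  if (length(roi) == 0L) stop("'roi' is empty")
  if (any(roi < 1L) || any(roi > nrow(data)))
    stop("'roi' indices outside the data rows")
  colMeans(data[roi, , drop = FALSE])
}

#' Per-voxel functional coordinate map
#'
#' Applies the coordinate estimator to every voxel: the seed series and
#' each voxel series are z-scored, then the per-basis estimator is run
#' with the seed as predictor. Voxels with zero variance cannot be
#' z-scored; they are flagged (row of \code{NA}) rather than dropped,
#' and their count is reported via a message.
#'
#' @param seed_ts length-\code{T} seed series.
#' @param data \code{V x T} matrix of voxel series.
#' @param order,convention basis truncation and normalization.
#' @param standardize z-score seed and voxel series first? Default
#'   \code{TRUE} (the imaging-pipeline convention).
#' @return an object of class \code{"funcoord_map"}: a \code{V x K}
#'   coefficient matrix with attributes \code{degenerate} (logical per
#'   voxel), \code{order}, \code{convention}, \code{n}.
#' @export
map_coordinates <- function(seed_ts, data, order = 5L,
                            convention = c("simulation", "unit"),
                            standardize = TRUE) {
  convention <- match.arg(convention)
  data <- as.matrix(data)
  if (ncol(data) != length(seed_ts))
    stop("time dimension mismatch between 'seed_ts' and 'data'")
  x <- if (standardize) zscore(seed_ts) else seed_ts
  B <- hermite_basis(x, basis_spec(order, convention))
  cs2 <- colSums(B^2)
  sds <- sqrt(rowMeans((data - rowMeans(data))^2))
  degen <- sds == 0
  if (all(degen)) stop("all voxel series are constant")
  if (any(degen))
    message(sum(degen), " degenerate (constant) voxel(s) flagged")
  Y <- data
  if (standardize)
    Y[!degen, ] <- (data[!degen, , drop = FALSE] -
                      rowMeans(data[!degen, , drop = FALSE])) / sds[!degen]
  co <- (Y %*% B) / matrix(cs2, nrow(data), order, byrow = TRUE)
  co[degen, ] <- NA_real_
  colnames(co) <- paste0("c", 0:(order - 1L))
  structure(co, degenerate = degen, order = as.integer(order),
            convention = convention, n = length(seed_ts),
            class = c("funcoord_map", "matrix", "array"))
}

#' @export
print.funcoord_map <- function(x, ...) {
  cat(sprintf(
    "Coordinate map: %d voxels x %d orders (convention '%s', T = %d, %d degenerate)\n",
    nrow(x), ncol(x), attr(x, "convention"), attr(x, "n"),
    sum(attr(x, "degenerate"))))
  invisible(x)
}

#' Seed-to-voxel functional connectivity map
#'
#' Pearson correlation of the seed series with every voxel series —
#' the linear map the coordinate analysis generalizes. Constant voxels
#' yield \code{NA}.
#'
#' @inheritParams map_coordinates
#' @return length-\code{V} numeric vector of correlations.
#' @export
fc_map <- function(seed_ts, data) {
  data <- as.matrix(data)
  if (ncol(data) != length(seed_ts))
    stop("time dimension mismatch between 'seed_ts' and 'data'")
  suppressWarnings(drop(stats::cor(seed_ts, t(data))))
}

#' Read and mask a 4-D NIfTI volume
#'
#' Loads a 4-D functional image and returns the \code{V x T} matrix of
#' series for the voxels inside a mask, plus the grid metadata needed
#' to write results back out.
#'
#' @param file path to a NIfTI-1 image (.nii or .nii.gz).
#' @param mask_file optional path to a 3-D mask image (non-zero =
#'   inside); default: all voxels.
#' @return a list with \code{data} (\code{V x T} matrix), \code{mask}
#'   (3-D logical array), \code{affine} (4x4), and \code{reference}
#'   (the image header, for round-tripping).
#' @export
read_masked_series <- function(file, mask_file = NULL) {
  img <- RNifti::readNifti(file)
  d <- dim(img)
  if (length(d) != 4L) stop("expected a 4-D image")
  mask <- if (is.null(mask_file)) {
    array(TRUE, d[1:3])
  } else {
    m <- RNifti::readNifti(mask_file)
    if (!all(dim(m)[1:3] == d[1:3])) stop("mask dimensions differ from data")
    array(as.array(m) != 0, d[1:3])
  }
  mat <- matrix(img, prod(d[1:3]), d[4])[which(mask), , drop = FALSE]
  list(data = mat, mask = mask,
       affine = structure(RNifti::xform(img), class = NULL),
       reference = img)
}

#' Write masked voxel values as a NIfTI volume
#'
#' Scatters per-voxel values (a vector, or a \code{V x K} matrix such
#' as a \code{\link{map_coordinates}} result, written as a 4-D stack
#' with order along the fourth axis) back into mask positions, zero
#' elsewhere.
#'
#' @param values length-\code{V} vector or \code{V x K} matrix.
#' @param mask 3-D logical array with \code{V} \code{TRUE} voxels.
#' @param file output path (.nii or .nii.gz).
#' @param reference optional NIfTI image to copy the header/affine
#'   from.
#' @return \code{file}, invisibly.
#' @export
write_masked_volume <- function(values, mask, file, reference = NULL) {
  values <- as.matrix(values)
  if (nrow(values) != sum(mask))
    stop("row count of 'values' must equal the mask voxel count")
  K <- ncol(values)
  arr <- array(0, c(dim(mask), K))
  flat <- matrix(0, length(mask), K)
  flat[which(mask), ] <- values
  arr[] <- flat
  if (K == 1L) arr <- array(arr, dim(mask))
  img <- if (is.null(reference)) RNifti::asNifti(arr)
  else RNifti::asNifti(arr, reference = reference)
  RNifti::writeNifti(img, file)
  invisible(file)
}
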