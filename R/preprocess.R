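#' Gaussian smoothing of a 3D volume
#'
#' Separable Gaussian filter applied along each axis with reflect padding.
#' The `diameter` is interpreted as the full width at half maximum of the
#' kernel in voxel units (the standard neuroimaging smoothing parameter), so
#' `sigma = diameter / (2 * sqrt(2 * log(2)))`. The kernel is truncated at
#' 4 sigma and normalized to unit sum, so constant volumes are preserved and
#' total intensity is conserved up to boundary truncation.
#'
#' @param v 3D numeric array.
#' @param diameter Kernel FWHM in voxels; must be positive.
#' @return Smoothed array, same shape as `v`.
#' @export
smooth_volume <- function(v, diameter = 3) {
  if (!is.array(v) || length(dim(v)) != 3) stop("v must be a 3D array")
  if (!is.numeric(diameter) || diameter <= 0) stop("diameter must be > 0")
  sigma <- diameter / (2 * sqrt(2 * log(2)))
  r <- max(1L, ceiling(4 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k <- k / sum(k)
  out <- v
  for (axis in 1:3) out <- convolve_axis(out, k, axis)
  out
}

# 1D convolution along one axis of a 3D array, reflect padding,
# kernel length 2r+1 centered.
convolve_axis <- function(v, k, axis) {
  d <- dim(v)
  r <- (length(k) - 1L) / 2L
  n <- d[axis]
  # reflect indices: (r .. 1 | 1 .. n | n .. n-r+1), clipped for tiny axes
  idx <- c(rev(seq_len(min(r, n))), seq_len(n), rev(seq_len(n))[seq_len(min(r, n))])
  while (length(idx) < n + 2 * r) idx <- c(idx[1], idx, idx[length(idx)])
  pad <- switch(axis,
    v[idx, , , drop = FALSE],
    v[, idx, , drop = FALSE],
    v[, , idx, drop = FALSE]
  )
  out <- array(0, d)
  for (j in seq_along(k)) {
    sl <- seq_len(n) + j - 1L
    shifted <- switch(axis,
      pad[sl, , , drop = FALSE],
      pad[, sl, , drop = FALSE],
      pad[, , sl, drop = FALSE]
    )
    out <- out + k[j] * shifted
  }
  out
}

#' Downsample a volume by a factor of two per axis
#'
#' Each output voxel is the mean of its 2x2x2 input block; at the far edge
#' of an odd-sized axis the partial block is averaged over the voxels that
#' exist. Output dimension along each axis is `ceiling(dim / 2)`.
#'
#' @param v 3D numeric array, every dimension >= 2.
#' @return Downsampled 3D array.
#' @export
downsample_half <- function(v) {
  if (!is.array(v) || length(dim(v)) != 3) stop("v must be a 3D array")
  d <- dim(v)
  if (any(d < 2)) stop("every dimension must be >= 2")
  groups <- lapply(d, function(n) ceiling(seq_len(n) / 2))
  counts <- lapply(groups, tabulate)
  s <- v
  for (axis in 1:3) {
    dd <- dim(s)
    perm <- c(axis, setdiff(1:3, axis))
    m <- matrix(aperm(s, perm), dd[axis], prod(dd[-axis]))
    agg <- rowsum(m, group = groups[[axis]], reorder = TRUE)
    s <- aperm(array(agg, c(nrow(agg), dd[perm[2]], dd[perm[3]])), order(perm))
  }
  denom <- outer(outer(counts[[1]], counts[[2]]), counts[[3]])
  s / denom
}

#' Group mask from a set of aligned volumes
#'
#' A voxel is retained when the fraction of volumes with a non-zero value at
#' that voxel is at least `min_fraction`. With the default 0.05 this is the
#' "non-zero in at least 5% of the subjects" rule; the complementary phrasing
#' "no activity across 95% of the subjects" removes exactly the voxels this
#' rule excludes.
#'
#' @param volumes List of 3D numeric arrays, all the same shape.
#' @param min_fraction Retention threshold in (0, 1].
#' @return Object of class `group_mask`: logical 3D array with attribute
#'   `n_retained`.
#' @export
build_group_mask <- function(volumes, min_fraction = 0.05) {
  if (length(volumes) == 0) stop("need at least one volume")
  if (min_fraction <= 0 || min_fraction > 1) stop("min_fraction must be in (0, 1]")
  d <- dim(volumes[[1]])
  if (length(d) != 3) stop("volumes must be 3D arrays")
  for (v in volumes) {
    if (!identical(dim(v), d)) stop("all volumes must share the same shape")
  }
  nz <- Reduce(`+`, lapply(volumes, function(v) (v != 0) * 1))
  mask <- (nz / length(volumes)) >= min_fraction
  structure(mask, n_retained = sum(mask), class = c("group_mask", class(mask)))
}

#' Flatten the retained voxels of a volume into a vector
#'
#' Extracts the voxels where `mask` is TRUE, in the array's native
#' column-major scan order, which is fixed and identical across volumes so
#' that component i of every flattened vector refers to the same voxel.
#'
#' @param v 3D numeric array.
#' @param mask Logical array of the same shape (e.g. a [build_group_mask()]).
#' @return Numeric vector of length `sum(mask)`.
#' @seealso [scatter_masked()] for the inverse embedding.
#' @export
flatten_masked <- function(v, mask) {
  if (!identical(dim(v), dim(mask))) stop("volume and mask shapes differ")
  as.numeric(v[which(mask)])
}

#' Scatter a flattened vector back into a volume
#'
#' Inverse of [flatten_masked()] on the retained voxels; excluded voxels are
#' set to `fill`.
#'
#' @param x Numeric vector, length `sum(mask)`.
#' @param mask Logical 3D array.
#' @param fill Value for voxels outside the mask.
#' @return 3D numeric array shaped like `mask`.
#' @export
scatter_masked <- function(x, mask, fill = 0) {
  if (length(x) != sum(mask)) stop("length(x) must equal sum(mask)")
  out <- array(fill, dim(mask))
  out[which(mask)] <- x
  out
}

#' Structural-volume preprocessing chain
#'
#' The canonical order for structural maps: smooth, then downsample by two,
#' then (given a mask built from the downsampled volumes) flatten. Provided
#' as a convenience wrapper; each step is exported individually.
#'
#' @param v 3D numeric array.
#' @param mask `group_mask` built on downsampled volumes, or NULL to return
#'   the downsampled volume itself.
#' @param diameter Smoothing FWHM in voxels.
#' @return Flattened numeric vector (or downsampled volume when `mask` is
#'   NULL).
#' @export
preprocess_volume <- function(v, mask = NULL, diameter = 3) {
  out <- downsample_half(smooth_volume(v, diameter))
  if (is.null(mask)) return(out)
  flatten_masked(out, mask)
}

#' Read a 3D volume from a NIfTI file
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @return 3D numeric array.
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) == 4 && dim(arr)[4] == 1) arr <- arr[, , , 1]
  if (length(dim(arr)) != 3) stop("expected a 3D volume: ", path)
  unclass(arr)
}

#' Write a volume (or a 0/1 mask) to a NIfTI file
#'
#' @param v 3D numeric or logical array.
#' @param path Destination `.nii`/`.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_volume <- function(v, path) {
  if (is.logical(v)) v <- array(as.numeric(v), dim(v))
  v <- array(as.numeric(v), dim(v))
  RNifti::writeNifti(RNifti::asNifti(v), path)
  invisible(path)
}
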