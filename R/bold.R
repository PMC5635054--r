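#' 4D BOLD time series
#'
#' @param data numeric 4D array, x * y * z * t.
#' @param voxel_size isotropic voxel edge, mm.
#' @param tr repetition time, s.
#' @param volume_onsets onset times, s; defaults to an arithmetic grid
#'   starting at 0 with step `tr`.
#' @param affine optional 4x4 spatial transform; defaults to a scaled
#'   identity built from `voxel_size`.
#' @return object of class `bold_series`.
#' @export
bold_series <- function(data, voxel_size, tr,
                        volume_onsets = seq(0, by = tr,
                                            length.out = dim(data)[4]),
                        affine = NULL) {
  stopifnot(length(dim(data)) == 4, dim(data)[4] >= 2, voxel_size > 0,
            tr > 0, length(volume_onsets) == dim(data)[4])
  if (is.null(affine)) {
    affine <- diag(c(voxel_size, voxel_size, voxel_size, 1))
  }
  structure(list(data = data, voxel_size = voxel_size, tr = tr,
                 volume_onsets = as.numeric(volume_onsets), affine = affine),
            class = "bold_series")
}

#' @export
print.bold_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<bold_series> %dx%dx%d voxels (%.1f mm) x %d volumes (TR %.1f s)\n",
              d[1], d[2], d[3], x$voxel_size, d[4], x$tr))
  invisible(x)
}

#' Write / read a BOLD series as NIfTI-1
#'
#' Voxel size and TR are carried in the header `pixdim`.
#'
#' @param bold a [bold_series()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path` invisibly (write); a [bold_series()] (read).
#' @export
write_bold_nifti <- function(bold, path) {
  img <- RNifti::asNifti(bold$data)
  RNifti::pixdim(img) <- c(rep(bold$voxel_size, 3), bold$tr)
  RNifti::pixunits(img) <- c("mm", "s")
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_bold_nifti
#' @export
read_bold_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  pd <- RNifti::pixdim(img)
  bold_series(array(as.numeric(img), dim(img)), voxel_size = pd[1],
              tr = if (length(pd) >= 4) pd[4] else 1)
}

#' Write / read a 3D map as NIfTI-1
#' @param map 3D numeric array.
#' @param voxel_size voxel edge, mm.
#' @param path file path.
#' @return `path` invisibly (write); 3D array (read).
#' @export
write_map_nifti <- function(map, voxel_size, path) {
  img <- RNifti::asNifti(map)
  RNifti::pixdim(img) <- rep(voxel_size, 3)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_map_nifti
#' @export
read_map_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  array(as.numeric(img), dim(img))
}

#' Drop initial saturation volumes
#'
#' @param bold a [bold_series()].
#' @param k number of initial volumes to remove (default 6).
#' @return a [bold_series()] with `k` fewer volumes; the onsets of the
#'   retained volumes keep their original acquisition times.
#' @export
drop_initial_volumes <- function(bold, k = 6) {
  stopifnot(inherits(bold, "bold_series"))
  nt <- dim(bold$data)[4]
  if (k >= nt) stop("cannot drop all volumes (k >= t)", call. = FALSE)
  if (k == 0) return(bold)
  bold_series(bold$data[, , , -(seq_len(k)), drop = FALSE],
              bold$voxel_size, bold$tr,
              volume_onsets = bold$volume_onsets[-(seq_len(k))],
              affine = bold$affine)
}

# 1D Gaussian smoothing matrix with nearest-edge replication
smoothing_matrix <- function(n, sigma_vox) {
  if (sigma_vox <= 0) return(diag(n))
  r <- ceiling(4 * sigma_vox)
  off <- (-r):r
  w <- exp(-off^2 / (2 * sigma_vox^2))
  w <- w / sum(w)
  S <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- pmin(pmax(i + off, 1L), n)       # replicate edges
    for (k in seq_along(j)) S[i, j[k]] <- S[i, j[k]] + w[k]
  }
  S
}

apply_along_axis1 <- function(arr4, S) {
  d <- dim(arr4)
  dim(arr4) <- c(d[1], prod(d[-1]))
  out <- S %*% arr4
  dim(out) <- d
  out
}

#' Spatial Gaussian smoothing
#'
#' Separable per-volume 3D Gaussian convolution with
#' `sigma = fwhm / (2 sqrt(2 ln 2))` per axis (in voxels via the header
#' voxel size), nearest-edge replication at the boundary.
#'
#' @param bold a [bold_series()].
#' @param fwhm_mm kernel full width at half maximum, mm (default 8).
#' @return the smoothed [bold_series()].
#' @export
gaussian_smooth <- function(bold, fwhm_mm = 8) {
  stopifnot(inherits(bold, "bold_series"))
  if (fwhm_mm < 0) stop("fwhm must be >= 0", call. = FALSE)
  if (fwhm_mm == 0) return(bold)
  sigma_vox <- fwhm_mm / (2 * sqrt(2 * log(2))) / bold$voxel_size
  d <- dim(bold$data)
  x <- bold$data
  for (ax in 1:3) {
    S <- smoothing_matrix(d[ax], sigma_vox)
    perm <- c(ax, setdiff(1:4, ax))
    x <- aperm(apply_along_axis1(aperm(x, perm), S), order(perm))
  }
  bold_series(x, bold$voxel_size, bold$tr, bold$volume_onsets, bold$affine)
}

# orthonormal drift basis: constant + linear trend + DCT cosines with
# periods >= cutoff_s
dct_drift_basis <- function(n, tr, cutoff_s) {
  k <- floor(2 * n * tr / cutoff_s)
  t0 <- 0:(n - 1)
  B <- cbind(rep(1, n), t0 - mean(t0))
  if (k >= 1) {
    C <- vapply(seq_len(k), function(r)
      cos(pi * (2 * t0 + 1) * r / (2 * n)), numeric(n))
    B <- cbind(B, C)
  }
  q <- qr.Q(qr(B))
  attr(q, "n_drift") <- ncol(q) - 1L   # drift dims beyond the constant
  q
}

#' Temporal high-pass by discrete-cosine projection
#'
#' Removes the mean, a linear trend, and discrete cosine components with
#' periods at or above `cutoff_s` by orthogonal projection, so the filter
#' is exactly idempotent. The number of drift dimensions removed (beyond
#' the constant) is attached as attribute `n_drift` so GLM degrees of
#' freedom can be adjusted.
#'
#' @param x a [bold_series()], an [fmri_regressor()], or a numeric vector.
#' @param cutoff_s cutoff period, s (default 128).
#' @param tr sampling interval, s (taken from the object when available).
#' @return the filtered object, same type as the input.
#' @export
highpass_time <- function(x, cutoff_s = 128, tr = NULL) {
  if (inherits(x, "bold_series")) {
    n <- dim(x$data)[4]
    if (cutoff_s <= 2 * x$tr) stop("cutoff must exceed 2*tr", call. = FALSE)
    Q <- dct_drift_basis(n, x$tr, cutoff_s)
    d <- dim(x$data)
    mat <- matrix(x$data, prod(d[1:3]), n)
    mat <- mat - (mat %*% Q) %*% t(Q)
    out <- bold_series(array(mat, d), x$voxel_size, x$tr, x$volume_onsets,
                       x$affine)
    attr(out, "n_drift") <- attr(Q, "n_drift")
    return(out)
  }
  if (inherits(x, "fmri_regressor")) {
    stopifnot(!is.null(tr) || length(x$volume_onsets) > 1)
    tr <- if (is.null(tr)) diff(x$volume_onsets[1:2]) else tr
    v <- highpass_time(x$values, cutoff_s, tr)
    out <- fmri_regressor(as.numeric(v), x$label, x$volume_onsets)
    attr(out, "n_drift") <- attr(v, "n_drift")
    return(out)
  }
  stopifnot(is.numeric(x), !is.null(tr))
  n <- length(x)
  if (n < 3) stop("series shorter than 3 samples", call. = FALSE)
  if (cutoff_s <= 2 * tr) stop("cutoff must exceed 2*tr", call. = FALSE)
  Q <- dct_drift_basis(n, tr, cutoff_s)
  out <- as.numeric(x - Q %*% crossprod(Q, x))
  attr(out, "n_drift") <- attr(Q, "n_drift")
  out
}
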